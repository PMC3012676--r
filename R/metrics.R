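#' Compute Beta-values from channel intensities
#'
#' The Beta-value is the methylated probe intensity divided by the overall
#' intensity of the probe pair,
#' \deqn{\beta = \frac{\max(y_{meth}, 0)}{\max(y_{unmeth}, 0) +
#'   \max(y_{meth}, 0) + \alpha},}
#' with negative intensities reset to zero and a constant offset
#' \eqn{\alpha} (default 100) regularising sites where both channels are
#' dim. With \eqn{\alpha > 0} the result always lies in `[0, 1)` and is
#' interpretable as the approximate fraction of methylated molecules at
#' the CpG site.
#'
#' @param x a `meth_intensity` tibble (see [intensity_tbl()]).
#' @param alpha non-negative offset added to the denominator. With
#'   `alpha = 0` any site whose two clamped channels are both zero is a
#'   division by zero and raises an error.
#'
#' @return A `meth_values` tibble with `scale = "beta"`.
#' @seealso [compute_m()], [beta_to_m()]
#' @examples
#' x <- intensity_tbl("cg01", "A1", meth = 900, unmeth = 0)
#' compute_beta(x)$value  # 900 / (900 + 100) = 0.9
#' @export
compute_beta <- function(x, alpha = 100) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, !is.na(alpha))
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  meth <- pmax(x$meth, 0)
  unmeth <- pmax(x$unmeth, 0)
  denom <- meth + unmeth + alpha
  if (alpha == 0) {
    zero <- !is.na(denom) & denom == 0
    if (any(zero)) {
      off <- paste0(x$site_id[zero], "/", x$array_id[zero])
      stop("division by zero with alpha = 0 at: ",
           paste(utils::head(off, 5), collapse = ", "), call. = FALSE)
    }
  }
  new_methylation_tbl(
    tibble::tibble(site_id = x$site_id, array_id = x$array_id,
                   value = meth / denom),
    scale = "beta", alpha = alpha,
    site_ids = site_ids(x), array_ids = array_ids(x)
  )
}

#' Compute M-values from channel intensities
#'
#' The M-value is the log2 ratio of the (offset-adjusted, clamped)
#' methylated to unmethylated channel intensities,
#' \deqn{M = \log_2\frac{\max(y_{meth}, 0) + \alpha}
#'   {\max(y_{unmeth}, 0) + \alpha}.}
#' The offset \eqn{\alpha} (default 1) keeps both numerator and
#' denominator strictly positive, so every M-value is finite; it also
#' damps the large M swings that tiny intensity-estimation errors would
#' otherwise cause near zero. An M-value of 0 means the two channels have
#' similar intensity (a roughly half-methylated site); positive values
#' mean more methylated than unmethylated molecules.
#'
#' @param x a `meth_intensity` tibble.
#' @param alpha strictly positive offset added to both channels.
#' @return A `meth_values` tibble with `scale = "m"`.
#' @seealso [compute_beta()], [m_to_beta()]
#' @examples
#' x <- intensity_tbl("cg01", "A1", meth = 2047, unmeth = 1023)
#' compute_m(x)$value  # log2(2048 / 1024) = 1
#' @export
compute_m <- function(x, alpha = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, !is.na(alpha))
  if (alpha <= 0) {
    stop("alpha must be > 0: the offset is what guarantees finite M-values",
         call. = FALSE)
  }
  new_methylation_tbl(
    tibble::tibble(
      site_id = x$site_id, array_id = x$array_id,
      value = log2((pmax(x$meth, 0) + alpha) / (pmax(x$unmeth, 0) + alpha))
    ),
    scale = "m", alpha = alpha,
    site_ids = site_ids(x), array_ids = array_ids(x)
  )
}

#' Convert Beta-values to M-values (logit transform)
#'
#' In the high-intensity limit where the offsets are negligible the two
#' metrics are linked by a logistic (base-2 logit) relationship,
#' \deqn{M = \log_2\frac{\beta}{1 - \beta}.}
#' Beta-values of 0.2, 0.5 and 0.8 map to M-values of -2, 0 and 2. The
#' transform is undefined at exactly 0 or 1; since user-supplied Beta
#' tables can contain boundary values, inputs are clipped into
#' `[clip, 1 - clip]` first. Set `clip = NULL` to disable clipping, in
#' which case boundary values raise an error.
#'
#' @param beta numeric vector of Beta-values, or a `meth_values` tibble
#'   with `scale = "beta"`.
#' @param clip boundary clip `eps`, or `NULL` to forbid boundary values.
#' @return The same shape as the input, on the M scale.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2 0 2
#' @export
beta_to_m <- function(beta, clip = 1e-6) {
  if (inherits(beta, "meth_values")) {
    if (!identical(meth_scale(beta), "beta")) {
      stop("input table is not on the beta scale", call. = FALSE)
    }
    out <- beta
    out$value <- beta_to_m(beta$value, clip = clip)
    attr(out, "scale") <- "m"
    attr(out, "alpha_used") <- NA_real_
    return(out)
  }
  v <- as.numeric(beta)
  ok <- !is.na(v)
  if (any(ok & (v < 0 | v > 1))) {
    stop("Beta-values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(clip)) {
    if (any(ok & (v == 0 | v == 1))) {
      stop("Beta-value of exactly 0 or 1 maps to an infinite M-value; ",
           "set `clip` to a small epsilon to clamp boundary values",
           call. = FALSE)
    }
  } else {
    stopifnot(is.numeric(clip), length(clip) == 1L, clip > 0, clip < 0.5)
    v <- pmin(pmax(v, clip), 1 - clip)
  }
  # single log of the odds ratio: exact at the 0.2/0.5/0.8 anchors,
  # where the two rounding errors of v and 1 - v cancel in the quotient
  log2(v / (1 - v))
}

#' Convert M-values to Beta-values (inverse logit)
#'
#' Inverts [beta_to_m()]: \deqn{\beta = \frac{2^M}{2^M + 1},} always in
#' `(0, 1)`. Evaluated through the symmetric form `1 / (1 + 2^-M)` for
#' positive M so large magnitudes cannot overflow.
#'
#' @param m numeric vector of M-values, or a `meth_values` tibble with
#'   `scale = "m"`. Values must be finite.
#' @return The same shape as the input, on the Beta scale.
#' @examples
#' m_to_beta(c(-2, 0, 2))  # 0.2 0.5 0.8
#' @export
m_to_beta <- function(m) {
  if (inherits(m, "meth_values")) {
    if (!identical(meth_scale(m), "m")) {
      stop("input table is not on the m scale", call. = FALSE)
    }
    out <- m
    out$value <- m_to_beta(m$value)
    attr(out, "scale") <- "beta"
    attr(out, "alpha_used") <- NA_real_
    return(out)
  }
  v <- as.numeric(m)
  if (any(!is.na(v) & !is.finite(v))) {
    stop("M-values must be finite", call. = FALSE)
  }
  # branch on sign so 2^|M| never overflows for large |M|
  out <- ifelse(v >= 0, 1 / (1 + 2^(-v)), 2^v / (2^v + 1))
  out[is.na(v)] <- NA_real_
  out
}

#' Express an M-value difference as a non-log fold change
#'
#' An M-value difference is a log2 fold change of the methylated to
#' unmethylated intensity ratio; `2^d` puts it back on the non-log
#' scale. Difference thresholds of 0.4 and 1.4 on the M scale are fold
#' changes of about 1.32 and 2.64.
#'
#' @param m_diff numeric vector of M-value differences.
#' @return `2^m_diff`.
#' @examples
#' m_to_fold_change(c(0.4, 1.4))
#' @export
m_to_fold_change <- function(m_diff) 2^m_diff
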