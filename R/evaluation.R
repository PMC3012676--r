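#' Titration profile of a design
#'
#' The per-array vector of sample-A mixing fractions, in array order.
#' Technical replicates carry their mixture's fraction repeated, so the
#' profile has one entry per physical array, not per mixture.
#'
#' @param design a `titration_design`.
#' @return A named numeric vector (names = array ids).
#' @export
titration_profile <- function(design) {
  stats::setNames(design$fraction_a, design$array_id)
}

#' Correlation-defined true positives of a titration experiment
#'
#' A site with a genuine methylation difference between the two base
#' samples must track the mixing fractions: its methylation profile
#' across arrays is (noisily) affine in the sample-A fraction. A site
#' is therefore declared a True Positive when the absolute Pearson
#' correlation between its methylation profile and the titration profile
#' exceeds `r_threshold` on *both* metric scales (default; per-scale
#' sets are available via `scales` for sensitivity analysis). Sites with
#' zero variance on either scale are excluded (their correlation is
#' undefined).
#'
#' @param beta a `meth_values` tibble on the Beta scale.
#' @param m a `meth_values` tibble on the M scale, same sites/arrays.
#' @param design a `titration_design` covering the same arrays.
#' @param r_threshold absolute-correlation threshold (default 0.8).
#' @param scales which scales must individually pass: `"both"`
#'   (default), `"beta"`, or `"m"`.
#' @return A list of class `tp_set`: `site_ids` (the TP sites),
#'   `r_threshold`, `scales`, and `correlations` (tibble: `site_id`,
#'   `r_beta`, `r_m`, `is_tp`).
#' @export
define_true_positives <- function(beta, m, design, r_threshold = 0.8,
                                  scales = c("both", "beta", "m")) {
  scales <- match.arg(scales)
  stopifnot(identical(meth_scale(beta), "beta"),
            identical(meth_scale(m), "m"))
  if (!setequal(array_ids(beta), design$array_id) ||
      !setequal(array_ids(m), design$array_id)) {
    stop("design and methylation tables cover different arrays",
         call. = FALSE)
  }
  if (!setequal(site_ids(beta), site_ids(m))) {
    stop("beta and m tables cover different sites", call. = FALSE)
  }
  profile <- titration_profile(design)
  site_cor <- function(values) {
    mm <- values_matrix(values)[, names(profile), drop = FALSE]
    sds <- apply(mm, 1, stats::sd)
    r <- rep(NA_real_, nrow(mm))
    ok <- !is.na(sds) & sds > 0
    if (any(ok)) {
      r[ok] <- as.vector(stats::cor(t(mm[ok, , drop = FALSE]), profile))
    }
    stats::setNames(r, rownames(mm))
  }
  r_beta <- site_cor(beta)
  r_m <- site_cor(m)[names(r_beta)]
  pass_beta <- !is.na(r_beta) & abs(r_beta) > r_threshold
  pass_m <- !is.na(r_m) & abs(r_m) > r_threshold
  is_tp <- switch(scales,
    both = pass_beta & pass_m,
    beta = pass_beta,
    m = pass_m
  )
  correlations <- tibble::tibble(
    site_id = names(r_beta), r_beta = unname(r_beta),
    r_m = unname(r_m), is_tp = unname(is_tp)
  )
  structure(
    list(site_ids = correlations$site_id[is_tp],
         r_threshold = r_threshold, scales = scales,
         correlations = correlations),
    class = "tp_set"
  )
}

#' @export
print.tp_set <- function(x, ...) {
  cat("True-positive set: ", length(x$site_ids), " of ",
      nrow(x$correlations), " sites with |r| > ", x$r_threshold,
      " (scales: ", x$scales, ")\n", sep = "")
  invisible(x)
}

#' @rdname define_true_positives
#' @param x a `tp_set`.
#' @param ... unused.
#' @method tidy tp_set
#' @export
tidy.tp_set <- function(x, ...) x$correlations

#' @rdname define_true_positives
#' @method glance tp_set
#' @export
glance.tp_set <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x$correlations),
                 n_tp = length(x$site_ids),
                 r_threshold = x$r_threshold, scales = x$scales)
}

#' True positive rate of a detected set
#'
#' `TPR = |TP intersect detected| / |detected|`: the fraction of the
#' sites a method calls that are in the true-positive set.
#'
#' @param detected character vector of detected site ids.
#' @param tp a `tp_set` or a character vector of TP site ids.
#' @return A number in `[0, 1]`, or `NA` when nothing was detected
#'   (the rate is undefined, not zero).
#' @export
tpr <- function(detected, tp) {
  tp_ids <- if (inherits(tp, "tp_set")) tp$site_ids else tp
  if (length(detected) == 0) return(NA_real_)
  sum(detected %in% tp_ids) / length(detected)
}

#' Detection rate of a detected set
#'
#' `DR = |TP intersect detected| / |TP|`: the fraction of the
#' true-positive set a method recovers.
#'
#' @inheritParams tpr
#' @return A number in `[0, 1]`.
#' @export
dr <- function(detected, tp) {
  tp_ids <- if (inherits(tp, "tp_set")) tp$site_ids else tp
  if (length(tp_ids) == 0) {
    stop("true-positive set is empty; DR undefined", call. = FALSE)
  }
  sum(detected %in% tp_ids) / length(tp_ids)
}

#' Top-N performance curve
#'
#' Evaluates a ranked candidate list cumulatively: the top N sites form
#' the evaluation set, with N running from `step` in increments of
#' `step` plus a terminal point at the full list length. For each N the
#' TPR and DR against the true-positive set are recorded, along with
#' `one_minus_dr` for ROC-style (1 - DR) vs TPR plotting.
#'
#' @param ranked character vector of site ids, best first (e.g. from
#'   [select_candidates()]).
#' @param tp a `tp_set` or character vector of TP site ids.
#' @param step grid spacing for N (default 50).
#' @return An `eval_curve` tibble: `x` (= N), `n_detected`, `tpr`, `dr`,
#'   `one_minus_dr`; attribute `axis = "top_n"`.
#' @export
top_n_curve <- function(ranked, tp, step = 50) {
  if (length(ranked) == 0) stop("ranked list is empty", call. = FALSE)
  grid <- if (length(ranked) >= step) {
    seq.int(step, length(ranked), by = step)
  } else integer(0)
  grid <- unique(c(grid, length(ranked)))
  out <- purrr::map_dfr(grid, function(n) {
    det <- ranked[seq_len(n)]
    tibble::tibble(x = n, n_detected = n,
                   tpr = tpr(det, tp), dr = dr(det, tp))
  })
  out$one_minus_dr <- 1 - out$dr
  structure(out, axis = "top_n",
            class = c("eval_curve", class(out)))
}

#' Difference-threshold sweep
#'
#' For each threshold in `thresholds`, selects candidates with
#' `p < p_cutoff` and absolute methylation difference above the
#' threshold, and records the detected count, TPR and DR. When nothing
#' is detected the TPR is recorded as `NA` (undefined), not 0.
#'
#' @param result a `meth_diff` table from [diff_methylation()].
#' @param tp a `tp_set` or character vector of TP site ids.
#' @param thresholds non-decreasing numeric vector of difference
#'   thresholds (include 0 to anchor the sweep at the pure p-gate).
#' @param p_cutoff p-value gate (default 0.05).
#' @return An `eval_curve` tibble: `x` (= threshold), `n_detected`,
#'   `tpr`, `dr`; attribute `axis = "threshold"`.
#' @export
threshold_sweep <- function(result, tp, thresholds, p_cutoff = 0.05) {
  if (is.unsorted(thresholds)) {
    stop("thresholds must be non-decreasing", call. = FALSE)
  }
  out <- purrr::map_dfr(thresholds, function(th) {
    det <- select_candidates(result, p_cutoff = p_cutoff,
                             diff_threshold = th)
    tibble::tibble(x = th, n_detected = length(det),
                   tpr = tpr(det, tp), dr = dr(det, tp))
  })
  structure(out, axis = "threshold",
            class = c("eval_curve", class(out)))
}

#' Suggest a difference-threshold range from a sweep
#'
#' Operationalises the visual "turning point" reading of a threshold
#' sweep. DR starts on a plateau and eventually falls: the *lower*
#' suggested threshold is the largest threshold at which DR is still
#' within `plateau_tolerance` (relative) of its value at the smallest
#' threshold -- raising the threshold up to there buys TPR without
#' giving up detection. TPR rises and then plateaus: the *upper*
#' suggested threshold is the smallest threshold at which TPR reaches
#' `(1 - plateau_tolerance) * max(TPR)` -- beyond it, further
#' thresholding no longer improves TPR much.
#'
#' @param curve an `eval_curve` with `axis = "threshold"`.
#' @param plateau_tolerance relative plateau tolerance (default 0.02).
#' @return A one-row tibble: `lower`, `upper`, `plateau_tolerance`,
#'   `flagged` (TRUE with a warning when `upper < lower`, which only
#'   happens for pathological non-monotone curves).
#' @export
suggest_thresholds <- function(curve, plateau_tolerance = 0.02) {
  if (!identical(attr(curve, "axis", exact = TRUE), "threshold")) {
    stop("need a threshold-axis curve", call. = FALSE)
  }
  if (nrow(curve) < 3) stop("need at least 3 sweep points", call. = FALSE)
  dr0 <- curve$dr[1]
  on_dr_plateau <- !is.na(curve$dr) &
    curve$dr >= (1 - plateau_tolerance) * dr0
  lower <- max(curve$x[on_dr_plateau])
  tpr_max <- max(curve$tpr, na.rm = TRUE)
  at_tpr_plateau <- !is.na(curve$tpr) &
    curve$tpr >= (1 - plateau_tolerance) * tpr_max
  upper <- min(curve$x[at_tpr_plateau])
  flagged <- upper < lower
  if (flagged) {
    warning("suggested upper threshold (", upper,
            ") is below the lower threshold (", lower,
            "); the sweep is not the expected plateau shape",
            call. = FALSE)
  }
  tibble::tibble(lower = lower, upper = upper,
                 plateau_tolerance = plateau_tolerance,
                 flagged = flagged)
}

#' Plot an evaluation curve
#'
#' Top-N curves are drawn ROC-style as TPR against 1 - DR (ideal
#' performance in the top-left corner); threshold sweeps as TPR and DR
#' against the difference threshold.
#'
#' @param object an `eval_curve` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eval_curve
#' @export
autoplot.eval_curve <- function(object, ...) {
  if (identical(attr(object, "axis", exact = TRUE), "top_n")) {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$one_minus_dr, y = .data$tpr)) +
      ggplot2::geom_path() + ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "1 - Detection Rate", y = "True Positive Rate")
  } else {
    long <- tidyr::pivot_longer(
      tibble::as_tibble(object)[c("x", "tpr", "dr")],
      c("tpr", "dr"), names_to = "metric", values_to = "rate"
    )
    ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$rate,
                                       colour = .data$metric)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "difference threshold", y = "rate")
  }
}

#' Write an evaluation curve as TSV
#' @param curve an `eval_curve` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  out <- tibble::tibble(
    x = fmt_num(curve$x), n_detected = curve$n_detected,
    TPR = fmt_num(curve$tpr), DR = fmt_num(curve$dr)
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
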