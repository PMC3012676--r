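#' Build an intensity table
#'
#' The package's central input container: a long tibble with one row per
#' (CpG site, array) pair carrying the methylated and unmethylated channel
#' intensities and the Illumina detection p-value. Intensities may be
#' negative (background adjustment can over-correct); the metric functions
#' clamp negatives to zero at compute time rather than at ingest.
#'
#' @param site_id character vector of CpG site identifiers.
#' @param array_id character vector of array identifiers.
#' @param meth,unmeth numeric fluorescence intensities for the methylated
#'   and unmethylated probe of each pair.
#' @param detection_p detection p-values in `[0, 1]`; large values mean the
#'   probe signal is indistinguishable from background.
#'
#' @return A tibble of class `meth_intensity` with columns `site_id`,
#'   `array_id`, `meth`, `unmeth`, `detection_p`. Site and array order are
#'   recorded in the `site_ids` / `array_ids` attributes.
#' @examples
#' intensity_tbl(
#'   site_id = rep(c("cg01", "cg02"), each = 2),
#'   array_id = rep(c("A1", "A2"), 2),
#'   meth = c(900, 880, 30, 25),
#'   unmeth = c(100, 120, 950, 940),
#'   detection_p = 1e-6
#' )
#' @export
intensity_tbl <- function(site_id, array_id, meth, unmeth,
                          detection_p = 0) {
  x <- tibble::tibble(
    site_id = as.character(site_id),
    array_id = as.character(array_id),
    meth = as.numeric(meth),
    unmeth = as.numeric(unmeth),
    detection_p = as.numeric(detection_p)
  )
  new_intensity_tbl(x)
}

new_intensity_tbl <- function(x, site_ids = NULL, array_ids = NULL) {
  stopifnot(all(c("site_id", "array_id", "meth", "unmeth",
                  "detection_p") %in% names(x)))
  bad_p <- !is.na(x$detection_p) &
    (x$detection_p < 0 | x$detection_p > 1)
  if (any(bad_p)) {
    stop("detection_p must lie in [0, 1]; offending site(s): ",
         paste(utils::head(unique(x$site_id[bad_p]), 5), collapse = ", "),
         call. = FALSE)
  }
  site_ids <- site_ids %||% unique(x$site_id)
  array_ids <- array_ids %||% unique(x$array_id)
  structure(
    tibble::as_tibble(x),
    site_ids = site_ids,
    array_ids = array_ids,
    class = c("meth_intensity", class(tibble::tibble()))
  )
}

#' Build a methylation-value table
#'
#' Holds per-(site, array) methylation measurements on a declared scale:
#' `"beta"` (methylated fraction in `[0, 1)`) or `"m"` (log2 ratio of the
#' channels, unbounded). The scale and the offset used to compute the
#' values are carried as attributes so downstream reports are
#' self-describing.
#'
#' @param x a data frame with columns `site_id`, `array_id`, `value`.
#' @param scale `"beta"` or `"m"`.
#' @param alpha non-negative offset used when the values were computed
#'   from intensities (`NA` if the values were supplied directly).
#'
#' @return A tibble of class `meth_values`.
#' @export
methylation_tbl <- function(x, scale = c("beta", "m"), alpha = NA_real_) {
  scale <- match.arg(scale)
  stopifnot(all(c("site_id", "array_id", "value") %in% names(x)))
  new_methylation_tbl(tibble::as_tibble(x), scale = scale, alpha = alpha)
}

new_methylation_tbl <- function(x, scale, alpha,
                                site_ids = NULL, array_ids = NULL) {
  structure(
    tibble::as_tibble(x[c("site_id", "array_id", "value")]),
    scale = scale,
    alpha_used = alpha,
    site_ids = site_ids %||% unique(x$site_id),
    array_ids = array_ids %||% unique(x$array_id),
    class = c("meth_values", class(tibble::tibble()))
  )
}

#' Scale of a methylation table
#' @param x a `meth_values` tibble.
#' @return `"beta"` or `"m"`.
#' @export
meth_scale <- function(x) attr(x, "scale", exact = TRUE)

#' Offset recorded in a methylation table
#' @param x a `meth_values` tibble.
#' @return the offset `alpha` used to compute the values, or `NA`.
#' @export
alpha_used <- function(x) attr(x, "alpha_used", exact = TRUE)

#' Array identifiers in container order
#' @param x a `meth_intensity` or `meth_values` tibble.
#' @return character vector of array ids.
#' @export
array_ids <- function(x) attr(x, "array_ids", exact = TRUE)

#' Site identifiers in container order
#' @param x a `meth_intensity` or `meth_values` tibble.
#' @return character vector of site ids.
#' @export
site_ids <- function(x) attr(x, "site_ids", exact = TRUE)

# site x array matrix view of a long table; rows/cols follow recorded order
values_matrix <- function(x, col = "value") {
  sids <- site_ids(x)
  aids <- array_ids(x)
  m <- matrix(NA_real_, nrow = length(sids), ncol = length(aids),
              dimnames = list(sids, aids))
  m[cbind(match(x$site_id, sids), match(x$array_id, aids))] <- x[[col]]
  m
}

matrix_to_long <- function(m) {
  tibble::tibble(
    site_id = rep(rownames(m), times = ncol(m)),
    array_id = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.meth_intensity <- function(x, ...) {
  cat("# Intensity table: ", length(site_ids(x)), " sites x ",
      length(array_ids(x)), " arrays\n", sep = "")
  NextMethod()
}

#' @export
print.meth_values <- function(x, ...) {
  cat("# Methylation values (scale = ", meth_scale(x),
      ", alpha = ", format(alpha_used(x)), "): ",
      length(site_ids(x)), " sites x ", length(array_ids(x)),
      " arrays\n", sep = "")
  NextMethod()
}
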