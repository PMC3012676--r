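#' Filter sites by detection p-value
#'
#' Removes CpG sites whose probe signal is unreliable across the
#' experiment: a site is dropped when the fraction of arrays with a
#' detection p-value worse (larger) than `p_threshold` exceeds
#' `sample_fraction`. Both comparisons are strict, so a site failing on
#' exactly half its arrays is kept at the default `sample_fraction = 0.5`.
#'
#' @param x a `meth_intensity` tibble.
#' @param p_threshold detection p-value above which an array's measurement
#'   counts as failed (default 1e-4).
#' @param sample_fraction fraction of failed arrays above which the site
#'   is removed (default 0.5).
#' @return The filtered `meth_intensity` tibble, with a `filter_report`
#'   attribute (retrieve it with [filter_report()]).
#' @examples
#' x <- intensity_tbl(
#'   site_id = rep(c("cg01", "cg02"), each = 2),
#'   array_id = rep(c("A1", "A2"), 2),
#'   meth = 100, unmeth = 100,
#'   detection_p = c(1e-6, 1e-6, 0.5, 0.5)
#' )
#' filter_report(detection_filter(x))
#' @export
detection_filter <- function(x, p_threshold = 1e-4, sample_fraction = 0.5) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            sample_fraction > 0, sample_fraction < 1)
  sids <- site_ids(x)
  fail <- x |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      frac_failed = mean(.data$detection_p > p_threshold, na.rm = TRUE),
      .groups = "drop"
    )
  removed <- fail$site_id[fail$frac_failed > sample_fraction]
  removed <- sids[sids %in% removed]  # preserve container order
  out <- new_intensity_tbl(
    x[!(x$site_id %in% removed), , drop = FALSE],
    site_ids = setdiff(sids, removed),
    array_ids = array_ids(x)
  )
  attr(out, "filter_report") <- tibble::tibble(
    n_sites_in = length(sids),
    n_sites_removed = length(removed),
    removed_site_ids = list(removed),
    rule = sprintf(
      "removed sites with > %g of arrays having detection_p > %g",
      sample_fraction, p_threshold
    )
  )
  out
}

#' Retrieve the report attached by [detection_filter()]
#' @param x a filtered `meth_intensity` tibble.
#' @return A one-row tibble: sites in, sites removed, removed ids (as a
#'   list column), and a text description of the rule applied.
#' @export
filter_report <- function(x) attr(x, "filter_report", exact = TRUE)

#' Simple scaling normalization (SSN)
#'
#' Rescales each array so that its mean probe intensity (methylated and
#' unmethylated channels pooled, negatives clamped to zero) equals the
#' grand mean of those per-array means. One common factor per array
#' multiplies both channels, so within-array meth/unmeth ratios -- and
#' hence M-values at zero offset -- are untouched; only the absolute
#' intensity level is harmonised across arrays.
#'
#' @param x a `meth_intensity` tibble.
#' @return A `meth_intensity` tibble with rescaled channels and a
#'   `scale_factors` attribute (named numeric, one factor per array).
#' @export
scaling_normalize <- function(x) {
  aids <- array_ids(x)
  if (length(aids) < 1) stop("no arrays to normalize", call. = FALSE)
  per_array <- x |>
    dplyr::group_by(.data$array_id) |>
    dplyr::summarise(
      pooled_mean = mean(c(pmax(.data$meth, 0), pmax(.data$unmeth, 0)),
                         na.rm = TRUE),
      .groups = "drop"
    )
  if (any(per_array$pooled_mean == 0)) {
    stop("array(s) with zero pooled mean intensity: ",
         paste(per_array$array_id[per_array$pooled_mean == 0],
               collapse = ", "), call. = FALSE)
  }
  target <- mean(per_array$pooled_mean)
  factors <- stats::setNames(target / per_array$pooled_mean,
                             per_array$array_id)
  out <- x
  f <- unname(factors[out$array_id])
  out$meth <- out$meth * f
  out$unmeth <- out$unmeth * f
  out <- new_intensity_tbl(out, site_ids = site_ids(x), array_ids = aids)
  attr(out, "scale_factors") <- factors[aids]
  out
}

#' Write a detection-filter report
#'
#' Removed site ids go to a TSV (one per line); the summary (counts and
#' rule) to a JSON sidecar `<path>.json`.
#'
#' @param report a report tibble from [filter_report()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  readr::write_tsv(
    tibble::tibble(site_id = report$removed_site_ids[[1]]),
    path, progress = FALSE
  )
  jsonlite::write_json(
    list(n_sites_in = report$n_sites_in,
         n_sites_removed = report$n_sites_removed,
         rule = report$rule),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}
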