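#' Per-site mean and standard deviation over technical replicates
#'
#' For each CpG site, summarises the spread of a methylation metric over
#' technical replicates. Within each replicate group the per-site mean and
#' sample (n-1) standard deviation are computed; groups are then pooled:
#' the pooled SD is the degrees-of-freedom-weighted root mean square of
#' the within-group SDs, and the pooled mean is the unweighted mean of the
#' group means. Sites missing a value in a group are excluded from that
#' group only. Groups with fewer than two arrays are ignored.
#'
#' @param values a `meth_values` tibble.
#' @param replicate_groups a named list of character vectors partitioning
#'   (a subset of) the array ids into technical-replicate groups, e.g.
#'   `list(Mix1 = c("Array1", "Array2"), Mix5 = c("Array7", "Array8"))`.
#' @return A tibble with columns `site_id`, `mean`, `sd`.
#' @seealso [bin_mean_sd()]
#' @export
replicate_mean_sd <- function(values, replicate_groups) {
  groups <- purrr::keep(replicate_groups, ~ length(.x) >= 2)
  if (length(groups) == 0) {
    stop("no replicate group with >= 2 arrays", call. = FALSE)
  }
  unknown <- setdiff(unlist(groups), array_ids(values))
  if (length(unknown) > 0) {
    stop("unknown array id(s) in replicate_groups: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  per_group <- purrr::imap_dfr(groups, function(arr, nm) {
    values |>
      dplyr::filter(.data$array_id %in% arr, !is.na(.data$value)) |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(
        g_mean = mean(.data$value),
        g_var = stats::var(.data$value),
        g_df = dplyr::n() - 1L,
        .groups = "drop"
      ) |>
      dplyr::filter(.data$g_df >= 1L)
  })
  per_group |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      mean = mean(.data$g_mean),
      sd = sqrt(sum(.data$g_df * .data$g_var) / sum(.data$g_df)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$site_id, site_ids(values)))
}

#' Bin per-site (mean, SD) pairs by mean rank
#'
#' Ranks sites by their mean methylation level and splits them into
#' `n_bins` contiguous, non-overlapping blocks of near-equal occupancy
#' (each holding ~1/`n_bins` of the data; with 20 bins, 5% per bin). The
#' median SD per bin traces how measurement noise depends on the mean --
#' the standard visual check for heteroscedasticity. Because binning uses
#' ranks, any strictly increasing transform of the means (e.g. Beta to
#' its logit) yields the identical site-to-bin assignment.
#'
#' @param pairs a tibble with columns `site_id`, `mean`, `sd`, as from
#'   [replicate_mean_sd()].
#' @param n_bins number of bins (default 20).
#' @return A tibble of class `mean_sd_bins`: `bin_index`, `mean_low`,
#'   `mean_high`, `n_sites`, `median_sd`, with the input pairs (plus
#'   their bin assignment) in the `pairs` attribute.
#' @export
bin_mean_sd <- function(pairs, n_bins = 20) {
  stopifnot(all(c("site_id", "mean", "sd") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < n_bins) {
    stop("need at least as many sites (", n, ") as bins (", n_bins, ")",
         call. = FALSE)
  }
  ranked <- pairs[order(pairs$mean, pairs$site_id), ]
  # earlier bins take the extra sites when n is not divisible by n_bins
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  ranked$bin_index <- rep(seq_len(n_bins), times = sizes)
  out <- ranked |>
    dplyr::group_by(.data$bin_index) |>
    dplyr::summarise(
      mean_low = min(.data$mean),
      mean_high = max(.data$mean),
      n_sites = dplyr::n(),
      median_sd = stats::median(.data$sd),
      .groups = "drop"
    )
  structure(out, pairs = ranked,
            class = c("mean_sd_bins", class(out)))
}

#' Histogram summary with a descriptive bimodality indicator
#'
#' Bins all non-missing values of a methylation table and counts local
#' maxima of the bin counts after a 3-bin moving-average smooth. Two
#' modes with one on each side of zero is the signature of an M-value
#' distribution (a methylated and an unmethylated mode); on the Beta
#' scale the same biology shows up as modes near 0 and 1, visually
#' compressed. The mode count is a descriptive device, not a formal
#' multimodality test.
#'
#' @param values a `meth_values` tibble.
#' @param n_breaks number of histogram cells (default 50).
#' @param min_prominence a local maximum counts as a mode only when its
#'   smoothed height reaches this fraction of the tallest smoothed cell
#'   (default 0.05), which keeps sampling jitter in thin tails from
#'   registering as modes.
#' @return A list of class `meth_histogram`: `table` (tibble `mid`,
#'   `count`), `n_modes`, `mode_positions` (bin mids of the modes,
#'   largest count first), `mode_signs` (for the two largest modes),
#'   `scale`.
#' @export
histogram_summary <- function(values, n_breaks = 50,
                              min_prominence = 0.05) {
  v <- values$value[!is.na(values$value)]
  if (length(unique(v)) < 2) {
    stop("need at least two distinct values", call. = FALSE)
  }
  breaks <- seq(min(v), max(v), length.out = n_breaks + 1)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_breaks)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(counts[1:2])
  sm[n_breaks] <- mean(counts[(n_breaks - 1):n_breaks])
  sm <- as.numeric(sm)
  floor_height <- min_prominence * max(sm)
  is_max <- vapply(seq_len(n_breaks), function(i) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < n_breaks) sm[i + 1] else -Inf
    sm[i] > left && sm[i] >= right && sm[i] >= floor_height
  }, logical(1))
  modes <- mids[is_max][order(sm[is_max], decreasing = TRUE)]
  structure(
    list(
      table = tibble::tibble(mid = mids, count = counts),
      n_modes = sum(is_max),
      mode_positions = modes,
      mode_signs = sign(utils::head(modes, 2)),
      scale = meth_scale(values)
    ),
    class = "meth_histogram"
  )
}

#' @export
print.meth_histogram <- function(x, ...) {
  cat("Histogram summary (scale = ", x$scale, "): ",
      sum(x$table$count), " values, ", nrow(x$table), " cells, ",
      x$n_modes, " mode(s)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname bin_mean_sd
#' @param x a `mean_sd_bins` object.
#' @param ... unused.
#' @method tidy mean_sd_bins
#' @export
tidy.mean_sd_bins <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("bin_index", "mean_low", "mean_high",
                                 "n_sites", "median_sd")])
}

#' @rdname bin_mean_sd
#' @method glance mean_sd_bins
#' @export
glance.mean_sd_bins <- function(x, ...) {
  med <- x$median_sd
  n_bins <- nrow(x)
  extreme <- c(1, n_bins)
  middle <- setdiff(seq_len(n_bins), c(1:2, (n_bins - 1):n_bins))
  tibble::tibble(
    n_bins = n_bins,
    n_sites = sum(x$n_sites),
    extreme_to_middle_ratio = max(med[extreme]) / stats::median(med[middle]),
    max_to_min_ratio = max(med) / min(med)
  )
}

#' Plot a mean-SD relation
#'
#' Per-site (mean, SD) scatter with the per-bin median SD overlaid in
#' red -- flat medians indicate homoscedasticity, a hump collapsing at
#' the extremes indicates the Beta-value's variance compression.
#'
#' @param object a `mean_sd_bins` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mean_sd_bins
#' @export
autoplot.mean_sd_bins <- function(object, ...) {
  pairs <- attr(object, "pairs", exact = TRUE)
  bins <- tidy(object)
  bins$mid <- (bins$mean_low + bins$mean_high) / 2
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean, y = .data$sd)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_point(
      data = bins,
      ggplot2::aes(x = .data$mid, y = .data$median_sd),
      colour = "red", size = 2
    ) +
    ggplot2::labs(x = "mean methylation level",
                  y = "standard deviation (technical replicates)")
}

#' Plot a histogram summary
#' @param object a `meth_histogram` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot meth_histogram
#' @export
autoplot.meth_histogram <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$table$mid[1:2])) +
    ggplot2::labs(x = paste0(object$scale, "-value"), y = "count")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
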