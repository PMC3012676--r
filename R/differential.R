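#' Welch's two-sample t-test, per CpG site
#'
#' Unequal-variance two-sample t-test of group A versus group B at every
#' site, with Welch-Satterthwaite degrees of freedom and a two-sided
#' p-value. Sites where either group has fewer than two non-missing
#' values get `NA` results. The degenerate case of zero variance in both
#' groups is defined by continuity: `p = 1` when the group means are also
#' equal, and `p = 0` (flagged with a warning) when they differ -- the
#' zero-noise limit of the test rather than a silent drop.
#'
#' Vectorised over sites; `stats::t.test()` gives identical numbers
#' site-by-site and is used as the reference in the package's tests.
#'
#' @param values a `meth_values` tibble.
#' @param group_a,group_b character vectors of array ids (each of length
#'   >= 2) defining the two groups.
#' @return A tibble: `site_id`, `mean_a`, `mean_b`, `t_statistic`, `df`,
#'   `p_value`, `degenerate` (logical: both variances zero).
#' @export
welch_test <- function(values, group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 arrays", call. = FALSE)
  }
  unknown <- setdiff(c(group_a, group_b), array_ids(values))
  if (length(unknown) > 0) {
    stop("unknown array id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  m <- values_matrix(values)
  summarize_group <- function(g) {
    sub <- m[, g, drop = FALSE]
    n <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    v <- rowSums((sub - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, mean = mu, var = v)
  }
  a <- summarize_group(group_a)
  b <- summarize_group(group_b)
  ok <- a$n >= 2 & b$n >= 2
  se2 <- a$var / a$n + b$var / b$n
  t_stat <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- ok & se2 == 0
  equal_means <- abs(a$mean - b$mean) < .Machine$double.eps^0.5
  t_stat[degenerate & equal_means] <- 0
  p[degenerate & equal_means] <- 1
  if (any(degenerate & !equal_means)) {
    warning(sum(degenerate & !equal_means),
            " site(s) with zero variance in both groups but unequal ",
            "means; p set to the zero-noise limit 0", call. = FALSE)
    t_stat[degenerate & !equal_means] <-
      sign(a$mean - b$mean)[degenerate & !equal_means] * Inf
    p[degenerate & !equal_means] <- 0
  }
  df[degenerate] <- NA_real_
  t_stat[!ok] <- NA_real_
  p[!ok] <- NA_real_
  tibble::tibble(
    site_id = rownames(m),
    mean_a = unname(a$mean), mean_b = unname(b$mean),
    t_statistic = unname(t_stat), df = unname(df),
    p_value = unname(p), degenerate = unname(degenerate)
  )
}

#' Assign sites to low / middle / high methylation range groups
#'
#' The logit relationship between the two metrics is approximately linear
#' only in its middle range, so performance is analysed separately in
#' three groups determined by a site's mean methylation level over the
#' compared arrays. Boundaries (middle interval closed):
#' * Beta scale: low `(0, 0.2)`, middle `[0.2, 0.8]`, high `(0.8, 1)`.
#' * M scale: low `(-Inf, -2)`, middle `[-2, 2]`, high `(2, Inf)`.
#'
#' @param site_means numeric vector of per-site mean methylation values.
#' @param scale `"beta"` or `"m"`.
#' @return A factor with levels `low`, `middle`, `high`.
#' @export
assign_range_group <- function(site_means, scale = c("beta", "m")) {
  scale <- match.arg(scale)
  bounds <- switch(scale, beta = c(0.2, 0.8), m = c(-2, 2))
  out <- dplyr::case_when(
    is.na(site_means) ~ NA_character_,
    site_means < bounds[1] ~ "low",
    site_means > bounds[2] ~ "high",
    TRUE ~ "middle"
  )
  factor(out, levels = c("low", "middle", "high"))
}

#' Differential methylation between two array groups
#'
#' Runs [welch_test()] on the chosen metric scale, computes the absolute
#' methylation difference `|mean_A - mean_B|` per site, and assigns each
#' site's low/middle/high range group from its mean over the compared
#' arrays. This is the per-site table that [select_candidates()] and the
#' titration evaluation consume.
#'
#' @inheritParams welch_test
#' @return A tibble of class `meth_diff`: `site_id`, `mean_a`, `mean_b`,
#'   `abs_diff`, `t_statistic`, `p_value`, `range_group`; the scale and
#'   groups are recorded as attributes.
#' @export
diff_methylation <- function(values, group_a, group_b) {
  wt <- welch_test(values, group_a, group_b)
  overall <- values |>
    dplyr::filter(.data$array_id %in% c(group_a, group_b)) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(site_mean = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  out <- wt |>
    dplyr::left_join(overall, by = "site_id") |>
    dplyr::mutate(
      abs_diff = abs(.data$mean_a - .data$mean_b),
      range_group = assign_range_group(.data$site_mean,
                                       meth_scale(values))
    ) |>
    dplyr::select("site_id", "mean_a", "mean_b", "abs_diff",
                  "t_statistic", "p_value", "range_group")
  structure(out,
            scale = meth_scale(values),
            group_a = group_a, group_b = group_b,
            class = c("meth_diff", class(out)))
}

#' @rdname diff_methylation
#' @param x a `meth_diff` table.
#' @param ... unused.
#' @method glance meth_diff
#' @export
glance.meth_diff <- function(x, ...) {
  tibble::tibble(
    scale = attr(x, "scale", exact = TRUE),
    n_sites = nrow(x),
    n_p_lt_0.05 = sum(x$p_value < 0.05, na.rm = TRUE),
    n_low = sum(x$range_group == "low", na.rm = TRUE),
    n_middle = sum(x$range_group == "middle", na.rm = TRUE),
    n_high = sum(x$range_group == "high", na.rm = TRUE)
  )
}

#' Select and rank candidate differentially methylated sites
#'
#' Applies the "difference-ranking with a non-stringent p-value cutoff"
#' paradigm: keep sites with `p_value < p_cutoff` (strict) and
#' `abs_diff > diff_threshold` (strict), then sort by absolute
#' methylation difference, largest first. Ties are broken by `site_id`
#' so the ranking is deterministic.
#'
#' @param result a `meth_diff` table from [diff_methylation()].
#' @param p_cutoff p-value gate (default 0.05).
#' @param diff_threshold minimum absolute methylation difference
#'   (default 0, i.e. the pure p-value gate).
#' @return A character vector of site ids, ranked.
#' @export
select_candidates <- function(result, p_cutoff = 0.05,
                              diff_threshold = 0) {
  keep <- !is.na(result$p_value) & result$p_value < p_cutoff &
    result$abs_diff > diff_threshold
  sel <- result[keep, ]
  sel$site_id[order(-sel$abs_diff, sel$site_id)]
}

#' Write a differential-methylation table as TSV
#' @param result a `meth_diff` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(result, path) {
  out <- tibble::tibble(
    TargetID = result$site_id,
    mean_A = fmt_num(result$mean_a),
    mean_B = fmt_num(result$mean_b),
    abs_diff = fmt_num(result$abs_diff),
    t = fmt_num(result$t_statistic),
    p = fmt_num(result$p_value),
    range_group = as.character(result$range_group)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
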