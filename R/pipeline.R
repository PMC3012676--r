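#' Configuration-driven pipeline runs
#'
#' Each `run_*()` function ties package stages into one reproducible run:
#' it resolves a configuration list against defaults, executes the
#' stage, writes its outputs as TSV into `out_dir`, and drops a
#' fully-resolved `config.json` (seed, package version and timestamp
#' included) alongside them so any output can be regenerated. These are
#' the functions behind the `inst/cli/methylmetrics.R` command-line
#' front-end; identical configs and seeds produce byte-identical TSVs.
#'
#' @param config a named list of parameters; unknown names are rejected.
#'   See each function's defaults in the implementation: `run_simulate`
#'   accepts the [simulate_titration()] parameters; `run_convert` takes
#'   `input` (an intensity or methylation TSV), `to` (`"beta"` or
#'   `"m"`), `alpha_beta`, `alpha_m`; `run_diagnose` takes `input`,
#'   `p_threshold`, `sample_fraction`, `n_bins`, `n_breaks`,
#'   `replicate_groups`; `run_evaluate` takes `input`, `design`
#'   (data frame or TSV path with columns array_id, fraction_a,
#'   mix_label), `groups_a`, `groups_b`, `r_threshold`, `p_cutoff`,
#'   `step`, `beta_thresholds`, `m_thresholds`.
#' @param out_dir output directory (created if missing).
#' @return A named list of written file paths, invisibly.
#' @name pipeline
NULL

resolve_config <- function(config, defaults, required = character()) {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, config)
  missing <- required[vapply(out[required], is.null, logical(1))]
  if (length(missing) > 0) {
    stop("missing required config field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

write_run_config <- function(config, out_dir) {
  config$tool_version <- as.character(utils::packageVersion("methylmetrics"))
  config$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  path
}

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
}

#' @rdname pipeline
#' @export
run_simulate <- function(config = list(), out_dir) {
  cfg <- resolve_config(config, list(
    n_sites = 27578L, diff_fraction = 0.3, gamma_shape = 16,
    mean_total_intensity = 3000, replicate_cv = 0.05,
    site_intensity_cv = 0.3, mixture_weights = c(0.4, 0.4, 0.2),
    seed = 1L
  ))
  ensure_out_dir(out_dir)
  sim <- simulate_titration(
    n_sites = cfg$n_sites, design = default_design(),
    diff_fraction = cfg$diff_fraction, gamma_shape = cfg$gamma_shape,
    mean_total_intensity = cfg$mean_total_intensity,
    replicate_cv = cfg$replicate_cv,
    site_intensity_cv = cfg$site_intensity_cv,
    mixture_weights = cfg$mixture_weights, seed = cfg$seed
  )
  paths <- list(
    intensities = file.path(out_dir, "intensities.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_intensity_table(sim$intensities, paths$intensities)
  write_simulation_truth(sim, paths$truth)
  paths$config <- write_run_config(cfg, out_dir)
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_convert <- function(config = list(), out_dir) {
  cfg <- resolve_config(config, list(
    input = NULL, to = "beta", alpha_beta = 100, alpha_m = 1,
    clip = 1e-6
  ), required = "input")
  if (!cfg$to %in% c("beta", "m")) {
    stop("unknown target scale: ", cfg$to, call. = FALSE)
  }
  ensure_out_dir(out_dir)
  is_meth_table <- file.exists(paste0(cfg$input, ".json"))
  if (is_meth_table) {
    x <- read_methylation_table(cfg$input)
    out <- if (identical(meth_scale(x), cfg$to)) x
    else if (cfg$to == "m") beta_to_m(x, clip = cfg$clip)
    else m_to_beta(x)
  } else {
    x <- read_intensity_table(cfg$input)
    out <- if (cfg$to == "beta") compute_beta(x, alpha = cfg$alpha_beta)
    else compute_m(x, alpha = cfg$alpha_m)
  }
  path <- file.path(out_dir, paste0(cfg$to, "_values.tsv"))
  write_methylation_table(out, path)
  paths <- list(values = path, config = write_run_config(cfg, out_dir))
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_diagnose <- function(config = list(), out_dir) {
  cfg <- resolve_config(config, list(
    input = NULL, p_threshold = 1e-4, sample_fraction = 0.5,
    n_bins = 20L, n_breaks = 50L, replicate_groups = NULL,
    alpha_beta = 100, alpha_m = 1
  ), required = "input")
  ensure_out_dir(out_dir)
  x <- read_intensity_table(cfg$input)
  x <- detection_filter(x, cfg$p_threshold, cfg$sample_fraction)
  report <- filter_report(x)
  x <- scaling_normalize(x)
  groups <- cfg$replicate_groups
  if (is.null(groups)) {
    # fall back on the default design's replicate structure when the
    # array ids match it
    d <- default_design()
    if (setequal(array_ids(x), d$array_id)) {
      groups <- split(d$array_id, d$mix_label)
    } else {
      stop("replicate_groups not given and arrays do not match the ",
           "default titration design", call. = FALSE)
    }
  }
  paths <- list(filter_report = file.path(out_dir, "filtered_sites.tsv"))
  write_filter_report(report, paths$filter_report)
  for (scale in c("beta", "m")) {
    vals <- if (scale == "beta") compute_beta(x, cfg$alpha_beta)
    else compute_m(x, cfg$alpha_m)
    bins <- bin_mean_sd(replicate_mean_sd(vals, groups), cfg$n_bins)
    hist <- histogram_summary(vals, cfg$n_breaks)
    bp <- file.path(out_dir, paste0(scale, "_mean_sd_bins.tsv"))
    hp <- file.path(out_dir, paste0(scale, "_histogram.tsv"))
    readr::write_tsv(tidy(bins), bp, progress = FALSE)
    readr::write_tsv(hist$table, hp, progress = FALSE)
    paths[[paste0(scale, "_bins")]] <- bp
    paths[[paste0(scale, "_hist")]] <- hp
  }
  paths$config <- write_run_config(cfg, out_dir)
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_evaluate <- function(config = list(), out_dir) {
  cfg <- resolve_config(config, list(
    input = NULL, design = NULL, groups_a = NULL, groups_b = NULL,
    r_threshold = 0.8, p_cutoff = 0.05, step = 50L,
    beta_thresholds = seq(0, 0.25, by = 0.0125),
    m_thresholds = seq(0, 2, by = 0.1),
    p_threshold = 1e-4, sample_fraction = 0.5,
    alpha_beta = 100, alpha_m = 1
  ), required = "input")
  ensure_out_dir(out_dir)
  design <- cfg$design
  if (is.null(design)) design <- default_design()
  if (is.character(design)) {
    d <- readr::read_tsv(design, col_types = readr::cols(
      array_id = readr::col_character(),
      fraction_a = readr::col_double(),
      mix_label = readr::col_character()
    ), progress = FALSE)
    design <- titration_design(d$fraction_a, d$array_id, d$mix_label)
  } else if (!inherits(design, "titration_design")) {
    design <- titration_design(design$fraction_a, design$array_id,
                               design$mix_label)
  }
  groups_a <- cfg$groups_a %||%
    design$array_id[design$fraction_a == 1][1:2]
  groups_b <- cfg$groups_b %||%
    design$array_id[design$fraction_a == 0][1:2]

  x <- read_intensity_table(cfg$input)
  x <- detection_filter(x, cfg$p_threshold, cfg$sample_fraction)
  x <- scaling_normalize(x)
  beta <- compute_beta(x, cfg$alpha_beta)
  m <- compute_m(x, cfg$alpha_m)
  tp <- define_true_positives(beta, m, design, cfg$r_threshold)

  paths <- list(tp_set = file.path(out_dir, "true_positives.tsv"))
  readr::write_tsv(
    dplyr::mutate(tidy(tp), r_beta = fmt_num(.data$r_beta),
                  r_m = fmt_num(.data$r_m)),
    paths$tp_set, na = "", progress = FALSE
  )
  for (scale in c("beta", "m")) {
    vals <- if (scale == "beta") beta else m
    diffr <- diff_methylation(vals, groups_a, groups_b)
    dp <- file.path(out_dir, paste0(scale, "_differential.tsv"))
    write_differential_table(diffr, dp)
    paths[[paste0(scale, "_differential")]] <- dp
    gated <- diffr[!is.na(diffr$p_value) &
                     diffr$p_value < cfg$p_cutoff, ]
    for (grp in c("low", "middle", "high")) {
      sub <- structure(gated[!is.na(gated$range_group) &
                               gated$range_group == grp, ],
                       class = class(diffr))
      if (nrow(sub) == 0) next
      ranked <- sub$site_id[order(-sub$abs_diff, sub$site_id)]
      cp <- file.path(out_dir, paste0(scale, "_", grp, "_topn.tsv"))
      write_curve(top_n_curve(ranked, tp, cfg$step), cp)
      paths[[paste0(scale, "_", grp, "_topn")]] <- cp
    }
    thresholds <- if (scale == "beta") cfg$beta_thresholds
    else cfg$m_thresholds
    sweep <- threshold_sweep(diffr, tp, thresholds, cfg$p_cutoff)
    sp <- file.path(out_dir, paste0(scale, "_threshold_sweep.tsv"))
    write_curve(sweep, sp)
    paths[[paste0(scale, "_sweep")]] <- sp
    sug <- tryCatch(suggest_thresholds(sweep),
                    warning = function(w) {
                      suppressWarnings(suggest_thresholds(sweep))
                    })
    sg <- file.path(out_dir,
                    paste0(scale, "_suggested_thresholds.tsv"))
    readr::write_tsv(sug, sg, progress = FALSE)
    paths[[paste0(scale, "_suggested")]] <- sg
  }
  cfg$design <- as.data.frame(design)
  cfg$groups_a <- groups_a
  cfg$groups_b <- groups_b
  paths$config <- write_run_config(cfg, out_dir)
  invisible(paths)
}
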