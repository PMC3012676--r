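#' Titration design
#'
#' Describes which fraction of sample A went onto each physical array.
#'
#' @param fraction_a numeric vector in `[0, 1]`, one entry per array.
#' @param array_id optional array identifiers (default `Array1..ArrayN`).
#' @param mix_label optional labels grouping technical replicates of the
#'   same mixture.
#' @return A tibble of class `titration_design` with columns `array_id`,
#'   `fraction_a`, `mix_label`.
#' @seealso [default_design()]
#' @export
titration_design <- function(fraction_a,
                             array_id = paste0("Array", seq_along(fraction_a)),
                             mix_label = paste0("Mix", match(fraction_a, sort(unique(fraction_a), decreasing = TRUE)))) {
  stopifnot(all(fraction_a >= 0 & fraction_a <= 1),
            !anyDuplicated(array_id))
  structure(
    tibble::tibble(array_id = as.character(array_id),
                   fraction_a = as.numeric(fraction_a),
                   mix_label = as.character(mix_label)),
    class = c("titration_design", class(tibble::tibble()))
  )
}

#' The default two-sample titration design
#'
#' Two base samples A and B mixed at five ratios -- 100:0, 90:10, 75:25,
#' 50:50 and 0:100 (percent A : percent B) -- measured with 2, 2, 1, 1
#' and 2 technical replicates respectively, for 8 arrays in total.
#'
#' @return A `titration_design` tibble of 8 arrays with `fraction_a`
#'   `(1, 1, 0.9, 0.9, 0.75, 0.5, 0, 0)`.
#' @export
default_design <- function() {
  fr <- c(1, 1, 0.9, 0.9, 0.75, 0.5, 0, 0)
  titration_design(
    fraction_a = fr,
    array_id = paste0("Array", seq_along(fr)),
    mix_label = c("Mix1", "Mix1", "Mix2", "Mix2", "Mix3", "Mix4",
                  "Mix5", "Mix5")
  )
}

#' Simulate an Infinium-like titration experiment
#'
#' Generates two-channel probe intensities with known per-site ground
#' truth, emulating the statistical structure of a HumanMethylation27-like
#' titration experiment:
#'
#' * Per-site true methylation fractions `p_A` are drawn from a bimodal
#'   mixture (a component concentrated near 0, one near 1, and a uniform
#'   middle component) so the population Beta-value histogram is bimodal.
#' * An exact count `round(diff_fraction * n_sites)` of sites, chosen
#'   without replacement, is truly differential: `p_B` is redrawn
#'   independently from the same mixture. All other sites have
#'   `p_B = p_A`.
#' * An array measuring a mixture with sample-A fraction `f` sees the
#'   site-level methylation fraction `f * p_A + (1 - f) * p_B` (the two
#'   samples contribute equal amounts of DNA).
#' * Channel intensities are independent Gamma draws with shape
#'   `gamma_shape`: methylated mean `T_i * p * s_a`, unmethylated mean
#'   `T_i * (1 - p) * s_a`, where `T_i` is a per-site total-intensity
#'   level (log-normal with arithmetic mean `mean_total_intensity` and
#'   coefficient of variation `site_intensity_cv`) and `s_a` a per-array
#'   log-normal technical factor with coefficient of variation
#'   `replicate_cv`.
#' * Detection p-values are set to 1e-6 everywhere: every simulated probe
#'   is real signal (failed probes are exercised with crafted fixtures,
#'   not simulated here).
#'
#' The defaults are tuned so that at least 95% of sites have a total
#' intensity (meth + unmeth) above 1000, matching what Infinium arrays
#' typically deliver.
#'
#' @param n_sites number of CpG sites.
#' @param design a `titration_design`; default [default_design()].
#' @param diff_fraction fraction of truly differential sites in `[0, 1]`.
#' @param gamma_shape shape of the Gamma intensity noise (larger = less
#'   channel noise; CV per channel is `1/sqrt(gamma_shape)`).
#' @param mean_total_intensity arithmetic mean of the per-site total
#'   intensity level, in fluorescence units.
#' @param replicate_cv coefficient of variation of the per-array
#'   technical scale factor.
#' @param site_intensity_cv coefficient of variation of the per-site
#'   total-intensity level across sites.
#' @param mixture_weights weights of the (near-0, near-1, middle uniform)
#'   components of the methylation prior; must sum to 1.
#' @param p_a,p_b optional length-`n_sites` vectors of true methylation
#'   fractions, bypassing the bimodal prior (and, when `p_b` is given,
#'   the `diff_fraction` machinery). Useful for controlled experiments
#'   where the truth must be fixed, not drawn.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A list with elements `intensities` (a `meth_intensity`
#'   tibble), `truth` (tibble: `site_id`, `p_a`, `p_b`,
#'   `is_differential`) and `params` (the fully-resolved parameter list,
#'   seed included).
#' @examples
#' sim <- simulate_titration(200, diff_fraction = 0.3, seed = 1)
#' mean(sim$truth$is_differential)
#' @export
simulate_titration <- function(n_sites,
                               design = default_design(),
                               diff_fraction = 0.3,
                               gamma_shape = 16,
                               mean_total_intensity = 3000,
                               replicate_cv = 0.05,
                               site_intensity_cv = 0.3,
                               mixture_weights = c(0.4, 0.4, 0.2),
                               p_a = NULL, p_b = NULL,
                               seed = 1L) {
  stopifnot(n_sites >= 1, diff_fraction >= 0, diff_fraction <= 1,
            gamma_shape > 0, mean_total_intensity > 0, replicate_cv >= 0,
            site_intensity_cv >= 0, length(mixture_weights) == 3,
            all(mixture_weights >= 0),
            abs(sum(mixture_weights) - 1) < 1e-8)
  if (!inherits(design, "titration_design")) {
    stop("design must be a titration_design", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  sids <- sprintf("cg%06d", seq_len(n_sites))
  if (is.null(p_a)) {
    p_a <- rbimodal(n_sites, mixture_weights)
  } else {
    stopifnot(length(p_a) == n_sites, all(p_a >= 0 & p_a <= 1))
  }
  if (is.null(p_b)) {
    p_b <- p_a
    n_diff <- round(diff_fraction * n_sites)
    diff_idx <- if (n_diff > 0) sort(sample.int(n_sites, n_diff))
    else integer(0)
    if (n_diff > 0) p_b[diff_idx] <- rbimodal(n_diff, mixture_weights)
  } else {
    stopifnot(length(p_b) == n_sites, all(p_b >= 0 & p_b <= 1))
  }
  is_diff <- p_a != p_b

  # log-normal with arithmetic mean mu and coefficient of variation cv
  rlnorm_mean_cv <- function(n, mu, cv) {
    if (cv == 0) return(rep(mu, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  }
  t_i <- rlnorm_mean_cv(n_sites, mean_total_intensity, site_intensity_cv)
  s_a <- rlnorm_mean_cv(nrow(design), 1, replicate_cv)

  n_arr <- nrow(design)
  meth <- matrix(NA_real_, n_sites, n_arr)
  unmeth <- matrix(NA_real_, n_sites, n_arr)
  for (a in seq_len(n_arr)) {
    f <- design$fraction_a[a]
    p <- f * p_a + (1 - f) * p_b
    mu_m <- t_i * p * s_a[a]
    mu_u <- t_i * (1 - p) * s_a[a]
    meth[, a] <- stats::rgamma(n_sites, shape = gamma_shape,
                               scale = mu_m / gamma_shape)
    unmeth[, a] <- stats::rgamma(n_sites, shape = gamma_shape,
                                 scale = mu_u / gamma_shape)
  }

  intensities <- new_intensity_tbl(
    tibble::tibble(
      site_id = rep(sids, times = n_arr),
      array_id = rep(design$array_id, each = n_sites),
      meth = as.vector(meth),
      unmeth = as.vector(unmeth),
      detection_p = 1e-6
    ),
    site_ids = sids, array_ids = design$array_id
  )
  truth <- tibble::tibble(site_id = sids, p_a = p_a, p_b = p_b,
                          is_differential = is_diff)
  params <- list(
    n_sites = n_sites, design = as.data.frame(design),
    diff_fraction = diff_fraction, gamma_shape = gamma_shape,
    mean_total_intensity = mean_total_intensity,
    replicate_cv = replicate_cv, site_intensity_cv = site_intensity_cv,
    mixture_weights = mixture_weights, seed = as.integer(seed)
  )
  list(intensities = intensities, truth = truth, params = params)
}

# bimodal methylation prior: Beta(2,20) near 0, Beta(20,2) near 1,
# Uniform(0,1) middle, mixed with the given weights
rbimodal <- function(n, w) {
  comp <- sample.int(3, n, replace = TRUE, prob = w)
  out <- numeric(n)
  out[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 20)
  out[comp == 2] <- stats::rbeta(sum(comp == 2), 20, 2)
  out[comp == 3] <- stats::runif(sum(comp == 3))
  out
}

# save/restore the global RNG state so simulation calls do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write simulation truth alongside its intensity table
#'
#' Writes the truth tibble as TSV (`TargetID`, `p_A`, `p_B`,
#' `is_differential` as 0/1) and all simulation parameters (seed
#' included) as a JSON sidecar `<path>.json`.
#'
#' @param sim a list from [simulate_titration()].
#' @param path output TSV path for the truth table.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(sim, path) {
  readr::write_tsv(
    tibble::tibble(
      TargetID = sim$truth$site_id,
      p_A = fmt_num(sim$truth$p_a),
      p_B = fmt_num(sim$truth$p_b),
      is_differential = as.integer(sim$truth$is_differential)
    ),
    path, progress = FALSE
  )
  jsonlite::write_json(sim$params, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
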