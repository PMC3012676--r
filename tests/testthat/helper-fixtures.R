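# shared fixture builders; everything is generated in code

# intensity table from site x array matrices
make_intensity <- function(meth, unmeth, detection_p = NULL,
                           site_id = NULL, array_id = NULL) {
  meth <- as.matrix(meth)
  unmeth <- as.matrix(unmeth)
  if (is.null(detection_p)) detection_p <- matrix(1e-6, nrow(meth), ncol(meth))
  detection_p <- as.matrix(detection_p)
  site_id <- site_id %||% sprintf("cg%03d", seq_len(nrow(meth)))
  array_id <- array_id %||% paste0("A", seq_len(ncol(meth)))
  intensity_tbl(
    site_id = rep(site_id, times = ncol(meth)),
    array_id = rep(array_id, each = nrow(meth)),
    meth = as.vector(meth),
    unmeth = as.vector(unmeth),
    detection_p = as.vector(detection_p)
  )
}

# methylation table from a site x array matrix
make_values <- function(m, scale = "beta", site_id = NULL,
                        array_id = NULL) {
  m <- as.matrix(m)
  site_id <- site_id %||% sprintf("cg%03d", seq_len(nrow(m)))
  array_id <- array_id %||% paste0("A", seq_len(ncol(m)))
  methylation_tbl(
    tibble::tibble(
      site_id = rep(site_id, times = ncol(m)),
      array_id = rep(array_id, each = nrow(m)),
      value = as.vector(m)
    ),
    scale = scale
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-scale within-range-group subset of a meth_diff table
group_subset <- function(diffr, grp) {
  keep <- !is.na(diffr$range_group) & diffr$range_group == grp
  structure(diffr[keep, ], class = class(diffr),
            scale = attr(diffr, "scale", exact = TRUE))
}

# p<0.05-gated, abs-diff-ranked candidate list within a range group
ranked_in_group <- function(diffr, grp, p_cutoff = 0.05) {
  sub <- group_subset(diffr, grp)
  sub <- sub[!is.na(sub$p_value) & sub$p_value < p_cutoff, ]
  sub$site_id[order(-sub$abs_diff, sub$site_id)]
}
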