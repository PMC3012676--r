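#' Read a GenomeStudio-style intensity table
#'
#' Parses the package's tab-separated intensity dialect: UTF-8, one header
#' row, first column `TargetID`, then one column triplet per array named
#' `<array>.Methylated`, `<array>.Unmethylated`, `<array>.Detection_Pval`.
#' Missing cells are empty. Column triplets are grouped per array and row
#' order is preserved from the file.
#'
#' @param path path to a TSV file.
#' @return A `meth_intensity` tibble.
#' @seealso [write_intensity_table()]
#' @export
read_intensity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # parse issues are re-raised as errors below, not left as warnings
  raw <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    TargetID = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, na = c("", "NA")))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("parse error at line ", probs$row[1], ": expected ",
         probs$expected[1], ", got ", probs$actual[1], call. = FALSE)
  }
  if (!"TargetID" %in% names(raw)) {
    stop("missing required column TargetID", call. = FALSE)
  }
  value_cols <- setdiff(names(raw), "TargetID")
  arrays <- unique(sub("\\.(Methylated|Unmethylated|Detection_Pval)$", "",
                       value_cols))
  needed <- as.vector(t(outer(
    arrays, c(".Methylated", ".Unmethylated", ".Detection_Pval"), paste0
  )))
  missing <- setdiff(needed, value_cols)
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  long <- purrr::map_dfr(arrays, function(a) {
    tibble::tibble(
      site_id = raw$TargetID,
      array_id = a,
      meth = raw[[paste0(a, ".Methylated")]],
      unmeth = raw[[paste0(a, ".Unmethylated")]],
      detection_p = raw[[paste0(a, ".Detection_Pval")]]
    )
  })
  new_intensity_tbl(long, site_ids = raw$TargetID, array_ids = arrays)
}

#' Write an intensity table
#'
#' Inverse of [read_intensity_table()] within float-format precision.
#' Numbers are written with 9 significant digits so repeated runs with the
#' same inputs produce byte-identical files.
#'
#' @param x a `meth_intensity` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path) {
  aids <- array_ids(x)
  wide <- tibble::tibble(TargetID = site_ids(x))
  for (a in aids) {
    sub <- x[x$array_id == a, ]
    idx <- match(wide$TargetID, sub$site_id)
    wide[[paste0(a, ".Methylated")]] <- fmt_num(sub$meth[idx])
    wide[[paste0(a, ".Unmethylated")]] <- fmt_num(sub$unmeth[idx])
    wide[[paste0(a, ".Detection_Pval")]] <- fmt_num(sub$detection_p[idx])
  }
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a methylation-value table
#'
#' One `TargetID` column plus one column per array; the scale and offset
#' are recorded in a JSON sidecar `<path>.json`.
#'
#' @param x a `meth_values` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(x, path) {
  m <- values_matrix(x)
  wide <- tibble::as_tibble(as.data.frame(apply(m, 2, fmt_num)))
  wide <- dplyr::bind_cols(tibble::tibble(TargetID = rownames(m)), wide)
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  jsonlite::write_json(
    list(scale = meth_scale(x), alpha_used = alpha_used(x)),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' Read a methylation-value table written by [write_methylation_table()]
#' @param path path to the TSV; the `<path>.json` sidecar supplies the
#'   scale and offset.
#' @return A `meth_values` tibble.
#' @export
read_methylation_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    TargetID = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, na = c("", "NA"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  arrays <- setdiff(names(raw), "TargetID")
  long <- purrr::map_dfr(arrays, function(a) {
    tibble::tibble(site_id = raw$TargetID, array_id = a, value = raw[[a]])
  })
  new_methylation_tbl(long, scale = meta$scale,
                      alpha = meta$alpha_used %||% NA_real_,
                      site_ids = raw$TargetID, array_ids = arrays)
}

# fixed 9-significant-digit formatting for reproducible text output
fmt_num <- function(x) {
  out <- formatC(x, digits = 9, format = "g")
  out[is.na(x)] <- NA_character_
  out
}
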