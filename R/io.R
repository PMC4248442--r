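# Plain-text readers and writers for the pipeline's table dialects.

#' @rdname expression_io
#' @param expr Expression data.frame.
#' @param path File path.
#' @export
write_expression_tsv <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write expression tables
#'
#' The expression TSV dialect has columns `gene_locus`, `probe_id`,
#' `raw_rep1`, `raw_rep2`, optionally extended with the normalized
#' columns (`norm_rep1`, `norm_rep2`, `norm_avg`, `expressed`,
#' `above_median`).
#'
#' @name expression_io
#' @export
read_expression_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read and write pathway definitions as JSON
#' @param pathways List of pathway definitions.
#' @param path File path.
#' @name pathway_io
#' @export
write_pathways_json <- function(pathways, path) {
  jsonlite::write_json(pathways, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname pathway_io
#' @export
read_pathways_json <- function(path) {
  pws <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(pws, function(pw) {
    pw$steps <- lapply(pw$steps, function(st) {
      st$step_index <- as.integer(st$step_index)
      st$genes <- as.character(unlist(st$genes))
      st
    })
    pw
  })
}

#' Read and write long-format PM kinetics
#' @param kinetics Long-format kinetics data.frame.
#' @param path File path.
#' @name kinetics_io
#' @export
write_kinetics_csv <- function(kinetics, path) {
  utils::write.csv(kinetics, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname kinetics_io
#' @export
read_kinetics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a species utilization matrix
#'
#' Expects a TSV with columns `source`, `type` (carbon/nitrogen), one
#' call column per species coded `growth` / `no_growth` / `NA`, and
#' optionally `differential` (logical). The packaged cross-species
#' comparison table ships at
#' `system.file("extdata", "table2_msm_mtb_utilization.tsv",
#' package = "feaspath")`.
#'
#' @param path File path.
#' @return data.frame with call columns as character (`NA` kept as the
#'   string-free R `NA`).
#' @export
read_utilization_matrix <- function(path) {
  um <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  call_cols <- grep("_call$", names(um), value = TRUE)
  for (cc in call_cols) {
    bad <- !(um[[cc]] %in% c("growth", "no_growth") | is.na(um[[cc]]))
    if (any(bad)) {
      stopf("invalid call '%s' in column %s", um[[cc]][bad][1], cc)
    }
  }
  if ("differential" %in% names(um) && is.character(um$differential)) {
    um$differential <- tolower(um$differential) == "true"
  }
  um
}
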