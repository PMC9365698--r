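#' Canonical unordered pair identifier
#'
#' Protein and cell-type pairs are unordered throughout the package; the
#' canonical id sorts the two members lexicographically and joins them with
#' `"--"`, which also serves as the deterministic tie-break key when ranking.
#'
#' @param a,b character vectors of ids (recycled).
#' @return character vector of pair ids.
#' @export
pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "--")
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the previous global RNG state so
#' generators never leak state into the caller's session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a bounded child seed so every stage draws from an independent stream
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483587L
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("iw_config_error", "error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a delimited table with a provenance header
#'
#' @param x data.frame or matrix.
#' @param path output path.
#' @param provenance named list written as `# key: value` comment lines.
#' @param row_names write row names as a leading `id` column.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(x, path, provenance = list(), row_names = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  }
  if (row_names) {
    x <- data.frame(id = rownames(x), x, check.names = FALSE)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix from TSV (first column = row ids, "NA" = missing)
#'
#' @param path TSV path; lines starting with `#` are skipped.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}
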