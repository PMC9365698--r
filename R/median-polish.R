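#' Two-way Tukey median polish
#'
#' Decomposes a bait x prey absorbance matrix into
#' `overall + row effect + column effect + residual` by iterated row and
#' column median sweeps (rows first). Missing cells are ignored by the
#' medians and stay missing in the residuals; the additive reconstruction
#' identity holds exactly for non-missing cells at every iteration. Screening
#' phases must be polished separately (per-phase batch removal) before their
#' scores are combined.
#'
#' @param x numeric matrix (a [signal_matrix()] or plain matrix) with at
#'   least 2 rows and 2 columns of non-missing data.
#' @param max_iter maximum number of full row+column sweeps.
#' @param tol convergence tolerance: iteration stops when the largest
#'   absolute change in any effect during a sweep is below `tol` (a.u.).
#' @return list with `overall` (scalar), `row` and `col` (named effect
#'   vectors), `residuals` (matrix, same dimnames and missingness as `x`),
#'   `iterations`, and `converged`.
#' @export
median_polish <- function(x, max_iter = 100L, tol = 1e-8) {
  phase <- attr(x, "phase")
  x <- unclass(x)
  if (!is.matrix(x) || nrow(x) < 2L || ncol(x) < 2L) {
    stop_config("median polish needs a matrix with >= 2 rows and columns")
  }
  if (any(rowSums(!is.na(x)) == 0L)) {
    stop("degenerate input: a row is entirely missing", call. = FALSE)
  }
  if (any(colSums(!is.na(x)) == 0L)) {
    stop("degenerate input: a column is entirely missing", call. = FALSE)
  }
  r <- x
  row_eff <- stats::setNames(numeric(nrow(x)), rownames(x))
  col_eff <- stats::setNames(numeric(ncol(x)), colnames(x))
  overall <- 0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    delta_max <- 0
    # row sweep
    rd <- apply(r, 1L, stats::median, na.rm = TRUE)
    r <- r - rd
    row_eff <- row_eff + rd
    cd0 <- stats::median(col_eff)
    overall <- overall + cd0
    col_eff <- col_eff - cd0
    delta_max <- max(delta_max, max(abs(rd)), abs(cd0))
    # column sweep
    cd <- apply(r, 2L, stats::median, na.rm = TRUE)
    r <- sweep(r, 2L, cd)
    col_eff <- col_eff + cd
    rd0 <- stats::median(row_eff)
    overall <- overall + rd0
    row_eff <- row_eff - rd0
    delta_max <- max(delta_max, max(abs(cd)), abs(rd0))
    if (delta_max < tol) {
      converged <- TRUE
      break
    }
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = r,
       iterations = iter, converged = converged, phase = phase)
}
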