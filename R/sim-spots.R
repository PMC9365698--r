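#' Simulate spot-level spatial transcriptomics with zonated gene pairs
#'
#' Lays spots on a square lattice (pitch 100 coordinate units, so the
#' 150-unit neighbour radius connects each spot to its 8-neighbourhood plus
#' itself). Planted "zonated" gene pairs occupy two spatially bordering 2x3
#' spot blocks; "distant" control pairs occupy blocks separated by well over
#' the neighbour radius; a large pool of ubiquitous background genes plus
#' mitochondrial (`MT-`) genes gives every spot realistic totals so the fixed
#' QC bounds are exercisable. All counts are Poisson.
#'
#' @param config a [sim_config()] (only the seed is used).
#' @param n_row,n_col lattice dimensions (>= 3).
#' @param pitch lattice pitch in coordinate units.
#' @param n_zonated,n_distant numbers of planted adjacent / distant pairs.
#' @param n_background ubiquitous background genes (sized so spots pass the
#'   gene-detection QC bound).
#' @param n_mito mitochondrial genes.
#' @param base_rate,mito_rate,zone_rate Poisson means for background,
#'   mitochondrial and planted zone genes.
#' @param qc_violations plant two QC-failing spots (low total, high
#'   mitochondrial fraction) and one gene detected in fewer than five spots.
#' @return list with `grid` (a [spot_grid()]) and `truth` (a
#'   [ground_truth()] whose `zonated_pairs` are the planted adjacent pairs;
#'   distant control pairs in attribute-free field `distant_pairs`).
#' @export
generate_spots <- function(config = sim_config(), n_row = 15L, n_col = 15L,
                           pitch = 100, n_zonated = 4L, n_distant = 3L,
                           n_background = 2400L, n_mito = 10L,
                           base_rate = 2, mito_rate = 20, zone_rate = 4,
                           qc_violations = TRUE) {
  if (n_row < 3L || n_col < 3L) {
    stop_config("configuration error: lattice must be at least 3x3")
  }
  slots <- slot_layout(n_row, n_col)
  need <- n_zonated + 2L * n_distant
  if (need > nrow(slots)) {
    stop_config("configuration error: lattice too small for requested pairs")
  }
  with_seed(derive_seed(config$seed, 3L), {
    spots <- expand.grid(row = seq_len(n_row), col = seq_len(n_col))
    spots <- data.frame(id = sprintf("S%04d", seq_len(nrow(spots))),
                        x = (spots$col - 1L) * pitch,
                        y = (spots$row - 1L) * pitch,
                        row = spots$row, col = spots$col,
                        stringsAsFactors = FALSE)
    n_spot <- nrow(spots)

    genes <- c(sprintf("BG%04d", seq_len(n_background)),
               sprintf("MT-%d", seq_len(n_mito)))
    counts <- cbind(
      matrix(stats::rpois(n_spot * n_background, base_rate), n_spot),
      matrix(stats::rpois(n_spot * n_mito, mito_rate), n_spot)
    )
    colnames(counts) <- genes

    in_block <- function(block) {
      spots$row >= block[1L] & spots$row <= block[2L] &
        spots$col >= block[3L] & spots$col <= block[4L]
    }
    add_gene <- function(counts, gene, mask) {
      v <- integer(n_spot)
      v[mask] <- stats::rpois(sum(mask), zone_rate) + 1L # guarantee detection
      counts <- cbind(counts, v)
      colnames(counts)[ncol(counts)] <- gene
      counts
    }

    zonated <- character()
    slot_i <- 1L
    for (k in seq_len(n_zonated)) {
      s <- slots[slot_i, ]; slot_i <- slot_i + 1L
      a <- c(s$row, s$row + 1L, s$col, s$col + 2L)       # top 2x3 block
      b <- c(s$row + 2L, s$row + 3L, s$col, s$col + 2L)  # bordering block
      ga <- sprintf("ZA%02d", k); gb <- sprintf("ZB%02d", k)
      counts <- add_gene(counts, ga, in_block(a))
      counts <- add_gene(counts, gb, in_block(b))
      zonated <- c(zonated, pair_id(ga, gb))
    }
    distant <- character()
    for (k in seq_len(n_distant)) {
      s1 <- slots[slot_i, ]; s2 <- slots[slot_i + 1L, ]; slot_i <- slot_i + 2L
      ga <- sprintf("DA%02d", k); gb <- sprintf("DB%02d", k)
      counts <- add_gene(counts, ga, in_block(c(s1$row, s1$row + 1L, s1$col, s1$col + 2L)))
      counts <- add_gene(counts, gb, in_block(c(s2$row, s2$row + 1L, s2$col, s2$col + 2L)))
      distant <- c(distant, pair_id(ga, gb))
    }

    if (qc_violations && n_spot >= 2L) {
      # one low-coverage spot and one mitochondria-dominated spot
      low <- n_spot - 1L; hi <- n_spot
      bgmt <- seq_len(n_background + n_mito) # leave planted zone genes alone
      counts[low, bgmt] <- stats::rpois(length(bgmt), base_rate * 0.2)
      counts[hi, seq_len(n_mito) + n_background] <-
        stats::rpois(n_mito, sum(counts[hi, ]) * 0.05)
      rare <- integer(n_spot); rare[seq_len(3L)] <- 1L
      counts <- cbind(counts, RARE1 = rare)
    }

    grid <- spot_grid(spots[, c("id", "x", "y")], counts,
                      mito_genes = grep("^MT-", colnames(counts), value = TRUE))
    truth <- ground_truth(zonated_pairs = zonated)
    truth$distant_pairs <- distant
    list(grid = grid, truth = truth)
  })
}

# non-overlapping 4x3 lattice regions separated by >= 2 lattice units
slot_layout <- function(n_row, n_col) {
  rows <- seq(1L, max(1L, n_row - 3L), by = 5L)
  cols <- seq(1L, max(1L, n_col - 2L), by = 4L)
  g <- expand.grid(row = rows, col = cols)
  g[g$row + 3L <= n_row & g$col + 2L <= n_col, , drop = FALSE]
}

#' Construct a spot grid container
#'
#' @param spots data.frame with columns `id`, `x`, `y` (finite coordinates).
#' @param counts integer matrix, spots x genes (row order matches `spots`).
#' @param mito_genes mitochondrial gene names; defaults to the `MT-` prefix
#'   convention.
#' @return a `spot_grid`.
#' @export
spot_grid <- function(spots, counts,
                      mito_genes = grep("^MT-", colnames(counts), value = TRUE)) {
  stopifnot(is.data.frame(spots), all(c("id", "x", "y") %in% names(spots)),
            is.matrix(counts), nrow(counts) == nrow(spots))
  if (any(!is.finite(spots$x)) || any(!is.finite(spots$y))) {
    stop_config("spot coordinates must be finite")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_config("spot counts must be non-negative integers")
  }
  rownames(counts) <- spots$id
  structure(list(spots = spots[, c("id", "x", "y")], counts = counts,
                 mito_genes = mito_genes),
            class = "spot_grid")
}
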