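# shared fixture builders and independent oracles

# tiny interaction network from pair strings "A--B" with optional kds
make_network <- function(pairs, kd = NA_real_) {
  ab <- do.call(rbind, strsplit(pairs, "--", fixed = TRUE))
  interaction_network(data.frame(protein_a = ab[, 1L], protein_b = ab[, 2L],
                                 kd = kd, stringsAsFactors = FALSE))
}

# bulk expression array from a mean matrix, exact replicates (no noise)
make_bulk <- function(means, n_rep = 4L, state = NULL) {
  arr <- array(rep(means, n_rep),
               dim = c(nrow(means), ncol(means), n_rep),
               dimnames = c(dimnames(means), list(sprintf("rep%d", 1:n_rep))))
  expression_matrix(arr, modality = "bulk", state = state)
}

# independent Tukey polish oracle: literal row/column median sweeps
oracle_polish <- function(x, n_sweeps = 50L) {
  overall <- 0
  row_eff <- numeric(nrow(x))
  col_eff <- numeric(ncol(x))
  r <- x
  for (s in seq_len(n_sweeps)) {
    for (i in seq_len(nrow(r))) {
      m <- stats::median(r[i, ], na.rm = TRUE)
      r[i, ] <- r[i, ] - m
      row_eff[i] <- row_eff[i] + m
    }
    m <- stats::median(col_eff)
    overall <- overall + m
    col_eff <- col_eff - m
    for (j in seq_len(ncol(r))) {
      m <- stats::median(r[, j], na.rm = TRUE)
      r[, j] <- r[, j] - m
      col_eff[j] <- col_eff[j] + m
    }
    m <- stats::median(row_eff)
    overall <- overall + m
    row_eff <- row_eff - m
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = r)
}

# brute-force AUC: fraction of positive/negative score pairs correctly
# ordered, ties counted one half (Mann-Whitney identity)
oracle_auc <- function(pos_scores, neg_scores) {
  total <- 0
  for (p in pos_scores) for (n in neg_scores) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos_scores) * length(neg_scores))
}

# independent colocalization enumeration: loops over all neighbour pairings
oracle_coloc <- function(xy, expr_a, expr_b, radius) {
  n <- nrow(xy)
  capable <- 0L
  denom <- 0L
  for (i in seq_len(n)) for (j in i:n) {
    d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    if (d > radius) next
    one_of <- function(k) expr_a[k] || expr_b[k]
    if (one_of(i) && one_of(j)) denom <- denom + 1L
    if ((expr_a[i] && expr_b[j]) || (expr_b[i] && expr_a[j])) {
      capable <- capable + 1L
    }
  }
  if (denom == 0L) 0 else capable / denom
}

# algebraic 2-type mass-action fixed point: scalar root in F2, quadratic F1
oracle_two_type_eq <- function(A, init, cfg) {
  c11 <- cfg$k_c * max(A[1, 1], cfg$epsilon) / cfg$kappa
  c12 <- cfg$k_c * max(A[1, 2], cfg$epsilon) / cfg$kappa
  c22 <- cfg$k_c * max(A[2, 2], cfg$epsilon) / cfg$kappa
  f1_of <- function(f2) {
    # c11 F1^2 + (1 + c12 f2) F1 - init1 = 0, positive root
    b <- 1 + c12 * f2
    if (c11 == 0) return(init[1] / b)
    (-b + sqrt(b^2 + 4 * c11 * init[1])) / (2 * c11)
  }
  g2 <- function(f2) f2 * (1 + c12 * f1_of(f2) + c22 * f2) - init[2]
  f2 <- stats::uniroot(g2, c(0, init[2]), tol = 1e-14)$root
  f1 <- f1_of(f2)
  list(F = c(f1, f2),
       D = matrix(c(c11 * f1^2 / 2, c12 * f1 * f2,
                    c12 * f1 * f2, c22 * f2^2 / 2), 2, 2))
}

# directed imaging contact counts by exhaustive O(n^2) loops
oracle_contacts <- function(cells, radius) {
  hits <- list()
  for (i in seq_len(nrow(cells) - 1L)) for (j in (i + 1L):nrow(cells)) {
    if (!is.null(cells$site) && cells$site[i] != cells$site[j]) next
    d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
    if (d <= radius) hits[[length(hits) + 1L]] <- c(i, j)
  }
  do.call(rbind, hits)
}
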