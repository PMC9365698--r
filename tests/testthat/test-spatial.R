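toy_grid <- function(x, y, counts) {
  spot_grid(data.frame(id = sprintf("s%d", seq_along(x)), x = x, y = y),
            counts)
}

test_that("spot QC applies the published bounds literally", {
  # 10 spots: 6 pass; low total, high total, high mito, few genes fail
  n_spots <- 10L
  base <- matrix(2L, n_spots, 2500L,
                 dimnames = list(NULL, c(sprintf("G%04d", 1:2490),
                                         sprintf("MT-%d", 1:10))))
  base[2, 1:1001] <- 1L                            # total 3999 -> removed
  base[3, ] <- 15L                                 # total 37500 -> removed
  base[4, 2491:2500] <- 130L                       # mito ~20.7% -> removed
  base[5, 1:600] <- 0L; base[5, 601:2500] <- 3L    # 1900 genes -> removed
  grid <- toy_grid(seq_len(n_spots) * 100, rep(0, n_spots), base)
  out <- qc_spots(grid)
  expect_setequal(out$spots$id, sprintf("s%d", c(1, 6:10)))
  expect_equal(unname(attr(out, "removed")["spots"]), 4L)
  # gene kept at exactly five spots, removed below
  cnt <- matrix(2L, 6, 2500,
                dimnames = list(NULL, colnames(base)))
  cnt[, 1] <- c(1L, 1L, 1L, 1L, 1L, 0L)  # 5 spots -> kept
  cnt[, 2] <- c(1L, 1L, 1L, 1L, 0L, 0L)  # 4 spots -> removed
  out2 <- qc_spots(toy_grid(seq_len(6) * 100, rep(0, 6), cnt),
                   min_counts = 0, min_genes = 0)
  expect_true("G0001" %in% colnames(out2$counts))
  expect_false("G0002" %in% colnames(out2$counts))
  expect_error(qc_spots(toy_grid(1:2, c(0, 0),
                                 matrix(0L, 2, 3,
                                        dimnames = list(NULL, c("a", "b", "c"))))),
               "QC removed all")
})

test_that("neighbour graph is self-inclusive with inclusive radius ties", {
  g <- neighbor_graph(toy_grid(c(0, 100, 300), c(0, 0, 0),
                               matrix(1L, 3, 2,
                                      dimnames = list(NULL, c("a", "b")))),
                      radius = 150)
  pairs <- paste(g[, 1], g[, 2])
  expect_true("1 2" %in% pairs)    # 100 apart: neighbours
  expect_false("2 3" %in% pairs)   # 200 apart: not
  expect_true(all(paste(1:3, 1:3) %in% pairs)) # self-inclusive
  # tie at exactly the radius is included
  g2 <- neighbor_graph(toy_grid(c(0, 150), c(0, 0),
                                matrix(1L, 2, 1,
                                       dimnames = list(NULL, "a"))), 150)
  expect_true("1 2" %in% paste(g2[, 1], g2[, 2]))
})

test_that("lattice degree matches brute-force distances", {
  xy <- expand.grid(x = seq(0, 400, 100), y = seq(0, 400, 100))
  cnt <- matrix(1L, nrow(xy), 1, dimnames = list(NULL, "g"))
  grid <- toy_grid(xy$x, xy$y, cnt)
  g <- neighbor_graph(grid, 150)
  # interior spot: 8 lattice neighbours + self
  centre <- which(xy$x == 200 & xy$y == 200)
  deg <- sum(g[, 1] == centre) + sum(g[, 2] == centre) - 1L
  expect_equal(deg, 9L)
  # brute force over all pairs
  for (k in 1:5) {
    i <- sample(nrow(xy), 1); j <- sample(nrow(xy), 1)
    d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    present <- any((g[, 1] == min(i, j)) & (g[, 2] == max(i, j)))
    expect_equal(present, d <= 150)
  }
})

test_that("colocalization scores match exhaustive enumeration", {
  xy <- cbind(c(0, 100, 200), c(0, 0, 0))
  mk <- function(ea, eb) {
    cnt <- cbind(p = as.integer(ea), q = as.integer(eb))
    toy_grid(xy[, 1], xy[, 2], cnt)
  }
  g3 <- neighbor_graph(mk(c(1, 0, 0), c(0, 0, 1)), 150)
  # disjoint non-adjacent expression scores zero
  expect_equal(as.numeric(
    colocalization_score(mk(c(1, 0, 0), c(0, 0, 1)), g3, "p", "q")), 0)
  # overlapping path expression: compare against the enumeration oracle
  cases <- list(c(1, 1, 0, 0, 1, 1), c(1, 0, 1, 0, 1, 0), c(1, 1, 1, 1, 1, 1),
                c(0, 1, 0, 1, 0, 1), c(1, 0, 0, 1, 1, 0))
  for (cs in cases) {
    ea <- cs[1:3] > 0; eb <- cs[4:6] > 0
    grid <- mk(ea, eb)
    got <- as.numeric(colocalization_score(grid, g3, "p", "q"))
    expect_equal(got, oracle_coloc(xy, ea, eb, 150), label = paste(cs, collapse = ""))
  }
  # co-expression everywhere scores 1
  expect_equal(as.numeric(
    colocalization_score(mk(c(1, 1, 1), c(1, 1, 1)), g3, "p", "q")), 1)
})

test_that("scores are invariant to rigid motions and uniform expression", {
  set.seed(31)
  xy <- expand.grid(x = seq(0, 300, 100), y = seq(0, 300, 100))
  ea <- runif(16) < 0.5; eb <- runif(16) < 0.5
  cnt <- cbind(p = as.integer(ea), q = as.integer(eb))
  s0 <- {
    grid <- toy_grid(xy$x, xy$y, cnt)
    as.numeric(colocalization_score(grid, neighbor_graph(grid, 150), "p", "q"))
  }
  th <- 0.7
  rx <- xy$x * cos(th) - xy$y * sin(th) + 500
  ry <- xy$x * sin(th) + xy$y * cos(th) - 200
  s1 <- {
    grid <- toy_grid(rx, ry, cnt)
    as.numeric(colocalization_score(grid, neighbor_graph(grid, 150), "p", "q"))
  }
  expect_equal(s0, s1)
  # all genes expressed in every spot: all pairwise scores equal
  cnt3 <- matrix(1L, 16, 3, dimnames = list(NULL, c("a", "b", "c")))
  grid3 <- toy_grid(xy$x, xy$y, cnt3)
  g <- neighbor_graph(grid3, 150)
  ss <- c(colocalization_score(grid3, g, "a", "b"),
          colocalization_score(grid3, g, "a", "c"),
          colocalization_score(grid3, g, "b", "c"))
  expect_equal(ss, rep(ss[1], 3))
  # identical expression pattern: score equals self-adjacency fraction
  expect_equal(as.numeric(colocalization_score(grid3, g, "a", "a")), 1)
})

test_that("partner permutation is derangement-style and seeded", {
  xy <- expand.grid(x = seq(0, 300, 100), y = seq(0, 300, 100))
  set.seed(44)
  cnt <- matrix(rbinom(16 * 4, 1, 0.5), 16, 4,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  grid <- toy_grid(xy$x, xy$y, cnt)
  g <- neighbor_graph(grid, 150)
  net <- make_network(c("a--b", "c--d"))
  # two disjoint edges: the only valid permutation swaps partners
  null1 <- permuted_null(net, grid, g, n_perm = 3L, seed = 5L)
  swapped <- colocalization_scores(grid, g, data.frame(
    protein_a = c("a", "c"), protein_b = c("d", "b")))$score
  expect_equal(null1$scores, rep(swapped, 3L))
  # seeded reproducibility
  n2 <- permuted_null(net, grid, g, n_perm = 3L, seed = 5L)
  expect_identical(null1, n2)
  expect_error(permuted_null(net[1, ], grid, g), "too few edges")
  expect_equal(permuted_null(net, grid, g, n_perm = 0L)$n_perm, 0L)
})

test_that("group comparison reproduces textbook one-way ANOVA", {
  known <- c(5.1, 4.8, 5.3, 5.0, 4.9)
  novel <- c(4.2, 4.5, 4.1, 4.4, 4.3)
  null <- c(3.0, 3.2, 2.9, 3.1, 3.3)
  res <- compare_groups(known, novel, null)
  # manual sums of squares
  all_v <- c(known, novel, null)
  gm <- mean(all_v)
  ss_b <- 5 * sum((c(mean(known), mean(novel), mean(null)) - gm)^2)
  ss_w <- sum((known - mean(known))^2) + sum((novel - mean(novel))^2) +
    sum((null - mean(null))^2)
  f_oracle <- (ss_b / 2) / (ss_w / 12)
  expect_equal(unname(res$anova["F"]), f_oracle, tolerance = 1e-10)
  expect_lt(res$anova["p"], 1e-6)
  expect_true(all(res$tukey$p_adj < 0.01))
  # identical groups: F ~ 0, Tukey p ~ 1
  same <- c(1, 1.01, 0.99, 1.02, 0.98)
  res0 <- compare_groups(same, same, same)
  expect_lt(unname(res0$anova["F"]), 1e-10)
  expect_true(all(res0$tukey$p_adj > 0.99))
  # degenerate variance reported as status
  resd <- compare_groups(c(1, 1), c(1, 1), c(1, 1))
  expect_match(resd$status, "degenerate")
  expect_error(compare_groups(1, c(1, 2), c(1, 2)), "at least 2")
})
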