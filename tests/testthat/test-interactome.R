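test_that("binarization boundaries match the stated rules", {
  sc <- expression_matrix(
    matrix(c(0.10, 0.099, 0.5, 0), 2, 2,
           dimnames = list(c("T1", "T2"), c("P1", "P2"))),
    modality = "single_cell")
  det <- binarize_expression(sc, sc_threshold = 0.10)
  expect_true(det["T1", "P1"])    # boundary fraction 0.10 is detected
  expect_false(det["T2", "P1"])
  expect_false(det["T2", "P2"])   # all-zero protein never detected

  # bulk: strictly more than half of replicates must be nonzero
  arr <- array(0, c(1, 2, 4), dimnames = list("T1", c("P1", "P2"),
                                              sprintf("r%d", 1:4)))
  arr[1, 1, 1:2] <- 5  # 2 of 4 -> not detected
  arr[1, 2, 1:3] <- 5  # 3 of 4 -> detected
  det <- binarize_expression(expression_matrix(arr, "bulk"))
  expect_false(det[1, 1])
  expect_true(det[1, 2])
  expect_error(binarize_expression(matrix(1)), "unknown modality")
})

test_that("raising the detection threshold never adds detections", {
  set.seed(8)
  vals <- matrix(runif(60), 6, 10,
                 dimnames = list(sprintf("T%d", 1:6), sprintf("P%d", 1:10)))
  expr <- expression_matrix(vals, "single_cell")
  prev <- binarize_expression(expr, 0.05)
  for (thr in c(0.1, 0.3, 0.6, 0.9)) {
    cur <- binarize_expression(expr, thr)
    expect_true(all(prev | !cur)) # cur subset of prev
    prev <- cur
  }
})

test_that("interaction key matches brute-force enumeration", {
  det <- matrix(FALSE, 2, 3, dimnames = list(c("A", "B"), c("p", "q", "r")))
  det["A", "p"] <- TRUE
  det["B", "q"] <- TRUE
  net <- make_network("p--q")
  key <- build_interaction_key(det, net)
  expect_equal(nrow(key), 2L) # the detected row plus its symmetric mirror
  expect_setequal(paste(key$cell_a, key$cell_b), c("A B", "B A"))

  # both proteins on both cell types: full ordered enumeration
  det[] <- TRUE
  key <- build_interaction_key(det, net)
  oracle <- expand.grid(cell_a = c("A", "B"), cell_b = c("A", "B"),
                        ord = 1:2, stringsAsFactors = FALSE)
  expect_equal(nrow(key), nrow(oracle))
  expect_true(all(key$ubiquitous))

  # symmetric closure: swapping cell labels leaves the key invariant
  key_swapped <- build_interaction_key(det[c(2, 1), , drop = FALSE], net)
  k1 <- key[order(key$cell_a, key$cell_b, key$protein_a), c(1, 2, 3, 4)]
  k2 <- key_swapped[order(key_swapped$cell_a, key_swapped$cell_b,
                          key_swapped$protein_a), c(1, 2, 3, 4)]
  expect_equal(k1, k2, ignore_attr = TRUE)

  # unmapped ids reported, never silently dropped
  expect_warning(build_interaction_key(det, make_network("p--zz")),
                 "unmapped")
  expect_warning(k0 <- build_interaction_key(det, net[0, ]), "empty network")
  expect_equal(nrow(k0), 0L)
})

test_that("affinity profiles report log and arithmetic means per entry", {
  det <- matrix(TRUE, 2, 4, dimnames = list(c("A", "B"),
                                            c("p", "q", "r", "s")))
  net <- make_network(c("p--q", "r--s"), kd = c(1e-6, 1e-4))
  key <- build_interaction_key(det, net)
  prof <- affinity_profile(key)
  ab <- prof$summary[prof$summary$cell_a == "A" & prof$summary$cell_b == "B", ]
  expect_equal(ab$n_interactions, 2L)
  expect_equal(ab$mean_kd_log, 1e-5)            # geometric mean of 1 and 100 uM
  expect_equal(ab$mean_kd_arith, (1e-6 + 1e-4) / 2) # 50.5 uM
  # single edge: mean equals its kd
  prof1 <- affinity_profile(build_interaction_key(det, make_network("p--q", 1e-6)))
  expect_equal(prof1$summary$mean_kd_log[1], 1e-6)
})

test_that("affinity switch test recovers planted regulation", {
  types <- c("T1", "T2")
  prots <- sprintf("P%d", 1:8)
  mu <- matrix(1000, 2, 8, dimnames = list(types, prots))
  rest <- make_bulk(mu, state = "resting")
  mu_act <- mu
  mu_act[, 1:2] <- mu[, 1:2] * 4    # up
  mu_act[, 3:4] <- mu[, 3:4] / 4    # down
  act <- make_bulk(mu_act, state = "activated")
  # up proteins carry strong affinities, down proteins weak ones
  net <- make_network(c("P1--P5", "P2--P6", "P1--P6", "P3--P7", "P4--P8",
                        "P3--P8"),
                      kd = c(1e-8, 2e-8, 1.5e-8, 1e-4, 2e-4, 1.5e-4))
  res <- affinity_switch_test(rest, act, net)
  expect_true(all(res$status == "ok"))
  sets <- attr(res, "sets")
  expect_length(sets$T1$up, 3L)   # P1 twice + P2 once
  expect_length(sets$T1$down, 3L)
  expect_true(all(res$p < 0.01))
  expect_true(all(res$direction == "activated shifts to stronger binding"))
  expect_true(all(res$p_holm >= res$p))

  # identical up/down affinity pools: t ~ 0, p ~ 1
  net_same <- make_network(c("P1--P5", "P3--P5"), kd = c(1e-6, 1e-6))
  mu2 <- mu; mu2[, 1] <- mu[, 1] * 4; mu2[, 3] <- mu[, 3] / 4
  # single values per group -> skipped with explicit status
  res2 <- affinity_switch_test(rest, make_bulk(mu2), net_same)
  expect_true(all(grepl("skipped", res2$status)))
})

test_that("eigenvector centrality matches a dense eigensolver", {
  w <- matrix(c(0, 4, 2, 1,
                4, 0, 1, 0,
                2, 1, 0, 3,
                1, 0, 3, 0), 4, 4, byrow = TRUE,
              dimnames = rep(list(sprintf("T%d", 1:4)), 2))
  cent <- eigenvector_centrality(w)
  eig <- eigen(w, symmetric = TRUE)
  v <- abs(eig$vectors[, 1])
  expect_equal(unname(cent), v / max(v), tolerance = 1e-8)
  # eigen-equation residual
  lam <- eig$values[1]
  expect_lt(max(abs(w %*% cent - lam * cent)) / max(abs(lam * cent)), 1e-8)
  # star graph: hub strictly greatest; complete graph: all equal
  star <- matrix(0, 4, 4, dimnames = rep(list(c("hub", "a", "b", "c")), 2))
  star["hub", c("a", "b", "c")] <- 1
  star[c("a", "b", "c"), "hub"] <- 1
  cs <- eigenvector_centrality(star)
  expect_true(all(cs["hub"] > cs[c("a", "b", "c")]))
  comp <- matrix(1, 3, 3, dimnames = rep(list(c("x", "y", "z")), 2))
  diag(comp) <- 0
  expect_equal(unname(eigenvector_centrality(comp)), rep(1, 3),
               tolerance = 1e-9)
  # isolated node gets 0 with a warning
  iso <- rbind(cbind(star, none = 0), none = 0)
  expect_warning(ci <- eigenvector_centrality(iso), "isolated")
  expect_equal(unname(ci["none"]), 0)
})

test_that("myeloid centrality comparison applies Welch + BH across tissues", {
  set.seed(2)
  d <- do.call(rbind, lapply(sprintf("tissue%d", 1:4), function(ti) {
    data.frame(tissue = ti,
               cell_type = sprintf("ct%d", 1:8),
               centrality = c(rnorm(3, 0.9, 0.05), rnorm(5, 0.4, 0.05)),
               is_myeloid = c(TRUE, TRUE, TRUE, rep(FALSE, 5)))
  }))
  res <- centrality_group_test(d)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$p < 0.01))
  expect_equal(res$p_bh, stats::p.adjust(res$p, "BH"))
})
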