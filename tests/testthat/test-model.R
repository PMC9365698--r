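test_that("surface density conversion assumes a spherical cell", {
  expect_equal(counts_to_density(0, 5), 0)
  expect_equal(counts_to_density(10000, 5), 10000 / (4 * pi * 25))
  expect_equal(counts_to_density(10000, 5), 31.83099, tolerance = 1e-6)
  # doubling the radius quarters the density
  expect_equal(counts_to_density(1000, 10), counts_to_density(1000, 5) / 4)
  expect_error(counts_to_density(10, 0), "radius")
})

test_that("saturation binding limits are exact", {
  cfg <- model_config()
  k2d <- 1e-6 * 6.02214076e23 / 1e15 * cfg$h # ~6 molecules/um^2 for 1 uM
  expect_equal(k2d, 6.02214076, tolerance = 1e-8)
  # half saturation (directional kernel)
  expect_equal(bound_density(10, k2d, 1e-6, cfg, symmetrize = FALSE), 5)
  # saturation limit
  expect_equal(bound_density(10, 1e9, 1e-6, cfg, symmetrize = FALSE), 10,
               tolerance = 1e-6)
  # no-binding limit: B -> 0 as K_D grows without bound
  expect_lt(bound_density(10, 10, 1e8, cfg), 1e-10)
  expect_gt(bound_density(10, 10, 1e8, cfg),
            bound_density(10, 10, 1e10, cfg))
  # symmetrized kernel averages the two role assignments
  expect_equal(bound_density(3, 7, 1e-6, cfg),
               (bound_density(3, 7, 1e-6, cfg, FALSE) +
                  bound_density(7, 3, 1e-6, cfg, FALSE)) / 2)
  expect_error(bound_density(1, 1, 0), "kd")
})

test_that("cell-pair affinity sums edges symmetrically and monotonically", {
  cfg <- model_config()
  dens <- matrix(c(10, 0, 5, 0, 0, 8), 2, 3,
                 dimnames = list(c("X", "Y"), c("p", "q", "r")))
  # single edge with p only on X and q only on Y
  dens1 <- matrix(c(10, 0, 0, 8), 2, 2,
                  dimnames = list(c("X", "Y"), c("p", "q")))
  A1 <- cell_pair_affinity(dens1, make_network("p--q", 1e-6), cfg)
  expect_equal(A1["X", "Y"],
               bound_density(10, 8, 1e-6, cfg) + bound_density(0, 0, 1e-6, cfg))
  expect_equal(A1, t(A1))
  # no shared detected edges -> zero
  A0 <- cell_pair_affinity(dens1, make_network("p--p", 1e-6), cfg)
  expect_equal(A0["X", "Y"], 0)
  # adding an edge never decreases any entry
  net2 <- make_network(c("p--q", "p--r"), kd = c(1e-6, 1e-6))
  dens3 <- matrix(runif(6, 1, 10), 2, 3,
                  dimnames = list(c("X", "Y"), c("p", "q", "r")))
  Aa <- cell_pair_affinity(dens3, make_network("p--q", 1e-6), cfg)
  Ab <- cell_pair_affinity(dens3, net2, cfg)
  expect_true(all(Ab - Aa >= -1e-15))
  # unannotated edges fall back to 1 uM with a flag
  Ad <- cell_pair_affinity(dens3, make_network("p--q"), cfg)
  expect_identical(attr(Ad, "defaulted_kd"), "p--q")
  expect_equal(unclass(Ad), unclass(Aa), ignore_attr = TRUE)
})

test_that("affinity is monotone in density and antitone in K_D", {
  cfg <- model_config()
  set.seed(3)
  dens <- matrix(runif(8, 0, 20), 2, 4,
                 dimnames = list(c("X", "Y"), sprintf("g%d", 1:4)))
  net <- make_network(c("g1--g2", "g3--g4"), kd = c(1e-6, 1e-5))
  A <- cell_pair_affinity(dens, net, cfg)
  dens_up <- dens; dens_up["X", "g1"] <- dens["X", "g1"] * 2
  expect_true(all(cell_pair_affinity(dens_up, net, cfg) - A >= -1e-15))
  net_weak <- net; net_weak$kd <- net$kd * 10
  expect_true(all(A - cell_pair_affinity(dens, net_weak, cfg) >= -1e-15))
})

test_that("2-type equilibrium matches the algebraic fixed point", {
  cfg <- model_config()
  set.seed(4)
  for (k in 1:10) {
    A <- matrix(runif(4, 0.1, 30), 2, 2,
                dimnames = rep(list(c("a", "b")), 2))
    A <- (A + t(A)) / 2
    init <- c(a = runif(1, 0.05, 0.4), b = runif(1, 0.05, 0.4))
    st <- integrate_doublets(A, init, cfg)
    orc <- oracle_two_type_eq(A, unname(init), cfg)
    expect_equal(unname(st$F), orc$F, tolerance = 1e-6)
    expect_equal(unname(st$D), unname(orc$D), tolerance = 1e-6)
  }
})

test_that("equilibrium satisfies conservation and detailed balance", {
  cfg <- model_config()
  set.seed(6)
  for (k in 1:20) {
    n <- sample(3:6, 1)
    A <- matrix(10^runif(n * n, -2, 1.7), n, n,
                dimnames = rep(list(sprintf("t%d", 1:n)), 2))
    A <- (A + t(A)) / 2
    init <- stats::setNames(runif(n, 0.02, 0.3), sprintf("t%d", 1:n))
    st <- integrate_doublets(A, init, cfg)
    total <- st$F + (rowSums(st$D) - diag(st$D)) + 2 * diag(st$D)
    expect_lt(max(abs(total - st$init_freq)) / max(init), 1e-6)
    expect_lt(st$residual, 1e-6)
  }
  # uniform affinity: doublets proportional to frequency products
  Au <- matrix(5, 3, 3, dimnames = rep(list(c("x", "y", "z")), 2))
  stu <- integrate_doublets(Au, c(x = 0.1, y = 0.2, z = 0.3), cfg)
  ratio <- stu$D / outer(stu$F, stu$F)
  off <- ratio[upper.tri(ratio)]
  expect_lt(diff(range(off)), 1e-8)
  expect_equal(unname(diag(ratio)), rep(off[1] / 2, 3), tolerance = 1e-8)
  # kappa -> Inf: everything stays unbound
  stk <- integrate_doublets(Au, c(x = 0.1, y = 0.2, z = 0.3),
                            model_config(kappa = 1e12))
  expect_lt(max(stk$D), 1e-10)
  expect_equal(unname(stk$F), c(0.1, 0.2, 0.3), tolerance = 1e-9)
})

test_that("equilibrium depends on k_c and kappa only through their ratio", {
  A <- matrix(c(4, 9, 9, 2), 2, 2, dimnames = rep(list(c("a", "b")), 2))
  init <- c(a = 0.2, b = 0.25)
  st1 <- integrate_doublets(A, init, model_config(k_c = 1, kappa = 2))
  st2 <- integrate_doublets(A, init, model_config(k_c = 5, kappa = 10))
  expect_equal(st1$D, st2$D, tolerance = 1e-9)
})

test_that("model scores follow the imaging formula and its symmetries", {
  cfg <- model_config()
  # hand-sized 3-type state: evaluate the formula directly
  D <- matrix(c(0.01, 0.03, 0.002,
                0.03, 0.005, 0.01,
                0.002, 0.01, 0.02), 3, 3,
              dimnames = rep(list(c("a", "b", "c")), 2))
  init <- c(a = 0.3, b = 0.3, c = 0.2)
  st <- structure(list(F = init, D = D, init_freq = init), class = "ode_state")
  s <- model_interaction_scores(st)
  f <- init / sum(init)
  total <- 2 * (sum(D[upper.tri(D)]) + sum(diag(D)))
  expect_equal(s["a", "b"], D["a", "b"] / (f["a"] * f["b"] * total),
               ignore_attr = TRUE)
  expect_equal(s["a", "a"], 2 * D["a", "a"] / (f["a"]^2 * total),
               ignore_attr = TRUE)
  expect_equal(s, t(s))
  # dominant affinity yields the maximal score
  A <- matrix(1, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  A["a", "b"] <- A["b", "a"] <- 50
  stq <- integrate_doublets(A, init, cfg)
  sq <- model_interaction_scores(stq)
  expect_equal(sq["a", "b"], max(sq), ignore_attr = TRUE)
  # zero-contact state is flagged undefined
  st0 <- structure(list(F = init, D = D * 0, init_freq = init),
                   class = "ode_state")
  expect_true(all(is.na(model_interaction_scores(st0))))
})

test_that("scores are invariant to frequency rescaling in the dilute limit", {
  A <- matrix(c(2, 5, 1, 5, 3, 2, 1, 2, 4), 3, 3,
              dimnames = rep(list(c("a", "b", "c")), 2))
  A <- (A + t(A)) / 2
  cfg <- model_config(kappa = 1e3) # weak binding: negligible depletion
  init <- c(a = 0.1, b = 0.2, c = 0.15)
  s1 <- model_interaction_scores(integrate_doublets(A, init, cfg))
  s2 <- model_interaction_scores(integrate_doublets(A, init * 3, cfg))
  expect_equal(s1, s2, tolerance = 1e-3)
})

test_that("protein knockout reshapes scores and never raises affinity", {
  cfg <- model_config()
  dens <- matrix(c(20, 0, 0, 15, 5, 5), 2, 3,
                 dimnames = list(c("X", "Y"), c("p", "q", "r")))
  net <- make_network(c("p--q", "r--r"), kd = c(1e-7, 1e-6))
  init <- c(X = 0.2, Y = 0.2)
  ko <- perturb_protein(dens, net, init, "p", cfg)
  # p is the sole linker of X-Y: its knockout lowers that score
  expect_lt(ko$delta["X", "Y"], 0)
  expect_true(all(ko$perturbed$affinity - ko$baseline$affinity <= 1e-12))
  # protein absent from all detected edges: no change anywhere
  dens4 <- cbind(dens, s = c(3, 3))
  ko0 <- perturb_protein(dens4, net, init, "s", cfg)
  expect_equal(max(abs(ko0$delta)), 0)
  expect_error(perturb_protein(dens, net, init, "nope", cfg),
               "unknown protein")
})

test_that("rank_and_compare rewards agreement and applies eligibility", {
  set.seed(12)
  pairs <- sprintf("cp%02d", 1:12)
  pred <- lapply(1:4, function(i) {
    stats::setNames(c(rep(2, 4), rep(0.01, 8))[sample(12)], pairs)
  })
  names(pred) <- sprintf("prot%d", 1:4)
  # measured tracks predicted with small noise
  meas <- lapply(pred, function(v) v + rnorm(12, 0, 0.05))
  res <- rank_and_compare(pred, meas)
  expect_true(all(res$status == "ok"))
  expect_true(all(res$p < 0.01))
  expect_equal(res$p_bh, stats::p.adjust(res$p, "BH"))
  # a protein predicted to do nothing is ineligible
  pred$flat <- stats::setNames(rep(1e-6, 12), pairs)
  meas$flat <- stats::setNames(rnorm(12, 0, 0.05), pairs)
  res2 <- rank_and_compare(pred, meas)
  expect_false(res2$eligible[res2$protein == "flat"])
  # random measured values: p not systematically small
  meas_null <- lapply(pred[1:4], function(v) {
    stats::setNames(rnorm(12), names(v))
  })
  res3 <- rank_and_compare(pred[1:4], meas_null)
  expect_true(any(res3$p > 0.05))
})
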