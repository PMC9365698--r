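#' Simulate a two-phase arrayed binding screen
#'
#' Generates bait-by-prey absorbance matrices with the additive structure the
#' median-polish normalization targets: signal = overall + plate-row effect +
#' plate-column effect + pair effect + Gaussian noise. True pairs receive the
#' pair effect in both bait-prey orientations; promiscuous baits receive an
#' elevated signal against a random subset of partners (single orientation,
#' the nonspecific-binder phenotype). The secondary phase re-screens an
#' all-versus-all matrix restricted to proteins involved in planted pairs or
#' promiscuity plus random extras, with independent plate effects and noise.
#'
#' @param config a [sim_config()].
#' @return list with elements `primary` and `secondary` (matrices of class
#'   `signal_matrix` with a `phase` attribute) and `truth`
#'   (a [ground_truth()] carrying planted pairs, promiscuous proteins and
#'   log-uniform planted K_D values).
#' @export
generate_screen <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_proteins
    ids <- sprintf("P%03d", seq_len(n))

    all_pairs <- utils::combn(ids, 2L)
    idx <- sample(ncol(all_pairs), config$n_true_pairs)
    true_pairs <- pair_id(all_pairs[1L, idx], all_pairs[2L, idx])

    n_prom <- round(config$promiscuity_rate * n)
    promiscuous <- if (n_prom > 0) sample(ids, n_prom) else character()

    kd <- 10^stats::runif(length(true_pairs),
                          config$kd_log10_range[1L],
                          config$kd_log10_range[2L])
    names(kd) <- true_pairs

    truth <- ground_truth(true_pairs = true_pairs,
                          promiscuous_proteins = promiscuous,
                          planted_kd = kd)

    primary <- simulate_phase(ids, truth, config, phase = "primary")

    in_truth <- unique(unlist(strsplit(true_pairs, "--", fixed = TRUE)))
    pool <- setdiff(ids, c(in_truth, promiscuous))
    extras <- if (length(pool)) {
      sample(pool, min(length(pool), max(2L, round(0.2 * n))))
    } else {
      character()
    }
    sec_ids <- sort(unique(c(in_truth, promiscuous, extras)))
    secondary <- simulate_phase(sec_ids, truth, config, phase = "secondary")

    list(primary = primary, secondary = secondary, truth = truth)
  })
}

# one phase: additive plate effects + planted pair/promiscuity structure
simulate_phase <- function(ids, truth, config, phase) {
  n <- length(ids)
  layout <- config$plate_layout
  # proteins fill the plate row-major; bait row / prey column effects are the
  # effects of the plate row and column each protein occupies
  plate_row <- ((seq_len(n) - 1L) %/% layout[2L]) %% layout[1L] + 1L
  plate_col <- (seq_len(n) - 1L) %% layout[2L] + 1L
  row_shift <- stats::rnorm(layout[1L], 0, config$row_effect_sd)[plate_row]
  col_shift <- stats::rnorm(layout[2L], 0, config$col_effect_sd)[plate_col]

  m <- outer(row_shift, col_shift, `+`) +
    matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
  dimnames(m) <- list(ids, ids)

  for (pid in truth$true_pairs) {
    ab <- strsplit(pid, "--", fixed = TRUE)[[1L]]
    if (all(ab %in% ids)) {
      m[ab[1L], ab[2L]] <- m[ab[1L], ab[2L]] + config$effect_size
      m[ab[2L], ab[1L]] <- m[ab[2L], ab[1L]] + config$effect_size
    }
  }
  for (p in intersect(truth$promiscuous_proteins, ids)) {
    partners <- setdiff(ids, p)
    k <- round(config$promiscuous_partner_frac * length(partners))
    if (k > 0) {
      hit <- sample(partners, k)
      m[p, hit] <- m[p, hit] + config$promiscuous_effect
    }
  }
  signal_matrix(m, phase = phase)
}

#' Construct a screen signal matrix
#'
#' A plain numeric matrix (bait rows, prey columns, absorbance a.u., `NA`
#' allowed) tagged with the screening phase.
#'
#' @param values numeric matrix with unique dimnames per axis.
#' @param phase `"primary"` or `"secondary"`.
#' @return a `signal_matrix`.
#' @export
signal_matrix <- function(values, phase = c("primary", "secondary")) {
  phase <- match.arg(phase)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_config("signal matrix must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values)) ||
      anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop_config("signal matrix needs unique row (bait) and column (prey) ids")
  }
  if (any(is.infinite(values))) {
    stop_config("signal matrix entries must be finite or NA")
  }
  structure(values, phase = phase, class = c("signal_matrix", "matrix", "array"))
}
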