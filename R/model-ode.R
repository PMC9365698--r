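#' Integrate the law-of-mass-action doublet system to equilibrium
#'
#' Cell types collide and form doublets at a constant rate `k_c` and
#' dissociate at `k_off(i,j) = kappa / max(A(i,j), epsilon)`, inversely
#' proportional to the relative cell-pair affinity:
#' `dD_ij/dt = k_c F_i F_j - k_off_ij D_ij` for distinct types and
#' `dD_ii/dt = (1/2) k_c F_i^2 - k_off_ii D_ii` for homotypic doublets
#' (standard dimerization bookkeeping: the half factor on formation, and a
#' homotypic doublet returns two free cells). Free-cell frequencies are
#' eliminated by exact per-type conservation,
#' `F_i = init_i - sum_{j != i} D_ij - 2 D_ii`, so conservation holds to
#' machine precision throughout. All cells start unbound at the supplied
#' blood frequencies.
#'
#' Integration uses an adaptive exponential-Euler scheme: with the free-cell
#' frequencies frozen each doublet equation is linear, so the update
#' `D <- D_ss + (D - D_ss) exp(-k_off dt)` is exact per step and remains
#' stable for the stiff `kappa/epsilon` off-rates of non-interacting pairs.
#' The step size shrinks whenever free frequencies would change by more than
#' 20% (or go negative) and grows geometrically otherwise. Once the
#' transient has decayed (relative rate below `sqrt(tol)`), the remaining
#' approach to equilibrium is completed by a damped Newton solve of the
#' mass-action fixed point in the free frequencies (the standard
#' run-to-steady-state strategy for stiff systems). Equilibrium is declared
#' when `max |dD/dt| / max(state)` drops below `config$tol`.
#'
#' @param A symmetric non-negative cell-pair affinity matrix
#'   (from [cell_pair_affinity()]).
#' @param init_freq named initial (all-unbound) frequencies per cell type.
#' @param config a [model_config()].
#' @return list of class `ode_state`: `F` (free frequencies), `D` (symmetric
#'   doublet matrix, diagonal = homotypic doublet frequency), `init_freq`,
#'   `residual` (max detailed-balance residual relative to the flux scale),
#'   `time`, `converged`.
#' @export
integrate_doublets <- function(A, init_freq, config = model_config()) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A < 0)) stop_config("affinities must be >= 0")
  n <- nrow(A)
  types <- rownames(A) %||% paste0("T", seq_len(n))
  init <- unname(init_freq[types] %||% init_freq)
  if (length(init) != n || any(init < 0)) {
    stop_config("init_freq must supply a non-negative frequency per type")
  }
  koff <- config$kappa / pmax(A, config$epsilon)
  half <- matrix(1, n, n); diag(half) <- 0.5
  cmat <- config$k_c / koff # equilibrium constants of doublet formation

  free_of <- function(D) init - (rowSums(D) - diag(D)) - 2 * diag(D)
  flux_scale <- max(config$k_c * outer(init, init)) + .Machine$double.xmin
  state_tol <- function(F, D) {
    max(max(F), max(D), .Machine$double.xmin)
  }

  # phase 1: exponential-Euler transient until the fast dynamics decay
  D <- matrix(0, n, n, dimnames = list(types, types))
  t_now <- 0
  dt <- 0.05 / max(config$k_c * max(init, 1e-300), 1e-300)
  coarse_tol <- max(sqrt(config$tol), config$tol)
  converged <- FALSE
  while (t_now < config$max_time) {
    F <- free_of(D)
    form <- config$k_c * half * outer(F, F)
    resid <- form - koff * D
    if (max(abs(resid)) / state_tol(F, D) < coarse_tol) break
    Dss <- form / koff
    Dnew <- Dss + (D - Dss) * exp(-koff * dt)
    Fnew <- free_of(Dnew)
    if (any(Fnew < -1e-12) ||
        max(abs(Fnew - F)) > 0.2 * max(max(F), 1e-300)) {
      dt <- dt / 2
      next
    }
    D <- Dnew
    t_now <- t_now + dt
    dt <- dt * 1.4
  }

  # phase 2: damped Newton on the fixed point in F
  # g_i(F) = F_i + sum_{j != i} c_ij F_i F_j + c_ii F_i^2 - init_i = 0,
  # with D_ij = c_ij F_i F_j (i != j) and D_ii = c_ii F_i^2 / 2.
  # (the homotypic doublet binds two cells of type i: 2 D_ii = c_ii F_i^2,
  #  so the conservation sum collapses to F_i * (C F)_i)
  F <- pmax(free_of(D), 0)
  g_of <- function(F) F + F * drop(cmat %*% F) - init
  for (newton in seq_len(200L)) {
    g <- g_of(F)
    if (max(abs(g)) < 1e-14 * max(init, 1) + config$tol^2) break
    J <- cmat * F # off-diagonal part: c_ik F_i
    diag(J) <- 1 + drop(cmat %*% F) + diag(cmat) * F
    step <- tryCatch(solve(J, g), error = function(e) g / diag(J))
    lambda <- 1
    repeat {
      F_try <- F - lambda * step
      if (all(F_try >= 0) && max(abs(g_of(F_try))) < max(abs(g))) {
        F <- F_try
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-12) break
    }
    if (lambda < 1e-12) break
  }
  D <- cmat * outer(F, F)
  diag(D) <- diag(cmat) * F^2 / 2
  dimnames(D) <- list(types, types)

  form <- config$k_c * half * outer(F, F)
  resid_rel <- max(abs(form - koff * D)) / state_tol(F, D)
  converged <- resid_rel < config$tol
  residual <- max(abs(form - koff * D)) / flux_scale
  if (!converged) {
    stop(errorCondition(
      "doublet integration did not reach equilibrium within max_time",
      class = c("iw_ode_error", "error"),
      state = list(F = stats::setNames(F, types), D = D, time = t_now)))
  }
  structure(list(F = stats::setNames(pmax(F, 0), types), D = D,
                 init_freq = stats::setNames(init, types),
                 residual = residual, time = t_now, converged = converged),
            class = "ode_state")
}

#' Interaction scores from an equilibrium doublet state
#'
#' Applies the same scoring equation used for the microscopy cell tables to
#' the model state. Contacts are doublets: the count of type-B cells "around"
#' type-A cells is `D_AB` for distinct types and `2 D_AA` for homotypic
#' pairs; the total contact count is `2 * sum(doublets)`; type fractions come
#' from the conserved initial frequencies. The score is
#' `specific / (f_A * f_B * total)`, so a system with uniform affinities
#' scores 1 everywhere.
#'
#' @param state an `ode_state` from [integrate_doublets()].
#' @return symmetric score matrix; all-`NA` with a `flagged` attribute when
#'   the state has no contacts.
#' @export
model_interaction_scores <- function(state) {
  D <- state$D
  n <- nrow(D)
  f <- state$init_freq / sum(state$init_freq)
  specific <- D
  diag(specific) <- 2 * diag(D)
  total <- 2 * (sum(D[upper.tri(D)]) + sum(diag(D)))
  if (total <= 0) {
    out <- matrix(NA_real_, n, n, dimnames = dimnames(D))
    attr(out, "flagged") <- "zero total contacts: scores undefined"
    return(out)
  }
  specific / (outer(f, f) * total)
}

#' In silico protein knockout
#'
#' Sets a protein's expression to zero across all cell types, rebuilds
#' densities, affinities, the equilibrium state and the score matrix, and
#' returns signed score changes against the baseline.
#'
#' @param densities cell_type x protein surface-density matrix.
#' @param network an [interaction_network()].
#' @param init_freq named initial frequencies.
#' @param protein_id protein to remove (must be a column of `densities`).
#' @param config a [model_config()].
#' @param baseline optional precomputed baseline result (list with `scores`)
#'   to avoid re-integration across repeated knockouts.
#' @return list with `delta` (perturbed - baseline scores), `abs_delta`,
#'   `baseline`, `perturbed` (each carrying `affinity`, `state`, `scores`).
#' @export
perturb_protein <- function(densities, network, init_freq, protein_id,
                            config = model_config(), baseline = NULL) {
  if (!(protein_id %in% colnames(densities))) {
    stop("unknown protein: ", protein_id, call. = FALSE)
  }
  run <- function(dens) {
    Aff <- cell_pair_affinity(dens, network, config)
    st <- integrate_doublets(Aff, init_freq, config)
    list(affinity = Aff, state = st, scores = model_interaction_scores(st))
  }
  if (is.null(baseline)) baseline <- run(densities)
  dens_ko <- densities
  dens_ko[, protein_id] <- 0
  perturbed <- run(dens_ko)
  delta <- perturbed$scores - baseline$scores
  list(delta = delta, abs_delta = abs(delta),
       baseline = baseline, perturbed = perturbed)
}

#' Compare predicted and measured perturbation magnitudes
#'
#' Implements the top-third prediction test: per protein, the cell pairs in
#' the top `top_fraction` of predicted |change| are contrasted with the
#' remaining pairs, and the measured |changes| of the two groups are compared
#' by a one-sided Welch t-test (alternative: predicted-top pairs show greater
#' measured change). Proteins whose prediction maximum falls below one fifth
#' of the median prediction maximum across proteins are excluded as
#' ineligible (the model predicts no meaningful perturbation for them).
#' p-values are Benjamini-Hochberg adjusted across tested proteins.
#'
#' @param predicted named list (per protein) of predicted score changes over
#'   cell pairs (named numeric vectors; signs ignored).
#' @param measured named list (per protein) of measured changes over the
#'   same cell-pair names.
#' @param top_fraction fraction of cell pairs forming the predicted-top
#'   group.
#' @param eligibility_fraction eligibility bound relative to the median
#'   prediction maximum.
#' @return data.frame per protein: `protein`, `eligible`, `n_top`, `n_rest`,
#'   `t`, `p`, `p_bh`, `status`.
#' @export
rank_and_compare <- function(predicted, measured, top_fraction = 1 / 3,
                             eligibility_fraction = 1 / 5) {
  proteins <- intersect(names(predicted), names(measured))
  pred_max <- vapply(predicted[proteins], function(v) max(abs(v)), numeric(1))
  bound <- eligibility_fraction * stats::median(pred_max)
  rows <- lapply(proteins, function(pr) {
    pv <- abs(predicted[[pr]])
    mv <- abs(measured[[pr]][names(pv)])
    eligible <- pred_max[[pr]] >= bound
    n_top <- max(1L, round(top_fraction * length(pv)))
    top_pairs <- names(sort(pv, decreasing = TRUE))[seq_len(n_top)]
    in_top <- names(pv) %in% top_pairs
    if (!eligible || sum(in_top) < 2L || sum(!in_top) < 2L) {
      status <- if (!eligible) "ineligible: below one-fifth of median maximum"
                else "skipped: <2 pairs per group"
      return(data.frame(protein = pr, eligible = eligible,
                        n_top = sum(in_top), n_rest = sum(!in_top),
                        t = NA_real_, p = NA_real_, status = status,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(mv[in_top], mv[!in_top], alternative = "greater",
                        var.equal = FALSE)
    data.frame(protein = pr, eligible = TRUE, n_top = sum(in_top),
               n_rest = sum(!in_top), t = unname(tt$statistic),
               p = tt$p.value, status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  tested <- !is.na(out$p)
  out$p_bh[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  rownames(out) <- NULL
  out
}
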