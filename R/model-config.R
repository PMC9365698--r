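#' Kinetic model configuration
#'
#' Houses the unnamed constants of the connectivity model. `h` is the
#' confinement length of the 3D-to-2D dissociation-constant conversion
#' (`K_2D = K_D * N_A * h`, molecules per um^2); the default 0.01 um gives
#' roughly 6 molecules/um^2 per uM of 3D K_D. `k_c` is the constant cell
#' collision rate, `kappa` the dissociation-rate scale (the off rate of a
#' cell pair is `kappa / max(A, epsilon)`, inversely proportional to the
#' relative cell-pair affinity A), and `epsilon` a numerical floor
#' preventing division by zero. Only relative (rank/ratio) connectivity
#' claims depend on these constants; at equilibrium results depend on
#' `k_c` and `kappa` only through their ratio.
#'
#' @param h confinement length, um.
#' @param k_c collision rate, per (frequency * time).
#' @param kappa dissociation scale, per time.
#' @param epsilon affinity floor (dimensionless guard).
#' @param tol equilibrium tolerance: integration stops when
#'   `max |dD/dt| / max(state)` falls below `tol`.
#' @param max_time pseudo-time budget before a non-convergence error.
#' @return a `model_config` list.
#' @export
model_config <- function(h = 0.01, k_c = 1, kappa = 1, epsilon = 1e-12,
                         tol = 1e-6, max_time = 1e7) {
  for (f in c("h", "k_c", "kappa", "epsilon")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop_config("configuration error: ", f, " must be > 0")
    }
  }
  structure(list(h = h, k_c = k_c, kappa = kappa, epsilon = epsilon,
                 tol = tol, max_time = max_time), class = "model_config")
}

#' Cell geometry and blood-frequency table
#'
#' @param df data.frame with columns `cell_type`, `radius_um`,
#'   `blood_frequency` and optional `subtype_of`, `proportion`.
#' @return validated data.frame of class `cell_geometry`.
#' @export
cell_geometry <- function(df) {
  stopifnot(all(c("cell_type", "radius_um", "blood_frequency") %in% names(df)))
  if (any(df$radius_um <= 0)) stop_config("geometry error: radius must be > 0")
  if (any(df$blood_frequency < 0)) {
    stop_config("geometry error: frequencies must be >= 0")
  }
  top <- if (is.null(df$subtype_of)) df else df[is.na(df$subtype_of), ]
  if (sum(top$blood_frequency) > 1 + 1e-9) {
    stop_config("geometry error: frequencies must sum to <= 1")
  }
  class(df) <- c("cell_geometry", "data.frame")
  df
}

#' Convert protein copies per cell to surface density
#'
#' Assumes all protein sits on an approximately spherical cell surface:
#' `rho = copies / (4 * pi * radius^2)`.
#'
#' @param copies_per_cell copies per cell (>= 0).
#' @param radius_um cell radius, um.
#' @return density in molecules per um^2.
#' @export
counts_to_density <- function(copies_per_cell, radius_um) {
  if (any(radius_um <= 0)) stop_config("radius must be > 0")
  if (any(copies_per_cell < 0)) stop_config("copies must be >= 0")
  copies_per_cell / (4 * pi * radius_um^2)
}

#' Merge expression subtypes into parent cell types
#'
#' Parent expression is the proportion-weighted average of its constituent
#' subtypes (e.g. merging NK dim/bright into a total NK population).
#' Proportions that do not sum to 1 within a parent are renormalized with a
#' warning.
#'
#' @param expr_values subtype x protein numeric matrix.
#' @param subtype_table data.frame with `subtype`, `parent`, `proportion`.
#' @return parent x protein matrix.
#' @export
merge_subtypes <- function(expr_values, subtype_table) {
  stopifnot(all(subtype_table$subtype %in% rownames(expr_values)))
  parents <- unique(subtype_table$parent)
  out <- matrix(0, length(parents), ncol(expr_values),
                dimnames = list(parents, colnames(expr_values)))
  for (p in parents) {
    sub <- subtype_table[subtype_table$parent == p, , drop = FALSE]
    w <- sub$proportion
    if (abs(sum(w) - 1) > 1e-9) {
      warning("subtype proportions for ", p, " sum to ", signif(sum(w), 4),
              "; renormalizing")
      w <- w / sum(w)
    }
    out[p, ] <- drop(w %*% expr_values[sub$subtype, , drop = FALSE])
  }
  out
}

# 3D molar K_D -> 2D density units (molecules / um^2); 1 L = 1e15 um^3
kd_to_2d <- function(kd_molar, h) {
  kd_molar * 6.02214076e23 / 1e15 * h
}

#' Equilibrium bound density of one receptor-ligand interaction
#'
#' Saturation (Michaelis-Menten) occupancy on surface densities:
#' `B = rho_rec * rho_lig / (K_2D + rho_lig)` with
#' `K_2D = K_D * N_A * h`. Because the network is undirected the
#' receptor/ligand role assignment is symmetrized by averaging both
#' directions.
#'
#' With `symmetrize = FALSE` the directional kernel is returned, for which
#' the textbook identities hold exactly: `B = rho_rec / 2` at
#' `rho_lig = K_2D` (half saturation) and `B -> rho_rec` as
#' `rho_lig -> Inf` (saturation).
#'
#' @param rho_rec,rho_lig surface densities, molecules per um^2.
#' @param kd_molar dissociation constant, molar (> 0).
#' @param config a [model_config()].
#' @param symmetrize average over both receptor/ligand role assignments.
#' @return bound density, molecules per um^2.
#' @export
bound_density <- function(rho_rec, rho_lig, kd_molar, config = model_config(),
                          symmetrize = TRUE) {
  if (any(kd_molar <= 0)) stop_config("kd must be > 0")
  if (any(rho_rec < 0) || any(rho_lig < 0)) stop_config("densities must be >= 0")
  k2d <- kd_to_2d(kd_molar, config$h)
  b <- rho_rec * rho_lig / (k2d + rho_lig)
  if (!symmetrize) return(b)
  (b + rho_lig * rho_rec / (k2d + rho_rec)) / 2
}

#' Relative cell-pair affinity matrix
#'
#' For each pair of cell types the affinities of all shared network
#' interactions are summed: every edge contributes the symmetrized bound
#' density computed from the first protein's density on one cell and the
#' second's on the other, in both assignments. Edges lacking a measured K_D
#' default to 1 uM (the low-micromolar centre of the affinity distribution)
#' and are flagged in the `defaulted_kd` attribute.
#'
#' @param densities cell_type x protein surface-density matrix
#'   (molecules per um^2).
#' @param network an [interaction_network()].
#' @param config a [model_config()].
#' @param default_kd K_D used for unannotated edges, molar.
#' @return symmetric cell_type x cell_type affinity matrix (summed bound
#'   densities, used relatively).
#' @export
cell_pair_affinity <- function(densities, network, config = model_config(),
                               default_kd = 1e-6) {
  types <- rownames(densities)
  A <- matrix(0, length(types), length(types), dimnames = list(types, types))
  defaulted <- character()
  for (e in seq_len(nrow(network))) {
    p <- network$protein_a[e]; q <- network$protein_b[e]
    if (!(p %in% colnames(densities)) || !(q %in% colnames(densities))) next
    kd <- network$kd[e]
    if (is.na(kd)) {
      kd <- default_kd
      defaulted <- c(defaulted, network$pair[e])
    }
    term <- outer(densities[, p], densities[, q],
                  function(rp, rq) bound_density(rp, rq, kd, config))
    A <- A + if (p == q) term else (term + t(term))
  }
  A <- (A + t(A)) / 2 # exact symmetry against rounding
  attr(A, "defaulted_kd") <- unique(defaulted)
  A
}
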