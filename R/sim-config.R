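#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the generators with defaults chosen to match the
#' statistical structure the downstream analysis assumes: additive plate
#' row/column effects plus Gaussian noise over planted true binder pairs, a
#' minority of promiscuous baits, cell-type-structured expression with
#' activation fold changes, and log-spread micromolar dissociation constants.
#'
#' @param n_proteins number of proteins in the screen library.
#' @param n_true_pairs number of planted true interacting pairs.
#' @param plate_layout integer `c(rows, cols)` of the plate grid used to
#'   assign shared row/column batch effects to baits and preys.
#' @param effect_size absorbance added to both orientations of a true pair
#'   (a.u.).
#' @param noise_sd Gaussian measurement noise sd (absorbance a.u.).
#' @param row_effect_sd,col_effect_sd sd of the additive plate row/column
#'   effects (absorbance a.u.).
#' @param promiscuity_rate fraction of proteins behaving as promiscuous
#'   (nonspecific) binders.
#' @param promiscuous_effect absorbance a promiscuous bait adds against each
#'   affected partner.
#' @param promiscuous_partner_frac fraction of partners a promiscuous bait
#'   reacts with (0.3: reproduces the recurrence-filter target phenotype).
#' @param n_cell_types number of cell types in expression matrices.
#' @param n_replicates bulk proteomics replicates per cell type and state.
#' @param activation_fold_range interval from which activation fold changes
#'   are drawn (applied up or down with equal probability).
#' @param activation_frac fraction of proteins regulated by activation.
#' @param expression_cv lognormal coefficient of variation of replicate noise.
#' @param kd_log10_range log10 molar interval for planted dissociation
#'   constants; the default `c(-7, -4)` centres the distribution in the low
#'   micromolar range with a long high-affinity tail.
#' @param seed integer seed; fixing it fixes every generated artifact.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 50L,
                       n_true_pairs = 10L,
                       plate_layout = c(16L, 24L),
                       effect_size = 2.0,
                       noise_sd = 0.1,
                       row_effect_sd = 0.05,
                       col_effect_sd = 0.05,
                       promiscuity_rate = 0.05,
                       promiscuous_effect = 1.5,
                       promiscuous_partner_frac = 0.3,
                       n_cell_types = 6L,
                       n_replicates = 4L,
                       activation_fold_range = c(2, 8),
                       activation_frac = 0.2,
                       expression_cv = 0.2,
                       kd_log10_range = c(-7, -4),
                       seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_true_pairs = as.integer(n_true_pairs),
    plate_layout = as.integer(plate_layout),
    effect_size = effect_size,
    noise_sd = noise_sd,
    row_effect_sd = row_effect_sd,
    col_effect_sd = col_effect_sd,
    promiscuity_rate = promiscuity_rate,
    promiscuous_effect = promiscuous_effect,
    promiscuous_partner_frac = promiscuous_partner_frac,
    n_cell_types = as.integer(n_cell_types),
    n_replicates = as.integer(n_replicates),
    activation_fold_range = as.numeric(activation_fold_range),
    activation_frac = activation_frac,
    expression_cv = expression_cv,
    kd_log10_range = as.numeric(kd_log10_range),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_proteins", "n_true_pairs", "n_cell_types", "n_replicates")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop_config("configuration error: ", f, " must be a count >= 1")
    }
  }
  if (length(cfg$plate_layout) != 2L || any(cfg$plate_layout < 1L)) {
    stop_config("configuration error: plate_layout must be positive rows x cols")
  }
  for (f in c("noise_sd", "row_effect_sd", "col_effect_sd")) {
    if (cfg[[f]] < 0) stop_config("configuration error: ", f, " must be >= 0")
  }
  if (cfg$promiscuity_rate < 0 || cfg$promiscuity_rate > 1) {
    stop_config("configuration error: promiscuity_rate must be in [0, 1]")
  }
  if (cfg$n_true_pairs > choose(cfg$n_proteins, 2)) {
    stop_config("configuration error: n_true_pairs exceeds number of distinct pairs")
  }
  if (diff(cfg$kd_log10_range) < 0 || any(!is.finite(cfg$kd_log10_range))) {
    stop_config("configuration error: kd_log10_range must be a finite interval")
  }
  if (any(cfg$activation_fold_range < 1) ||
      diff(cfg$activation_fold_range) < 0) {
    stop_config("configuration error: activation_fold_range must be >= 1 and ordered")
  }
  invisible(cfg)
}

#' Ground truth labels for synthetic fixtures
#'
#' @param true_pairs character vector of canonical pair ids (see [pair_id()]).
#' @param promiscuous_proteins character vector of protein ids.
#' @param planted_kd named numeric vector (molar), names = pair ids.
#' @param planted_cell_preferences matrix of association propensities over
#'   cell-type pairs (1 = random mixing).
#' @param zonated_pairs character vector of gene pair ids planted as
#'   spatially adjacent.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(true_pairs = character(),
                         promiscuous_proteins = character(),
                         planted_kd = numeric(),
                         planted_cell_preferences = NULL,
                         zonated_pairs = character()) {
  if (length(planted_kd) && any(planted_kd <= 0)) {
    stop_config("ground truth error: all planted K_D must be > 0")
  }
  if (!is.null(planted_cell_preferences) &&
      (any(!is.finite(planted_cell_preferences)) ||
       any(planted_cell_preferences < 0))) {
    stop_config("ground truth error: preferences must be finite and >= 0")
  }
  structure(list(
    true_pairs = true_pairs,
    promiscuous_proteins = promiscuous_proteins,
    planted_kd = planted_kd,
    planted_cell_preferences = planted_cell_preferences,
    zonated_pairs = zonated_pairs
  ), class = "ground_truth")
}
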