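#' Simulate cell-type-structured protein expression with activation states
#'
#' Produces bulk-style counts-per-cell matrices (cell types x proteins x
#' replicates) in a resting and an activated state. Each protein is expressed
#' in a random subset of cell types with a lognormal baseline; a planted
#' subset of proteins is up- or down-regulated by fold changes drawn from
#' `activation_fold_range`, applied across all expressing cell types.
#' Replicate noise is lognormal with coefficient of variation
#' `expression_cv`. A subtype table (proportions summing to 1 within each
#' parent type) accompanies the matrices for subtype-merging workflows.
#'
#' @param config a [sim_config()].
#' @param protein_ids optional protein id vector (defaults to the screen ids
#'   implied by `config$n_proteins`).
#' @return list with `resting` and `activated` (both [expression_matrix()] of
#'   modality `"bulk"`), `subtype_table`
#'   (data.frame subtype/parent/proportion), and `regulation` (data.frame of
#'   planted per-protein fold changes; fold > 1 up, < 1 down upon activation).
#' @export
generate_expression <- function(config = sim_config(), protein_ids = NULL) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, 2L), {
    ids <- protein_ids %||% sprintf("P%03d", seq_len(config$n_proteins))
    n_prot <- length(ids)
    types <- sprintf("CT%02d", seq_len(config$n_cell_types))

    # baseline mean counts/cell: lognormal across proteins, on/off structure
    base <- 10^stats::runif(n_prot, 2.5, 4.5)
    on <- matrix(stats::runif(config$n_cell_types * n_prot) < 0.6,
                 config$n_cell_types, n_prot)
    # guarantee each protein is expressed somewhere
    none <- colSums(on) == 0
    if (any(none)) on[cbind(sample(config$n_cell_types, sum(none), TRUE),
                            which(none))] <- TRUE
    mu <- sweep(on * 1.0, 2L, base, `*`)
    dimnames(mu) <- list(types, ids)

    n_reg <- round(config$activation_frac * n_prot)
    reg_idx <- if (n_reg > 0) sample(n_prot, n_reg) else integer()
    fold <- rep(1, n_prot)
    if (n_reg > 0) {
      f <- stats::runif(n_reg, config$activation_fold_range[1L],
                        config$activation_fold_range[2L])
      up <- stats::runif(n_reg) < 0.5
      fold[reg_idx] <- ifelse(up, f, 1 / f)
    }
    mu_act <- sweep(mu, 2L, fold, `*`)

    draw <- function(m) {
      sdlog <- sqrt(log(1 + config$expression_cv^2))
      arr <- array(0, dim = c(nrow(m), ncol(m), config$n_replicates),
                   dimnames = list(rownames(m), colnames(m),
                                   sprintf("rep%d", seq_len(config$n_replicates))))
      for (r in seq_len(config$n_replicates)) {
        noise <- matrix(stats::rlnorm(length(m), -sdlog^2 / 2, sdlog),
                        nrow(m), ncol(m))
        arr[, , r] <- m * noise
      }
      arr
    }

    resting <- expression_matrix(draw(mu), modality = "bulk", state = "resting")
    activated <- expression_matrix(draw(mu_act), modality = "bulk",
                                   state = "activated")

    # first parent type carries two subtypes (dim/bright-style 0.9/0.1 split)
    subtype_table <- data.frame(
      subtype = c(paste0(types[1L], c("_dim", "_bright")), types[-1L]),
      parent = c(types[1L], types[1L], types[-1L]),
      proportion = c(0.9, 0.1, rep(1, length(types) - 1L)),
      stringsAsFactors = FALSE
    )

    list(resting = resting, activated = activated,
         subtype_table = subtype_table,
         regulation = data.frame(protein = ids, fold = fold,
                                 regulated = seq_len(n_prot) %in% reg_idx,
                                 stringsAsFactors = FALSE))
  })
}

#' Construct an expression matrix container
#'
#' Bulk modality stores a 3-d array (cell types x proteins x replicates) of
#' counts per cell; single-cell modality stores a matrix of detection
#' fractions (share of cells with at least one read) in `[0, 1]`.
#'
#' @param values array (bulk) or matrix (single-cell) with dimnames.
#' @param modality `"bulk"` or `"single_cell"`.
#' @param state optional `"resting"` or `"activated"`.
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(values, modality = c("bulk", "single_cell"),
                              state = NULL) {
  modality <- match.arg(modality)
  if (modality == "bulk") {
    if (!is.array(values) || length(dim(values)) != 3L) {
      stop_config("bulk expression must be a cell_type x protein x replicate array")
    }
  } else {
    if (!is.matrix(values)) {
      stop_config("single-cell expression must be a cell_type x protein matrix")
    }
    if (any(values > 1 + 1e-12, na.rm = TRUE)) {
      stop_config("single-cell detection fractions must be <= 1")
    }
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_config("expression values must be >= 0")
  }
  structure(list(values = values, modality = modality, state = state),
            class = "expression_matrix")
}

#' Cell types covered by an expression matrix
#' @param expr an [expression_matrix()].
#' @return character vector of cell-type ids.
#' @export
expr_cell_types <- function(expr) {
  if (expr$modality == "bulk") dimnames(expr$values)[[1L]] else rownames(expr$values)
}

#' Per cell type mean expression across replicates
#' @param expr an [expression_matrix()].
#' @return cell_type x protein numeric matrix (detection fractions are
#'   returned as-is for single-cell modality).
#' @export
expr_means <- function(expr) {
  if (expr$modality == "bulk") apply(expr$values, c(1L, 2L), mean) else expr$values
}
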