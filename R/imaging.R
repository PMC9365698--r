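#' Find cell-cell contacts within a well
#'
#' Cells are scored as interacting when their nuclear centroids lie within a
#' Euclidean distance of `radius` pixels (inclusive). Contacts are found per
#' image site (they never span sites) and pooled over all sites of the well.
#'
#' @param cells data.frame for one well with columns `x`, `y`, `cell_type`
#'   and optionally `site` (single site assumed when absent).
#' @param radius contact radius in pixels.
#' @return data.frame of unordered contact pairs with columns `i`, `j`
#'   (row indices into `cells`), `type_i`, `type_j`.
#' @export
find_contacts <- function(cells, radius = 40) {
  if (is.null(cells$site)) cells$site <- 1L
  out <- lapply(split(seq_len(nrow(cells)), cells$site), function(idx) {
    if (length(idx) < 2L) return(NULL)
    d <- as.matrix(stats::dist(cells[idx, c("x", "y")]))
    hit <- which(d <= radius & upper.tri(d), arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(i = idx[hit[, 1L]], j = idx[hit[, 2L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(i = integer(), j = integer())
  }
  out$type_i <- cells$cell_type[out$i]
  out$type_j <- cells$cell_type[out$j]
  rownames(out) <- NULL
  out
}

#' Cell-cell interaction score
#'
#' `score = specific / (f_A * f_B * total)`: the count of type-B cells within
#' the contact radius around type-A cells, normalized by the product of the
#' two type fractions and the total contact count. Under random mixing the
#' expected score is 1 for every pair, including homotypic pairs.
#'
#' @param specific specific-interaction count.
#' @param f_a,f_b cell-type fractions of all cells (> 0).
#' @param total total interaction count (> 0).
#' @return the score, or flagged `NA` when the denominator is zero.
#' @export
interaction_score <- function(specific, f_a, f_b, total) {
  denom <- f_a * f_b * total
  if (!is.finite(denom) || denom <= 0) {
    return(structure(NA_real_, flagged = "undefined: zero denominator"))
  }
  specific / denom
}

#' Interaction scores for all cell-type pairs of one well
#'
#' The specific count of pair (A, B) is the number of B cells around A cells
#' over all contacts: `N_AB` for distinct types and `2 N_AA` for homotypic
#' pairs (each member of a homotypic contact counts around the other). The
#' total is the total directed contact count, `2 x` the number of contact
#' pairs. This makes the score matrix symmetric, calibrated to 1 under
#' random mixing, and identical in form to the model-state scoring.
#'
#' @param cells data.frame for one well (`x`, `y`, `cell_type`, optional
#'   `site`).
#' @param radius contact radius in pixels.
#' @param types cell-type universe (defaults to types present).
#' @return list with `scores` (symmetric matrix, `NA` where undefined),
#'   `specific`, `total`, `fractions`.
#' @export
well_interaction_scores <- function(cells, radius = 40, types = NULL) {
  types <- types %||% sort(unique(cells$cell_type))
  contacts <- find_contacts(cells, radius)
  frac <- table(factor(cells$cell_type, levels = types)) / nrow(cells)
  specific <- matrix(0, length(types), length(types),
                     dimnames = list(types, types))
  if (nrow(contacts)) {
    tab <- table(factor(contacts$type_i, levels = types),
                 factor(contacts$type_j, levels = types))
    undirected <- unclass(tab + t(tab)) # N_AB off-diagonal, 2*N_AA diagonal
    specific <- undirected
  }
  total <- 2 * nrow(contacts)
  scores <- matrix(NA_real_, length(types), length(types),
                   dimnames = list(types, types))
  for (a in types) for (b in types) {
    scores[a, b] <- interaction_score(specific[a, b], frac[[a]], frac[[b]],
                                      total)
  }
  list(scores = scores, specific = specific, total = total,
       fractions = stats::setNames(as.numeric(frac), types))
}

#' Interaction scores for every well of a cell table
#'
#' @param cell_table data.frame with `well`, `site`, `x`, `y`, `cell_type`.
#' @param radius contact radius in pixels.
#' @param types optional cell-type universe shared across wells.
#' @return data.frame `well`, `type_a`, `type_b`, `score` (one row per
#'   unordered pair), plus `is_control` when present in the input.
#' @export
score_cell_table <- function(cell_table, radius = 40, types = NULL) {
  types <- types %||% sort(unique(cell_table$cell_type))
  out <- lapply(split(cell_table, cell_table$well), function(w) {
    s <- well_interaction_scores(w, radius, types)$scores
    idx <- which(upper.tri(s, diag = TRUE), arr.ind = TRUE)
    data.frame(well = w$well[1L],
               type_a = types[idx[, 1L]], type_b = types[idx[, 2L]],
               score = s[idx],
               is_control = if (!is.null(w$is_control)) w$is_control[1L] else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Normalize an observed value against its control average
#'
#' `(obs - ctrl) / max(obs, ctrl)`: bounded in `[-1, 1]`, 0 means no change
#' relative to control. The convention for `obs = ctrl = 0` is 0 (flagged).
#'
#' @param observed,control_mean non-negative values (vectorized).
#' @return normalized values in `[-1, 1]`.
#' @export
normalize_to_control <- function(observed, control_mean) {
  if (any(observed < 0 | control_mean < 0, na.rm = TRUE)) {
    stop_config("normalization inputs must be >= 0")
  }
  denom <- pmax(observed, control_mean)
  out <- ifelse(denom > 0, (observed - control_mean) / denom, 0)
  attr(out, "flagged") <- which(denom == 0)
  out
}

#' Test condition effects against controls with FDR control
#'
#' For every unit (a condition x cell-pair stratum assembled by the caller,
#' e.g. per dose or dose-aggregated), the raw per-replicate values are
#' compared against the matched control replicates by a two-sided Welch's
#' t-test; the control-normalized effect size is reported alongside.
#' p-values are Benjamini-Hochberg adjusted across all tested units and
#' flagged significant at the given false discovery rate (default 10%).
#' Units can be excluded up front by a minimum-cell-count filter for rare
#' populations.
#'
#' @param values data.frame with columns `unit`, `value`, `role`
#'   (`"condition"` or `"control"`), optional `n_cells`.
#' @param fdr false-discovery-rate threshold.
#' @param min_cells drop units whose median `n_cells` falls below this.
#' @return data.frame per unit: raw means, `normalized` effect in `[-1, 1]`,
#'   `t`, `p`, `p_bh`, `significant`, `status`.
#' @export
test_effects <- function(values, fdr = 0.10, min_cells = 0) {
  stopifnot(all(c("unit", "value", "role") %in% names(values)))
  rows <- lapply(split(values, values$unit), function(d) {
    cond <- d$value[d$role == "condition"]
    ctrl <- d$value[d$role == "control"]
    if (min_cells > 0 && !is.null(d$n_cells) &&
        stats::median(d$n_cells, na.rm = TRUE) < min_cells) {
      return(data.frame(unit = d$unit[1L], mean_condition = mean(cond),
                        mean_control = mean(ctrl), normalized = NA_real_,
                        t = NA_real_, p = NA_real_,
                        status = "excluded: below minimum cell count",
                        stringsAsFactors = FALSE))
    }
    if (length(cond) < 2L || length(ctrl) < 2L) {
      return(data.frame(unit = d$unit[1L], mean_condition = mean(cond),
                        mean_control = mean(ctrl), normalized = NA_real_,
                        t = NA_real_, p = NA_real_,
                        status = "skipped: <2 replicates per side",
                        stringsAsFactors = FALSE))
    }
    p <- tryCatch(
      stats::t.test(cond, ctrl, var.equal = FALSE),
      error = function(e) NULL # constant data: t-test undefined
    )
    data.frame(
      unit = d$unit[1L], mean_condition = mean(cond),
      mean_control = mean(ctrl),
      normalized = as.numeric(normalize_to_control(mean(cond), mean(ctrl))),
      t = if (is.null(p)) 0 else unname(p$statistic),
      p = if (is.null(p)) 1 else p$p.value,
      status = "ok", stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  tested <- !is.na(out$p)
  out$p_bh[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out$significant <- !is.na(out$p_bh) & out$p_bh < fdr
  rownames(out) <- NULL
  out
}
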