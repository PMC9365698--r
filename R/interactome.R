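#' Binarize expression into detected / not detected
#'
#' Single-cell modality: a protein is detected in a cell type when its
#' detection fraction is at least `sc_threshold` (the common 10% precedent;
#' the boundary is inclusive). Bulk modality: detected when expression is
#' non-zero in strictly more than half of the replicates (a literal
#' "majority of replicates").
#'
#' @param expr an [expression_matrix()].
#' @param sc_threshold single-cell detection-fraction threshold.
#' @return logical cell_type x protein matrix.
#' @export
binarize_expression <- function(expr, sc_threshold = 0.10) {
  if (!inherits(expr, "expression_matrix")) {
    stop("unknown modality: expression_matrix input required", call. = FALSE)
  }
  if (expr$modality == "single_cell") {
    expr$values >= sc_threshold
  } else {
    frac_nonzero <- apply(expr$values > 0, c(1L, 2L), mean)
    frac_nonzero > 0.5
  }
}

#' Read / construct an interaction network edge table
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`, optional
#'   `kd` (dissociation constant, molar) and `provenance`
#'   (screen/literature/both).
#' @return normalized data.frame of class `interaction_network` with a
#'   canonical `pair` column, duplicate edges removed.
#' @export
interaction_network <- function(edges) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(edges)))
  if (is.null(edges$kd)) edges$kd <- NA_real_
  if (is.null(edges$provenance)) edges$provenance <- "screen"
  if (any(!is.na(edges$kd) & edges$kd <= 0)) {
    stop_config("network error: K_D must be > 0 where present")
  }
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  out <- data.frame(protein_a = a, protein_b = b, pair = pair_id(a, b),
                    kd = edges$kd, provenance = edges$provenance,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$pair), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_network", "data.frame")
  out
}

#' Build the master cell-pair interaction key
#'
#' Iterates over all ordered pairs of cell types (including self-pairs) and
#' every network edge in both protein orderings: a row `(A, B, p, q)` is
#' emitted when `p` is detected on `A` and `q` is detected on `B`. The
#' enumeration automatically contains the symmetric mirror `(B, A, q, p)` of
#' every row. Edges detected for every cell pair are flagged `ubiquitous`
#' (display filtering); proteins in the network but absent from the
#' expression matrix are reported in the `unmapped` attribute, never silently
#' dropped.
#'
#' @param detected logical cell_type x protein matrix from
#'   [binarize_expression()].
#' @param network an [interaction_network()].
#' @return data.frame of class `interaction_key` with columns `cell_a`,
#'   `cell_b`, `protein_a`, `protein_b`, `pair`, `kd`, `ubiquitous`.
#' @export
build_interaction_key <- function(detected, network) {
  if (!nrow(network)) {
    warning("empty network: returning empty interaction key")
  }
  types <- rownames(detected)
  mapped <- network$protein_a %in% colnames(detected) &
    network$protein_b %in% colnames(detected)
  unmapped <- unique(c(network$protein_a, network$protein_b))
  unmapped <- setdiff(unmapped, colnames(detected))
  if (length(unmapped)) {
    warning("unmapped protein ids (reported, not dropped silently): ",
            paste(unmapped, collapse = ", "))
  }
  net <- network[mapped, , drop = FALSE]

  rows <- list()
  for (e in seq_len(nrow(net))) {
    p <- net$protein_a[e]; q <- net$protein_b[e]
    orders <- if (p == q) list(c(p, q)) else list(c(p, q), c(q, p))
    for (o in orders) {
      on_a <- types[detected[, o[1L]]]
      on_b <- types[detected[, o[2L]]]
      if (!length(on_a) || !length(on_b)) next
      g <- expand.grid(cell_a = on_a, cell_b = on_b,
                       stringsAsFactors = FALSE)
      g$protein_a <- o[1L]; g$protein_b <- o[2L]
      g$pair <- net$pair[e]; g$kd <- net$kd[e]
      rows[[length(rows) + 1L]] <- g
    }
  }
  key <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(cell_a = character(), cell_b = character(),
               protein_a = character(), protein_b = character(),
               pair = character(), kd = numeric(), stringsAsFactors = FALSE)
  }
  n_cell_pairs <- length(types)^2
  per_edge <- table(unique(key[, c("cell_a", "cell_b", "pair")])$pair)
  key$ubiquitous <- as.vector(per_edge[key$pair] == n_cell_pairs)
  rownames(key) <- NULL
  attr(key, "unmapped") <- unmapped
  class(key) <- c("interaction_key", "data.frame")
  key
}

#' Affinity profile of each cell-type pair
#'
#' For every unordered cell-type pair, collects the dissociation constants of
#' the distinct molecular interactions detected between the two cell types
#' (one entry per detected edge) and summarizes them by the log-scale
#' (geometric) mean alongside the arithmetic mean. Pairs with no
#' K_D-annotated rows are flagged.
#'
#' @param key an [build_interaction_key()] result.
#' @return list with `profiles` (named list of K_D vectors, molar) and
#'   `summary` (data.frame cell_a/cell_b/n_interactions/n_with_kd/
#'   mean_kd_log/mean_kd_arith/flagged).
#' @export
affinity_profile <- function(key) {
  cp <- pair_id(key$cell_a, key$cell_b)
  split_kd <- split(key[, c("pair", "kd")], cp)
  profiles <- lapply(split_kd, function(d) {
    d <- d[!duplicated(d$pair), , drop = FALSE]
    stats::setNames(d$kd, d$pair)
  })
  summary <- do.call(rbind, lapply(names(profiles), function(nm) {
    kd <- profiles[[nm]]
    kd_ok <- kd[!is.na(kd)]
    ab <- strsplit(nm, "--", fixed = TRUE)[[1L]]
    data.frame(cell_a = ab[1L], cell_b = ab[2L],
               n_interactions = length(kd), n_with_kd = length(kd_ok),
               mean_kd_log = if (length(kd_ok)) 10^mean(log10(kd_ok)) else NA_real_,
               mean_kd_arith = if (length(kd_ok)) mean(kd_ok) else NA_real_,
               flagged = length(kd_ok) == 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(profiles = profiles, summary = summary)
}

#' Activation affinity-switch test
#'
#' Classifies surface proteins as up- or down-regulated upon activation by a
#' fold change on mean counts (pseudocount 1) exceeding `fold_threshold` in
#' either direction, pools the binding affinities of every interaction each
#' classified protein participates in (multi-interaction proteins contribute
#' one K_D per interaction), and compares the up vs down log10 K_D sets per
#' cell type with a two-sided Welch's t-test, Holm-corrected across cell
#' types.
#'
#' @param resting,activated bulk [expression_matrix()] objects over the same
#'   cell types and proteins.
#' @param network an [interaction_network()] with K_D annotations.
#' @param fold_threshold fold-change bound (strictly greater than).
#' @return data.frame per cell type: `cell_type`, `n_up`, `n_down`,
#'   `t`, `p`, `p_holm`, `direction`, `status` (`"ok"` or
#'   `"skipped: <2 values in a group"`); attribute `sets` holds the pooled
#'   log10 K_D vectors.
#' @export
affinity_switch_test <- function(resting, activated, network,
                                 fold_threshold = 2) {
  types <- intersect(expr_cell_types(resting), expr_cell_types(activated))
  if (!length(types)) {
    stop_config("no cell types shared between resting and activated states")
  }
  mr <- expr_means(resting)[types, , drop = FALSE]
  ma <- expr_means(activated)[types, , drop = FALSE]
  fold <- (ma + 1) / (mr + 1)

  kd_of <- function(proteins) {
    rows <- network$protein_a %in% proteins | network$protein_b %in% proteins
    sub <- network[rows, , drop = FALSE]
    out <- numeric()
    for (e in seq_len(nrow(sub))) {
      hits <- sum(c(sub$protein_a[e], sub$protein_b[e]) %in% proteins)
      out <- c(out, rep(sub$kd[e], hits))
    }
    out[!is.na(out)]
  }

  res <- list()
  sets <- list()
  for (ct in types) {
    up <- colnames(fold)[fold[ct, ] > fold_threshold]
    down <- colnames(fold)[fold[ct, ] < 1 / fold_threshold]
    kd_up <- log10(kd_of(up))
    kd_down <- log10(kd_of(down))
    sets[[ct]] <- list(up = kd_up, down = kd_down)
    if (length(kd_up) < 2L || length(kd_down) < 2L) {
      res[[ct]] <- data.frame(cell_type = ct, n_up = length(kd_up),
                              n_down = length(kd_down), t = NA_real_,
                              p = NA_real_, direction = NA_character_,
                              status = "skipped: <2 values in a group",
                              stringsAsFactors = FALSE)
      next
    }
    tt <- stats::t.test(kd_up, kd_down, alternative = "two.sided",
                        var.equal = FALSE)
    res[[ct]] <- data.frame(
      cell_type = ct, n_up = length(kd_up), n_down = length(kd_down),
      t = unname(tt$statistic), p = tt$p.value,
      direction = if (mean(kd_up) < mean(kd_down)) {
        "activated shifts to stronger binding"
      } else {
        "activated shifts to weaker binding"
      },
      status = "ok", stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out$p_holm <- NA_real_
  tested <- !is.na(out$p)
  out$p_holm[tested] <- stats::p.adjust(out$p[tested], method = "holm")
  out <- out[, c("cell_type", "n_up", "n_down", "t", "p", "p_holm",
                 "direction", "status")]
  rownames(out) <- NULL
  attr(out, "sets") <- sets
  out
}
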