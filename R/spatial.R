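#' Quality-control filtering of spots and genes
#'
#' Keeps spots with total transcript counts between `min_counts` and
#' `max_counts` (inclusive bounds, published values 4,000-36,000), with
#' strictly fewer than `max_mito_frac` of reads from mitochondrial genes,
#' and with at least `min_genes` distinct genes detected. Genes must be
#' detected in at least `min_spots` spots (evaluated after spot filtering).
#'
#' @param grid a [spot_grid()].
#' @param min_counts,max_counts total-count bounds per spot.
#' @param max_mito_frac mitochondrial read-fraction bound (exclusive).
#' @param min_genes minimum distinct genes per spot.
#' @param min_spots minimum spots per gene (inclusive).
#' @return filtered `spot_grid`; removal counts in the `removed` attribute.
#' @export
qc_spots <- function(grid, min_counts = 4000, max_counts = 36000,
                     max_mito_frac = 0.20, min_genes = 2000, min_spots = 5) {
  stopifnot(inherits(grid, "spot_grid"))
  counts <- grid$counts
  total <- rowSums(counts)
  mito <- if (length(grid$mito_genes)) {
    rowSums(counts[, intersect(grid$mito_genes, colnames(counts)),
                   drop = FALSE])
  } else {
    rep(0, nrow(counts))
  }
  genes_per_spot <- rowSums(counts > 0)
  keep_spot <- total >= min_counts & total <= max_counts &
    (mito / pmax(total, 1)) < max_mito_frac & genes_per_spot >= min_genes
  counts <- counts[keep_spot, , drop = FALSE]
  keep_gene <- colSums(counts > 0) >= min_spots
  counts <- counts[, keep_gene, drop = FALSE]
  if (!nrow(counts) || !ncol(counts)) {
    stop("QC removed all spots or all genes", call. = FALSE)
  }
  out <- spot_grid(grid$spots[keep_spot, , drop = FALSE], counts,
                   mito_genes = intersect(grid$mito_genes, colnames(counts)))
  attr(out, "removed") <- c(spots = sum(!keep_spot), genes = sum(!keep_gene))
  out
}

#' Self-inclusive spot neighbour graph
#'
#' Spots within Euclidean distance `radius` (inclusive, ties at exactly the
#' radius are neighbours) are connected; every spot is also its own
#' neighbour, so same-spot co-expression counts as a pairing. The default
#' 150 coordinate units encompasses only immediately connected neighbouring
#' spots on the array.
#'
#' @param grid a [spot_grid()].
#' @param radius neighbour radius in coordinate units.
#' @return two-column integer matrix of spot-index pairings `(i, j)` with
#'   `i <= j` (class `spot_pairings`), including the self pairings.
#' @export
neighbor_graph <- function(grid, radius = 150) {
  xy <- as.matrix(grid$spots[, c("x", "y")])
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  adj <- d <= radius
  idx <- which(adj & upper.tri(adj, diag = FALSE), arr.ind = TRUE)
  out <- rbind(cbind(seq_len(n), seq_len(n)), idx)
  colnames(out) <- c("i", "j")
  structure(out[order(out[, 1L], out[, 2L]), , drop = FALSE],
            class = c("spot_pairings", "matrix", "array"))
}

#' Colocalization score of a receptor-ligand gene pair
#'
#' Fraction of spot pairings that are "interaction-capable": among all
#' neighbour pairings (including same-spot) in which both members express at
#' least one of the two genes (one count or more), the share where one
#' member expresses the first gene and the other the second. With
#' `denominator = "all"` the documented alternative is used: all neighbour
#' pairings tissue-wide.
#'
#' @param grid a (QC-filtered) [spot_grid()].
#' @param graph pairings from [neighbor_graph()].
#' @param gene_a,gene_b gene names; a gene absent from the grid scores 0
#'   with a `flagged` attribute.
#' @param denominator `"expressed"` (default) or `"all"`.
#' @return score in `[0, 1]`.
#' @export
colocalization_score <- function(grid, graph, gene_a, gene_b,
                                 denominator = c("expressed", "all")) {
  denominator <- match.arg(denominator)
  counts <- grid$counts
  if (!(gene_a %in% colnames(counts)) || !(gene_b %in% colnames(counts))) {
    return(structure(0, flagged = "gene absent from grid"))
  }
  ea <- counts[, gene_a] > 0
  eb <- counts[, gene_b] > 0
  i <- graph[, 1L]; j <- graph[, 2L]
  capable <- (ea[i] & eb[j]) | (eb[i] & ea[j])
  denom <- if (denominator == "all") {
    rep(TRUE, nrow(graph))
  } else {
    (ea[i] | eb[i]) & (ea[j] | eb[j])
  }
  if (!sum(denom)) {
    return(structure(0, flagged = "no expressing pairings"))
  }
  sum(capable & denom) / sum(denom)
}

#' Colocalization scores for every edge of a network
#'
#' @param grid,graph as in [colocalization_score()].
#' @param network an [interaction_network()] (or data.frame with
#'   `protein_a`, `protein_b`).
#' @param denominator passed through.
#' @return data.frame `pair`, `gene_a`, `gene_b`, `score`.
#' @export
colocalization_scores <- function(grid, graph, network,
                                  denominator = "expressed") {
  score <- mapply(function(a, b) {
    as.numeric(colocalization_score(grid, graph, a, b, denominator))
  }, network$protein_a, network$protein_b)
  data.frame(pair = pair_id(network$protein_a, network$protein_b),
             gene_a = network$protein_a, gene_b = network$protein_b,
             score = unname(score), stringsAsFactors = FALSE)
}

#' Permuted-pair null distribution of colocalization scores
#'
#' Keeps the same proteins as the true network but randomly permutes which
#' are paired together: the partner column is permuted and a draw is
#' rejected while any edge keeps its original partner (derangement-style
#' random matching over the edge multiset). Scores are recomputed for every
#' permuted edge.
#'
#' @param network an [interaction_network()] with at least 2 edges.
#' @param grid,graph as in [colocalization_score()].
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param denominator passed through.
#' @return list with `scores` (pooled permuted-pair scores),
#'   `per_perm_mean`, `n_perm`.
#' @export
permuted_null <- function(network, grid, graph, n_perm = 100L, seed = 1L,
                          denominator = "expressed") {
  if (nrow(network) < 2L) {
    stop("too few edges to permute partners", call. = FALSE)
  }
  if (n_perm < 1L) {
    return(list(scores = numeric(), per_perm_mean = numeric(), n_perm = 0L))
  }
  with_seed(seed, {
    all_scores <- vector("list", n_perm)
    for (k in seq_len(n_perm)) {
      tries <- 0L
      repeat {
        perm <- sample(nrow(network))
        if (!any(network$protein_b[perm] == network$protein_b)) break
        tries <- tries + 1L
        if (tries > 10000L) {
          stop("too few distinct partners to permute", call. = FALSE)
        }
      }
      permuted <- data.frame(protein_a = network$protein_a,
                             protein_b = network$protein_b[perm],
                             stringsAsFactors = FALSE)
      all_scores[[k]] <- colocalization_scores(grid, graph, permuted,
                                               denominator)$score
    }
    list(scores = unlist(all_scores),
         per_perm_mean = vapply(all_scores, mean, numeric(1)),
         n_perm = n_perm)
  })
}

#' Omnibus and pairwise comparison of colocalization score groups
#'
#' One-way ANOVA across the known / novel / permuted-null score sets,
#' followed by Tukey's honestly-significant-difference post-hoc test.
#' Degenerate (zero-variance) inputs are reported via `status` instead of
#' erroring.
#'
#' @param known_scores,novel_scores,null_scores numeric vectors (each of
#'   length >= 2).
#' @return list with `anova` (`F`, `p`, `df`), `tukey` (data.frame of
#'   pairwise adjusted p-values and mean differences), `status`.
#' @export
compare_groups <- function(known_scores, novel_scores, null_scores) {
  groups <- list(known = known_scores, novel = novel_scores,
                 null = null_scores)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  df <- data.frame(
    score = unlist(groups),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))))
  )
  if (stats::var(df$score) == 0) {
    return(list(anova = c(F = 0, p = 1), tukey = NULL,
                status = "degenerate: zero variance across all groups"))
  }
  fit <- stats::aov(score ~ group, data = df)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  list(
    anova = c(F = an$`F value`[1L], p = an$`Pr(>F)`[1L],
              df1 = an$Df[1L], df2 = an$Df[2L]),
    tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL,
                       stringsAsFactors = FALSE),
    status = "ok"
  )
}
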