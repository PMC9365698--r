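#' Weighted cell-type interaction graph from an interaction key
#'
#' Edge weight between two cell types = number of distinct detected
#' molecular interactions between them (undirected; self-edges kept for
#' homotypic pairs).
#'
#' @param key an [build_interaction_key()] result.
#' @return symmetric numeric matrix of interaction counts.
#' @export
interaction_count_graph <- function(key) {
  types <- sort(unique(c(key$cell_a, key$cell_b)))
  w <- matrix(0, length(types), length(types), dimnames = list(types, types))
  uniq <- unique(data.frame(a = pmin(key$cell_a, key$cell_b),
                            b = pmax(key$cell_a, key$cell_b),
                            pair = key$pair, stringsAsFactors = FALSE))
  tab <- table(pair_id(uniq$a, uniq$b))
  for (nm in names(tab)) {
    ab <- strsplit(nm, "--", fixed = TRUE)[[1L]]
    w[ab[1L], ab[2L]] <- tab[[nm]]
    w[ab[2L], ab[1L]] <- tab[[nm]]
  }
  w
}

#' Eigenvector centrality of a weighted undirected cell-type graph
#'
#' Principal-eigenvector centrality by power iteration (tolerance 1e-10 on
#' the max absolute change per iteration), normalized so the maximum
#' centrality is 1. Nodes outside the dominant connected component receive
#' centrality 0; fully isolated nodes additionally raise a warning.
#'
#' @param w symmetric non-negative weight matrix, or an interaction key
#'   (converted via [interaction_count_graph()]).
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return named centrality vector in `[0, 1]`.
#' @export
eigenvector_centrality <- function(w, tol = 1e-10, max_iter = 100000L) {
  if (inherits(w, "interaction_key")) w <- interaction_count_graph(w)
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (any(w < 0) || max(abs(w - t(w))) > 1e-12) {
    stop_config("centrality needs a symmetric non-negative weight matrix")
  }
  iso <- rowSums(w) == 0 & diag(w) == 0
  if (any(iso)) {
    warning("isolated cell type(s) assigned centrality 0: ",
            paste(rownames(w)[iso], collapse = ", "))
  }
  # diagonal shift: keeps eigenvectors, breaks the +/- lambda degeneracy of
  # bipartite graphs so power iteration cannot oscillate
  sigma <- 0.1 * max(rowSums(w))
  v <- rep(1, nrow(w))
  for (i in seq_len(max_iter)) {
    v_new <- drop(w %*% v) + sigma * v
    m <- max(abs(v_new))
    if (m == 0) {
      v <- v_new
      break
    }
    v_new <- v_new / m
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v <- pmax(v, 0)
  v[iso] <- 0
  if (max(v) > 0) v <- v / max(v)
  stats::setNames(v, rownames(w))
}

#' Compare myeloid centrality against other lineages across tissues
#'
#' Per tissue, a two-sided Welch's t-test of the centralities of myeloid
#' cell types against all other cell types; p-values corrected across
#' tissues by the Benjamini-Hochberg procedure.
#'
#' @param centralities data.frame with columns `tissue`, `cell_type`,
#'   `centrality`, `is_myeloid`.
#' @return data.frame per tissue with group means, `t`, `p`, `p_bh`,
#'   `status`.
#' @export
centrality_group_test <- function(centralities) {
  stopifnot(all(c("tissue", "cell_type", "centrality", "is_myeloid") %in%
                  names(centralities)))
  out <- lapply(split(centralities, centralities$tissue), function(d) {
    a <- d$centrality[d$is_myeloid]
    b <- d$centrality[!d$is_myeloid]
    if (length(a) < 2L || length(b) < 2L) {
      return(data.frame(tissue = d$tissue[1L], mean_myeloid = mean(a),
                        mean_other = mean(b), t = NA_real_, p = NA_real_,
                        status = "skipped: <2 cell types in a group",
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(tissue = d$tissue[1L], mean_myeloid = mean(a),
               mean_other = mean(b), t = unname(tt$statistic),
               p = tt$p.value, status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_bh <- NA_real_
  tested <- !is.na(out$p)
  out$p_bh[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  rownames(out) <- NULL
  out
}
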