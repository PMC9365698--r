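#' Sum polished signals across bait-prey orientations
#'
#' For each unordered protein pair the pair score is the sum of the polished
#' signals in the two measurement orientations, `s(a->b) + s(b->a)`;
#' homophilic pairs (a protein against itself) are doubled, `2 * s(a->a)`.
#' When only one orientation was measured the available value is used
#' un-doubled and the pair is flagged `single_orientation`; pairs with both
#' orientations missing are excluded (counted in the `n_excluded` attribute).
#'
#' @param polished residual matrix from [median_polish()], or a raw numeric
#'   matrix on a shared protein-id universe.
#' @return data.frame of class `pair_scores` with columns `protein_a`,
#'   `protein_b` (lexicographic order), `pair`, `score_ab`, `score_ba`,
#'   `combined`, `homophilic`, `single_orientation`.
#' @export
sum_orientations <- function(polished) {
  m <- if (is.list(polished)) polished$residuals else unclass(polished)
  ids <- sort(union(rownames(m), colnames(m)))
  full <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  full[rownames(m), colnames(m)] <- m

  comb <- utils::combn(length(ids), 2L)
  ai <- c(comb[1L, ], seq_along(ids))
  bi <- c(comb[2L, ], seq_along(ids))
  s_ab <- full[cbind(ai, bi)]
  s_ba <- full[cbind(bi, ai)]
  homophilic <- ai == bi

  combined <- ifelse(homophilic, 2 * s_ab, s_ab + s_ba)
  single <- xor(is.na(s_ab), is.na(s_ba)) & !homophilic
  combined[single] <- ifelse(is.na(s_ab[single]), s_ba[single], s_ab[single])

  keep <- !(is.na(s_ab) & is.na(s_ba))
  res <- data.frame(
    protein_a = ids[ai], protein_b = ids[bi],
    pair = pair_id(ids[ai], ids[bi]),
    score_ab = s_ab, score_ba = s_ba, combined = combined,
    homophilic = homophilic, single_orientation = single,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  res <- res[order(-res$combined, res$pair), ]
  rownames(res) <- NULL
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    message(n_excl, " pair(s) excluded: both orientations missing")
  }
  attr(res, "n_excluded") <- n_excl
  class(res) <- c("pair_scores", "data.frame")
  res
}

#' Select primary-screen hits for re-testing
#'
#' Pairs whose combined polished signal reaches `threshold` (the published
#' selection rule is "at least 1.0") are selected, after removing pairs that
#' involve a protein flagged as giving highly variable background. The flag
#' list is a manual input, mirroring how such proteins were identified.
#'
#' @param scores a `pair_scores` data.frame from [sum_orientations()].
#' @param threshold selection threshold on the combined score (a.u.).
#' @param background_proteins protein ids to exclude.
#' @return subset of `scores` (same columns), ordered by decreasing score.
#' @export
select_primary_hits <- function(scores, threshold = 1.0,
                                background_proteins = character()) {
  keep <- scores$combined >= threshold &
    !(scores$protein_a %in% background_proteins) &
    !(scores$protein_b %in% background_proteins)
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine primary- and secondary-screen scores
#'
#' Weighted sum valuing the lower-throughput secondary measurements
#' `secondary_weight` times more than the primary measurements (published
#' weight: 3). Pairs absent from the secondary screen keep their primary-only
#' score and are flagged `unconfirmed`.
#'
#' @param primary_scores,secondary_scores `pair_scores` data.frames.
#' @param secondary_weight non-negative weight on the secondary score.
#' @return data.frame with `pair`, `primary`, `secondary`, `combined`,
#'   `unconfirmed`, ordered by decreasing combined score (ties broken by
#'   pair id).
#' @export
combine_screens <- function(primary_scores, secondary_scores,
                            secondary_weight = 3) {
  if (!is.numeric(secondary_weight) || secondary_weight < 0) {
    stop_config("configuration error: secondary_weight must be >= 0")
  }
  sec <- stats::setNames(secondary_scores$combined, secondary_scores$pair)
  has_sec <- primary_scores$pair %in% names(sec)
  combined <- primary_scores$combined +
    ifelse(has_sec, secondary_weight * sec[primary_scores$pair], 0)
  out <- data.frame(
    pair = primary_scores$pair,
    protein_a = primary_scores$protein_a,
    protein_b = primary_scores$protein_b,
    primary = primary_scores$combined,
    secondary = ifelse(has_sec, sec[primary_scores$pair], NA_real_),
    combined = combined,
    homophilic = primary_scores$homophilic,
    unconfirmed = !has_sec,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$combined, out$pair), ]
  rownames(out) <- NULL
  out
}

#' Exclude promiscuous proteins by recurrence among top-ranked pairs
#'
#' A protein appearing more than `max_appearances` times among the
#' `top_n` highest-ranked pairs (published rule: more than 20 times in the
#' top 1,000) is excluded together with every pair it participates in. Ties
#' in the ranking are broken by lexicographic pair id so the cut is
#' deterministic. If fewer than `top_n` pairs exist the rule is applied to
#' all of them.
#'
#' @param scores data.frame with `pair`, `protein_a`, `protein_b` and a
#'   `combined` score column.
#' @param top_n size of the ranking window.
#' @param max_appearances exclusion bound (exclusive: exactly
#'   `max_appearances` appearances is kept).
#' @return list with `kept` (filtered scores), `excluded_proteins`, and
#'   `appearances` (named counts within the window).
#' @export
filter_promiscuous <- function(scores, top_n = 1000L, max_appearances = 20L) {
  ord <- order(-scores$combined, scores$pair)
  top <- scores[ord, , drop = FALSE][seq_len(min(top_n, nrow(scores))), ,
                                     drop = FALSE]
  counts <- table(c(top$protein_a, top$protein_b))
  excluded <- names(counts)[counts > max_appearances]
  keep <- !(scores$protein_a %in% excluded | scores$protein_b %in% excluded)
  kept <- scores[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded_proteins = excluded,
       appearances = as.integer(counts) |> stats::setNames(names(counts)))
}
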