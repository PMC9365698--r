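#' Reference interaction sets for benchmarking
#'
#' @param positives character vector of canonical pair ids with literature
#'   (or stringent quantitative/structural) support.
#' @param negatives character vector of pair ids, or `NULL` when
#'   `negative_mode = "random"`.
#' @param negative_mode `"measured"` (supplied negatives) or `"random"`
#'   (sampled reproducibly from the scored non-positive pairs).
#' @param negative_ratio size of the random negative set as a multiple of
#'   the positives.
#' @return a `reference_sets` list.
#' @export
reference_sets <- function(positives, negatives = NULL,
                           negative_mode = c("measured", "random"),
                           negative_ratio = 10) {
  negative_mode <- match.arg(negative_mode)
  positives <- unique(positives)
  if (negative_mode == "measured") {
    negatives <- unique(negatives)
    if (length(intersect(positives, negatives))) {
      stop_config("reference sets error: positives and negatives overlap")
    }
  }
  structure(list(positives = positives, negatives = negatives,
                 negative_mode = negative_mode,
                 negative_ratio = negative_ratio),
            class = "reference_sets")
}

#' Benchmark screen scores against reference interaction sets
#'
#' Every distinct score is evaluated as a classification threshold; the ROC
#' curve (FPR, TPR) and precision-recall curve are tabulated and the area
#' under the ROC curve computed by the trapezoid rule. With
#' `negative_mode = "random"`, negatives are drawn without replacement from
#' the scored non-positive pairs (`negative_ratio` times the number of
#' positives), seeded for reproducibility. If an expression-evidence flag is
#' supplied, pairs involving proteins without detectable recombinant
#' expression are dropped before evaluation.
#'
#' @param scores data.frame with `pair`, `protein_a`, `protein_b` and a
#'   `combined` column (pairs absent from the reference sets are ignored).
#' @param refs a [reference_sets()].
#' @param expressed optional character vector of proteins with expression
#'   evidence; `NULL` keeps all.
#' @param seed seed for random negative sampling.
#' @return list of class `benchmark_result` with `roc_points`
#'   (threshold/FPR/TPR), `pr_points` (threshold/recall/precision), `auc`,
#'   `n_positive`, `n_negative`.
#' @export
benchmark <- function(scores, refs, expressed = NULL, seed = 1L) {
  stopifnot(inherits(refs, "reference_sets"))
  df <- scores
  if (!is.null(expressed)) {
    df <- df[df$protein_a %in% expressed & df$protein_b %in% expressed, ,
             drop = FALSE]
  }
  pos <- intersect(refs$positives, df$pair)
  neg <- if (refs$negative_mode == "random") {
    pool <- setdiff(df$pair, refs$positives)
    n_draw <- min(length(pool), round(refs$negative_ratio * length(pos)))
    with_seed(seed, sample(pool, n_draw))
  } else {
    intersect(refs$negatives, df$pair)
  }
  if (!length(pos) || !length(neg)) {
    stop("benchmark error: empty positive or negative reference set",
         call. = FALSE)
  }
  s <- stats::setNames(df$combined, df$pair)
  roc_pr_points(score = c(s[pos], s[neg]),
                label = c(rep(TRUE, length(pos)), rep(FALSE, length(neg))))
}

# ROC / PR tabulation over all distinct score thresholds, trapezoid AUC
roc_pr_points <- function(score, label) {
  stopifnot(length(score) == length(label), !any(is.na(score)))
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]
  label <- label[ord]
  P <- sum(label)
  N <- sum(!label)
  # cut after each run of tied scores
  last_of_tie <- c(score[-length(score)] != score[-1L], TRUE)
  tp <- cumsum(label)[last_of_tie]
  fp <- cumsum(!label)[last_of_tie]
  thr <- score[last_of_tie]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  precision <- c(1, ifelse(tp + fp > 0, tp / (tp + fp), 1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(
    roc_points = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
    pr_points = data.frame(threshold = c(Inf, thr), recall = tpr,
                           precision = precision),
    auc = auc, n_positive = P, n_negative = N
  ), class = "benchmark_result")
}
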