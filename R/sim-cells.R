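#' Simulate imaging-derived cell tables with planted association preferences
#'
#' Emulates nuclear-centroid tables from high-content imaging. Cells are
#' placed uniformly at random in each well; for every cell-type pair with
#' association propensity above 1, extra partner cells are co-placed within
#' the contact radius of randomly chosen "seed" cells with probability
#' proportional to `(preference - 1)`. Propensity 1 therefore corresponds
#' exactly to random mixing (expected interaction score 1), and the expected
#' within-radius co-occurrence of a pair increases monotonically with its
#' planted preference. Control wells always use uniform preference 1.
#'
#' @param config a [sim_config()] (seed and `n_cell_types` are used when
#'   `preferences` is `NULL`).
#' @param preferences square numeric matrix of association propensities
#'   (dimnames = cell types, values >= 0, 1 = random mixing). `NULL` means
#'   uniform 1 over `config$n_cell_types` types.
#' @param n_wells number of condition wells.
#' @param n_control_wells number of control wells (uniform preferences).
#' @param cells_per_well baseline cells placed per well before co-placement.
#' @param well_size well side length in pixels.
#' @param contact_radius co-placement radius in pixels (the imaging contact
#'   radius).
#' @param co_rate scale linking `(preference - 1)` to the per-seed
#'   co-placement probability.
#' @param type_freq named cell-type frequencies (defaults to uniform).
#' @param n_sites image sites per well.
#' @param seed optional seed overriding `config$seed`.
#' @return data.frame with columns `well`, `site`, `x`, `y`, `cell_type`,
#'   `is_control`.
#' @export
generate_cell_table <- function(config = sim_config(), preferences = NULL,
                                n_wells = 10L, n_control_wells = 2L,
                                cells_per_well = 300L, well_size = 1000,
                                contact_radius = 40, co_rate = 0.3,
                                type_freq = NULL, n_sites = 1L, seed = NULL) {
  if (is.null(preferences)) {
    types <- sprintf("CT%02d", seq_len(config$n_cell_types))
    preferences <- matrix(1, length(types), length(types),
                          dimnames = list(types, types))
  }
  types <- rownames(preferences)
  if (is.null(types) || nrow(preferences) != ncol(preferences)) {
    stop_config("preferences must be a square matrix with cell-type dimnames")
  }
  if (any(!is.finite(preferences)) || any(preferences < 0)) {
    stop_config("preferences must be finite and >= 0")
  }
  if (is.null(type_freq)) {
    type_freq <- stats::setNames(rep(1 / length(types), length(types)), types)
  }
  type_freq <- type_freq / sum(type_freq)

  with_seed(seed %||% derive_seed(config$seed, 4L), {
    wells <- c(sprintf("W%02d", seq_len(n_wells)),
               if (n_control_wells > 0) sprintf("C%02d", seq_len(n_control_wells)))
    out <- vector("list", length(wells))
    for (w in seq_along(wells)) {
      is_control <- startsWith(wells[w], "C")
      pref <- if (is_control) {
        matrix(1, length(types), length(types), dimnames = dimnames(preferences))
      } else {
        preferences
      }
      per_site <- vector("list", n_sites)
      for (s in seq_len(n_sites)) {
        n0 <- cells_per_well
        df <- data.frame(
          x = stats::runif(n0, 0, well_size),
          y = stats::runif(n0, 0, well_size),
          cell_type = sample(types, n0, replace = TRUE, prob = type_freq),
          stringsAsFactors = FALSE
        )
        extra <- list()
        for (i in seq_along(types)) for (j in i:length(types)) {
          p_extra <- co_rate * max(pref[i, j] - 1, 0) * type_freq[j]
          if (p_extra <= 0) next
          seeds <- df[df$cell_type == types[i], , drop = FALSE]
          if (!nrow(seeds)) next
          take <- stats::runif(nrow(seeds)) < min(p_extra, 1)
          if (!any(take)) next
          ang <- stats::runif(sum(take), 0, 2 * pi)
          rad <- contact_radius * 0.75 * sqrt(stats::runif(sum(take)))
          extra[[length(extra) + 1L]] <- data.frame(
            x = pmin(pmax(seeds$x[take] + rad * cos(ang), 0), well_size),
            y = pmin(pmax(seeds$y[take] + rad * sin(ang), 0), well_size),
            cell_type = types[j], stringsAsFactors = FALSE
          )
        }
        if (length(extra)) df <- rbind(df, do.call(rbind, extra))
        df$site <- s
        per_site[[s]] <- df
      }
      df <- do.call(rbind, per_site)
      df$well <- wells[w]
      df$is_control <- is_control
      out[[w]] <- df[, c("well", "site", "x", "y", "cell_type", "is_control")]
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
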