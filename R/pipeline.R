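#' Default end-to-end run configuration
#'
#' Every stage parameter defaults to the published analysis setting:
#' selection threshold 1.0 a.u., secondary weight 3, promiscuity rule
#' >20 appearances in the top 1,000, single-cell detection threshold 10%,
#' fold-change threshold 2, neighbour radius 150 units, contact radius
#' 40 px, 100 permutations, FDR 10%, top-third prediction test with the
#' one-fifth-of-median eligibility rule.
#'
#' @param seed integer seed propagated (with derived sub-seeds) to every
#'   stage.
#' @param sim a [sim_config()] for the synthetic inputs.
#' @param ... overrides for individual parameters (must match existing
#'   names).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, sim = sim_config(seed = seed), ...) {
  cfg <- list(
    seed = as.integer(seed),
    sim = sim,
    selection_threshold = 1.0,
    secondary_weight = 3,
    top_n = 1000L,
    max_appearances = 20L,
    negative_ratio = 10,
    sc_threshold = 0.10,
    fold_threshold = 2,
    coloc_radius = 150,
    n_perm = 100L,
    contact_radius = 40,
    fdr = 0.10,
    top_fraction = 1 / 3,
    eligibility_fraction = 1 / 5,
    model = model_config()
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop_config("schema error: unknown run_config field(s): ",
                paste(bad, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  num_pos <- c("selection_threshold", "coloc_radius", "contact_radius")
  for (f in num_pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop_config("schema error: field '", f, "' must be a positive number")
    }
  }
  if (cfg$secondary_weight < 0) {
    stop_config("schema error: field 'secondary_weight' must be >= 0")
  }
  if (cfg$fdr <= 0 || cfg$fdr >= 1) {
    stop_config("schema error: field 'fdr' must be in (0, 1)")
  }
  invisible(cfg)
}

#' Load a run configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` or `.json`); keys mirror
#'   [run_config()] arguments, with `sim:` holding [sim_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim_args <- raw$sim %||% list()
  raw$sim <- NULL
  seed <- raw$seed %||% 1L
  raw$seed <- NULL
  sim_args$seed <- sim_args$seed %||% seed
  do.call(run_config,
          c(list(seed = seed, sim = do.call(sim_config, sim_args)), raw))
}

#' Run the full synthetic-data pipeline
#'
#' Executes the stages in dependency order: simulate (screen, expression,
#' spots, cell tables) -> screen processing (per-phase median polish,
#' orientation sums, selection, 3x-weighted combination, promiscuity filter,
#' benchmark against planted truth) -> interactome assembly (binarization,
#' interaction key, affinity profile, centrality) -> connectivity model
#' (densities, affinities, equilibrium, scores, one knockout) -> spatial
#' colocalization (QC, neighbour graph, true vs permuted-null scores) ->
#' imaging (well scores, control-normalized effects). All outputs are
#' written as TSV/JSON with a provenance header; identical config + seed
#' gives byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return manifest: named list of output paths (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("iw_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(
    package = paste0("immunowire ", as.character(utils::packageVersion("immunowire"))),
    seed = config$seed,
    config_hash = substr(jsonlite_hash(config), 1, 12)
  )
  paths <- list()
  emit <- function(name, x, file, row_names = FALSE) {
    p <- file.path(out_dir, file)
    write_tsv_provenance(x, p, prov, row_names = row_names)
    paths[[name]] <<- p
  }
  emit_json <- function(name, x, file) {
    p <- file.path(out_dir, file)
    jsonlite::write_json(c(list(.provenance = prov), x), p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[[name]] <<- p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(paste0("stage '", name, "' failed: ",
                                 conditionMessage(e)),
                          class = c("iw_stage_error", "error"), stage = name))
    })
  }

  # -- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    scr <- generate_screen(config$sim)
    expr <- generate_expression(config$sim)
    spots <- generate_spots(config$sim)
    types <- expr_cell_types(expr$resting)
    pref <- matrix(1, length(types), length(types),
                   dimnames = list(types, types))
    pref[1L, 2L] <- pref[2L, 1L] <- 3 # one planted association preference
    cells <- generate_cell_table(config$sim, pref)
    list(screen = scr, expr = expr, spots = spots, cells = cells,
         preferences = pref)
  })
  emit("cells", sim$cells, "cells.tsv")
  emit("screen_primary", as.data.frame(unclass(sim$screen$primary)),
       "screen_primary.tsv", row_names = TRUE)

  # -- screen processing ------------------------------------------------
  screen <- stage("screen", {
    pol_p <- median_polish(sim$screen$primary)
    pol_s <- median_polish(sim$screen$secondary)
    sc_p <- sum_orientations(pol_p$residuals)
    sc_s <- sum_orientations(pol_s$residuals)
    hits <- select_primary_hits(sc_p, config$selection_threshold)
    combined <- combine_screens(hits, sc_s, config$secondary_weight)
    filt <- filter_promiscuous(combined, config$top_n, config$max_appearances)
    refs <- reference_sets(sim$screen$truth$true_pairs,
                           negative_mode = "random",
                           negative_ratio = config$negative_ratio)
    bench <- benchmark(sc_p, refs, seed = derive_seed(config$seed, 11L))
    list(scores = sc_p, hits = hits, combined = combined, filt = filt,
         bench = bench)
  })
  emit("ranked_pairs", screen$filt$kept, "ranked_pairs.tsv")
  emit("roc_points", screen$bench$roc_points, "roc_points.tsv")
  emit_json("screen_summary", list(
    auc = screen$bench$auc,
    n_hits = nrow(screen$hits),
    excluded_promiscuous = screen$filt$excluded_proteins
  ), "screen_summary.json")

  # -- interactome assembly --------------------------------------------
  assembly <- stage("integrate", {
    net <- interaction_network(data.frame(
      protein_a = sub("--.*", "", screen$filt$kept$pair),
      protein_b = sub(".*--", "", screen$filt$kept$pair),
      kd = unname(sim$screen$truth$planted_kd[screen$filt$kept$pair]),
      provenance = "screen", stringsAsFactors = FALSE
    ))
    det <- binarize_expression(sim$expr$resting, config$sc_threshold)
    key <- build_interaction_key(det, net)
    prof <- affinity_profile(key)
    cent <- eigenvector_centrality(key)
    switch_res <- affinity_switch_test(sim$expr$resting, sim$expr$activated,
                                       net, config$fold_threshold)
    list(net = net, det = det, key = key, prof = prof, cent = cent,
         switch = switch_res)
  })
  emit("interaction_key", as.data.frame(assembly$key), "interaction_key.tsv")
  emit("affinity_summary", assembly$prof$summary, "affinity_summary.tsv")
  emit_json("centrality", as.list(assembly$cent), "centrality.json")
  emit("affinity_switch", assembly$switch, "affinity_switch.tsv")

  # -- connectivity model ----------------------------------------------
  model <- stage("model", {
    types <- expr_cell_types(sim$expr$resting)
    geometry <- cell_geometry(data.frame(
      cell_type = types,
      radius_um = seq(4, 8, length.out = length(types)),
      blood_frequency = rep(0.9 / length(types), length(types)),
      stringsAsFactors = FALSE
    ))
    means <- expr_means(sim$expr$resting)
    dens <- sweep(means, 1L, 4 * pi * geometry$radius_um^2, `/`)
    init <- stats::setNames(geometry$blood_frequency, types)
    aff <- cell_pair_affinity(dens, assembly$net, config$model)
    st <- integrate_doublets(aff, init, config$model)
    scores <- model_interaction_scores(st)
    ko_protein <- assembly$net$protein_a[1L]
    ko <- perturb_protein(dens, assembly$net, init, ko_protein, config$model,
                          baseline = list(affinity = aff, state = st,
                                          scores = scores))
    list(geometry = geometry, densities = dens, affinity = aff, state = st,
         scores = scores, ko = ko, ko_protein = ko_protein)
  })
  emit("affinity_matrix", as.data.frame(model$affinity),
       "affinity_matrix.tsv", row_names = TRUE)
  emit("model_scores", as.data.frame(model$scores), "model_scores.tsv",
       row_names = TRUE)
  emit("knockout_delta", as.data.frame(model$ko$delta), "knockout_delta.tsv",
       row_names = TRUE)

  # -- spatial colocalization ------------------------------------------
  coloc <- stage("coloc", {
    grid <- qc_spots(sim$spots$grid)
    graph <- neighbor_graph(grid, config$coloc_radius)
    zon <- sim$spots$truth$zonated_pairs
    net <- data.frame(protein_a = sub("--.*", "", zon),
                      protein_b = sub(".*--", "", zon),
                      stringsAsFactors = FALSE)
    true_scores <- colocalization_scores(grid, graph, net)
    null <- permuted_null(net, grid, graph, config$n_perm,
                          seed = derive_seed(config$seed, 12L))
    list(scores = true_scores, null = null)
  })
  emit("coloc_scores", coloc$scores, "coloc_scores.tsv")
  emit_json("coloc_null", list(per_perm_mean = coloc$null$per_perm_mean),
            "coloc_null.json")

  # -- imaging ----------------------------------------------------------
  imaging <- stage("imaging", {
    scores <- score_cell_table(sim$cells, config$contact_radius)
    cond <- scores[!scores$is_control, ]
    ctrl <- scores[scores$is_control, ]
    unit <- function(d) paste(d$type_a, d$type_b, sep = "--")
    vals <- rbind(
      data.frame(unit = unit(cond), value = cond$score, role = "condition"),
      data.frame(unit = unit(ctrl), value = ctrl$score, role = "control")
    )
    vals <- vals[is.finite(vals$value), ]
    effects <- test_effects(vals, fdr = config$fdr)
    list(scores = scores, effects = effects)
  })
  emit("well_scores", imaging$scores, "well_scores.tsv")
  emit("imaging_effects", imaging$effects, "imaging_effects.tsv")

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    c(list(.provenance = prov),
      lapply(paths, function(p) list(file = basename(p),
                                     md5 = unname(tools::md5sum(p))))),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- manifest_path
  invisible(paths)
}

# stable hash of a configuration for provenance headers
jsonlite_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
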