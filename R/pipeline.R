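#' Default pipeline configuration
#'
#' Every downstream default appears here exactly once; [run_pipeline()]
#' rejects unknown keys. Seeds for each stochastic stage are derived from the
#' single `seed` entry.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    nrows = 16L, ncols = 16L,
    n_continuous = 4L, n_categorical = 2L,
    correlation_length = 4,
    n_codes = 4L,
    n_species = 12L,
    n_sites = 200L,
    class_thresholds = c(0.1, 0.5),
    scenario = c(temp = 2.85, precip = -0.5),
    beta = 0.1,
    min_presences = 5L,
    sdm_scale = "raw",
    class_weights = DEFAULT_CLASS_WEIGHTS,
    weighting_convention = "normalized",
    allometric_mode = "printed",
    missing_fraction = 0.2,
    trait_sigma2 = 0.25,
    trait_root = c(SLA = log(15), CH = log(0.4), RD = log(0.4)),
    K = 5L,
    n_init = 10L,
    seed = 1L
  )
}

stage_seed <- function(seed, offset) (as.integer(seed) * 101L + offset) %% 2147483647L

#' Run the full synthetic trait-change pipeline
#'
#' Executes, in order: landscape simulation, species + occurrence simulation,
#' phylogeny + trait simulation, trait imputation, per-class maxent SDMs with
#' current and scenario projections, weighted-abundance combination, relative
#' biomass, k-means regionalization of species changes, and CWMT / categorical
#' change surfaces with regional summaries and species contributions for the
#' field and shrub layers. Any stage error aborts with the stage named.
#'
#' @param config list of overrides for [default_config()]; unknown keys are
#'   rejected before any stage runs.
#' @param out_dir optional directory; when given, key outputs are written
#'   (grids, CSVs, Newick, YAML) and a manifest of file checksums is returned.
#' @return list with the main objects of every stage plus (when `out_dir` is
#'   given) `manifest`, a data.frame of output files and md5 checksums.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  seed <- cfg$seed

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  env <- stage("simulate-landscape", generate_landscape(
    cfg$nrows, cfg$ncols, cfg$n_continuous, cfg$n_categorical,
    cfg$correlation_length, n_codes = cfg$n_codes, seed = stage_seed(seed, 1L)))
  env_future <- stage("apply-scenario", apply_scenario(env, cfg$scenario))

  truths <- stage("simulate-species", generate_species(
    env, cfg$n_species, seed = stage_seed(seed, 2L)))
  occ <- stage("sample-occurrences", sample_occurrences(
    truths, env, cfg$n_sites, cfg$class_thresholds, seed = stage_seed(seed, 3L)))

  ids <- vapply(truths, `[[`, character(1), "id")
  pfg <- stats::setNames(vapply(truths, `[[`, character(1), "pfg"), ids)
  tree <- stage("simulate-phylogeny", simulate_phylogeny(
    ids, seed = stage_seed(seed, 4L)))
  traits_raw <- stage("simulate-traits", simulate_traits(
    tree, sigma2 = cfg$trait_sigma2, root_state = unname(cfg$trait_root),
    missing_fraction = cfg$missing_fraction, pfg = pfg,
    seed = stage_seed(seed, 5L)))
  imp <- stage("impute-traits", impute_traits(traits_raw, tree))
  traits <- imp$traits

  sdms <- stage("fit-sdm", fit_all_sdms(
    occ, env, env_future, beta = cfg$beta,
    min_presences = cfg$min_presences, scale = cfg$sdm_scale))

  combine <- function(surfs) {
    weighted_abundance(surfs[[1L]], surfs[[2L]], surfs[[3L]],
                       weights = cfg$class_weights,
                       convention = cfg$weighting_convention)
  }
  fitted_sp <- names(sdms)[vapply(sdms, function(s) any(s$fitted), logical(1))]
  abund_cur <- stage("abundance", lapply(sdms[fitted_sp],
                                         function(s) combine(s$current)))
  abund_fut <- stage("abundance", lapply(sdms[fitted_sp],
                                         function(s) combine(s$future)))

  heights <- stats::setNames(traits$CH, traits$species_id)
  forms <- stats::setNames(ifelse(pfg[traits$species_id] == "tree",
                                  "tree", "non-tree"), traits$species_id)

  layers_out <- list()
  for (layer in c("field", "shrub")) {
    pool <- intersect(layer_pool(traits, layer), fitted_sp)
    if (length(pool) < 2) next
    sh_cur <- stage("biomass", relative_biomass(
      abund_cur[pool], heights, forms, mode = cfg$allometric_mode))
    sh_fut <- stage("biomass", relative_biomass(
      abund_fut[pool], heights, forms, mode = cfg$allometric_mode))
    res <- list(pool = pool, shares_current = sh_cur, shares_future = sh_fut)
    for (tr in c("SLA", "CH", "RD")) {
      tv <- stats::setNames(traits[[tr]], traits$species_id)
      res[[paste0("cwmt_", tr)]] <- list(
        current = cwmt(sh_cur, tv), future = cwmt(sh_fut, tv),
        delta = delta_surface(cwmt(sh_cur, tv), cwmt(sh_fut, tv)))
      res[[paste0("contrib_", tr)]] <-
        species_contribution(sh_cur, sh_fut, tv)
    }
    for (ct in c("leaf_persistence", "clonality", "mycorrhiza")) {
      if (!ct %in% names(traits)) next
      lv <- stats::setNames(traits[[ct]], traits$species_id)
      prof_cur <- categorical_profile(sh_cur, lv)
      prof_fut <- categorical_profile(sh_fut, lv)
      res[[paste0("profile_", ct)]] <- list(
        current = prof_cur, future = prof_fut,
        delta = delta_surface(prof_cur, prof_fut))
    }
    layers_out[[layer]] <- res
  }
  if (!length(layers_out)) stop("pipeline stage 'cwmt' failed: no layer pool with >= 2 fitted species")

  # regionalization over the pooled species changes of all computed layers
  all_cur <- do.call(c, unname(lapply(layers_out, `[[`, "shares_current")))
  all_fut <- do.call(c, unname(lapply(layers_out, `[[`, "shares_future")))
  keep <- !duplicated(names(all_cur))
  change <- stage("regions", build_change_matrix(all_cur[keep], all_fut[keep]))
  K_eff <- min(cfg$K, nrow(unique(change$X)))
  regions <- stage("regions", kmeans_regions(
    change$X, K = K_eff, n_init = cfg$n_init, seed = stage_seed(seed, 6L)))
  rgrid <- region_grid(regions, change)

  summaries <- list()
  for (layer in names(layers_out)) {
    for (tr in c("SLA", "CH", "RD")) {
      s <- regional_summary(layers_out[[layer]][[paste0("cwmt_", tr)]]$delta, rgrid)
      s$layer <- layer; s$trait <- tr
      summaries[[paste(layer, tr)]] <- s
    }
  }
  summaries <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))

  out <- list(config = cfg, env = env, env_future = env_future,
              truths = truths, occurrences = occ, tree = tree,
              traits = traits, imputation = imp$report, sdms = sdms,
              abundance_current = abund_cur, abundance_future = abund_fut,
              layers = layers_out, change = change, regions = regions,
              region_grid = rgrid, regional_summaries = summaries)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_env_stack(env, file.path(out_dir, "env_current"))
    write_env_stack(env_future, file.path(out_dir, "env_future"))
    utils::write.csv(occ, file.path(out_dir, "occurrences.csv"), row.names = FALSE)
    utils::write.csv(traits, file.path(out_dir, "traits_imputed.csv"), row.names = FALSE)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    write_scenario(scenario_delta(cfg$scenario), file.path(out_dir, "scenario.yml"))
    write_grid(rgrid, file.path(out_dir, "regions.asc"),
               cellsize = env$cellsize, origin = env$origin)
    utils::write.csv(summaries, file.path(out_dir, "regional_summaries.csv"),
                     row.names = FALSE)
    for (layer in names(layers_out)) {
      for (tr in c("SLA", "CH", "RD")) {
        write_grid(layers_out[[layer]][[paste0("cwmt_", tr)]]$delta,
                   file.path(out_dir, sprintf("%s__%s__delta.asc", layer, tr)),
                   cellsize = env$cellsize, origin = env$origin)
      }
    }
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    out$manifest <- data.frame(
      file = sub(paste0("^", out_dir, "/?"), "", files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE
    )
  }
  out
}
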