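#' Read a pipeline run configuration from YAML or JSON
#'
#' A run configuration names the inputs (real data paths or a `simulate`
#' block), the per-taxon breeding windows, and the tuning parameters of
#' every stage; a single master `seed` makes the whole run reproducible.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(cfg, class = c("run_config", "list"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full niche-evolution pipeline
#'
#' Executes occurrence preparation, ellipsoid niche modelling, pairwise
#' equivalency testing and bin-based ancestral reconstruction in order,
#' either on real inputs (`config$paths`) or on a simulated world
#' (`config$simulate`). Any stage error aborts with the stage name. Every
#' run is deterministic for a fixed config, and the returned `metadata`
#' records the config hash, the seeds used and the package version.
#'
#' @param config a `run_config` list (see [read_run_config()]); the
#'   recognised blocks are `simulate` (passed to [scenario_config()]) or
#'   `paths` (`occurrences`, `layers`, `areas`, `tree`), plus optional
#'   `windows`, `prep` (`max_uncert_km`, `thin_km`), `enm` (`inclusion`,
#'   `n_subsets`), `compare` (`n_reps`, `alpha`, `n_subsets`), `evolve`
#'   (`n_bins`, `trim`, `graft` = list(new_tip, sister)) and `seed`.
#' @param out_dir optional directory; when given, models (JSON), the
#'   score matrix and p-values (CSV), per-variable bin tables and node
#'   states (CSV) and the metadata block (JSON) are written there.
#' @return A list with `occurrences`, `prep_logs`, `models`,
#'   `comparisons` (a `score_matrix`), `reconstructions` (per variable),
#'   `tree`, `metadata`.
#' @export
run_all <- function(config, out_dir = NULL) {
  seed <- as.integer(config$seed %||% 1L)

  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- sim$seed %||% seed
      world <- make_world(do.call(scenario_config, sim))
      list(occ = world$occurrences, stack = world$stack,
           areas = world$areas, tree = world$tree)
    } else if (!is.null(config$paths)) {
      p <- config$paths
      for (f in c("occurrences", "layers", "areas", "tree"))
        if (is.null(p[[f]]) || !all(file.exists(p[[f]])))
          stop("missing input path for `", f, "`")
      occ_all <- read_occurrences(p$occurrences)
      list(occ = split(occ_all, occ_all$taxon),
           stack = read_env_stack(p$layers),
           areas = read_polygons(p$areas),
           tree = read_newick(p$tree))
    } else stop("config needs a `simulate` or `paths` block")
  })
  if (!is.null(config$variables))
    inputs$stack <- stage("inputs",
                          select_variables(inputs$stack, config$variables))
  taxa <- names(inputs$occ)
  inputs$occ <- lapply(inputs$occ, function(o) {
    class(o) <- c("occurrence_df", "data.frame"); o
  })

  prep_cfg <- config$prep %||% list()
  prepped <- stage("prep", lapply(taxa, function(tx)
    prep_occurrences(inputs$occ[[tx]], area = inputs$areas[[tx]],
                     windows = config$windows,
                     max_uncert_km = prep_cfg$max_uncert_km %||% 10,
                     thin_km = prep_cfg$thin_km, seed = seed)))
  names(prepped) <- taxa
  occ <- lapply(prepped, `[[`, "records")

  enm_cfg <- config$enm %||% list()
  models <- stage("enm", lapply(taxa, function(tx) {
    em <- extract_values(inputs$stack, occ[[tx]], taxon = tx)
    fit_mve(em, inclusion = enm_cfg$inclusion %||% 0.90,
            n_subsets = enm_cfg$n_subsets %||% 5000, seed = seed)
  }))
  names(models) <- taxa

  cmp_cfg <- config$compare %||% list()
  comparisons <- stage("compare",
    pairwise_matrix(models, inputs$areas, inputs$stack,
                    n_reps = cmp_cfg$n_reps %||% 100,
                    alpha = cmp_cfg$alpha %||% 0.05, seed = seed,
                    inclusion = enm_cfg$inclusion %||% 0.90,
                    n_subsets = cmp_cfg$n_subsets %||% 500))

  ev_cfg <- config$evolve %||% list()
  tree <- inputs$tree
  if (!is.null(ev_cfg$graft))
    tree <- stage("evolve", graft_taxon(tree, ev_cfg$graft$new_tip,
                                        ev_cfg$graft$sister))
  recon <- stage("evolve", {
    vars <- names(inputs$stack$layers)
    lapply(setNames(vars, vars), function(v) {
      sub <- select_variables(inputs$stack, v)
      occ_vals <- lapply(taxa, function(tx)
        extract_values(sub, occ[[tx]], taxon = tx)$values[, 1])
      m_vals <- lapply(taxa, function(tx)
        stack_values(sub, area_cells(sub, inputs$areas[[tx]]))[, 1])
      names(occ_vals) <- names(m_vals) <- taxa
      tab <- build_bin_table(occ_vals, m_vals,
                             n_bins = ev_cfg$n_bins %||% 20,
                             trim = ev_cfg$trim %||% 0.05, variable = v)
      reconstruct_bins(tab, tree)
    })
  })

  metadata <- list(
    config_hash = digest_config(config), seed = seed,
    package_version = as.character(utils::packageVersion("nichellipse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  out <- list(occurrences = occ,
              prep_logs = lapply(prepped, `[[`, "prep_log"),
              models = models, comparisons = comparisons,
              reconstructions = recon, tree = tree, metadata = metadata)
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

# order-independent config fingerprint without external digest packages
digest_config <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(js)) *
                        (seq_along(utf8ToInt(as.character(js))) %% 97 + 1)) %%
            .Machine$integer.max)
}

write_run_outputs <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tx in names(out$models))
    write_ellipsoid(out$models[[tx]],
                    file.path(dir, paste0("model_", tx, ".json")))
  write.csv(out$comparisons$p_values, file.path(dir, "comparisons.csv"),
            row.names = FALSE)
  write.csv(out$comparisons$scores, file.path(dir, "score_matrix.csv"))
  for (v in names(out$reconstructions))
    write.csv(out$reconstructions[[v]]$node_states,
              file.path(dir, paste0("node_states_", v, ".csv")))
  write_newick(out$tree, file.path(dir, "tree_used.nwk"))
  jsonlite::write_json(out$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
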