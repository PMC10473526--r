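#' Run the trait-network analysis pipeline from a configuration
#'
#' Orchestrates the stages end to end with reproducible seeding and file
#' contracts: `simulate` (synthetic trait panel), `impute` (PMM completion),
#' `transform` (skewness-guided normalisation), `structure` (fold-averaged
#' bootstrap Tabu/BIC network), `gp` (per-node GP fits), `intervene`
#' (do-intervention curves), `optimize` (ideotype batch), `heritability`
#' (raw vs residual table) and `gwas_sim` (mediated-pleiotropy power table).
#' Stages run in dependency order; each writes its artifacts plus a manifest
#' (parameters, derived seed, input checksums) into its own sub-directory,
#' and a JSON-lines log records stage, message and elapsed seconds. Every
#' stochastic stage derives its seed deterministically from the global seed
#' and the stage name, so rerunning an identical configuration reproduces
#' identical artifacts.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognised top-level fields: `seed` (integer), `outdir`, `group`
#'   (optional group filter, e.g. `"A"`), `stages` (character vector;
#'   default all), `input_csv` (trait-table CSV to start from instead of
#'   simulating), and one optional parameter block per stage (`simulate`,
#'   `impute`, `structure`, `gp`, `intervene`, `optimize`, `heritability`,
#'   `gwas_sim`).
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% stop("config$outdir is required")
  all_stages <- c("simulate", "impute", "transform", "structure", "gp",
                  "intervene", "optimize", "heritability", "gwas_sim")
  stages <- config$stages %||% all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]  # dependency order
  if (!is.null(config$input_csv) && !file.exists(config$input_csv)) {
    stop("input_csv not found: ", config$input_csv)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "log.jsonl")
  log_line <- function(stage, level, message, elapsed = NULL) {
    rec <- list(stage = stage, level = level, message = message)
    if (!is.null(elapsed)) rec$elapsed_s <- round(elapsed, 3)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }
  stage_seed <- function(stage) {
    (seed * 131L + match(stage, all_stages) * 7919L) %% .Machine$integer.max
  }
  manifest <- function(stage, params, inputs = character(0), outputs) {
    dir <- file.path(outdir, stage)
    inputs <- as.character(inputs[!vapply(inputs, is.null, logical(1L))])
    obj <- list(stage = stage, seed = stage_seed(stage), parameters = params,
                input_checksums = as.list(tools::md5sum(inputs)),
                outputs = outputs,
                package_version = as.character(utils::packageVersion("ideonet")))
    jsonlite::write_json(obj, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  state <- new.env(parent = emptyenv())

  get_table <- function() {
    if (!is.null(state$table)) return(state$table)
    if (is.null(config$input_csv)) stop("no trait table: run 'simulate' or set input_csv")
    tab <- read_trait_table(config$input_csv)
    if (!is.null(config$group)) tab <- trait_table_subset(tab, tab$group == config$group)
    state$table <- tab
    tab
  }

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    log_line(stage, "info", "stage started")
    dir <- file.path(outdir, stage)
    dir.create(dir, showWarnings = FALSE)
    ok <- tryCatch({
      run_stage(stage, config, state, dir, stage_seed(stage), get_table, manifest)
      TRUE
    }, error = function(e) {
      log_line(stage, "error", conditionMessage(e),
               proc.time()[["elapsed"]] - t0)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    if (ok) log_line(stage, "info", "stage completed",
                     proc.time()[["elapsed"]] - t0)
  }
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(stage, config, state, dir, sseed, get_table, manifest) {
  pars <- config[[stage]] %||% list()
  switch(stage,
    simulate = {
      spec <- if (is.null(pars$scm) || identical(pars$scm, "example")) {
        example_trait_network(
          n_varieties = pars$n_varieties %||% 94L,
          reps_per_variety = pars$reps_per_variety %||% 5L,
          missing_rate = pars$missing_rate %||% 0.05,
          group_coef_delta = pars$group_coef_delta %||% 0.2)
      } else scm_spec_from_list(pars$scm)
      sim <- generate_scm_table(spec, seed = sseed)
      if (spec$missing_rate > 0) {
        sim <- inject_missingness(sim, spec$missing_rate, seed = sseed + 1L)
      }
      tab <- sim$table
      if (!is.null(config$group)) tab <- trait_table_subset(tab, tab$group == config$group)
      state$table <- tab
      state$truth <- spec
      write_trait_table(tab, file.path(dir, "traits.csv"))
      write_scm_spec_json(spec, file.path(dir, "scm_spec.json"))
      manifest(stage, pars, outputs = c("traits.csv", "scm_spec.json"))
    },
    impute = {
      tab <- get_table()
      state$table <- impute_pmm(tab, donors = pars$donors %||% 5L,
                                n_iterations = pars$n_iterations %||% 5L,
                                seed = sseed)
      write_trait_table(state$table, file.path(dir, "traits_imputed.csv"))
      manifest(stage, pars, outputs = "traits_imputed.csv")
    },
    transform = {
      tab <- get_table()
      spec <- if (!is.null(pars$spec_yaml)) {
        read_transform_spec_yaml(pars$spec_yaml)
      } else select_transforms(tab)
      state$transforms <- spec
      state$table <- apply_transform(tab, spec)
      write_transform_spec_yaml(spec, file.path(dir, "transforms.yaml"))
      write_trait_table(state$table, file.path(dir, "traits_transformed.csv"))
      manifest(stage, pars,
               inputs = if (!is.null(pars$spec_yaml)) pars$spec_yaml else character(0),
               outputs = c("transforms.yaml", "traits_transformed.csv"))
    },
    structure = {
      tab <- get_table()
      constraints <- if (!is.null(pars$whitelist_csv) || !is.null(pars$blacklist_csv)) {
        read_edge_constraints(pars$whitelist_csv, pars$blacklist_csv,
                              tier_map = if (!is.null(state$truth)) state$truth$tiers)
      } else if (!is.null(state$truth)) {
        edge_constraints(tier_map = state$truth$tiers)
      } else edge_constraints()
      avg <- average_across_folds(tab, n_folds = pars$n_folds %||% 5L,
                                  constraints = constraints,
                                  replicates = pars$replicates %||% 500L,
                                  seed = sseed,
                                  strength_threshold = pars$strength_threshold %||% 0.5,
                                  consensus = pars$consensus %||% "majority")
      state$dag <- avg$consensus
      state$constraints <- constraints
      write_dag_json(avg$consensus, file.path(dir, "consensus_dag.json"))
      dag_to_dot(avg$consensus, file.path(dir, "consensus_dag.dot"))
      for (f in seq_along(avg$folds)) {
        write_dag_json(avg$folds[[f]], file.path(dir, sprintf("fold_%d_dag.json", f)))
      }
      manifest(stage, pars,
               inputs = c(pars$whitelist_csv, pars$blacklist_csv),
               outputs = c("consensus_dag.json", "consensus_dag.dot"))
    },
    gp = {
      tab <- get_table()
      if (is.null(state$dag)) stop("gp stage needs a learnt structure")
      cfg <- gp_sampler_config(mode = pars$mode %||% "mcmc",
                               chains = pars$chains %||% 4L,
                               warmup = pars$warmup %||% 1000L,
                               iter = pars$iter %||% 1000L,
                               seed = sseed)
      state$network <- fit_trait_network(state$dag, tab, cfg)
      diag <- lapply(state$network$node_models, function(m) {
        if (inherits(m, "gp_node_model")) m$diagnostics[c("mode", "converged")] else NULL
      })
      jsonlite::write_json(diag[!vapply(diag, is.null, logical(1L))],
                           file.path(dir, "gp_diagnostics.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      manifest(stage, pars, outputs = "gp_diagnostics.json")
    },
    intervene = {
      if (is.null(state$network)) stop("intervene stage needs fitted GP models")
      trait <- pars$trait %||% stop("intervene stage needs a trait")
      res <- do_intervene(state$network, trait,
                          n_grid = pars$n_grid %||% 20L,
                          n_draws = pars$n_draws %||% 1000L, seed = sseed)
      write_intervention_csv(res, file.path(dir, "intervention.csv"))
      manifest(stage, pars, outputs = "intervention.csv")
    },
    optimize = {
      if (is.null(state$network)) stop("optimize stage needs fitted GP models")
      props <- propose_ideotypes(state$network,
                                 yield = pars$yield,
                                 q = pars$q %||% 10L,
                                 constrained = pars$constrained %||% TRUE,
                                 threshold = pars$threshold %||% 0.95,
                                 restarts = pars$restarts %||% 50L,
                                 seed = sseed)
      write_ideotypes_csv(props, file.path(dir, "ideotypes.csv"))
      manifest(stage, pars, outputs = "ideotypes.csv")
    },
    heritability = {
      tab <- get_table()
      if (is.null(state$network)) stop("heritability stage needs fitted GP models")
      h2 <- heritability_table(tab, state$network)
      utils::write.csv(h2, file.path(dir, "heritability.csv"), row.names = FALSE)
      manifest(stage, pars, outputs = "heritability.csv")
    },
    gwas_sim = {
      grid <- if (!is.null(pars$grid)) as.data.frame(pars$grid) else
        expand.grid(gamma = c(0, 1, 3), sigma = c(0.1, 0.5))
      pw <- power_experiment(grid, n_reps = pars$n_reps %||% 50L,
                             n_plants = pars$n_plants %||% 200L,
                             seed = sseed)
      utils::write.csv(pw, file.path(dir, "power.csv"), row.names = FALSE)
      manifest(stage, pars, outputs = "power.csv")
    })
  invisible(NULL)
}
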