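#' End-to-end run configuration
#'
#' Bundles and validates everything a full atlas run needs. Every source of
#' randomness must be an explicit seed: the generator seed lives in
#' `generator`, the harness/fold-plan seed in `seed`.
#'
#' @param generator A [generator_config()] (or `NULL` with `cohort_path` +
#'   `hierarchy_path` to ingest files instead).
#' @param cohort_path,hierarchy_path Delimited-text inputs when not
#'   simulating.
#' @param exclusions An [exclusion_criteria()].
#' @param min_cases Minimum cases per phenotype.
#' @param missing_threshold Missingness filter threshold.
#' @param tau Altered-set threshold.
#' @param omega Jaccard weight of the composite similarity.
#' @param specs List of [model_spec()]s for the discrimination stage
#'   (`NULL` skips model fitting).
#' @param k,n_min,c_min Consensus parameters.
#' @param epv_threshold EPV flag threshold.
#' @param robustness_k Cluster counts for the statin-robustness ARI sweep.
#' @param seed Master seed for fold plans, bootstraps and attribution
#'   sampling.
#' @return A validated `run_config`.
#' @export
run_config <- function(generator = NULL, cohort_path = NULL,
                       hierarchy_path = NULL,
                       exclusions = exclusion_criteria(),
                       min_cases = 100, missing_threshold = 0.20,
                       tau = 0.5, omega = 0.5, specs = NULL,
                       k = 30, n_min = 10, c_min = 0.8,
                       epv_threshold = 5, robustness_k = 2:10, seed) {
  if (missing(seed)) rlang::abort("run_config(): `seed` must be given explicitly")
  if (is.null(generator)) {
    assert_that(!is.null(cohort_path) && !is.null(hierarchy_path),
                "provide either `generator` or cohort/hierarchy paths")
    for (p in c(cohort_path, hierarchy_path)) {
      assert_that(file.exists(p), paste0("input file not found: ", p))
    }
  } else {
    assert_that(inherits(generator, "generator_config"),
                "`generator` must come from generator_config()")
  }
  structure(list(generator = generator, cohort_path = cohort_path,
                 hierarchy_path = hierarchy_path, exclusions = exclusions,
                 min_cases = min_cases, missing_threshold = missing_threshold,
                 tau = tau, omega = omega, specs = specs, k = k,
                 n_min = n_min, c_min = c_min,
                 epv_threshold = epv_threshold, robustness_k = robustness_k,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML-style key-value text
#' @param config A `run_config` (only scalar + generator fields persist;
#'   model specs must be rebuilt in code).
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  flat <- config[c("min_cases", "missing_threshold", "tau", "omega", "k",
                   "n_min", "c_min", "epv_threshold", "seed")]
  flat$robustness_k <- config$robustness_k
  if (!is.null(config$generator)) {
    flat$generator <- unclass(config$generator)
  }
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- if (!is.null(y$generator)) {
    g <- y$generator
    g$region_weights <- unlist(g$region_weights)
    do.call(generator_config, g)
  } else NULL
  run_config(generator = gen, min_cases = y$min_cases,
             missing_threshold = y$missing_threshold, tau = y$tau,
             omega = y$omega, k = y$k, n_min = y$n_min, c_min = y$c_min,
             epv_threshold = y$epv_threshold,
             robustness_k = unlist(y$robustness_k), seed = y$seed)
}

#' ARI between two dendrograms over a sweep of cluster counts
#' @param a,b `similarity_atlas` or `linkage` objects over the same
#'   phenotypes.
#' @param ks Integer vector of cluster counts.
#' @return Tibble `k`, `ari`.
#' @export
ari_sweep <- function(a, b, ks = 2:10) {
  la <- if (inherits(a, "similarity_atlas")) a$linkage else a
  lb <- if (inherits(b, "similarity_atlas")) b$linkage else b
  ks <- ks[ks >= 1 & ks <= length(la$labels)]
  tibble::tibble(k = ks,
                 ari = purrr::map_dbl(ks, function(k)
                   adjustedRandIndexSafe(cut_partition(la, k),
                                         cut_partition(lb, k))))
}

adjustedRandIndexSafe <- function(a, b) adjusted_rand_index(a, b)

#' Ground-truth phenotype-group partition of a synthetic cohort
#' @param cohort A synthetic cohort carrying ground truth.
#' @param phenotypes Restrict to these phenotype codes (default: all).
#' @return Tibble `phenotype`, `cluster` (planted group as integer label).
#' @export
planted_partition <- function(cohort, phenotypes = NULL) {
  gt <- attr(cohort, "ground_truth")
  assert_that(!is.null(gt), "cohort carries no ground truth")
  pg <- gt$phenotype_groups
  if (!is.null(phenotypes)) {
    pg <- dplyr::filter(pg, .data$phenotype %in% phenotypes)
  }
  tibble::tibble(phenotype = pg$phenotype,
                 cluster = as.integer(factor(pg$group)))
}

#' Run the full atlas pipeline
#'
#' Stage order: generate/ingest, assembly, profiling, atlas, statin
#' robustness, discrimination + attribution consensus, parsimonious-subset
#' re-evaluation. Tabular outputs are written as TSV, the dendrogram as
#' Newick, and the manifest as JSON. Stages whose inputs (by config hash)
#' are unchanged can be resumed from the cache directory.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param stages Character subset of
#'   `c("cohort","assembly","profile","atlas","robustness","models")`.
#' @param resume Reuse cached stage outputs when the config hash matches.
#' @return A `run_manifest` list (config hash, per-stage hashes, package
#'   version, wall timestamps) with the stage outputs in `$artifacts`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("cohort", "assembly", "profile", "atlas",
                                    "robustness", "models"),
                         resume = TRUE) {
  assert_that(inherits(config, "run_config"),
              "`config` must come from run_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  cfg_hash <- rlang::hash(unclass(config))
  manifest <- list(config_hash = cfg_hash,
                   version = as.character(utils::packageVersion("metaboatlas")),
                   stages = list())
  art <- list()
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    cache <- file.path(cache_dir, paste0(name, "_", cfg_hash, ".rds"))
    if (resume && file.exists(cache)) {
      out <- readRDS(cache)
    } else {
      out <- tryCatch(fn(), error = function(e) {
        rlang::abort(paste0("pipeline stage `", name, "` failed: ",
                            conditionMessage(e)))
      })
      saveRDS(out, cache)
    }
    manifest$stages[[name]] <<- list(hash = rlang::hash(out),
                                     started = format(t0),
                                     finished = format(Sys.time()))
    out
  }

  if ("cohort" %in% stages) {
    art$cohort <- run_stage("cohort", function() {
      if (!is.null(config$generator)) generate_cohort(config$generator)
      else read_cohort(config$cohort_path,
                       read_hierarchy(config$hierarchy_path))
    })
  }
  if ("assembly" %in% stages) {
    art$assembly <- run_stage("assembly", function() {
      ex <- apply_exclusions(art$cohort, config$exclusions)
      validate_flow_arithmetic(ex$ledger)
      frame <- build_phenotype_frame(ex$cohort, min_cases = config$min_cases)
      readr::write_tsv(ex$ledger, file.path(out_dir, "flow_ledger.tsv"))
      long <- ex$cohort |>
        dplyr::select("participant_id", "phenotype_codes")
      readr::write_tsv(long, file.path(out_dir, "cohort_roles.tsv"))
      list(cohort = ex$cohort, ledger = ex$ledger, frame = frame)
    })
  }
  if ("profile" %in% stages) {
    art$profiles <- run_stage("profile", function() {
      pr <- compute_profiles(art$assembly$cohort, art$assembly$frame,
                             tau = config$tau)
      wide <- pr |>
        dplyr::select("phenotype", "feature", "mean_z") |>
        tidyr::pivot_wider(names_from = "feature", values_from = "mean_z")
      readr::write_tsv(wide, file.path(out_dir, "profiles_meanz.tsv"))
      pr
    })
  }
  if ("atlas" %in% stages) {
    art$atlas <- run_stage("atlas", function() {
      at <- composite_similarity(art$profiles, omega = config$omega)
      write_atlas(at, out_dir)
      at
    })
  }
  if ("robustness" %in% stages) {
    art$robustness <- run_stage("robustness", function() {
      adj <- build_atlas(art$assembly$cohort, art$assembly$frame,
                         tau = config$tau, omega = config$omega,
                         statin_adjust = TRUE)
      sweep <- ari_sweep(art$atlas, adj, config$robustness_k)
      readr::write_tsv(sweep, file.path(out_dir, "statin_ari_sweep.tsv"))
      list(adjusted_atlas = adj, ari = sweep)
    })
  }
  if ("models" %in% stages && !is.null(config$specs)) {
    art$models <- run_stage("models", function() {
      study <- run_consensus_study(art$assembly$cohort, art$assembly$frame,
                                   config$specs, seed = config$seed,
                                   k = config$k, n_min = config$n_min,
                                   c_min = config$c_min)
      res_tbl <- purrr::map(study$results, function(rs)
        dplyr::bind_rows(purrr::map(rs, tidy))) |> dplyr::bind_rows()
      readr::write_tsv(res_tbl, file.path(out_dir, "discrimination.tsv"))
      write_consensus(study$consensus, file.path(out_dir, "consensus.txt"))
      edges <- sankey_edges(study$tables, study$consensus)
      readr::write_tsv(edges, file.path(out_dir, "sankey_edges.tsv"))
      sel_met <- grep("^met_",
                      study$consensus$feature[study$consensus$selected],
                      value = TRUE)
      parsimonious <- NULL
      if (length(sel_met) >= 1) {
        p1 <- art$assembly$frame$phenotype[1]
        plan <- make_fold_plan(art$assembly$cohort, art$assembly$frame, p1,
                               seed = derive_seed(config$seed, "pars"))
        sp <- model_spec("xgboost", "metabolites",
                         grid = list(list(nrounds = 100, max_depth = 3,
                                          eta = 0.1)),
                         seed = derive_seed(config$seed, "pars_spec"))
        parsimonious <- evaluate_feature_subset(
          art$assembly$cohort, art$assembly$frame, sp, plan, sel_met,
          bootstrap_B = 200)
      }
      list(study = study, parsimonious = parsimonious)
    })
  }
  manifest$artifacts <- art
  jsonlite::write_json(manifest[c("config_hash", "version", "stages")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(manifest, class = "run_manifest")
}
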