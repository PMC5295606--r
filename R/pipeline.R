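#' Configuration for an end-to-end prediction run
#'
#' Bundles input paths and the analysis constants. Defaults follow the
#' method's stated operating points: seed sets with AUC >= 0.9 are called
#' highly predictive, FDR is controlled at 5%, displayed clusters keep
#' edges with LLS above 3.0 and neighbors linked to at least two partners,
#' and an extended results table additionally exports seed sets with
#' AUC >= 0.7.
#'
#' @param network,interactions,complexes,mapping input file paths (any may
#'   be `NULL` when the corresponding stage is not run or `simulate`
#'   provides them).
#' @param out_dir output directory for artifacts.
#' @param interaction_type,organism,year_cutoff,min_partners,exclude_pairs_in_network
#'   seed-construction filters, see [filter_policy()].
#' @param min_auc predictive-seed-set gate (default 0.9).
#' @param extended_auc AUC floor of the extended export (default 0.7).
#' @param fdr FDR level for enrichment (default 0.05).
#' @param lls_cutoff,min_links display-cluster parameters (defaults 3.0, 2).
#' @param universe enrichment universe policy (see [enrich_complexes()]).
#' @param top_k optional candidate-list truncation.
#' @param withhold_mode,withhold_cutoffs,replicates withholding plan
#'   (stage `withhold`); `NULL` mode skips the stage.
#' @param world world generator settings: a [world_spec()] (stage
#'   `simulate`).
#' @param rng_seed master seed; all per-stage seeds derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(network = NULL, interactions = NULL, complexes = NULL,
                       mapping = NULL, out_dir = "netgi-out",
                       interaction_type = NULL, organism = NULL,
                       year_cutoff = NULL, min_partners = 2L,
                       exclude_pairs_in_network = TRUE, min_auc = 0.9,
                       extended_auc = 0.7, fdr = 0.05, lls_cutoff = 3.0,
                       min_links = 2L, universe = "catalog", top_k = NULL,
                       withhold_mode = NULL, withhold_cutoffs = NULL,
                       replicates = 20L, world = NULL, rng_seed = 1L) {
  structure(list(network = network, interactions = interactions,
                 complexes = complexes, mapping = mapping, out_dir = out_dir,
                 interaction_type = interaction_type, organism = organism,
                 year_cutoff = year_cutoff,
                 min_partners = as.integer(min_partners),
                 exclude_pairs_in_network = isTRUE(exclude_pairs_in_network),
                 min_auc = min_auc, extended_auc = extended_auc, fdr = fdr,
                 lls_cutoff = lls_cutoff, min_links = as.integer(min_links),
                 universe = universe, top_k = top_k,
                 withhold_mode = withhold_mode,
                 withhold_cutoffs = withhold_cutoffs,
                 replicates = as.integer(replicates), world = world,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  path
}

#' Run the prediction pipeline
#'
#' Executes the requested stages in order, writing tab-separated artifacts
#' plus a machine-readable `manifest.json` (inputs, parameters, seed, row
#' counts -- no timestamps, so identical config + seed gives byte-identical
#' artifacts). Stages:
#' \describe{
#'   \item{simulate}{generate a synthetic world from `config$world` and
#'     write it under `out_dir/world/`; its files become the run's inputs.}
#'   \item{score}{build seed sets ([build_seed_sets()]), evaluate each
#'     ([evaluate_seed_set()]); writes `seed_results.tsv` and the extended
#'     `seed_results_auc0.7.tsv` export.}
#'   \item{predict}{rank novel candidates for predictive seed sets;
#'     writes `candidates.tsv`.}
#'   \item{enrich}{complex enrichment with BH-FDR; writes
#'     `enrichment.tsv`.}
#'   \item{withhold}{enrichment detectability under withholding; writes
#'     `withholding_curve.tsv` (needs `withhold_mode`/`withhold_cutoffs`).}
#' }
#' A stage failure aborts with an error and removes the partial artifacts
#' created by this run.
#'
#' @param config a [run_config()].
#' @param stages character vector of stage names, executed in the order
#'   given.
#' @return Invisibly, a list with the loaded objects, computed results and
#'   artifact paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "score", "predict",
                                    "enrich", "withhold")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- character()
  note <- function(p) { created <<- c(created, p); p }

  res <- list(artifacts = character())
  ok <- FALSE
  on.exit(if (!ok && length(created)) unlink(created, recursive = TRUE))

  if ("simulate" %in% stages) {
    if (is.null(config$world)) config$world <- world_spec()
    spec <- config$world
    spec$rng_seed <- derive_seed(config$rng_seed, 1L)
    world <- generate_world(spec)
    paths <- write_world(world, note(file.path(config$out_dir, "world")))
    config$network <- paths[["network"]]
    config$interactions <- paths[["interactions"]]
    config$complexes <- paths[["complexes"]]
    res$world <- world
  }

  mapping <- if (!is.null(config$mapping)) read_mapping(config$mapping)
  # when `simulate` ran, later stages use the in-memory world (its network
  # keeps isolated genes, which a bare edge list cannot carry)
  load_net <- function() {
    if (!is.null(res$world)) return(res$world$network)
    if (is.null(config$network)) stop("no network path configured", call. = FALSE)
    if (!file.exists(config$network)) {
      stop("network file not found: ", config$network, call. = FALSE)
    }
    net <- read_network(config$network)
    if (!is.null(mapping)) net <- translate_genes(net, mapping)
    net
  }
  load_gi <- function() {
    if (!is.null(res$world)) return(res$world$interactions)
    if (is.null(config$interactions)) {
      stop("no interaction path configured", call. = FALSE)
    }
    if (!file.exists(config$interactions)) {
      stop("interaction file not found: ", config$interactions, call. = FALSE)
    }
    gi <- read_interactions(config$interactions)
    if (!is.null(mapping)) gi <- translate_genes(gi, mapping)
    gi
  }

  counts <- list()

  if (any(c("score", "predict") %in% stages)) {
    net <- load_net()
    gi <- load_gi()
    policy <- filter_policy(min_partners = config$min_partners,
                            exclude_pairs_in_network = config$exclude_pairs_in_network,
                            year_cutoff = config$year_cutoff,
                            interaction_type = config$interaction_type,
                            organism = config$organism)
    sets <- build_seed_sets(gi, net, policy)
    results <- lapply(sets, function(s) evaluate_seed_set(net, s))
    tab <- seed_results_table(results)
    res$seed_results <- results
    if ("score" %in% stages) {
      res$artifacts["seed_results"] <-
        note(write_tsv(tab, file.path(config$out_dir, "seed_results.tsv")))
      ext <- tab[tab$auc >= config$extended_auc, , drop = FALSE]
      res$artifacts["seed_results_extended"] <-
        note(write_tsv(ext, file.path(config$out_dir, "seed_results_auc0.7.tsv")))
      counts$seed_sets <- nrow(tab)
      counts$seed_sets_extended <- nrow(ext)
    }
    if ("predict" %in% stages) {
      cand <- do.call(rbind, lapply(results, rank_candidates,
                                    min_auc = config$min_auc,
                                    top_k = config$top_k))
      if (is.null(cand)) cand <- rank_candidates_empty()
      res$candidates <- cand
      res$artifacts["candidates"] <-
        note(write_tsv(cand, file.path(config$out_dir, "candidates.tsv")))
      counts$candidates <- nrow(cand)
    }
  }

  if (any(c("enrich", "withhold") %in% stages)) {
    gi <- load_gi()
    if (!is.null(res$world)) {
      cpx <- res$world$complexes
    } else {
      if (is.null(config$complexes)) {
        stop("no complex path configured", call. = FALSE)
      }
      if (!file.exists(config$complexes)) {
        stop("complex file not found: ", config$complexes, call. = FALSE)
      }
      cpx <- read_complexes(config$complexes)
      if (!is.null(mapping)) cpx <- translate_genes(cpx, mapping)
    }
    gi_e <- filter_gi(gi, interaction_type = config$interaction_type,
                      organism = config$organism)
    if ("enrich" %in% stages) {
      enr <- enrich_complexes(cpx, gi_e, universe = config$universe,
                              fdr = config$fdr)
      res$enrichment <- enr
      res$artifacts["enrichment"] <-
        note(write_tsv(as.data.frame(enr),
                       file.path(config$out_dir, "enrichment.tsv")))
      counts$complexes <- nrow(enr)
      counts$significant_complexes <- sum(enr$significant)
    }
    if ("withhold" %in% stages) {
      if (is.null(config$withhold_mode) || is.null(config$withhold_cutoffs)) {
        stop("withhold stage needs withhold_mode and withhold_cutoffs",
             call. = FALSE)
      }
      plan <- withholding_plan(config$withhold_mode, config$withhold_cutoffs,
                               rng_seed = derive_seed(config$rng_seed, 2L),
                               replicates = config$replicates)
      curve <- enrichment_curve(gi_e, cpx, plan, universe = config$universe,
                                fdr = config$fdr)
      res$withholding_curve <- curve
      res$artifacts["withholding_curve"] <-
        note(write_tsv(as.data.frame(curve),
                       file.path(config$out_dir, "withholding_curve.tsv")))
      counts$withholding_points <- nrow(curve)
    }
  }

  # record paths relative to out_dir so equal runs give equal manifests
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    root <- paste0(normalizePath(config$out_dir, mustWork = FALSE), "/")
    sub(root, "", normalizePath(p, mustWork = FALSE), fixed = TRUE)
  }
  params <- config[setdiff(names(config), "world")]
  for (f in c("network", "interactions", "complexes", "mapping")) {
    params[[f]] <- rel(params[[f]])
  }
  manifest <- list(
    package = "netgi",
    stages = stages,
    parameters = params,
    world_spec = if (!is.null(config$world)) unclass(config$world),
    rng_seed = config$rng_seed,
    row_counts = counts,
    artifacts = lapply(as.list(res$artifacts), rel)
  )
  manifest$parameters <- manifest$parameters[
    !vapply(manifest$parameters, is.null, logical(1L))]
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  note(mpath)
  res$artifacts["manifest"] <- mpath
  ok <- TRUE
  invisible(res)
}

rank_candidates_empty <- function() {
  data.frame(seed = character(), candidate = character(), score = numeric(),
             rank = integer(), score_percentile = numeric(),
             seed_auc = numeric(), stringsAsFactors = FALSE)
}
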