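#' Specification of a synthetic benchmark world
#'
#' Defines a fully synthetic triple -- functional network, genetic
#' interaction set, protein-complex catalog -- with known ground truth,
#' embodying the generative hypothesis that functionally related genes
#' share genetic interaction partners. The network consists of disjoint
#' functional modules (complete cliques at `within_module_lls`) over a
#' sparse background of weaker edges. Coherent seed genes draw their
#' interaction partners from a single module; control seeds draw partners
#' uniformly. Enriched complexes are gene sets whose internal pairs
#' interact at a planted rate far above the genome-wide background.
#'
#' `partner_noise` is the fraction of each coherent seed's partners drawn
#' from outside its module, realised as `floor(partner_noise *
#' partners_per_seed)` out-of-module draws per seed (a fraction of a
#' finite set; rounded down, so small rates on small sets yield none).
#'
#' @param n_genes total number of genes.
#' @param n_modules number of disjoint functional modules.
#' @param module_size genes per module (scalar, or length-2 range sampled
#'   per module).
#' @param within_module_lls LLS weight of within-module edges (default 4.0,
#'   above the 3.0 display cutoff).
#' @param background_edge_prob probability of a background edge between
#'   any pair not in a common module.
#' @param background_lls LLS weight of background edges (default 0.5,
#'   below the display cutoff).
#' @param n_coherent_seeds number of module-coherent seed genes.
#' @param partners_per_seed partners per seed set (>= 2).
#' @param partner_noise fraction of a coherent seed's partners drawn from
#'   outside its module (see Details).
#' @param n_random_seeds number of uniform-control seed genes.
#' @param n_enriched_complexes,n_null_complexes planted enriched / null
#'   complex counts.
#' @param complex_size_range inclusive member-count range per complex.
#' @param within_complex_interaction_prob planted interaction rate among
#'   an enriched complex's member pairs.
#' @param background_interaction_prob genome-wide background interaction
#'   rate (complex layer).
#' @param seed_interaction_type,complex_interaction_type class labels
#'   attached to the two interaction layers.
#' @param rng_seed integer seed; every quantity is reproducible under it.
#' @return An object of class `world_spec`.
#' @export
world_spec <- function(n_genes = 500L, n_modules = 10L, module_size = 15L,
                       within_module_lls = 4.0, background_edge_prob = 0.01,
                       background_lls = 0.5, n_coherent_seeds = 20L,
                       partners_per_seed = 6L, partner_noise = 0.1,
                       n_random_seeds = 20L, n_enriched_complexes = 10L,
                       n_null_complexes = 40L, complex_size_range = c(6L, 12L),
                       within_complex_interaction_prob = 0.5,
                       background_interaction_prob = 0.005,
                       seed_interaction_type = "Phenotypic Enhancement",
                       complex_interaction_type = "Negative Genetic",
                       rng_seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
               module_size = as.integer(module_size),
               within_module_lls = within_module_lls,
               background_edge_prob = background_edge_prob,
               background_lls = background_lls,
               n_coherent_seeds = as.integer(n_coherent_seeds),
               partners_per_seed = as.integer(partners_per_seed),
               partner_noise = partner_noise,
               n_random_seeds = as.integer(n_random_seeds),
               n_enriched_complexes = as.integer(n_enriched_complexes),
               n_null_complexes = as.integer(n_null_complexes),
               complex_size_range = as.integer(complex_size_range),
               within_complex_interaction_prob = within_complex_interaction_prob,
               background_interaction_prob = background_interaction_prob,
               seed_interaction_type = seed_interaction_type,
               complex_interaction_type = complex_interaction_type,
               rng_seed = as.integer(rng_seed))
  probs <- c(spec$background_edge_prob, spec$partner_noise,
             spec$within_complex_interaction_prob,
             spec$background_interaction_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                       call. = FALSE)
  if (any(spec$module_size < 3L)) stop("module_size must be >= 3", call. = FALSE)
  if (spec$partners_per_seed < 2L) stop("partners_per_seed must be >= 2",
                                        call. = FALSE)
  if (spec$partners_per_seed > min(spec$module_size)) {
    stop("partners_per_seed exceeds module_size", call. = FALSE)
  }
  if (length(spec$complex_size_range) == 1L) {
    spec$complex_size_range <- rep(spec$complex_size_range, 2L)
  }
  if (spec$complex_size_range[1L] < 2L ||
      spec$complex_size_range[2L] < spec$complex_size_range[1L]) {
    stop("invalid complex_size_range", call. = FALSE)
  }
  n_module_genes <- spec$n_modules * max(spec$module_size)
  if (n_module_genes > spec$n_genes) {
    stop("module demand exceeds n_genes", call. = FALSE)
  }
  if (spec$n_coherent_seeds + spec$n_random_seeds >
      spec$n_genes - n_module_genes) {
    stop("not enough non-module genes to host the requested seeds",
         call. = FALSE)
  }
  if (spec$complex_size_range[2L] > spec$n_genes) {
    stop("complex size exceeds n_genes", call. = FALSE)
  }
  structure(spec, class = "world_spec")
}

#' Generate a synthetic world
#'
#' Draws the modular functional network, the two genetic-interaction
#' layers (seed-centric and complex-centric) and the complex catalog
#' described by a [world_spec()], together with ground-truth labels.
#' No seed-layer interaction pair (the interactions used for prediction)
#' is ever a network edge: seeds live outside the modules and background
#' edges coinciding with any interacting pair are suppressed, mirroring
#' the circularity guard applied to real inputs. Enrichment-layer pairs
#' falling inside one module may coincide with clique edges; enrichment
#' never consults the network. Fully reproducible under `spec$rng_seed`;
#' the caller's RNG state is left untouched.
#'
#' @param spec a [world_spec()].
#' @return An object of class `synthetic_world`: list with `network`
#'   ([functional_network()] over all genes, isolated genes included),
#'   `interactions` ([gi_table()]), `complexes` ([complex_table()]),
#'   `truth` (seed and complex ground-truth labels plus per-seed partner
#'   lists) and `spec`.
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  with_seed(spec$rng_seed, generate_world_impl(spec))
}

generate_world_impl <- function(spec) {
  n <- spec$n_genes
  width <- max(4L, nchar(as.character(n)))
  genes <- sprintf(paste0("G%0", width, "d"), seq_len(n))

  sizes <- if (length(spec$module_size) == 2L) {
    sample(seq(spec$module_size[1L], spec$module_size[2L]),
           spec$n_modules, replace = TRUE)
  } else {
    rep(spec$module_size[1L], spec$n_modules)
  }
  stopifnot(sum(sizes) <= n)
  bounds <- cumsum(c(0L, sizes))
  modules <- lapply(seq_len(spec$n_modules), function(i) {
    genes[(bounds[i] + 1L):bounds[i + 1L]]
  })
  module_of <- stats::setNames(rep(seq_len(spec$n_modules), sizes),
                               genes[seq_len(sum(sizes))])
  free_genes <- genes[(sum(sizes) + 1L):n]

  # --- seed genes and their interaction partners -------------------------
  n_seeds <- spec$n_coherent_seeds + spec$n_random_seeds
  seed_genes <- if (n_seeds > 0L) sample(free_genes, n_seeds) else character()
  coherent <- seq_len(spec$n_coherent_seeds)
  n_out <- floor(spec$partner_noise * spec$partners_per_seed)
  n_in <- spec$partners_per_seed - n_out
  partner_list <- list()
  seed_module <- integer(n_seeds)
  for (i in seq_len(n_seeds)) {
    s <- seed_genes[i]
    if (i %in% coherent) {
      m <- ((i - 1L) %% spec$n_modules) + 1L
      seed_module[i] <- m
      inside <- sample(modules[[m]], n_in)
      pool <- setdiff(genes, c(modules[[m]], s))
      outside <- if (n_out > 0L) sample(pool, n_out) else character()
      partner_list[[s]] <- sort(c(inside, outside))
    } else {
      seed_module[i] <- NA_integer_
      partner_list[[s]] <- sort(sample(setdiff(genes, s),
                                       spec$partners_per_seed))
    }
  }
  seed_int <- if (n_seeds > 0L) {
    data.frame(a = rep(seed_genes, lengths(partner_list)),
               b = unlist(partner_list, use.names = FALSE),
               type = spec$seed_interaction_type, stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(), b = character(), type = character())
  }

  # --- protein complexes and the complex interaction layer ---------------
  n_cpx <- spec$n_enriched_complexes + spec$n_null_complexes
  cpx_sizes <- if (n_cpx > 0L) {
    sample(seq(spec$complex_size_range[1L], spec$complex_size_range[2L]),
           n_cpx, replace = TRUE)
  } else {
    integer()
  }
  cpx_ids <- sprintf("CPX%03d", seq_len(n_cpx))
  cpx_members <- lapply(cpx_sizes, function(k) sort(sample(genes, k)))
  enriched_ids <- cpx_ids[seq_len(spec$n_enriched_complexes)]

  planted <- list()
  for (i in seq_len(spec$n_enriched_complexes)) {
    mem <- cpx_members[[i]]
    pr <- utils::combn(mem, 2L)
    take <- stats::runif(ncol(pr)) < spec$within_complex_interaction_prob
    if (any(take)) {
      planted[[length(planted) + 1L]] <-
        data.frame(a = pr[1L, take], b = pr[2L, take],
                   stringsAsFactors = FALSE)
    }
  }
  n_pairs <- n * (n - 1) / 2
  n_bg_int <- stats::rbinom(1L, n_pairs, spec$background_interaction_prob)
  bg_int <- if (n_bg_int > 0L) {
    ij <- unrank_pairs(sort(sample(n_pairs, n_bg_int)), n)
    data.frame(a = genes[ij[, "i"]], b = genes[ij[, "j"]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(), b = character())
  }
  cpx_int <- rbind(do.call(rbind, planted), bg_int)
  cpx_int <- if (!is.null(cpx_int) && nrow(cpx_int)) {
    cpx_int <- cpx_int[!duplicated(pair_key(cpx_int$a, cpx_int$b)), ,
                       drop = FALSE]
    data.frame(a = cpx_int$a, b = cpx_int$b,
               type = spec$complex_interaction_type, stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(), b = character(), type = character())
  }

  interactions <- gi_table(a = c(seed_int$a, cpx_int$a),
                           b = c(seed_int$b, cpx_int$b),
                           type = c(seed_int$type, cpx_int$type),
                           organism = "synthetic", year = NA_integer_,
                           quiet = TRUE)

  # --- functional network ------------------------------------------------
  mod_edges <- do.call(rbind, lapply(modules, function(mem) {
    pr <- utils::combn(mem, 2L)
    data.frame(a = pr[1L, ], b = pr[2L, ], lls = spec$within_module_lls,
               stringsAsFactors = FALSE)
  }))
  n_bg_edges <- stats::rbinom(1L, n_pairs, spec$background_edge_prob)
  bg_edges <- if (n_bg_edges > 0L) {
    ij <- unrank_pairs(sort(sample(n_pairs, n_bg_edges)), n)
    data.frame(a = genes[ij[, "i"]], b = genes[ij[, "j"]],
               lls = spec$background_lls, stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(), b = character(), lls = numeric())
  }
  if (nrow(bg_edges)) {
    same_module <- !is.na(module_of[bg_edges$a]) &
      !is.na(module_of[bg_edges$b]) &
      module_of[bg_edges$a] == module_of[bg_edges$b]
    gi_keys <- pair_key(interactions$a, interactions$b)
    is_gi <- pair_key(bg_edges$a, bg_edges$b) %in% gi_keys
    bg_edges <- bg_edges[!(same_module | is_gi), , drop = FALSE]
  }
  network <- functional_network(rbind(mod_edges, bg_edges), genes = genes)

  truth <- list(
    genes = genes,
    modules = modules,
    seeds = data.frame(seed = seed_genes,
                       coherent = seq_len(n_seeds) %in% coherent,
                       module = seed_module, stringsAsFactors = FALSE),
    partners = partner_list,
    complexes = data.frame(complex_id = cpx_ids,
                           enriched = cpx_ids %in% enriched_ids,
                           stringsAsFactors = FALSE)
  )
  cpx_tab <- if (n_cpx > 0L) {
    complex_table(rep(cpx_ids, cpx_sizes), unlist(cpx_members))
  } else {
    complex_table(character(), character())
  }
  structure(list(network = network, interactions = interactions,
                 complexes = cpx_tab, truth = truth, spec = spec),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic world:", length(x$network$genes), "genes,",
      nrow(x$network$edges), "network edges,",
      nrow(x$interactions), "interaction records,",
      length(unique(x$complexes$complex_id)), "complexes\n")
  invisible(x)
}

#' Ground-truth seed sets of a synthetic world
#'
#' Builds [seed_set()] objects directly from the generator's truth labels
#' (all partners are network genes by construction).
#'
#' @param world a [generate_world()] result.
#' @param which `"coherent"`, `"control"` or `"all"`.
#' @return Named list of [seed_set()] objects.
#' @export
truth_seed_sets <- function(world, which = c("all", "coherent", "control")) {
  which <- match.arg(which)
  stopifnot(inherits(world, "synthetic_world"))
  df <- world$truth$seeds
  keep <- switch(which, all = rep(TRUE, nrow(df)), coherent = df$coherent,
                 control = !df$coherent)
  seeds <- df$seed[keep]
  out <- lapply(seeds, function(s) {
    seed_set(s, world$truth$partners[[s]],
             interaction_type = world$spec$seed_interaction_type)
  })
  stats::setNames(out, seeds)
}

#' Write a synthetic world to disk
#'
#' Emits `network.tsv` (edge list), `interactions.tsv` (BioGRID-style
#' columns), `complexes.tsv` and `truth.json` (ground truth + generator
#' parameters + full gene list, so isolated genes survive the round
#' trip). Re-reading with [read_world()] reproduces the world; equal
#' specs give byte-identical files.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             interactions = file.path(dir, "interactions.tsv"),
             complexes = file.path(dir, "complexes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_network(world$network, paths[["network"]])
  write_interactions(world$interactions, paths[["interactions"]])
  write_complexes(world$complexes, paths[["complexes"]])
  truth <- world$truth
  truth$spec <- unclass(world$spec)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a synthetic world back from disk
#'
#' @param dir directory written by [write_world()].
#' @return A `synthetic_world` object.
#' @export
read_world <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  spec <- do.call(world_spec, truth$spec)
  genes <- truth$genes
  network <- read_network(file.path(dir, "network.tsv"), genes = genes)
  interactions <- read_interactions(file.path(dir, "interactions.tsv"))
  complexes <- read_complexes(file.path(dir, "complexes.tsv"))
  truth$partners <- lapply(truth$partners, unlist)
  truth$modules <- lapply(truth$modules, unlist)
  truth$spec <- NULL
  structure(list(network = network, interactions = interactions,
                 complexes = complexes, truth = truth, spec = spec),
            class = "synthetic_world")
}
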