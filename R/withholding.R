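#' Plan for a withholding simulation
#'
#' Describes how known genetic interactions are progressively withheld:
#' by interaction degree (`degree_above` removes every pair touching a
#' gene whose degree exceeds the cutoff, emulating the loss of hub
#' knowledge; `degree_below` removes pairs both of whose endpoints fall
#' under the cutoff) or uniformly at random (`random_pairs`, averaged over
#' seeded replicates).
#'
#' @param mode one of `"degree_above"`, `"degree_below"`, `"random_pairs"`.
#' @param cutoffs strictly monotone integer degree cutoffs (degree modes)
#'   or proportions in `[0, 1]` (random mode).
#' @param rng_seed master seed for random mode.
#' @param replicates replicate draws per proportion in random mode.
#' @return An object of class `withholding_plan`.
#' @export
withholding_plan <- function(mode = c("degree_above", "degree_below",
                                      "random_pairs"),
                             cutoffs, rng_seed = 1L, replicates = 20L) {
  mode <- match.arg(mode)
  cutoffs <- as.numeric(cutoffs)
  if (!length(cutoffs)) stop("need at least one cutoff", call. = FALSE)
  d <- diff(cutoffs)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("cutoffs must be strictly monotone", call. = FALSE)
  }
  if (mode == "random_pairs" && any(cutoffs < 0 | cutoffs > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (mode != "random_pairs" && any(cutoffs < 0)) {
    stop("degree cutoffs must be >= 0", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  structure(list(mode = mode, cutoffs = cutoffs,
                 rng_seed = as.integer(rng_seed), replicates = replicates),
            class = "withholding_plan")
}

#' Withhold interaction pairs by gene degree
#'
#' Degrees are computed once on the full input set (interaction degree is
#' a property of the original data, not of the progressively reduced
#' sets). `mode = "above"` removes every record in which either endpoint
#' has degree strictly greater than `cutoff`; `mode = "below"` removes
#' records both of whose endpoints have degree strictly less than
#' `cutoff`.
#'
#' @param interactions a [gi_table()] (typically restricted to one
#'   interaction class).
#' @param cutoff non-negative integer degree cutoff.
#' @param mode `"above"` or `"below"`.
#' @return List with `interactions` (the reduced [gi_table()]) and
#'   `withheld_fraction` (removed records / original records).
#' @export
withhold_by_degree <- function(interactions, cutoff, mode = c("above", "below")) {
  mode <- match.arg(mode)
  if (cutoff < 0) stop("cutoff must be >= 0", call. = FALSE)
  x <- as.data.frame(interactions)
  n0 <- nrow(x)
  if (!n0) {
    return(list(interactions = interactions, withheld_fraction = 0))
  }
  deg <- gi_degree(interactions)
  da <- deg[x$a]; db <- deg[x$b]
  remove <- if (mode == "above") da > cutoff | db > cutoff
            else da < cutoff & db < cutoff
  kept <- x[!remove, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("gi_table", "data.frame")
  list(interactions = kept, withheld_fraction = sum(remove) / n0)
}

#' Withhold a random proportion of interaction pairs
#'
#' Removes `floor(proportion * N)` distinct records chosen uniformly
#' without replacement; reproducible under `rng_seed` and independent of
#' the caller's RNG state.
#'
#' @param interactions a [gi_table()].
#' @param proportion proportion in `[0, 1]`.
#' @param rng_seed integer seed.
#' @return List with `interactions` and `withheld_fraction`.
#' @export
withhold_random <- function(interactions, proportion, rng_seed = 1L) {
  if (proportion < 0 || proportion > 1) {
    stop("proportion must lie in [0, 1]", call. = FALSE)
  }
  x <- as.data.frame(interactions)
  n0 <- nrow(x)
  n_rm <- floor(proportion * n0)
  if (n_rm > 0L) {
    idx <- with_seed(rng_seed, sample.int(n0, n_rm))
    x <- x[-idx, , drop = FALSE]
  }
  rownames(x) <- NULL
  class(x) <- c("gi_table", "data.frame")
  list(interactions = x,
       withheld_fraction = if (n0) n_rm / n0 else 0)
}

#' Enrichment detectability under progressive withholding
#'
#' For each point of the plan the interaction set is reduced, the
#' background rate `p` is recomputed on the reduced set (by default: the
#' simulation pretends the withheld pairs are unknown), complex enrichment
#' is evaluated with BH-FDR control, and the number of significantly
#' enriched complexes is recorded. The gene universe is resolved once
#' from the original inputs and held fixed across points (the hypothetical
#' is "fewer known interactions", not "fewer genes"). In random mode each
#' proportion is averaged over seeded replicate draws.
#'
#' Points are ordered by increasing severity (decreasing cutoff for
#' `degree_above`, increasing cutoff for `degree_below`, increasing
#' proportion for `random_pairs`).
#'
#' @param interactions a [gi_table()] (restricted to one class upstream).
#' @param complexes a [complex_table()].
#' @param plan a [withholding_plan()].
#' @param universe universe policy as in [enrich_complexes()], resolved
#'   against the original inputs.
#' @param fdr FDR level (default 0.05).
#' @param recompute_background recompute `p` on each reduced set
#'   (default `TRUE`); when `FALSE` the original-set `p` is reused.
#' @param network optional network for `universe = "network"`.
#' @return Data frame of class `withholding_curve`: one row per point with
#'   `cutoff`, `withheld_fraction`, `n_significant` (replicate mean in
#'   random mode), `n_significant_min`, `n_significant_max`,
#'   `n_eligible`, `frac_significant`.
#' @export
enrichment_curve <- function(interactions, complexes, plan,
                             universe = "catalog", fdr = 0.05,
                             recompute_background = TRUE, network = NULL) {
  stopifnot(inherits(plan, "withholding_plan"))
  uni <- build_universe(universe, interactions = interactions,
                        complexes = complexes, network = network)
  params0 <- background_rate(interactions, uni)

  run_point <- function(reduced) {
    params <- if (recompute_background) background_rate(reduced$interactions, uni)
              else params0
    tab <- complex_enrichment(complexes, reduced$interactions, params)
    sig <- logical(nrow(tab))
    if (any(tab$eligible)) {
      sig[tab$eligible] <- bh_fdr(tab$pvalue[tab$eligible], fdr)
    }
    c(n_significant = sum(sig), n_eligible = sum(tab$eligible),
      withheld_fraction = reduced$withheld_fraction)
  }

  cutoffs <- plan$cutoffs
  cutoffs <- switch(plan$mode,
    degree_above = sort(cutoffs, decreasing = TRUE),
    degree_below = sort(cutoffs),
    random_pairs = sort(cutoffs))

  rows <- lapply(seq_along(cutoffs), function(i) {
    cut <- cutoffs[i]
    if (plan$mode == "random_pairs") {
      reps <- vapply(seq_len(plan$replicates), function(r) {
        seed_r <- derive_seed(plan$rng_seed, i * 10000L + r)
        run_point(withhold_random(interactions, cut, seed_r))
      }, numeric(3L))
      data.frame(cutoff = cut,
                 withheld_fraction = mean(reps["withheld_fraction", ]),
                 n_significant = mean(reps["n_significant", ]),
                 n_significant_min = min(reps["n_significant", ]),
                 n_significant_max = max(reps["n_significant", ]),
                 n_eligible = reps["n_eligible", 1L])
    } else {
      mode <- if (plan$mode == "degree_above") "above" else "below"
      v <- run_point(withhold_by_degree(interactions, cut, mode))
      data.frame(cutoff = cut,
                 withheld_fraction = v[["withheld_fraction"]],
                 n_significant = v[["n_significant"]],
                 n_significant_min = v[["n_significant"]],
                 n_significant_max = v[["n_significant"]],
                 n_eligible = v[["n_eligible"]])
    }
  })
  out <- do.call(rbind, rows)
  out$frac_significant <- ifelse(out$n_eligible > 0,
                                 out$n_significant / out$n_eligible, 0)
  rownames(out) <- NULL
  attr(out, "mode") <- plan$mode
  attr(out, "fdr") <- fdr
  attr(out, "recompute_background") <- recompute_background
  attr(out, "rng_seed") <- plan$rng_seed
  class(out) <- c("withholding_curve", "data.frame")
  out
}
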