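#' Background genetic-interaction rate over a gene universe
#'
#' The background probability `p` of the binomial enrichment model is the
#' proportion of all possible gene pairs in the universe that are known to
#' genetically interact: `p = |interacting pairs within universe| /
#' choose(|universe|, 2)`. Pairs are counted once regardless of
#' interaction class multiplicity; restrict the table upstream for a
#' per-class analysis.
#'
#' @param interactions a [gi_table()].
#' @param universe character vector of gene identifiers (>= 2 after
#'   deduplication).
#' @return An object of class `enrichment_params`: list with `p`,
#'   `universe`, `n_interacting_pairs`, `n_possible_pairs`.
#' @export
background_rate <- function(interactions, universe) {
  universe <- sort(unique(trimws(as.character(universe))))
  universe <- universe[nzchar(universe)]
  if (length(universe) < 2L) {
    stop("universe must contain at least two genes", call. = FALSE)
  }
  x <- as.data.frame(interactions)
  inside <- x$a %in% universe & x$b %in% universe
  keys <- unique(pair_key(x$a[inside], x$b[inside]))
  n_pairs <- length(keys)
  n_possible <- choose(length(universe), 2)
  structure(list(p = n_pairs / n_possible, universe = universe,
                 n_interacting_pairs = n_pairs,
                 n_possible_pairs = n_possible),
            class = "enrichment_params")
}

#' @export
print.enrichment_params <- function(x, ...) {
  cat(sprintf("background rate p = %.3g (%d interacting / %g possible pairs, %d genes)\n",
              x$p, x$n_interacting_pairs, x$n_possible_pairs,
              length(x$universe)))
  invisible(x)
}

#' Exact binomial upper tail P(X >= k)
#'
#' Upper-tail probability of a Binomial(n, p) count, computed exactly (no
#' normal approximation -- complexes are small and approximations fail at
#' small n). `P(X >= 0) = 1` identically.
#'
#' @param k observed count (0 <= k <= n).
#' @param n number of trials.
#' @param p success probability.
#' @return `P(X >= k)`.
#' @export
binomial_tail <- function(k, n, p) {
  k <- as.integer(k); n <- as.integer(n)
  if (length(k) != 1L || length(n) != 1L || length(p) != 1L) {
    stop("binomial_tail is scalar", call. = FALSE)
  }
  if (is.na(k) || is.na(n) || is.na(p) || k < 0L || n < 0L || k > n ||
      p < 0 || p > 1) {
    stop("binomial_tail: need 0 <= k <= n and 0 <= p <= 1", call. = FALSE)
  }
  if (k == 0L) return(1)
  stats::pbinom(k - 1L, size = n, prob = p, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Standard BH step-up at FDR level `q`: sort p-values ascending, find the
#' largest rank `i` with `p(i) <= i*q/m`, and flag every hypothesis with a
#' p-value at or below that cutoff (equal p-values share a decision).
#'
#' @param pvalues numeric p-values in `(0, 1]`.
#' @param q FDR level in `(0, 1)` (default 0.05).
#' @return Logical vector of flags, aligned with `pvalues`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) return(logical(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Binomial enrichment of genetic interactions within protein complexes
#'
#' For each complex, `m` is the number of members inside the universe,
#' the number of trials is `n = choose(m, 2)` (all possible member pairs),
#' and `k` is the number of member pairs known to genetically interact;
#' the p-value is the exact binomial upper tail `P(X >= k)` at the
#' background rate `params$p`. Complexes with fewer than two members in
#' the universe are reported with `n = 0`, `pvalue = 1` and flagged
#' ineligible.
#'
#' @param complexes a [complex_table()].
#' @param interactions a [gi_table()] (restrict to one interaction class
#'   upstream for per-class analyses).
#' @param params an `enrichment_params` from [background_rate()].
#' @return Data frame with one row per complex: `complex_id`, `m`, `n`,
#'   `k`, `p_background`, `pvalue`, `eligible`.
#' @export
complex_enrichment <- function(complexes, interactions, params) {
  stopifnot(inherits(params, "enrichment_params"))
  members <- complex_members(complexes)
  x <- as.data.frame(interactions)
  inside <- x$a %in% params$universe & x$b %in% params$universe
  keys <- unique(pair_key(x$a[inside], x$b[inside]))
  rows <- lapply(names(members), function(id) {
    mem <- intersect(unique(members[[id]]), params$universe)
    m <- length(mem)
    if (m < 2L) {
      return(data.frame(complex_id = id, m = m, n = 0L, k = 0L,
                        p_background = params$p, pvalue = 1,
                        eligible = FALSE, stringsAsFactors = FALSE))
    }
    pr <- utils::combn(sort(mem), 2L)
    k <- sum(pair_key(pr[1L, ], pr[2L, ]) %in% keys)
    n <- choose(m, 2)
    data.frame(complex_id = id, m = m, n = as.integer(n), k = as.integer(k),
               p_background = params$p,
               pvalue = binomial_tail(k, n, params$p),
               eligible = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full complex-enrichment analysis with FDR control
#'
#' Convenience wrapper: computes the background rate on the chosen
#' universe, runs [complex_enrichment()], and adds a `significant` column
#' from [bh_fdr()] applied to the eligible complexes (ineligible complexes
#' are never significant).
#'
#' @param complexes a [complex_table()].
#' @param interactions a [gi_table()].
#' @param universe either a character vector of genes, or one of
#'   `"catalog"` (genes in the complex catalog union the interaction set;
#'   the default) or, with `network` supplied, `"network"`.
#' @param fdr FDR level (default 0.05).
#' @param network optional [functional_network()] backing
#'   `universe = "network"`.
#' @return The [complex_enrichment()] table with a `significant` column;
#'   the `enrichment_params` used are attached as attribute `"params"`.
#' @export
enrich_complexes <- function(complexes, interactions, universe = "catalog",
                             fdr = 0.05, network = NULL) {
  uni <- build_universe(universe, interactions = interactions,
                        complexes = complexes, network = network)
  params <- background_rate(interactions, uni)
  tab <- complex_enrichment(complexes, interactions, params)
  tab$significant <- FALSE
  if (any(tab$eligible)) {
    tab$significant[tab$eligible] <- bh_fdr(tab$pvalue[tab$eligible], fdr)
  }
  attr(tab, "params") <- params
  attr(tab, "fdr") <- fdr
  tab
}

#' Resolve a universe policy to a gene vector
#'
#' @param universe a character vector of genes (used as-is when longer
#'   than 1 or not a keyword), `"catalog"` (complex-catalog genes union
#'   interaction genes) or `"network"` (the network's gene set).
#' @param interactions,complexes,network inputs the keywords draw from.
#' @return Character vector of gene identifiers.
#' @export
build_universe <- function(universe, interactions = NULL, complexes = NULL,
                           network = NULL) {
  if (is.character(universe) && length(universe) == 1L &&
      universe %in% c("catalog", "network")) {
    if (universe == "network") {
      if (is.null(network)) stop("universe = \"network\" needs a network",
                                 call. = FALSE)
      return(network$genes)
    }
    x <- if (!is.null(interactions)) as.data.frame(interactions)
    genes <- c(if (!is.null(complexes)) complexes$gene,
               if (!is.null(x)) c(x$a, x$b))
    if (!length(genes)) stop("empty catalog universe", call. = FALSE)
    return(sort(unique(genes)))
  }
  sort(unique(trimws(as.character(universe))))
}
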