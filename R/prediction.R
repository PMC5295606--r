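#' Rank novel candidate interaction partners from a predictive seed set
#'
#' When a seed set is predictive (AUC at or above `min_auc`, default 0.9,
#' the high-confidence band), the non-partner genes that score highest
#' against the partners are its predicted novel interaction partners.
#' Candidates are the label-0 genes with a strictly positive score, sorted
#' by score descending with ties broken by gene id ascending (so the
#' ordering is fully deterministic), optionally truncated to `top_k`.
#' A below-threshold seed set yields an empty list.
#'
#' The `score_percentile` column is a derived convenience (percentile of
#' the candidate's score among all scored genes) for cross-seed
#' comparison; raw scores are unnormalised edge-weight sums.
#'
#' @param result a `seed_set_result` from [evaluate_seed_set()].
#' @param min_auc minimum AUC gate (default 0.9).
#' @param top_k optional maximum number of candidates.
#' @return Data frame of class `candidate_list` with columns `seed`,
#'   `candidate`, `score`, `rank`, `score_percentile`, `seed_auc`.
#' @export
rank_candidates <- function(result, min_auc = 0.9, top_k = NULL) {
  stopifnot(inherits(result, "seed_set_result"))
  empty <- data.frame(seed = character(), candidate = character(),
                      score = numeric(), rank = integer(),
                      score_percentile = numeric(), seed_auc = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("candidate_list", "data.frame")
  if (result$auc < min_auc) return(empty)
  cand <- names(result$scores)[result$labels == 0L & result$scores > 0]
  if (!length(cand)) return(empty)
  sc <- result$scores[cand]
  ord <- order(-sc, cand)
  cand <- cand[ord]; sc <- sc[ord]
  if (!is.null(top_k)) {
    k <- min(length(cand), as.integer(top_k))
    cand <- cand[seq_len(k)]; sc <- sc[seq_len(k)]
  }
  all_scores <- result$scores
  pct <- vapply(sc, function(s) 100 * mean(all_scores <= s), numeric(1L))
  out <- data.frame(seed = result$seed_set$seed, candidate = cand,
                    score = unname(sc), rank = seq_along(cand),
                    score_percentile = unname(pct), seed_auc = result$auc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("candidate_list", "data.frame")
  out
}

#' Extract the displayable functional cluster around a partner set
#'
#' Reproduces the display rule used for predictive clusters: only
#' functional-network edges with LLS strictly above `lls_cutoff`
#' (default 3.0) are kept, and a non-partner gene is shown only if, after
#' that edge filter, it connects to at least `min_links` (default 2)
#' distinct partners. Partners are always retained. The returned edge set
#' is restricted to supra-cutoff edges among the retained nodes.
#'
#' @param network a [functional_network()].
#' @param partners character vector of partner genes (must be network
#'   genes).
#' @param lls_cutoff minimum (exclusive) edge weight to display.
#' @param min_links minimum number of distinct partner links a non-partner
#'   node needs to be displayed.
#' @return An object of class `display_cluster`: list with `nodes`,
#'   `edges` (data frame `a`, `b`, `lls`) and `is_partner` (named logical).
#' @export
extract_display_cluster <- function(network, partners, lls_cutoff = 3.0,
                                    min_links = 2L) {
  stopifnot(inherits(network, "functional_network"))
  partners <- unique(trimws(as.character(partners)))
  missing <- setdiff(partners, network$genes)
  if (length(missing)) {
    stop("partner(s) not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  min_links <- as.integer(min_links)
  e <- network$edges[network$edges$lls > lls_cutoff, , drop = FALSE]
  touch <- e$a %in% partners | e$b %in% partners
  et <- e[touch, , drop = FALSE]
  # distinct partner links per non-partner neighbor, after the edge filter
  nb <- c(et$b[et$a %in% partners], et$a[et$b %in% partners])
  pt <- c(et$a[et$a %in% partners], et$b[et$b %in% partners])
  ok <- !(nb %in% partners)
  links <- tapply(pt[ok], nb[ok], function(v) length(unique(v)))
  keep_nb <- names(links)[links >= min_links]
  nodes <- sort(unique(c(partners, keep_nb)))
  ef <- e[e$a %in% nodes & e$b %in% nodes, , drop = FALSE]
  rownames(ef) <- NULL
  structure(list(nodes = nodes, edges = ef,
                 is_partner = stats::setNames(nodes %in% partners, nodes),
                 lls_cutoff = lls_cutoff, min_links = min_links),
            class = "display_cluster")
}

#' @export
print.display_cluster <- function(x, ...) {
  cat("display cluster:", length(x$nodes), "genes (",
      sum(x$is_partner), "partners ),", nrow(x$edges),
      "edges with LLS >", x$lls_cutoff, "\n")
  invisible(x)
}
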