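#' Summed edge-weight score of every network gene against a partner set
#'
#' Each gene `g` in the functional network receives the sum of LLS edge
#' weights between `g` and the known interaction partners; absent edges
#' contribute 0. Because the network has no self-edges, a partner's own
#' score omits its self-term, so ranking the partners by this score is an
#' implicit leave-one-out cross-validation over the partner set.
#'
#' @param network a [functional_network()].
#' @param partners character vector of partner genes; all must be present
#'   in the network (callers intersect first; see [build_seed_sets()]).
#' @return Named numeric vector of scores over all network genes.
#' @export
score_vector <- function(network, partners) {
  stopifnot(inherits(network, "functional_network"))
  partners <- unique(trimws(as.character(partners)))
  missing <- setdiff(partners, network$genes)
  if (length(missing)) {
    stop("partner(s) not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(partners) < 2L) {
    stop("need at least two partners", call. = FALSE)
  }
  s <- Matrix::rowSums(network$adjacency[, partners, drop = FALSE])
  stats::setNames(as.numeric(s), network$genes)
}

#' Binary label vector marking the known partners
#'
#' 1 for partners, 0 otherwise; genes listed in `exclude` (typically the
#' seed gene itself when it happens to be a network node) are removed from
#' the vector entirely, so they are neither positives nor negatives.
#'
#' @param network a [functional_network()].
#' @param partners character vector of partner genes (subset of the
#'   network's genes).
#' @param exclude genes to remove from the evaluation.
#' @return Named integer vector of 0/1 labels.
#' @export
label_vector <- function(network, partners, exclude = character()) {
  stopifnot(inherits(network, "functional_network"))
  partners <- unique(trimws(as.character(partners)))
  missing <- setdiff(partners, network$genes)
  if (length(missing)) {
    stop("partner(s) not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  genes <- setdiff(network$genes, exclude)
  stats::setNames(as.integer(genes %in% setdiff(partners, exclude)), genes)
}

#' Rank-based ROC AUC with midrank tie handling
#'
#' The area under the ROC curve computed as the Mann-Whitney statistic:
#' `AUC = (sum of positive ranks - n1*(n1+1)/2) / (n1*n0)` with midranks
#' for ties, i.e. the probability that a random positive outscores a
#' random negative, ties counting 1/2. With no score signal at all the
#' statistic is exactly 0.5.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 label vector. When both vectors are named the labels
#'   are aligned to the scores by name.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (!is.null(names(scores)) && !is.null(names(labels))) {
    if (!setequal(names(scores), names(labels))) {
      stop("scores and labels cover different genes", call. = FALSE)
    }
    labels <- labels[names(scores)]
  }
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: need at least one positive and one negative label",
         call. = FALSE)
  }
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a seed set on a functional network
#'
#' Composes [score_vector()], [label_vector()] and [roc_auc()]: partners
#' are intersected with the network's genes, every network gene is scored
#' by its summed edge weight to the partners, partners are labelled 1, and
#' the leave-one-out ROC AUC summarises how tightly the partners cluster
#' in the network -- the measure of how predictive the seed set is for
#' novel interactions.
#'
#' @param network a [functional_network()].
#' @param seed_set a [seed_set()].
#' @param exclude_seed when the seed gene is itself a network node, remove
#'   it from the evaluation rather than scoring it as a negative
#'   (default `TRUE`).
#' @return An object of class `seed_set_result` with components
#'   `seed_set`, `scores`, `labels`, `auc`, `n_positives`, `n_negatives`.
#' @export
evaluate_seed_set <- function(network, seed_set, exclude_seed = TRUE) {
  stopifnot(inherits(network, "functional_network"),
            inherits(seed_set, "seed_set"))
  partners <- intersect(seed_set$partners, network$genes)
  if (length(partners) < 2L) {
    stop("seed set ", seed_set$seed,
         " has fewer than two partners in the network", call. = FALSE)
  }
  exclude <- if (exclude_seed) intersect(seed_set$seed, network$genes) else character()
  s <- score_vector(network, partners)
  if (length(exclude)) s <- s[setdiff(names(s), exclude)]
  l <- label_vector(network, partners, exclude = exclude)
  l <- l[names(s)]
  structure(
    list(seed_set = seed_set, scores = s, labels = l,
         auc = roc_auc(s, l),
         n_positives = sum(l == 1L), n_negatives = sum(l == 0L)),
    class = "seed_set_result"
  )
}

#' @export
print.seed_set_result <- function(x, ...) {
  cat(sprintf("seed %s [%s]: %d partners in network, AUC = %.4f\n",
              x$seed_set$seed, x$seed_set$interaction_type,
              x$n_positives, x$auc))
  invisible(x)
}

#' Proportion of seed sets exceeding AUC thresholds
#'
#' For each threshold `t`, the fraction of seed-set results with
#' `AUC >= t`; non-increasing in `t`.
#'
#' @param results list of `seed_set_result` objects (or a numeric vector
#'   of AUCs).
#' @param thresholds numeric thresholds in `[0, 1]`.
#' @return Data frame with columns `threshold`, `proportion`, `n_exceeding`.
#' @export
auc_sweep <- function(results, thresholds = seq(0.1, 0.9, by = 0.1)) {
  aucs <- if (is.numeric(results)) {
    as.numeric(results)
  } else {
    vapply(results, function(r) {
      if (inherits(r, "seed_set_result")) r$auc else as.numeric(r)
    }, numeric(1L))
  }
  if (!length(aucs)) stop("no seed-set results to sweep", call. = FALSE)
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  data.frame(threshold = thresholds,
             proportion = vapply(thresholds, function(t) mean(aucs >= t),
                                 numeric(1L)),
             n_exceeding = vapply(thresholds, function(t) sum(aucs >= t),
                                  integer(1L)))
}

#' Tabulate seed-set results
#'
#' Flat summary table (one row per seed set) of the kind released as raw
#' data alongside a scoring run.
#'
#' @param results list of `seed_set_result` objects.
#' @return Data frame with columns `seed`, `interaction_type`,
#'   `n_partners_total`, `n_partners_in_network`, `auc`.
#' @export
seed_results_table <- function(results) {
  if (!length(results)) {
    return(data.frame(seed = character(), interaction_type = character(),
                      n_partners_total = integer(),
                      n_partners_in_network = integer(), auc = numeric()))
  }
  do.call(rbind, lapply(results, function(r) {
    data.frame(seed = r$seed_set$seed,
               interaction_type = r$seed_set$interaction_type,
               n_partners_total = r$seed_set$n_partners_total,
               n_partners_in_network = r$n_positives,
               auc = r$auc, stringsAsFactors = FALSE)
  }))
}
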