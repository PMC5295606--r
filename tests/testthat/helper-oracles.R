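# Independent brute-force oracles and tiny fixture builders.

# AUC as the exhaustive mean over positive x negative score comparisons,
# ties counting 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# BH step-up by direct scan: largest rank i with p(i) <= i*q/m flags all
# hypotheses of rank <= i.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  flags <- logical(m)
  ok <- which(p[o] <= seq_len(m) * q / m)
  if (length(ok)) flags[o[seq_len(max(ok))]] <- TRUE
  flags
}

# Summed edge weights by an explicit double loop over (gene, partner).
oracle_scores <- function(network, partners) {
  genes <- network_genes(network)
  out <- numeric(length(genes))
  names(out) <- genes
  for (g in genes) {
    for (p in partners) {
      out[g] <- out[g] + edge_weight(network, g, p)
    }
  }
  out
}

# Random weighted network on n genes with m edges (no self-edges, unique
# pairs), optionally with a discrete weight set to force ties.
rand_network <- function(n, m, weights = NULL, genes_extra = NULL) {
  genes <- sprintf("g%03d", seq_len(n))
  all_pairs <- t(combn(genes, 2))
  pick <- sample(nrow(all_pairs), min(m, nrow(all_pairs)))
  w <- if (is.null(weights)) round(runif(length(pick), 0.1, 5), 3)
       else sample(weights, length(pick), replace = TRUE)
  functional_network(
    data.frame(a = all_pairs[pick, 1], b = all_pairs[pick, 2], lls = w),
    genes = c(genes, genes_extra)
  )
}

# Random interaction table over a gene alphabet.
rand_gi <- function(n_records, genes, types = c("Synthetic Lethality",
                                                "Phenotypic Enhancement")) {
  a <- sample(genes, n_records, replace = TRUE)
  b <- sample(genes, n_records, replace = TRUE)
  keep <- a != b
  suppressWarnings(gi_table(a[keep], b[keep],
                            sample(types, sum(keep), replace = TRUE),
                            organism = "test"))
}

# Seed-set construction by independent per-gene grouping with the same
# four filter steps applied in order.
oracle_seed_sets <- function(interactions, network, policy) {
  x <- as.data.frame(interactions)
  if (!is.null(policy$interaction_type)) {
    x <- x[tolower(trimws(x$type)) == tolower(trimws(policy$interaction_type)), ]
  }
  if (!is.null(policy$organism)) {
    x <- x[tolower(trimws(x$organism)) == tolower(trimws(policy$organism)), ]
  }
  if (!is.null(policy$year_cutoff)) {
    x <- x[is.na(x$year) | x$year >= policy$year_cutoff, ]
  }
  genes <- unique(c(x$a, x$b))
  net_edge_keys <- paste(pmin(network$edges$a, network$edges$b),
                         pmax(network$edges$a, network$edges$b))
  out <- list()
  for (g in sort(genes)) {
    partners <- unique(c(x$b[x$a == g], x$a[x$b == g]))
    partners <- partners[partners %in% network_genes(network)]
    if (policy$exclude_pairs_in_network) {
      k <- paste(pmin(g, partners), pmax(g, partners))
      partners <- partners[!(k %in% net_edge_keys)]
    }
    if (length(partners) >= policy$min_partners) {
      out[[g]] <- sort(partners)
    }
  }
  out
}
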