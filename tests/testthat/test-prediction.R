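fig1_like_network <- function() {
  # five-gene functional cluster A-E; A, C, D, E are known partners of a
  # query gene X outside the network, B is the remaining cluster member;
  # F-G and the isolated o* genes form the unclustered background
  cl <- t(combn(c("A", "B", "C", "D", "E"), 2))
  functional_network(
    data.frame(a = c(cl[, 1], "F"), b = c(cl[, 2], "G"),
               lls = c(rep(2.0, nrow(cl)), 0.5)),
    genes = sprintf("o%02d", 1:20))
}

test_that("below-threshold seed sets yield no candidates", {
  net <- fig1_like_network()
  res <- evaluate_seed_set(net, seed_set("X", c("A", "F"), "T"))
  out <- rank_candidates(res, min_auc = 0.9)
  expect_equal(nrow(out), 0L)
})

test_that("the remaining cluster member is the top-ranked candidate", {
  net <- fig1_like_network()
  res <- evaluate_seed_set(net, seed_set("X", c("A", "C", "D", "E"), "T"))
  expect_gte(res$auc, 0.9)
  out <- rank_candidates(res, min_auc = 0.9)
  expect_equal(out$candidate[1], "B")
  expect_equal(out$score[1], 4 * 2.0)
  # zero-score genes are never candidates
  expect_false(any(c("F", "G") %in% out$candidate))
})

test_that("candidate ordering matches a brute-force sort with stable ties", {
  set.seed(131)
  for (i in 1:10) {
    net <- rand_network(40, 120, weights = c(1, 1, 2, 3))  # force ties
    parts <- sample(network_genes(net), 4)
    res <- evaluate_seed_set(net, seed_set("X", parts, "T"))
    out <- rank_candidates(res, min_auc = 0)
    sc <- res$scores[res$labels == 0 & res$scores > 0]
    want <- names(sc)[order(-sc, names(sc))]
    expect_identical(out$candidate, want)
    expect_true(all(diff(out$score) <= 0))
    # byte-identical reproducibility of the ordering
    expect_identical(out, rank_candidates(res, min_auc = 0))
  }
})

test_that("top_k truncates after sorting", {
  net <- fig1_like_network()
  res <- evaluate_seed_set(net, seed_set("X", c("A", "C", "D"), "T"))
  full <- rank_candidates(res, min_auc = 0)
  top1 <- rank_candidates(res, min_auc = 0, top_k = 1)
  expect_equal(nrow(top1), 1L)
  expect_identical(top1$candidate, full$candidate[1])
})

test_that("display cluster applies the LLS cutoff and min-links rule", {
  net <- functional_network(data.frame(
    a = c("P1", "P2", "N1", "N1", "N2", "P1"),
    b = c("P2", "P3", "P1", "P2", "P1", "Z"),
    lls = c(3.5, 3.5, 3.5, 3.5, 3.5, 1.0)))
  cl <- extract_display_cluster(net, c("P1", "P2", "P3"))
  expect_true("N1" %in% cl$nodes)      # two supra-cutoff partner links
  expect_false("N2" %in% cl$nodes)     # only one partner link
  expect_false("Z" %in% cl$nodes)      # below the LLS cutoff
  expect_true(all(cl$edges$lls > 3.0))

  # all weights at or below the cutoff: partners only, no edges
  net_low <- functional_network(data.frame(a = c("P1", "P2"),
                                           b = c("P2", "Q"),
                                           lls = c(3.0, 2.0)))
  cl_low <- extract_display_cluster(net_low, c("P1", "P2"))
  expect_setequal(cl_low$nodes, c("P1", "P2"))
  expect_equal(nrow(cl_low$edges), 0L)
})

test_that("display cluster matches a brute-force filter-then-count pass", {
  set.seed(141)
  for (i in 1:10) {
    net <- rand_network(30, 150, weights = c(0.5, 2.5, 3.5, 4.5))
    partners <- sample(network_genes(net), 5)
    cl <- extract_display_cluster(net, partners)
    e <- net$edges[net$edges$lls > 3.0, ]
    keep <- partners
    for (g in setdiff(network_genes(net), partners)) {
      links <- unique(c(e$b[e$a == g & e$b %in% partners],
                        e$a[e$b == g & e$a %in% partners]))
      if (length(links) >= 2) keep <- c(keep, g)
    }
    expect_setequal(cl$nodes, keep)
    want_edges <- e[e$a %in% keep & e$b %in% keep, ]
    expect_equal(nrow(cl$edges), nrow(want_edges))
    # subgraph property
    net_keys <- paste(net$edges$a, net$edges$b)
    expect_true(all(paste(cl$edges$a, cl$edges$b) %in% net_keys))
  }
})

test_that("raising the cutoffs never adds nodes or edges", {
  set.seed(151)
  net <- rand_network(30, 150, weights = c(2.5, 3.2, 3.8, 4.5))
  partners <- sample(network_genes(net), 5)
  base <- extract_display_cluster(net, partners, lls_cutoff = 3.0,
                                  min_links = 2)
  higher <- extract_display_cluster(net, partners, lls_cutoff = 3.5,
                                    min_links = 2)
  stricter <- extract_display_cluster(net, partners, lls_cutoff = 3.0,
                                      min_links = 3)
  expect_true(all(higher$nodes %in% base$nodes))
  expect_true(all(stricter$nodes %in% base$nodes))
  expect_lte(nrow(higher$edges), nrow(base$edges))
  expect_lte(nrow(stricter$edges), nrow(base$edges))
})
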