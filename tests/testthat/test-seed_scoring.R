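test_that("score_vector is the additive edge-weight sum with 0 for absences", {
  net <- functional_network(data.frame(a = c("g", "g"), b = c("A", "C"),
                                       lls = c(1.0, 2.0)),
                            genes = c("A", "C", "D", "g"))
  s <- score_vector(net, c("A", "C", "D"))
  expect_equal(unname(s["g"]), 3.0)
  expect_equal(unname(s["D"]), 0)          # no edges to any partner
  # a partner's own score has no self-term: leave-one-out by construction
  expect_equal(unname(s["A"]), 0)

  # partners with no incident edges at all: every score is 0
  net0 <- functional_network(data.frame(a = "X", b = "Y", lls = 1),
                             genes = c("P1", "P2", "X", "Y"))
  expect_true(all(score_vector(net0, c("P1", "P2")) == 0))

  expect_error(score_vector(net, c("A", "NOPE")), "not in network")
})

test_that("score_vector equals the double-loop oracle on a random instance", {
  set.seed(71)
  net <- rand_network(60, 150)
  partners <- sample(network_genes(net), 5)
  expect_equal(score_vector(net, partners), oracle_scores(net, partners),
               tolerance = 1e-12)
})

test_that("label_vector marks partners and honors exclusion", {
  net <- functional_network(data.frame(a = "A", b = "B", lls = 1),
                            genes = c("A", "B", "C", "D", "E", "X"))
  l <- label_vector(net, c("A", "B"))
  expect_equal(sum(l), 2L)
  expect_equal(unname(l[c("A", "B")]), c(1L, 1L))

  l2 <- label_vector(net, c("A", "B"), exclude = "X")
  expect_false("X" %in% names(l2))
  s2 <- score_vector(net, c("A", "B"))
  expect_setequal(setdiff(names(s2), names(l2)), "X")

  set.seed(72)
  parts <- sample(network_genes(net), 3)
  excl <- sample(network_genes(net), 2)
  l3 <- label_vector(net, parts, exclude = excl)
  expect_equal(sum(l3), length(setdiff(parts, excl)))
})

test_that("roc_auc handles the degenerate and pure-tie cases", {
  expect_equal(roc_auc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(2, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "at least one")
  expect_error(roc_auc(1:4, c(0, 0, 0, 0)), "at least one")
})

test_that("roc_auc equals the pairwise oracle and satisfies its symmetries", {
  set.seed(81)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    scores <- sample(0:12, n, replace = TRUE) / 3   # heavy ties
    labels <- integer(n)
    labels[sample(n, sample(2:(n %/% 3), 1))] <- 1L
    a <- roc_auc(scores, labels)
    expect_equal(a, oracle_auc(scores, labels), tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(roc_auc(exp(scores), labels), a, tolerance = 1e-12)
    expect_equal(roc_auc(2 * scores + 7, labels), a, tolerance = 1e-12)
    # complementarity under label flip
    expect_equal(roc_auc(scores, 1L - labels), 1 - a, tolerance = 1e-12)
  }
})

test_that("a planted partner clique is called highly predictive", {
  # 5 partners mutually linked at LLS 5.0 over a sparse 0.1-weight background
  set.seed(91)
  partners <- sprintf("P%d", 1:5)
  others <- sprintf("o%02d", 1:45)
  clique <- t(combn(partners, 2))
  bg_pick <- t(combn(others, 2))
  bg_pick <- bg_pick[sample(nrow(bg_pick), 60), ]
  net <- functional_network(
    data.frame(a = c(clique[, 1], bg_pick[, 1]),
               b = c(clique[, 2], bg_pick[, 2]),
               lls = c(rep(5.0, nrow(clique)), rep(0.1, nrow(bg_pick)))))
  res <- evaluate_seed_set(net, seed_set("X", partners, "T"))
  expect_gte(res$auc, 0.9)
  expect_equal(res$n_positives, 5L)
})

test_that("random partner sets score near 0.5 on an uninformative network", {
  set.seed(101)
  aucs <- replicate(100, {
    net <- rand_network(40, 120)
    parts <- sample(network_genes(net), 4)
    evaluate_seed_set(net, seed_set("X", parts, "T"))$auc
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("evaluate_seed_set excludes the seed gene from the vectors", {
  net <- functional_network(data.frame(a = c("X", "A"), b = c("Z", "B"),
                                       lls = c(1, 2)),
                            genes = c("A", "B", "C", "X", "Z"))
  ss <- seed_set("X", c("A", "B"), "T")
  res <- evaluate_seed_set(net, ss)
  expect_false("X" %in% names(res$scores))
  expect_false("X" %in% names(res$labels))
  res_keep <- evaluate_seed_set(net, ss, exclude_seed = FALSE)
  expect_true("X" %in% names(res_keep$scores))

  # minimum-size (2-partner) seed set evaluates to a finite AUC
  expect_true(is.finite(res$auc))
  expect_equal(res$n_positives + res$n_negatives, length(res$scores))
})

test_that("evaluate_seed_set is deterministic", {
  set.seed(111)
  net <- rand_network(50, 140)
  ss <- seed_set("X", sample(network_genes(net), 4), "T")
  r1 <- evaluate_seed_set(net, ss)
  r2 <- evaluate_seed_set(net, ss)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$auc, r2$auc)
})

test_that("auc_sweep matches threshold counting and is non-increasing", {
  expect_equal(auc_sweep(c(1.0, 1.0), thresholds = 0.9)$proportion, 1.0)
  set.seed(121)
  aucs <- runif(200)
  sw <- auc_sweep(aucs)
  expect_equal(sw$proportion,
               vapply(sw$threshold, function(t) mean(aucs >= t), 1),
               tolerance = 1e-15)
  expect_true(all(diff(sw$proportion) <= 0))
  expect_equal(auc_sweep(aucs, thresholds = 0)$proportion, 1.0)
  expect_error(auc_sweep(numeric()), "no seed-set results")
  expect_error(auc_sweep(aucs, thresholds = c(0.5, 1.2)), "0, 1")
})
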