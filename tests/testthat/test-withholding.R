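star_gi <- function() {
  gi_table(rep("HUB", 10), sprintf("s%02d", 1:10), "T")
}

test_that("degree-based withholding removes hub pairs", {
  out <- withhold_by_degree(star_gi(), cutoff = 5, mode = "above")
  expect_equal(nrow(out$interactions), 0L)
  expect_equal(out$withheld_fraction, 1.0)

  # cutoff 0, mode above: every endpoint has degree >= 1 > 0
  set.seed(191)
  gi <- rand_gi(60, sprintf("g%02d", 1:15))
  out0 <- withhold_by_degree(gi, cutoff = 0, mode = "above")
  expect_equal(nrow(out0$interactions), 0L)
  expect_equal(out0$withheld_fraction, 1.0)
})

test_that("degree withholding matches a filter with full-set degrees", {
  set.seed(201)
  gi <- rand_gi(120, sprintf("g%02d", 1:20))
  deg <- gi_degree(gi)
  for (cutoff in c(1, 3, 6)) {
    above <- withhold_by_degree(gi, cutoff, "above")$interactions
    want_keep <- !(deg[gi$a] > cutoff | deg[gi$b] > cutoff)
    expect_equal(nrow(above), sum(want_keep))
    expect_setequal(paste(above$a, above$b, above$type),
                    paste(gi$a, gi$b, gi$type)[want_keep])
    below <- withhold_by_degree(gi, cutoff, "below")$interactions
    want_keep_b <- !(deg[gi$a] < cutoff & deg[gi$b] < cutoff)
    expect_equal(nrow(below), sum(want_keep_b))
  }
})

test_that("random withholding is reproducible and hits its boundaries", {
  set.seed(211)
  gi <- rand_gi(1200, sprintf("g%03d", 1:60))
  id <- withhold_random(gi, 0, rng_seed = 5)
  expect_identical(as.data.frame(id$interactions), as.data.frame(gi))
  expect_equal(id$withheld_fraction, 0)
  full <- withhold_random(gi, 1, rng_seed = 5)
  expect_equal(nrow(full$interactions), 0L)

  r1 <- withhold_random(gi, 0.5, rng_seed = 42)
  r2 <- withhold_random(gi, 0.5, rng_seed = 42)
  r3 <- withhold_random(gi, 0.5, rng_seed = 43)
  expect_identical(as.data.frame(r1$interactions),
                   as.data.frame(r2$interactions))
  expect_false(identical(as.data.frame(r1$interactions),
                         as.data.frame(r3$interactions)))
  expect_equal(r1$withheld_fraction, floor(0.5 * nrow(gi)) / nrow(gi))
})

test_that("withholding does not perturb the caller's RNG stream", {
  gi <- star_gi()
  set.seed(7)
  before <- runif(1)
  set.seed(7)
  invisible(withhold_random(gi, 0.5, rng_seed = 99))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("enrichment_curve reproduces the unwithheld run at proportion 0", {
  w <- generate_world(world_spec(rng_seed = 23))
  gi <- filter_gi(w$interactions,
                  interaction_type = w$spec$complex_interaction_type)
  direct <- enrich_complexes(w$complexes, gi, fdr = 0.05)
  plan <- withholding_plan("random_pairs", c(0, 1), rng_seed = 9,
                           replicates = 3)
  curve <- enrichment_curve(gi, w$complexes, plan, fdr = 0.05)
  expect_equal(curve$n_significant[curve$cutoff == 0],
               sum(direct$significant))
  expect_equal(curve$n_significant_min[curve$cutoff == 0],
               curve$n_significant_max[curve$cutoff == 0])
  # full withholding: k = 0 everywhere so every p-value is 1
  expect_equal(curve$n_significant[curve$cutoff == 1], 0)
})

test_that("withheld fraction grows with plan severity", {
  set.seed(221)
  gi <- rand_gi(300, sprintf("g%02d", 1:25))
  cpx <- complex_table(rep(sprintf("C%d", 1:5), each = 5),
                       sample(sprintf("g%02d", 1:25), 25))
  plan_deg <- withholding_plan("degree_above", c(20, 10, 5, 2), rng_seed = 1)
  cv <- enrichment_curve(gi, cpx, plan_deg)
  expect_true(all(diff(cv$withheld_fraction) >= 0))
  plan_rnd <- withholding_plan("random_pairs", c(0.2, 0.5, 0.8),
                               rng_seed = 1, replicates = 4)
  cv2 <- enrichment_curve(gi, cpx, plan_rnd)
  expect_true(all(diff(cv2$withheld_fraction) >= 0))
})

test_that("enrichment_curve is deterministic under its seed", {
  w <- generate_world(world_spec(rng_seed = 29, n_genes = 200L,
                                 n_modules = 5L, n_coherent_seeds = 5L,
                                 n_random_seeds = 5L,
                                 n_enriched_complexes = 4L,
                                 n_null_complexes = 10L))
  gi <- filter_gi(w$interactions,
                  interaction_type = w$spec$complex_interaction_type)
  plan <- withholding_plan("random_pairs", c(0.3, 0.6), rng_seed = 77,
                           replicates = 5)
  c1 <- enrichment_curve(gi, w$complexes, plan)
  c2 <- enrichment_curve(gi, w$complexes, plan)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("fixed-background mode reuses the original rate", {
  w <- generate_world(world_spec(rng_seed = 31))
  gi <- filter_gi(w$interactions,
                  interaction_type = w$spec$complex_interaction_type)
  plan <- withholding_plan("random_pairs", 0.9, rng_seed = 3, replicates = 2)
  recomputed <- enrichment_curve(gi, w$complexes, plan)
  fixed <- enrichment_curve(gi, w$complexes, plan,
                            recompute_background = FALSE)
  # with the original (larger) p held fixed, enrichment is harder to call
  expect_lte(fixed$n_significant, recomputed$n_significant)
})
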