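test_that("world_spec validates its feasibility constraints", {
  expect_error(world_spec(n_genes = 100L, n_modules = 10L,
                          module_size = 15L), "module demand")
  expect_error(world_spec(module_size = 2L), ">= 3")
  expect_error(world_spec(partners_per_seed = 1L), ">= 2")
  expect_error(world_spec(partner_noise = 1.5), "\\[0, 1\\]")
  expect_error(world_spec(n_genes = 160L, n_modules = 10L,
                          module_size = 15L, n_coherent_seeds = 20L),
               "non-module genes")
})

test_that("generated worlds satisfy the structural invariants", {
  w <- generate_world(world_spec(rng_seed = 37))
  net <- w$network
  expect_true(all(net$edges$a != net$edges$b))
  expect_equal(anyDuplicated(paste(net$edges$a, net$edges$b)), 0L)
  expect_true(all(net$edges$lls > 0 & is.finite(net$edges$lls)))
  expect_length(network_genes(net), w$spec$n_genes)

  gi <- w$interactions
  expect_true(all(gi$a != gi$b))
  expect_true(all(c(gi$a, gi$b) %in% network_genes(net)))

  # circularity guard: no interaction of the prediction (seed) layer is a
  # network edge; enrichment-layer pairs inside one module may legitimately
  # coincide with clique edges, since enrichment never consults the network
  seed_gi <- filter_gi(gi, interaction_type = w$spec$seed_interaction_type)
  net_keys <- paste(net$edges$a, net$edges$b)
  expect_length(intersect(paste(seed_gi$a, seed_gi$b), net_keys), 0L)

  # truth labels cover all seeds and complexes
  expect_equal(nrow(w$truth$seeds),
               w$spec$n_coherent_seeds + w$spec$n_random_seeds)
  expect_setequal(w$truth$complexes$complex_id,
                  unique(w$complexes$complex_id))
  expect_true(all(unlist(w$truth$partners) %in% network_genes(net)))
})

test_that("generation is deterministic under rng_seed", {
  w1 <- generate_world(world_spec(rng_seed = 41))
  w2 <- generate_world(world_spec(rng_seed = 41))
  w3 <- generate_world(world_spec(rng_seed = 42))
  expect_identical(w1$network$edges, w2$network$edges)
  expect_identical(as.data.frame(w1$interactions),
                   as.data.frame(w2$interactions))
  expect_identical(w1$truth, w2$truth)
  expect_false(identical(w1$network$edges, w3$network$edges))
})

test_that("noise-free isolated modules give the exact closed-form AUC", {
  # With no background edges and no out-of-module partners, every gene in
  # the seed's module outranks the rest: partners score (k-1)*w, the
  # module's other members k*w, everyone else 0. Hence each partner beats
  # exactly the zero-score negatives and AUC = n_zero / n_negatives.
  spec <- world_spec(partner_noise = 0, background_edge_prob = 0,
                     background_interaction_prob = 0, rng_seed = 43)
  w <- generate_world(spec)
  sets <- truth_seed_sets(w, "coherent")
  k <- spec$partners_per_seed
  n_neg <- spec$n_genes - 1L - k
  n_zero <- n_neg - (spec$module_size - k)
  for (s in sets[1:5]) {
    res <- evaluate_seed_set(w$network, s)
    expect_equal(res$auc, n_zero / n_neg, tolerance = 1e-12)
    expect_gte(res$auc, 0.9)
  }
})

test_that("module-coherent seeds are predictive, controls are not", {
  w <- generate_world(world_spec(rng_seed = 47))
  coh <- vapply(truth_seed_sets(w, "coherent"), function(s)
    evaluate_seed_set(w$network, s)$auc, 1)
  ctl <- vapply(truth_seed_sets(w, "control"), function(s)
    evaluate_seed_set(w$network, s)$auc, 1)
  expect_gte(mean(coh >= 0.9), 0.9)
  expect_lt(mean(ctl), mean(coh))
})

test_that("partner noise places the requested fraction outside the module", {
  spec <- world_spec(partner_noise = 0.5, partners_per_seed = 6L,
                     rng_seed = 53)
  w <- generate_world(spec)
  df <- w$truth$seeds
  for (i in which(df$coherent)) {
    mod <- w$truth$modules[[df$module[i]]]
    partners <- w$truth$partners[[df$seed[i]]]
    expect_equal(sum(!(partners %in% mod)),
                 floor(0.5 * spec$partners_per_seed))
  }
})

test_that("worlds round-trip through disk byte-identically", {
  spec <- world_spec(rng_seed = 59, n_genes = 120L, n_modules = 4L,
                     module_size = 8L, n_coherent_seeds = 4L,
                     partners_per_seed = 4L, n_random_seeds = 4L,
                     n_enriched_complexes = 3L, n_null_complexes = 5L)
  w <- generate_world(spec)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_world(w, d1)
  write_world(generate_world(spec), d2)
  for (f in c("network.tsv", "interactions.tsv", "complexes.tsv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  w2 <- read_world(d1)
  expect_identical(w2$network$edges, w$network$edges)
  expect_identical(network_genes(w2$network), network_genes(w$network))
  expect_identical(as.data.frame(w2$interactions),
                   as.data.frame(w$interactions))
  expect_identical(as.data.frame(w2$complexes), as.data.frame(w$complexes))
  expect_identical(w2$truth$seeds, w$truth$seeds)
})

test_that("minimum-size modules still produce a valid world", {
  spec <- world_spec(n_genes = 40L, n_modules = 2L, module_size = 3L,
                     partners_per_seed = 2L, n_coherent_seeds = 2L,
                     n_random_seeds = 2L, n_enriched_complexes = 1L,
                     n_null_complexes = 2L, complex_size_range = c(3L, 4L),
                     rng_seed = 61)
  w <- generate_world(spec)
  d <- withr::local_tempdir()
  paths <- write_world(w, d)
  expect_true(all(file.exists(paths)))
  expect_s3_class(read_world(d), "synthetic_world")
})
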