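test_that("empirical tails count ties in both tails", {
  t1 <- empirical_tails(2, c(1, 2, 3, 4))
  expect_equal(t1$p_low, 0.5)
  expect_equal(t1$p_high, 0.75)
  t2 <- empirical_tails(5, rep(5, 10))
  expect_equal(t2$p_low, 1)
  expect_equal(t2$p_high, 1)
  t3 <- empirical_tails(-10, 1:20)
  expect_equal(t3$p_low, 0)
  expect_equal(t3$p_high, 1)
  expect_error(empirical_tails(1, numeric(0)), "at least one")

  # p_low + p_high = 1 + ties/n, for any sample
  set.seed(1)
  for (i in 1:20) {
    sims <- sample(-5:5, 50, replace = TRUE)
    obs <- sample(-6:6, 1)
    tt <- empirical_tails(obs, sims)
    expect_equal(tt$p_low + tt$p_high, 1 + mean(sims == obs))
  }

  expect_equal(format_empirical_p(0, 2000), "<0.0005")
  expect_equal(format_empirical_p(0.316, 2000), "0.316")
})

test_that("delta is antisymmetric, zero on identical trees, additive", {
  pair <- limenitis_hypothesis_pair()
  swapped <- hypothesis_pair(pair$tree_MM, pair$tree_R)
  same <- hypothesis_pair(pair$tree_R, pair$tree_R)
  trees <- simulate_replicate(limenitis_model("R2"), seed = 21)
  map <- setNames(sub("\\|.*$", "", unique(unlist(lapply(trees, `[[`,
                                                         "tip.label")))),
                  unique(unlist(lapply(trees, `[[`, "tip.label"))))
  d <- delta_statistic(trees, map, pair)
  expect_equal(delta_statistic(trees, map, swapped), -d)
  expect_equal(delta_statistic(trees, map, same), 0)
  # additivity over loci
  per_locus <- vapply(trees, function(t) delta_statistic(list(t), map, pair),
                      numeric(1))
  expect_equal(sum(per_locus), d)
  # and delta decomposes as the difference of the two summed counts
  expect_equal(d, summed_dc(trees, map, pair$tree_R) -
                 summed_dc(trees, map, pair$tree_MM))
})

test_that("observed statistics are validated and default to the study's", {
  obs <- limenitis_observed()
  expect_equal(obs$delta, -15)
  expect_equal(obs$dc_R, 93)
  expect_equal(obs$dc_MM, 108)
  expect_error(observed_statistics(dc_R = 93, dc_MM = 108, delta = -10),
               "must equal")
  expect_error(summed_dc(list(), limenitis_observed,
                         limenitis_hypothesis_pair()$tree_R),
               "at least one")
})

test_that("hypothesis pairs must share a leaf set", {
  expect_error(hypothesis_pair("((A,B),C);", "(A,B);"), "leaf set")
  # nonbinary species trees are allowed as long as they are rooted
  expect_no_error(hypothesis_pair("((A,B,C),D);", "(((A,B),C),D);"))
  pair <- limenitis_hypothesis_pair()
  expect_setequal(pair$tree_R$tip.label, limenitis_lineages)
  expect_true(ape::is.monophyletic(pair$tree_R, c("arthemis", "astyanax")))
  expect_true(ape::is.monophyletic(pair$tree_MM,
                                   c("arizonensis", "astyanax")))
})

test_that("model evaluation is seeded, reproducible, and decides support", {
  m <- limenitis_model("R2")
  fit1 <- evaluate_model(m, nreps = 40, seed = 3,
                         sampling = tiny_sampling())
  fit2 <- evaluate_model(m, nreps = 40, seed = 3,
                         sampling = tiny_sampling())
  expect_identical(fit1$replicates, fit2$replicates)
  expect_equal(fit1$replicates$delta,
               fit1$replicates$dc_R - fit1$replicates$dc_MM)
  expect_s3_class(glance(fit1), "tbl_df")
  expect_equal(nrow(tidy(fit1)), 40)

  # an observation far outside the simulated range is rejected on the
  # first criterion under either support rule
  obs <- observed_statistics(dc_R = 0, dc_MM = 1000)
  lo <- evaluate_model(m, observed = obs, nreps = 40, seed = 3,
                       sampling = tiny_sampling())
  expect_equal(lo$tails_delta$p_low, 0)
  expect_false(lo$supported)
  expect_false(evaluate_model(m, observed = obs, nreps = 40, seed = 3,
                              sampling = tiny_sampling(),
                              support_rule = "central")$supported)

  # an observation at the simulated median is supported
  med <- fit1$replicates
  obs2 <- observed_statistics(
    dc_R = round(stats::median(med$dc_R)),
    dc_MM = round(stats::median(med$dc_R)) -
      round(stats::median(med$delta)))
  hi <- evaluate_model(m, observed = obs2, nreps = 40, seed = 3,
                       sampling = tiny_sampling())
  expect_true(hi$supported)
})

test_that("the support rules differ exactly at the alpha/2..alpha band", {
  tails_mid <- empirical_tails(3, c(rep(1, 96), 2, 3, 3, 4))
  # min tail = 0.03: inside the central 95% but below the 0.05 tail rule
  expect_false(dcboot:::min_tail_ok(tails_mid, 0.05, "tail"))
  expect_true(dcboot:::min_tail_ok(tails_mid, 0.05, "central"))
})

test_that("a model suite summarizes one row per model, deterministically", {
  models <- limenitis_models()[c("MM1", "R2")]
  s1 <- run_model_suite(models, nreps = 30, seed = 9,
                        sampling = tiny_sampling())
  s2 <- run_model_suite(models, nreps = 30, seed = 9,
                        sampling = tiny_sampling())
  expect_identical(s1$summary, s2$summary)
  expect_equal(nrow(tidy(s1)), 2)
  expect_equal(tidy(s1)$model_id, c("MM1", "R2"))
  g <- glance(s1)
  expect_equal(g$n_models, 2)
  expect_true(all(c("n_supported", "supported_models") %in% names(g)))
  # autoplot builds without evaluating devices
  expect_s3_class(autoplot(s1), "ggplot")
  expect_s3_class(autoplot(s1$results$MM1), "ggplot")
})
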