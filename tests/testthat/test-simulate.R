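test_that("simulation is reproducible and validates its configuration", {
  s1 <- simulate_trios(n_genes = 50, seed = 5)
  s2 <- simulate_trios(n_genes = 50, seed = 5)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$truth, s2$truth)
  expect_true(all(s1$expression$values > 0))

  bad <- mode_class_proportions(); bad[1] <- bad[1] + 0.1
  expect_error(simulate_trios(class_proportions = bad), "sum to 1")
  expect_error(simulate_trios(effect_size = 1), "effect_size")
  expect_error(simulate_trios(noise_sd = -1), "noise_sd")
})

test_that("an all-transgressive-up simulation is up versus both parents", {
  props <- stats::setNames(rep(0, 13), c(as.character(1:12), "none"))
  props[c("5", "6", "8")] <- 1 / 3
  sim <- simulate_trios(n_genes = 200, class_proportions = props,
                        noise_sd = 0, seed = 1, n_crosses = 1)
  calls <- call_degs(sim$expression, sim$trios$A)
  expect_true(all(calls$call == "up"))
})

test_that("noise-free classification recovers every truth label", {
  sim <- simulate_trios(n_genes = 1000, noise_sd = 0, seed = 20)
  for (cr in names(sim$trios)) {
    cl <- classify_modes(sim$expression, sim$trios[[cr]])
    truth <- sim$truth[sim$truth$cross_id == cr, ]
    truth <- truth[match(cl$gene_id, truth$gene_id), ]
    expect_identical(cl$class, truth$class)
  }
})

test_that("misclassification is monotone in the noise level", {
  rates <- sapply(c(0, 0.1, 0.25, 0.5), function(sd) {
    sim <- simulate_trios(n_genes = 1500, noise_sd = sd, seed = 31)
    cl <- classify_modes(sim$expression, sim$trios$A)
    truth <- sim$truth[sim$truth$cross_id == "A", ]
    truth <- truth[match(cl$gene_id, truth$gene_id), ]
    mean(cl$class != truth$class)
  })
  expect_equal(rates[1], 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("injected cross-overlap genes drive the universal DEG sets", {
  sim <- simulate_trios(n_genes = 34, noise_sd = 0, seed = 2,
                        n_universal_up = 11, n_universal_down = 7,
                        n_discordant_ab = 14, n_discordant_ba = 2)
  commons <- lapply(sim$trios, function(tr)
    common_degs_per_cross(call_degs(sim$expression, tr), tr))
  sets <- universal_degs(commons$A, commons$B)
  expect_length(sets$universal_up, 11)
  expect_length(sets$universal_down, 7)
  expect_length(sets$discordant, 16)
  expect_error(simulate_trios(n_genes = 5, n_universal_up = 6), "exceeds")
  expect_error(simulate_trios(n_genes = 5, n_crosses = 1, n_universal_up = 2),
               "n_crosses = 2")
})

test_that("simulated trait trios carry exact heterosis ground truth", {
  tt <- simulate_trait_trios(n_traits = 40, seed = 9)
  het <- heterosis_table(tt)
  merged <- merge(het, tt[, c("trait_name", "true_mph", "true_hph")],
                  by = "trait_name")
  expect_equal(merged$mph_percent, merged$true_mph, tolerance = 1e-9)
  expect_equal(merged$hph_percent, merged$true_hph, tolerance = 1e-9)

  neg <- simulate_trait_trios(n_traits = 20, mph_range = c(-60, -55), seed = 4)
  het_neg <- heterosis_table(neg)
  expect_true(all(het_neg$mph_percent < 0))
  expect_true(all(het_neg$hph_percent < 0))  # F1 below MP < HP

  # constructed inversion: F1 = 1.3101 * MP gives MPH 31.01
  expect_equal(mid_parent_heterosis(37.2, 34.7, 1.3101 * (37.2 + 34.7) / 2),
               31.01)
  expect_equal(high_parent_heterosis(5, 8, 8), 0)
})
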