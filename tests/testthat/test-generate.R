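test_that("profile generation is deterministic and matches the survey design", {
  cfg <- tiny_config(n_subjects = 225, n_facets_per_trait = 3,
                     n_items_per_facet = 4, scale_min = 1, scale_max = 5)
  p1 <- generate_profiles(cfg)
  p2 <- generate_profiles(cfg)
  expect_identical(p1, p2)
  # faceted 60-item design: 5 traits x 3 facets x 4 items
  expect_equal(ncol(p1$item_responses), 60L)
  expect_equal(nrow(p1$item_responses), 225L)
  expect_equal(length(unique(p1$keying$facet)), 15L)
  expect_true(all(p1$item_responses >= 1 & p1$item_responses <= 5))
  expect_true(all(p1$item_responses == round(p1$item_responses)))
  # every item keyed to exactly one facet and trait
  expect_equal(anyDuplicated(p1$keying$item), 0L)
  expect_true(all(colnames(p1$item_responses) %in% p1$keying$item))
})

test_that("noise-free items are internally consistent (alpha = 1)", {
  cfg <- tiny_config(n_subjects = 40, item_noise_sd = 0,
                     n_items_per_facet = 4)
  prof <- generate_profiles(cfg)
  keyed <- prof$item_responses
  rev <- prof$keying$reverse[match(colnames(keyed), prof$keying$item)]
  keyed[, rev] <- sum(prof$scale) - keyed[, rev]
  for (f in unique(prof$keying$facet)) {
    cols <- prof$keying$item[prof$keying$facet == f]
    # all keyed items within a facet identical up to rounding
    expect_true(all(apply(keyed[, cols], 1, function(x) diff(range(x))) <= 1))
    expect_gt(cronbach_alpha(keyed[, cols]), 0.98)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(gen_config(scale_min = 5, scale_max = 5), "scale bounds")
  expect_error(gen_config(n_images = 10, n_categories = 3), "multiple")
  expect_error(gen_config(gaze_coupling = 1.5), "gaze_coupling")
  expect_error(gen_config(n_subjects = 0), "count")
  cfg <- tiny_config(n_voxels_per_region = 2)
  expect_error(generate_fmri_dataset(generate_profiles(cfg), cfg),
               "n_voxels_per_region")
})

test_that("closed-form oracle obeys its algebraic special cases", {
  cfg <- list(shared_signal_weight = 1, trait_coupling = 1, noise_sd = 1)
  # orthogonal unit traits: (1 + 0) / sqrt(3 * 3) = 1/3
  expect_equal(expected_dyad_correlation(c(1, 0), c(0, 1), cfg), 1 / 3)
  # identical traits, sigma = 0 -> perfect synchrony
  cfg0 <- list(shared_signal_weight = 1, trait_coupling = 1, noise_sd = 0)
  p <- c(0.4, -1.2, 0.7)
  expect_equal(expected_dyad_correlation(p, p, cfg0), 1)
  # gamma = 0 -> a^2 / (a^2 + sigma^2), independent of traits
  cfgg <- list(shared_signal_weight = 2, trait_coupling = 0, noise_sd = 1)
  expect_equal(expected_dyad_correlation(c(9, 9), c(-3, 0), cfgg), 4 / 5)
  expect_error(
    expected_dyad_correlation(c(1, 1), c(1, 1),
      list(shared_signal_weight = 0, trait_coupling = 0, noise_sd = 0)),
    "undefined")
})

test_that("generated magnitude series converge to the correlation oracle", {
  cfg <- tiny_config(n_subjects = 2, n_regions = 1, n_subcortical = 0,
                     n_runs = 1, n_timepoints_per_run = 50000,
                     shared_signal_weight = 1, trait_coupling = 0.5,
                     noise_sd = 1, seed = 202)
  prof <- generate_profiles(cfg)
  fmri <- generate_fmri_dataset(prof, cfg)
  r_emp <- nm_synchrony(fmri$magnitude[1, 1, ], fmri$magnitude[2, 1, ])
  r_exp <- expected_dyad_correlation(prof$latent_traits[1, ],
                                     prof$latent_traits[2, ], cfg)
  expect_lt(abs(r_emp - r_exp), 0.02)
})

test_that("degenerate coupling limits behave as the model predicts", {
  # gamma = 0, sigma ~ 0: synchrony ~ 1 regardless of personality
  cfg <- tiny_config(n_subjects = 4, n_regions = 2, n_subcortical = 0,
                     n_runs = 1, n_timepoints_per_run = 300,
                     trait_coupling = 0, noise_sd = 1e-8)
  fmri <- generate_fmri_dataset(generate_profiles(cfg), cfg)
  for (r in 1:2)
    expect_equal(nm_synchrony(fmri$magnitude[1, r, ], fmri$magnitude[2, r, ]),
                 1, tolerance = 1e-6)
  # gamma = 0, a = 0: pure noise, synchrony ~ 0
  cfg0 <- tiny_config(n_subjects = 4, n_regions = 1, n_subcortical = 0,
                      n_runs = 1, n_timepoints_per_run = 20000,
                      shared_signal_weight = 0, trait_coupling = 0,
                      noise_sd = 1, seed = 5)
  fmri0 <- generate_fmri_dataset(generate_profiles(cfg0), cfg0)
  expect_lt(abs(nm_synchrony(fmri0$magnitude[1, 1, ],
                             fmri0$magnitude[2, 1, ])), 0.03)
})

test_that("EEG generator limits: identical epochs at zero noise, null ISC for pure noise", {
  cfg <- tiny_config(n_subjects = 3, n_channels = 6, epoch_length = 100,
                     n_images = 2, n_categories = 2, noise_sd = 0,
                     trait_coupling = 0)
  eeg <- generate_eeg_dataset(generate_profiles(cfg), cfg)
  expect_equal(eeg$epochs[1, , , ], eeg$epochs[2, , , ])
  expect_equal(dim(eeg$epochs), c(3L, 2L, 6L, 100L))

  cfg0 <- tiny_config(n_subjects = 2, n_channels = 4, epoch_length = 1500,
                      n_images = 20, n_categories = 2,
                      shared_signal_weight = 0, trait_coupling = 0,
                      noise_sd = 1, seed = 31)
  eeg0 <- generate_eeg_dataset(generate_profiles(cfg0), cfg0)
  isc <- dyad_isc(eeg0$epochs[1, , , ], eeg0$epochs[2, , , ],
                  n_components = 3)
  expect_lt(abs(isc), 0.05)
})

test_that("gaze generator: exchangeable at zero coupling, trait-ordered at full coupling", {
  # one attractor, zero dispersion: every subject fixates one point
  cfg1 <- tiny_config(n_subjects = 4, attractors_per_image = 1,
                      attractor_sd = 0, n_images = 3, n_categories = 3)
  gz1 <- generate_gaze_dataset(generate_profiles(cfg1), cfg1)
  tab1 <- gaze_similarity_table(gz1)
  expect_equal(tab1$value, rep(0, 6))

  # gaze_coupling = 0: regression of gaze similarity on personality
  # similarity is null (95% CI covers 0 over replicate datasets)
  betas <- vapply(1:20, function(rep) {
    cfg <- tiny_config(n_subjects = 10, gaze_coupling = 0, n_images = 4,
                       n_categories = 2, seed = 400 + rep)
    prof <- generate_profiles(cfg)
    gz <- generate_gaze_dataset(prof, cfg)
    tab <- build_dyad_table(prof, gaze = gaze_similarity_table(gz))
    fit <- standardized_ols(tab, "gaze_similarity", "personality_similarity")
    fit$coefficients$beta[1]
  }, numeric(1))
  ci <- mean(betas) + c(-2, 2) * sd(betas) / sqrt(length(betas))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("full-coupling gaze: identical-trait dyads beat maximally distant dyads", {
  cfg <- tiny_config(n_subjects = 4, gaze_coupling = 1, n_images = 10,
                     n_categories = 2, attractors_per_image = 4,
                     attractor_sd = 20, n_fixations_per_image = 12,
                     seed = 77)
  prof <- generate_profiles(cfg)
  # plant traits: subjects 1-2 identical, 3-4 opposite extremes
  prof$latent_traits[1, ] <- 1.5
  prof$latent_traits[2, ] <- 1.5
  prof$latent_traits[3, ] <- -1.5
  prof$latent_traits[4, ] <- 1.5
  gz <- generate_gaze_dataset(prof, cfg)
  same <- dyad_gaze_similarity(1, 2, gz)
  diff <- dyad_gaze_similarity(1, 3, gz)
  expect_gt(same, diff)
})
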