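test_that("dyad table assembly yields the design counts and flags mismatches", {
  cfg3 <- tiny_config(n_subjects = 3)
  tab3 <- build_dyad_table(generate_profiles(cfg3))
  expect_equal(nrow(tab3), 3L)

  cfg <- tiny_config(n_subjects = 6, n_regions = 2, n_subcortical = 0,
                     n_runs = 2, n_timepoints_per_run = 25)
  prof <- generate_profiles(cfg)
  fmri <- generate_fmri_dataset(prof, cfg)
  syn <- dyadic_synchrony_table(fmri)
  tab <- build_dyad_table(prof, synchrony = syn)
  expect_equal(nrow(tab), 15L)
  expect_true(all(c("NM_R001", "NP_R002", "personality_similarity",
                    "gender_similarity") %in% names(tab)))

  bad <- syn
  bad$subject_a <- sub("S", "X", bad$subject_a)
  expect_error(build_dyad_table(prof, synchrony = bad), "inconsistent")
})

test_that("standardized OLS returns correlations and normal-equation solutions", {
  cfg <- tiny_config(n_subjects = 8, seed = 3)
  prof <- generate_profiles(cfg)
  set.seed(30)
  tab <- table_with_outcomes(prof, list(y = rnorm(28)))

  # single predictor: beta equals the dyadic Pearson correlation
  fit <- standardized_ols(tab, "y", "personality_similarity")
  expect_equal(fit$coefficients$beta[1],
               cor(tab$y, tab$personality_similarity), tolerance = 1e-12)

  # outcome identical to predictor: beta 1, residuals 0
  tab$y2 <- tab$personality_similarity
  fit2 <- standardized_ols(tab, "y2", "personality_similarity")
  expect_equal(fit2$coefficients$beta[1], 1, tolerance = 1e-12)
  expect_lt(max(abs(fit2$residuals)), 1e-12)

  # two-predictor toy solved by hand via the normal equations
  toy <- data.frame(y = c(1, 3, 2, 5, 4, 6), x1 = c(1, 2, 3, 4, 5, 6),
                    x2 = c(2, 1, 4, 3, 6, 5))
  fit3 <- standardized_ols(toy, "y", c("x1", "x2"))
  Z <- scale(toy)
  beta_hand <- solve(crossprod(Z[, 2:3]), crossprod(Z[, 2:3], Z[, 1]))
  expect_equal(fit3$coefficients$beta, as.numeric(beta_hand),
               tolerance = 1e-10)

  # collinear designs are named
  toy$x3 <- toy$x1
  expect_error(standardized_ols(toy, "y", c("x1", "x3")), "collinear")
})

test_that("subject permutation test resolves mechanical and null effects", {
  cfg <- tiny_config(n_subjects = 12, seed = 8)
  prof <- generate_profiles(cfg)
  tab <- build_dyad_table(prof)

  # outcome mechanically equal to the predictor: minimum attainable p
  tab$y <- tab$personality_similarity
  pr <- subject_permutation_test(tab, "y", "personality_similarity",
                                 n_permutations = 999, seed = 2)
  expect_equal(pr$beta_obs, 1, tolerance = 1e-12)
  expect_equal(pr$p_permutation, 1 / 1000)

  # pure-noise outcome: permutation p well away from the floor
  set.seed(31)
  tab$y0 <- rnorm(nrow(tab))
  pr0 <- subject_permutation_test(tab, "y0", "personality_similarity",
                                  n_permutations = 199, seed = 3)
  expect_gt(pr0$p_permutation, 0.05)
  expect_true(pr0$p_permutation <= 1)
})

test_that("statistics are invariant under consistent subject relabeling", {
  cfg <- tiny_config(n_subjects = 9, seed = 15)
  prof <- generate_profiles(cfg)
  set.seed(44)
  tab <- table_with_outcomes(prof, list(y = rnorm(36)))
  fit <- standardized_ols(tab, "y", "personality_similarity",
                          covariates = "age_similarity")

  # relabel subjects: remap every dyadic column through the same relabeling
  n <- 9
  pairs <- attr(tab, "pair_index")
  lookup <- dyadsync:::pair_lookup(n, pairs)
  perm <- c(4, 1, 9, 2, 7, 3, 8, 5, 6)
  remap <- lookup[cbind(perm[pairs$a], perm[pairs$b])]
  tab2 <- tab
  for (cl in setdiff(names(tab), c("subject_a", "subject_b")))
    tab2[[cl]] <- tab[[cl]][remap]
  fit2 <- standardized_ols(tab2, "y", "personality_similarity",
                           covariates = "age_similarity")
  expect_equal(fit2$coefficients$beta, fit$coefficients$beta,
               tolerance = 1e-12)
})

test_that("BH-FDR matches a brute-force step-up scan", {
  # worked example: thresholds i * q / 4 reject all four
  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$rejected))
  expect_false(any(fdr_bh(rep(1, 5))$rejected))
  expect_true(fdr_bh(0.04, q = 0.05)$rejected)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  brute_force_bh <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ks <- which(p[o] <= seq_len(m) * q / m)
    rej <- logical(m)
    if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
    rej
  }
  set.seed(50)
  for (i in 1:200) {
    m <- sample(1:6, 1)
    p <- sample(seq(0, 1, by = 0.01), m, replace = TRUE)
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_identical(fdr_bh(p, q)$rejected, brute_force_bh(p, q))
  }
})

test_that("network coefficient tests equal the one-sample t formula", {
  b <- c(0.1, 0.2, 0.15, 0.25)
  res <- network_coefficient_test(b, rep("DMN", 4))
  t_hand <- mean(b) / (sd(b) / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_error(network_coefficient_test(rep(0, 4), rep("DMN", 4)),
               "zero-variance")
  expect_error(network_coefficient_test(0.3, "DMN"), "fewer than 2")

  # null betas -> uniform p-values across many networks
  set.seed(51)
  betas <- rnorm(400)
  labels <- rep(sprintf("N%02d", 1:40), each = 10)
  ps <- network_coefficient_test(betas, labels)$p
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("per-subject effects use n-1 observations each", {
  cfg <- tiny_config(n_subjects = 16, seed = 12)
  prof <- generate_profiles(cfg)
  tab <- build_dyad_table(prof)
  tab$y <- tab$personality_similarity
  res <- per_subject_effects(tab, "y", "personality_similarity")
  expect_equal(res$n_obs_per_subject, 15L)
  expect_equal(unname(res$betas), rep(1, 16), tolerance = 1e-10)
  expect_equal(res$fraction_positive, 1)
})

test_that("mediation decomposition obeys c = c' + a*b and recovers structure", {
  cfg <- tiny_config(n_subjects = 14, seed = 9)
  prof <- generate_profiles(cfg)
  n_dyads <- 14 * 13 / 2
  set.seed(60)
  tab <- table_with_outcomes(prof, list(
    m = rnorm(n_dyads), y = rnorm(n_dyads)))
  med <- mediation_analysis(tab, "personality_similarity", "m", "y",
                            n_permutations = 99, seed = 4)
  expect_equal(med$total_c$beta,
               med$direct_c_prime$beta + med$indirect$beta,
               tolerance = 1e-8)

  # fully mediated chain: indirect ~ total, direct ~ 0
  set.seed(61)
  x <- tab$personality_similarity
  tab$m_c <- scale(x)[, 1] + 0.3 * rnorm(n_dyads)
  tab$y_c <- tab$m_c + 0.3 * rnorm(n_dyads)
  med_c <- mediation_analysis(tab, "personality_similarity", "m_c", "y_c",
                              n_permutations = 199, seed = 5)
  expect_gt(med_c$indirect$beta, 0.5 * med_c$total_c$beta)
  expect_lt(abs(med_c$direct_c_prime$beta), 0.25)
  expect_lt(med_c$path_a$p_permutation, 0.05)

  # null-b construction: indirect permutation p rarely significant
  ps <- vapply(1:20, function(rep) {
    set.seed(600 + rep)
    tabr <- tab
    tabr$m_n <- rnorm(n_dyads)
    tabr$y_n <- scale(x)[, 1] + rnorm(n_dyads)
    mediation_analysis(tabr, "personality_similarity", "m_n", "y_n",
                       n_permutations = 99, seed = 6)$indirect$p_permutation
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("effect-size comparisons use pooled-variance t with df = 2k - 2", {
  cm <- cbind(personality = rep(0.2, 6),
              gender = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.2))
  res <- compare_effect_sizes(cm, "personality", "gender")
  expect_equal(res$df, 10)
  # hand-computed pooled t
  sp2 <- (5 * var(cm[, 1]) + 5 * var(cm[, 2])) / 10
  t_hand <- (mean(cm[, 1]) - mean(cm[, 2])) / sqrt(sp2 * (2 / 6))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(compare_effect_sizes(cbind(a = 1:5, b = 1:5), "a", "b")$t, 0)
  expect_error(compare_effect_sizes(cbind(a = 1), "a", "a"), "focal")
})

test_that("coefficient contrasts use the joint model covariance", {
  set.seed(70)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(y = x1 + 0.2 * x2 + rnorm(n), x1 = x1, x2 = x2)
  fit <- standardized_ols(d, "y", c("x1", "x2"))
  ct <- coefficient_contrast(fit, "x1", "x2")
  expect_equal(ct$difference,
               fit$coefficients$beta[1] - fit$coefficients$beta[2])
  expect_lt(ct$p, 0.01)
  ct_same <- coefficient_contrast(fit, "x1", "x1")
  expect_equal(ct_same$difference, 0)
})
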