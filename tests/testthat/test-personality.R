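test_that("trait scoring reflects reverse-keyed items and averages facets", {
  keying <- make_keying("agreeableness")
  resp <- matrix(c(7, 1), 1, 2,
                 dimnames = list("S1", keying$item))
  sc <- score_traits(resp, keying, 1, 7)
  # (7, 1) with the second item reverse-keyed reflects to (7, 7)
  expect_equal(unname(sc$facets[1, 1]), 7)
  expect_equal(unname(sc$traits[1, 1]), 7)

  # all items at midpoint -> all trait scores at midpoint
  keying5 <- make_keying(letters[1:5])
  resp5 <- matrix(4, 3, 10, dimnames = list(NULL, keying5$item))
  sc5 <- score_traits(resp5, keying5, 1, 7)
  expect_true(all(sc5$traits == 4))

  # faceted design yields 5 traits and 15 facets
  cfg <- tiny_config(n_subjects = 6, n_facets_per_trait = 3,
                     n_items_per_facet = 4, scale_min = 1, scale_max = 5)
  prof <- generate_profiles(cfg)
  sc2 <- score_traits(prof$item_responses, prof$keying, 1, 5)
  expect_equal(ncol(sc2$traits), 5L)
  expect_equal(ncol(sc2$facets), 15L)

  resp_na <- resp; resp_na[1, 1] <- NA
  expect_error(score_traits(resp_na, keying, 1, 7), "missing")
})

test_that("cronbach alpha matches its defining formula", {
  # duplicated columns -> alpha = 1
  set.seed(1)
  x <- rnorm(30)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # population covariance [[1, .5], [.5, 1]] -> alpha = 2 * (1 - 2/3) = 2/3
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  items <- MASS::mvrnorm(50, mu = c(0, 0), Sigma = S, empirical = TRUE)
  expect_equal(cronbach_alpha(items), 2 / 3, tolerance = 1e-10)
  # independent items -> alpha ~ 0
  set.seed(2)
  noise <- matrix(rnorm(5000 * 4), 5000, 4)
  expect_lt(abs(cronbach_alpha(noise)), 0.1)
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "variance")
  expect_error(cronbach_alpha(matrix(rnorm(5), 5, 1)), "2 items")
})

test_that("similarity metrics match hand-computed distances", {
  x <- c(7, 5, 3, 6, 2); y <- c(4, 1, 3, 2, 6)
  # |diffs| = (3, 4, 0, 4, 4); sum of squares = 57
  expect_equal(personality_similarity(x, y, similarity_metric("euclidean")),
               -sqrt(57))
  expect_equal(personality_similarity(x, y, similarity_metric("manhattan")),
               -15)
  expect_equal(personality_similarity(x, y, similarity_metric("supremum")),
               -4)
  expect_equal(personality_similarity(x, y, similarity_metric("canberra")),
               -(3 / 11 + 4 / 6 + 0 / 6 + 4 / 8 + 4 / 8))
  expect_equal(personality_similarity(x, y,
               similarity_metric("euclidean", invert = FALSE)), sqrt(57))
  # identity: zero distance under every metric
  for (m in c("euclidean", "manhattan", "canberra", "supremum"))
    expect_equal(personality_similarity(x, x, similarity_metric(m)), 0)
  expect_error(personality_similarity(1:3, 1:4), "length")
  expect_error(personality_similarity(c(1, -1), c(-1, 1),
                                      similarity_metric("canberra")),
               "canberra")
})

test_that("metric inequalities and triangle inequality hold on random triples", {
  set.seed(42)
  specs <- lapply(c("euclidean", "manhattan", "supremum"),
                  similarity_metric, invert = FALSE)
  for (i in 1:1000) {
    v <- matrix(rnorm(15), 3, 5)
    d_e <- personality_similarity(v[1, ], v[2, ], specs[[1]])
    d_m <- personality_similarity(v[1, ], v[2, ], specs[[2]])
    d_s <- personality_similarity(v[1, ], v[2, ], specs[[3]])
    expect_true(d_e <= d_m + 1e-12)
    expect_true(d_s <= d_e + 1e-12)
    expect_true(d_e >= 0 && d_m >= 0 && d_s >= 0)
    for (sp in specs) {
      dij <- personality_similarity(v[1, ], v[2, ], sp)
      dik <- personality_similarity(v[1, ], v[3, ], sp)
      dkj <- personality_similarity(v[3, ], v[2, ], sp)
      expect_true(dij <= dik + dkj + 1e-12)
    }
  }
})

test_that("similarities are symmetric in subject order", {
  set.seed(3)
  x <- rnorm(5); y <- rnorm(5)
  for (m in c("euclidean", "manhattan", "canberra", "supremum"))
    expect_equal(personality_similarity(x, y, similarity_metric(m)),
                 personality_similarity(y, x, similarity_metric(m)))
  pi1 <- list(gender = "female", age = 18, handedness = "right",
              nationality = "USA", ethnicity = "Asian;Mixed",
              political_ideology = 2)
  pj1 <- list(gender = "female", age = 21, handedness = "left",
              nationality = "UK", ethnicity = "Mixed",
              political_ideology = 6)
  s_ij <- demographic_similarity(pi1, pj1)
  s_ji <- demographic_similarity(pj1, pi1)
  expect_equal(s_ij, s_ji)
})

test_that("socio-demographic codings follow the binary/absolute-difference rules", {
  pi1 <- list(gender = "female", age = 18, handedness = "right",
              nationality = "USA", ethnicity = "Asian;Mixed",
              political_ideology = 2)
  pj1 <- list(gender = "female", age = 21, handedness = "left",
              nationality = "UK", ethnicity = "Mixed",
              political_ideology = 6)
  s <- demographic_similarity(pi1, pj1)
  expect_equal(s$gender_similarity, 1)          # same gender
  expect_equal(s$age_similarity, -3)            # |18 - 21| negated
  expect_equal(s$handedness_similarity, 0)
  expect_equal(s$nationality_similarity, 0)
  expect_equal(s$ethnicity_similarity, 1)       # {Asian, Mixed} & {Mixed}
  expect_equal(s$politics_similarity, -4)
  pj2 <- pj1; pj2$ethnicity <- "Black/African"
  expect_equal(demographic_similarity(pi1, pj2)$ethnicity_similarity, 0)
  expect_error(demographic_similarity(pi1[-1], pj1), "missing")
})

test_that("split-half reliability tracks item noise", {
  # noise-free inventory: both halves identical up to rounding
  cfg0 <- tiny_config(n_subjects = 30, item_noise_sd = 0,
                      n_items_per_facet = 4)
  prof0 <- generate_profiles(cfg0)
  r0 <- split_half_reliability(prof0$item_responses, prof0$keying, 1, 7)
  expect_gt(r0, 0.95)

  # pure-noise items: reliability ~ 0
  set.seed(9)
  keying <- make_keying(letters[1:5], 4L, reverse_second = FALSE)
  noise <- matrix(sample(1:7, 200 * 20, TRUE), 200, 20,
                  dimnames = list(NULL, keying$item))
  r_noise <- split_half_reliability(noise, keying, 1, 7)
  expect_lt(abs(r_noise), 0.1)

  # reliability decreases monotonically in item noise (averaged replicates)
  mean_rel <- vapply(c(0, 1, 3), function(nsd) {
    mean(vapply(1:10, function(rep) {
      cfg <- tiny_config(n_subjects = 25, item_noise_sd = nsd,
                         n_items_per_facet = 4, seed = 500 + rep)
      prof <- generate_profiles(cfg)
      split_half_reliability(prof$item_responses, prof$keying, 1, 7)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rel) < 0))
})

test_that("n subjects yield exactly n(n-1)/2 dyad rows", {
  cfg <- tiny_config(n_subjects = 7)
  tab <- build_dyad_table(generate_profiles(cfg))
  expect_equal(nrow(tab), 21L)
  expect_equal(anyDuplicated(tab[, c("subject_a", "subject_b")]), 0L)
  expect_true(all(tab$subject_a < tab$subject_b))
})
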