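#' @title Synthetic multi-subject study generators
#' @description
#' The generators in this file produce surveys, region-level fMRI-like data,
#' multichannel EEG-like epochs, and fixation sequences for a set of
#' subjects whose cross-subject (dyadic) structure is controlled by a small
#' number of coupling parameters. Each subject carries a latent trait vector
#' \eqn{p_i}; neural signals mix a stimulus-driven component shared by all
#' subjects (weight `a`) with trait-weighted shared components (weight
#' `gamma`), so that the expected cross-subject correlation of any two
#' subjects' signals is an increasing function of \eqn{p_i \cdot p_j} with
#' the closed form in [expected_dyad_correlation()]. Setting `gamma = 0`
#' makes synchrony independent of personality (the null model).
#' @name synthetic-data
NULL

# Unit-variance smooth signal: moving-average filtered white noise.
smooth_unit_signal <- function(n, window) {
  x <- stats::rnorm(n + window)
  if (window > 1L) {
    y <- stats::filter(x, rep(1 / window, window), sides = 1)
    y <- y[(window + 1):(window + n)]
  } else {
    y <- x[seq_len(n)]
  }
  as.numeric((y - mean(y)) / stats::sd(y))
}

cortical_networks <- c("visual", "somatomotor", "dorsal attention",
                       "ventral attention", "limbic", "frontoparietal",
                       "default mode")

#' Generate subject profiles: latent traits, item responses, demographics
#'
#' Latent trait scores are drawn i.i.d. standard normal per subject and
#' trait. Facet latents correlate `facet_cor` with their parent trait.
#' Item responses render the facet latent onto the Likert scale
#' (affine map to the scale midpoint, unit chosen so +/-3 SD spans the
#' scale), add `item_noise_sd` Gaussian noise, reflect reverse-keyed items,
#' then clip and round. Demographics are sampled from fixed categorical
#' distributions approximating a university sample.
#'
#' @param config a [gen_config()] object.
#' @return An object of class `"profile_set"`: a list with `subject_id`,
#'   `latent_traits` (subjects x traits, the generative \eqn{p_i}),
#'   `item_responses` (subjects x items), `keying` (item -> trait, facet,
#'   reverse flag), `scale` (`c(min, max)`) and `demographics`.
#' @export
generate_profiles <- function(config) {
  validate_gen_config(config)
  set.seed(substream_seed(config, 1L))
  n <- config$n_subjects
  K <- config$n_traits
  Ff <- config$n_facets_per_trait
  m <- config$n_items_per_facet
  ids <- sprintf("S%03d", seq_len(n))

  trait_names <- if (K == 5L) {
    c("openness", "conscientiousness", "extraversion", "agreeableness",
      "neuroticism")
  } else sprintf("trait%02d", seq_len(K))

  z <- matrix(stats::rnorm(n * K), n, K, dimnames = list(ids, trait_names))

  rho <- config$facet_cor
  facet_names <- as.vector(t(outer(trait_names, seq_len(Ff),
                                   function(tr, f) paste0(tr, "_f", f))))
  fl <- matrix(0, n, K * Ff, dimnames = list(ids, facet_names))
  for (t in seq_len(K)) {
    for (f in seq_len(Ff)) {
      e <- stats::rnorm(n)
      fl[, (t - 1L) * Ff + f] <- rho * z[, t] + sqrt(1 - rho^2) * e
    }
  }

  lo <- config$scale_min
  hi <- config$scale_max
  mid <- (lo + hi) / 2
  unit <- (hi - lo) / 6

  n_items <- K * Ff * m
  item_names <- character(n_items)
  keying <- data.frame(item = character(n_items), trait = character(n_items),
                       facet = character(n_items), reverse = logical(n_items),
                       stringsAsFactors = FALSE)
  items <- matrix(0, n, n_items, dimnames = list(ids, NULL))
  idx <- 0L
  for (t in seq_len(K)) {
    for (f in seq_len(Ff)) {
      latent_on_scale <- mid + unit * fl[, (t - 1L) * Ff + f]
      for (j in seq_len(m)) {
        idx <- idx + 1L
        rev <- (j %% 2L == 0L)  # every second item reverse-keyed
        resp <- latent_on_scale + stats::rnorm(n, sd = config$item_noise_sd)
        if (rev) resp <- (lo + hi) - resp
        items[, idx] <- pmin(hi, pmax(lo, round(resp)))
        item_names[idx] <- sprintf("%s_i%d", facet_names[(t - 1L) * Ff + f], j)
        keying$item[idx] <- item_names[idx]
        keying$trait[idx] <- trait_names[t]
        keying$facet[idx] <- facet_names[(t - 1L) * Ff + f]
        keying$reverse[idx] <- rev
      }
    }
  }
  colnames(items) <- item_names

  ethnicities <- c("Asian", "Hispanic/Latinx", "Caucasian/White", "Mixed",
                   "Black/African")
  eth_p <- c(0.32, 0.29, 0.24, 0.14, 0.02)
  demographics <- data.frame(
    subject_id = ids,
    gender = sample(c("female", "male"), n, TRUE, prob = c(0.61, 0.39)),
    age = pmax(18, round(stats::rnorm(n, mean = 20.5, sd = 2.5))),
    handedness = sample(c("right", "left"), n, TRUE, prob = c(0.9, 0.1)),
    nationality = sample(c("USA", "China", "India", "UK"), n, TRUE,
                         prob = c(0.7, 0.15, 0.1, 0.05)),
    political_ideology = sample(1:7, n, TRUE,
                                prob = c(1, 2, 3, 4, 3, 2, 1) / 16),
    stringsAsFactors = FALSE
  )
  # ethnicity as a set: one primary label, occasionally a second
  demographics$ethnicity <- vapply(seq_len(n), function(i) {
    k <- 1L + stats::rbinom(1L, 1L, 0.15)
    paste(sample(ethnicities, k, prob = eth_p), collapse = ";")
  }, character(1))

  structure(list(subject_id = ids, latent_traits = z,
                 item_responses = items, keying = keying,
                 scale = c(lo, hi), demographics = demographics),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("Profile set: %d subjects, %d items (%d traits x %d facet(s)), scale %g-%g\n",
              length(x$subject_id), ncol(x$item_responses),
              ncol(x$latent_traits),
              length(unique(x$keying$facet)) / ncol(x$latent_traits),
              x$scale[1], x$scale[2]))
  invisible(x)
}

#' Generate a region-parcellated fMRI-like dataset
#'
#' For region \eqn{r}, subject \eqn{i}'s spatially-averaged magnitude series
#' is \eqn{x_{ir}(t) = a s_r(t) + \gamma \sum_k p_{ik} g_{rk}(t) +
#' \epsilon_{ir}(t)} with \eqn{s_r} and \eqn{g_{rk}} unit-variance smooth
#' signals shared across subjects and \eqn{\epsilon} i.i.d. Gaussian noise.
#' Voxel-level pattern arrays follow the same model independently per voxel
#' (voxel-specific \eqn{s} and \eqn{g}). The time axis is partitioned into
#' `n_runs` runs of `n_timepoints_per_run` samples.
#'
#' @param profiles a `"profile_set"` from [generate_profiles()].
#' @param config a [gen_config()] object.
#' @return An object of class `"fmri_dataset"`: `magnitude` (subject x
#'   region x time), `patterns` (subject x region x voxel x time),
#'   `run_boundaries` (first index of each run), `region_meta`,
#'   `exclusion_mask` (subject x run, all `FALSE` by default).
#' @export
generate_fmri_dataset <- function(profiles, config) {
  validate_gen_config(config)
  stopifnot(inherits(profiles, "profile_set"))
  if (nrow(profiles$latent_traits) != config$n_subjects)
    stop("profiles and config disagree on the number of subjects",
         call. = FALSE)
  if (config$n_voxels_per_region < 3L)
    stop("n_voxels_per_region must be >= 3 (spatial correlation undefined below 3)",
         call. = FALSE)
  set.seed(substream_seed(config, 2L))

  n <- config$n_subjects
  R <- config$n_regions
  V <- config$n_voxels_per_region
  Tt <- config$n_runs * config$n_timepoints_per_run
  p <- profiles$latent_traits
  K <- ncol(p)
  a <- config$shared_signal_weight
  g_w <- config$trait_coupling
  sig <- config$noise_sd
  win <- config$signal_smooth

  magnitude <- array(0, dim = c(n, R, Tt),
                     dimnames = list(profiles$subject_id, NULL, NULL))
  patterns <- array(0, dim = c(n, R, V, Tt))

  for (r in seq_len(R)) {
    s <- smooth_unit_signal(Tt, win)
    g <- matrix(0, K, Tt)
    for (k in seq_len(K)) g[k, ] <- smooth_unit_signal(Tt, win)
    shared <- p %*% g                       # n x Tt
    noise <- matrix(stats::rnorm(n * Tt, sd = sig), n, Tt)
    magnitude[, r, ] <- a * rep(s, each = n) + g_w * shared + noise
    for (v in seq_len(V)) {
      sv <- smooth_unit_signal(Tt, win)
      gv <- matrix(0, K, Tt)
      for (k in seq_len(K)) gv[k, ] <- smooth_unit_signal(Tt, win)
      noisev <- matrix(stats::rnorm(n * Tt, sd = sig), n, Tt)
      patterns[, r, v, ] <- a * rep(sv, each = n) + g_w * (p %*% gv) + noisev
    }
  }

  n_cortical <- R - config$n_subcortical
  network <- c(rep_len(cortical_networks, n_cortical),
               rep("subcortical", config$n_subcortical))
  region_meta <- data.frame(
    region = sprintf("R%03d", seq_len(R)),
    hemisphere = rep_len(c("LH", "RH"), R),
    network = network,
    stringsAsFactors = FALSE
  )

  structure(list(
    magnitude = magnitude,
    patterns = patterns,
    run_boundaries = seq(1L, Tt, by = config$n_timepoints_per_run),
    n_timepoints_per_run = config$n_timepoints_per_run,
    region_meta = region_meta,
    exclusion_mask = matrix(FALSE, n, config$n_runs,
                            dimnames = list(profiles$subject_id, NULL)),
    subject_id = profiles$subject_id
  ), class = "fmri_dataset")
}

#' Generate a multichannel EEG-like epoched dataset
#'
#' Per image, `n_sources` latent source time courses follow the same
#' shared-plus-trait-weighted model as the fMRI magnitudes. Sources are
#' mixed to `n_channels` channels by a fixed full-rank forward matrix
#' (common to all subjects), and per-subject sensor noise with standard
#' deviation `noise_sd / 2` is added; with `noise_sd = 0` all subjects'
#' epochs are identical.
#'
#' @inheritParams generate_fmri_dataset
#' @return An object of class `"eeg_dataset"`: `epochs` (subject x image x
#'   channel x time), `sampling_rate`, `image_meta` (image id, category),
#'   and the `forward` mixing matrix.
#' @export
generate_eeg_dataset <- function(profiles, config) {
  validate_gen_config(config)
  stopifnot(inherits(profiles, "profile_set"))
  if (nrow(profiles$latent_traits) != config$n_subjects)
    stop("profiles and config disagree on the number of subjects",
         call. = FALSE)
  set.seed(substream_seed(config, 3L))

  n <- config$n_subjects
  M <- config$n_images
  C <- config$n_channels
  Tt <- config$epoch_length
  Q <- min(config$n_sources, C)
  p <- profiles$latent_traits
  K <- ncol(p)
  a <- config$shared_signal_weight
  g_w <- config$trait_coupling
  sig <- config$noise_sd
  win <- config$signal_smooth

  A <- matrix(stats::rnorm(C * Q), C, Q)
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  if (qr(A)$rank < Q)
    stop("singular forward matrix; regenerate with a different seed",
         call. = FALSE)

  epochs <- array(0, dim = c(n, M, C, Tt),
                  dimnames = list(profiles$subject_id, NULL, NULL, NULL))
  for (m in seq_len(M)) {
    s <- matrix(0, Q, Tt)
    g <- array(0, dim = c(Q, K, Tt))
    for (q in seq_len(Q)) {
      s[q, ] <- smooth_unit_signal(Tt, win)
      for (k in seq_len(K)) g[q, k, ] <- smooth_unit_signal(Tt, win)
    }
    for (i in seq_len(n)) {
      U <- matrix(0, Q, Tt)
      for (q in seq_len(Q)) {
        U[q, ] <- a * s[q, ] + g_w * drop(p[i, ] %*% g[q, , ]) +
          stats::rnorm(Tt, sd = sig)
      }
      sensor <- matrix(stats::rnorm(C * Tt, sd = sig / 2), C, Tt)
      epochs[i, m, , ] <- A %*% U + sensor
    }
  }

  image_meta <- data.frame(
    image = sprintf("I%03d", seq_len(M)),
    category = rep(sprintf("C%02d", seq_len(config$n_categories)),
                   each = M %/% config$n_categories),
    stringsAsFactors = FALSE
  )

  structure(list(epochs = epochs, sampling_rate = config$sampling_rate,
                 image_meta = image_meta, forward = A,
                 subject_id = profiles$subject_id),
            class = "eeg_dataset")
}

#' Generate per-image fixation sequences
#'
#' Each image carries `attractors_per_image` attractor locations. A
#' subject's fixation targets are drawn from a mixture over attractors
#' whose weights interpolate, with coefficient `gaze_coupling`, between a
#' prior shared by all subjects and a trait-determined prior
#' (softmax of an image-specific attractor-by-trait loading applied to the
#' subject's latent traits). Fixation positions scatter around the chosen
#' attractor with `attractor_sd` pixels of isotropic Gaussian dispersion;
#' durations are gamma-distributed around 300 ms with a 50 ms floor.
#'
#' @inheritParams generate_fmri_dataset
#' @return An object of class `"gaze_dataset"`: `fixations` (a list by
#'   subject of lists by image of data frames with `x`, `y`, `duration`),
#'   `screen_dims`, and `image_meta`.
#' @export
generate_gaze_dataset <- function(profiles, config) {
  validate_gen_config(config)
  stopifnot(inherits(profiles, "profile_set"))
  set.seed(substream_seed(config, 4L))

  n <- config$n_subjects
  M <- config$n_images
  Kat <- config$attractors_per_image
  nf <- config$n_fixations_per_image
  w <- config$screen_dims[1]
  h <- config$screen_dims[2]
  p <- profiles$latent_traits
  cpl <- config$gaze_coupling

  fixations <- rep(list(vector("list", M)), n)
  names(fixations) <- profiles$subject_id

  for (m in seq_len(M)) {
    centers <- cbind(stats::runif(Kat, 0.1 * w, 0.9 * w),
                     stats::runif(Kat, 0.1 * h, 0.9 * h))
    shared_w <- stats::rgamma(Kat, shape = 1)
    shared_w <- shared_w / sum(shared_w)
    B <- matrix(stats::rnorm(Kat * ncol(p)), Kat, ncol(p))
    for (i in seq_len(n)) {
      e <- exp(B %*% p[i, ] - max(B %*% p[i, ]))
      trait_w <- as.numeric(e / sum(e))
      mix <- (1 - cpl) * shared_w + cpl * trait_w
      att <- sample.int(Kat, nf, replace = TRUE, prob = mix)
      x <- pmin(w - 1e-6, pmax(0, centers[att, 1] +
                                 stats::rnorm(nf, sd = config$attractor_sd)))
      y <- pmin(h - 1e-6, pmax(0, centers[att, 2] +
                                 stats::rnorm(nf, sd = config$attractor_sd)))
      duration <- pmax(50, round(stats::rgamma(nf, shape = 4, scale = 75)))
      if (any(duration <= 0)) stop("zero-duration fixation generated",
                                   call. = FALSE)
      fixations[[i]][[m]] <- data.frame(x = x, y = y, duration = duration)
    }
  }

  image_meta <- data.frame(image = sprintf("I%03d", seq_len(M)),
                           stringsAsFactors = FALSE)
  structure(list(fixations = fixations, screen_dims = c(w, h),
                 image_meta = image_meta, subject_id = profiles$subject_id),
            class = "gaze_dataset")
}

#' Closed-form expected dyadic correlation under the generative model
#'
#' For two subjects with latent trait vectors `p_i`, `p_j` and model
#' weights `a` (shared signal), `gamma` (trait coupling) and `sigma`
#' (noise), the expected Pearson correlation between their signals is
#' \deqn{\rho_{ij} = \frac{a^2 + \gamma^2\, p_i \cdot p_j}
#'   {\sqrt{(a^2 + \gamma^2 \|p_i\|^2 + \sigma^2)
#'          (a^2 + \gamma^2 \|p_j\|^2 + \sigma^2)}}.}
#' This is the oracle against which empirical synchrony computed on
#' generated data is validated.
#'
#' @param p_i,p_j latent trait vectors (equal length).
#' @param config a [gen_config()] object, or a list with elements
#'   `shared_signal_weight`, `trait_coupling`, `noise_sd`.
#' @return Expected correlation in `[-1, 1]`.
#' @export
expected_dyad_correlation <- function(p_i, p_j, config) {
  stopifnot(length(p_i) == length(p_j))
  a <- config$shared_signal_weight
  g <- config$trait_coupling
  s <- config$noise_sd
  if (a == 0 && g == 0 && s == 0)
    stop("all of a, gamma, sigma are zero: correlation undefined",
         call. = FALSE)
  vi <- a^2 + g^2 * sum(p_i^2) + s^2
  vj <- a^2 + g^2 * sum(p_j^2) + s^2
  if (vi == 0 || vj == 0)
    stop("zero variance for at least one subject: correlation undefined",
         call. = FALSE)
  (a^2 + g^2 * sum(p_i * p_j)) / sqrt(vi * vj)
}
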