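#' Generator configuration
#'
#' Builds and validates the configuration object consumed by all synthetic
#' data generators ([generate_profiles()], [generate_fmri_dataset()],
#' [generate_eeg_dataset()], [generate_gaze_dataset()]). Defaults describe
#' a video-watching fMRI study with a short (10-item) Big Five inventory;
#' [gen_config_eeg()] gives the image-viewing EEG design with a 60-item,
#' 15-facet inventory.
#'
#' The neural generative model for every region (and, for EEG, every latent
#' source) is
#' \deqn{x_i(t) = a\, s(t) + \gamma \sum_k p_{ik}\, g_k(t) + \epsilon_i(t),}
#' where \eqn{s} and \eqn{g_k} are unit-variance smooth signals shared across
#' subjects, \eqn{p_i} is subject \eqn{i}'s latent trait vector, and
#' \eqn{\epsilon_i} is i.i.d. Gaussian noise with standard deviation
#' \eqn{\sigma}. Under this model the expected cross-subject correlation has
#' the closed form implemented in [expected_dyad_correlation()].
#'
#' @param n_subjects number of subjects.
#' @param n_traits number of broad traits (Big Five: 5).
#' @param n_facets_per_trait facets per trait (1 for a TIPI-like short form,
#'   3 for a BFI-2-like faceted inventory).
#' @param n_items_per_facet questionnaire items per facet.
#' @param scale_min,scale_max Likert response bounds (integers).
#' @param item_noise_sd standard deviation of item-level response noise, on
#'   the Likert scale.
#' @param facet_cor correlation between a facet latent and its parent trait
#'   latent (1 collapses facets onto the trait).
#' @param n_regions total number of brain regions (parcels).
#' @param n_subcortical how many of `n_regions` are labelled "subcortical";
#'   the rest cycle through the seven cortical networks.
#' @param n_voxels_per_region voxels per region for pattern arrays.
#' @param n_runs,n_timepoints_per_run fMRI run structure.
#' @param signal_smooth moving-average window (in samples) used to create
#'   the smooth shared signals.
#' @param n_images,n_categories stimulus set for the EEG/gaze design;
#'   `n_images` must be a multiple of `n_categories`.
#' @param n_channels,epoch_length,sampling_rate EEG montage and epoch shape.
#' @param n_sources number of latent cortical sources mixed into channels.
#' @param shared_signal_weight weight `a` of the stimulus-driven signal
#'   component shared by all subjects.
#' @param trait_coupling weight `gamma` of the trait-weighted shared signal
#'   components; 0 makes synchrony independent of personality.
#' @param noise_sd standard deviation `sigma` of subject-specific noise.
#' @param gaze_coupling in \[0, 1\]: mixing weight between a shared fixation
#'   prior (0) and a trait-determined prior (1).
#' @param attractors_per_image number of fixation attractors per image.
#' @param n_fixations_per_image fixations generated per subject and image.
#' @param attractor_sd spatial dispersion of fixations around an attractor,
#'   in pixels.
#' @param screen_dims `c(width, height)` in pixels.
#' @param seed master integer seed; per-dataset substreams are derived from
#'   it by fixed offsets (profiles +1, fMRI +2, EEG +3, gaze +4).
#'
#' @return A list of class `"gen_config"`.
#' @examples
#' cfg <- gen_config(n_subjects = 8, n_regions = 4, n_subcortical = 0,
#'                   n_timepoints_per_run = 50)
#' @export
gen_config <- function(n_subjects = 66,
                       n_traits = 5,
                       n_facets_per_trait = 1,
                       n_items_per_facet = 2,
                       scale_min = 1,
                       scale_max = 7,
                       item_noise_sd = 1,
                       facet_cor = 0.75,
                       n_regions = 214,
                       n_subcortical = 14,
                       n_voxels_per_region = 20,
                       n_runs = 4,
                       n_timepoints_per_run = 450,
                       signal_smooth = 5,
                       n_images = 104,
                       n_categories = 26,
                       n_channels = 32,
                       epoch_length = 1500,
                       sampling_rate = 500,
                       n_sources = 3,
                       shared_signal_weight = 1,
                       trait_coupling = 0.3,
                       noise_sd = 2,
                       gaze_coupling = 0.5,
                       attractors_per_image = 5,
                       n_fixations_per_image = 8,
                       attractor_sd = 60,
                       screen_dims = c(1920, 1080),
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_traits = as.integer(n_traits),
    n_facets_per_trait = as.integer(n_facets_per_trait),
    n_items_per_facet = as.integer(n_items_per_facet),
    scale_min = scale_min,
    scale_max = scale_max,
    item_noise_sd = item_noise_sd,
    facet_cor = facet_cor,
    n_regions = as.integer(n_regions),
    n_subcortical = as.integer(n_subcortical),
    n_voxels_per_region = as.integer(n_voxels_per_region),
    n_runs = as.integer(n_runs),
    n_timepoints_per_run = as.integer(n_timepoints_per_run),
    signal_smooth = as.integer(signal_smooth),
    n_images = as.integer(n_images),
    n_categories = as.integer(n_categories),
    n_channels = as.integer(n_channels),
    epoch_length = as.integer(epoch_length),
    sampling_rate = sampling_rate,
    n_sources = as.integer(n_sources),
    shared_signal_weight = shared_signal_weight,
    trait_coupling = trait_coupling,
    noise_sd = noise_sd,
    gaze_coupling = gaze_coupling,
    attractors_per_image = as.integer(attractors_per_image),
    n_fixations_per_image = as.integer(n_fixations_per_image),
    attractor_sd = attractor_sd,
    screen_dims = screen_dims,
    seed = as.integer(seed)
  )
  class(cfg) <- "gen_config"
  validate_gen_config(cfg)
  cfg
}

#' EEG/image study configuration preset
#'
#' Preset matching an image-viewing EEG design: a 60-item faceted inventory
#' (5 traits x 3 facets x 4 items on a 1-5 scale), 104 images in 26
#' categories, 32 channels sampled at 500 Hz with 3-second epochs.
#'
#' @param ... overrides passed on to [gen_config()].
#' @return A `"gen_config"` object.
#' @export
gen_config_eeg <- function(...) {
  defaults <- list(
    n_subjects = 225, n_facets_per_trait = 3, n_items_per_facet = 4,
    scale_min = 1, scale_max = 5, item_noise_sd = 0.7,
    n_images = 104, n_categories = 26,
    n_channels = 32, epoch_length = 1500, sampling_rate = 500
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(gen_config, args)
}

validate_gen_config <- function(cfg) {
  counts <- c("n_subjects", "n_traits", "n_facets_per_trait",
              "n_items_per_facet", "n_regions", "n_voxels_per_region",
              "n_runs", "n_timepoints_per_run", "n_images", "n_categories",
              "n_channels", "epoch_length", "attractors_per_image",
              "n_fixations_per_image", "n_sources", "signal_smooth")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("config field '", f, "' must be a count >= 1", call. = FALSE)
  }
  if (cfg$scale_max <= cfg$scale_min)
    stop("invalid scale bounds: scale_max must exceed scale_min",
         call. = FALSE)
  if (cfg$item_noise_sd < 0 || cfg$noise_sd < 0)
    stop("noise standard deviations must be nonnegative", call. = FALSE)
  if (cfg$shared_signal_weight < 0 || cfg$trait_coupling < 0)
    stop("signal weights must be nonnegative", call. = FALSE)
  if (cfg$gaze_coupling < 0 || cfg$gaze_coupling > 1)
    stop("gaze_coupling must lie in [0, 1]", call. = FALSE)
  if (cfg$n_images %% cfg$n_categories != 0L)
    stop("n_images must be a multiple of n_categories", call. = FALSE)
  if (cfg$n_subcortical < 0L || cfg$n_subcortical > cfg$n_regions)
    stop("n_subcortical must lie in [0, n_regions]", call. = FALSE)
  if (length(cfg$screen_dims) != 2L || any(cfg$screen_dims < 1))
    stop("screen_dims must be c(width, height) in pixels", call. = FALSE)
  invisible(cfg)
}

# Substream seeds: fixed offsets from the master seed, kept within 32-bit
# integer range.
substream_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) + offset) %% .Machine$integer.max)
}

#' @export
print.gen_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  subjects: %d; traits: %d x %d facet(s) x %d item(s), scale %g-%g\n",
              x$n_subjects, x$n_traits, x$n_facets_per_trait,
              x$n_items_per_facet, x$scale_min, x$scale_max))
  cat(sprintf("  fMRI: %d regions (%d subcortical), %d voxels/region, %d runs x %d timepoints\n",
              x$n_regions, x$n_subcortical, x$n_voxels_per_region,
              x$n_runs, x$n_timepoints_per_run))
  cat(sprintf("  EEG: %d channels, epochs of %d samples @ %g Hz, %d images (%d categories)\n",
              x$n_channels, x$epoch_length, x$sampling_rate,
              x$n_images, x$n_categories))
  cat(sprintf("  coupling: a = %g, gamma = %g, sigma = %g, gaze = %g; seed %d\n",
              x$shared_signal_weight, x$trait_coupling, x$noise_sd,
              x$gaze_coupling, x$seed))
  invisible(x)
}
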