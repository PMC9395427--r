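# Shared fixture builders; all randomness is seeded by the caller.

tiny_config <- function(...) {
  defaults <- list(
    n_subjects = 8, n_regions = 3, n_subcortical = 1,
    n_voxels_per_region = 4, n_runs = 4, n_timepoints_per_run = 30,
    n_images = 6, n_categories = 3, n_channels = 4, epoch_length = 60,
    n_fixations_per_image = 5, seed = 11
  )
  do.call(gen_config, utils::modifyList(defaults, list(...)))
}

fix_dist <- function(mass) {
  structure(list(mass = mass / sum(mass), grid_dims = dim(mass)),
            class = "fixation_distribution")
}

# point mass at grid cell (row, col)
point_mass <- function(H, W, row, col) {
  m <- matrix(0, H, W)
  m[row, col] <- 1
  fix_dist(m)
}

# TIPI-like keying for hand-built item matrices
make_keying <- function(traits, items_per_trait = 2L,
                        reverse_second = TRUE) {
  n <- length(traits) * items_per_trait
  data.frame(
    item = sprintf("%s_i%d", rep(traits, each = items_per_trait),
                   rep(seq_len(items_per_trait), length(traits))),
    trait = rep(traits, each = items_per_trait),
    facet = rep(paste0(traits, "_f1"), each = items_per_trait),
    reverse = if (reverse_second)
      rep(seq_len(items_per_trait) %% 2L == 0L, length(traits))
    else rep(FALSE, n),
    stringsAsFactors = FALSE
  )
}

# dyad table with directly assigned outcome columns, for inference tests
table_with_outcomes <- function(profiles, outcomes) {
  tab <- build_dyad_table(profiles)
  for (nm in names(outcomes)) tab[[nm]] <- outcomes[[nm]]
  tab
}
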