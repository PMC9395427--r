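#' Run the full dyadic analysis pipeline on a synthetic study
#'
#' Executes, in order: profile generation, fMRI synchrony, EEG ISC, gaze
#' similarity, dyad-table assembly, per-region standardized regressions
#' with subject-shuffling permutation tests and BH-FDR across regions,
#' per-network coefficient tests, split-half reliabilities, per-subject
#' effect distributions, and (when gaze data are present) a mediation
#' analysis of gaze similarity between personality similarity and EEG
#' synchrony. Covariates with zero variance at the realized sample are
#' dropped with a message. All stages derive their randomness from the
#' config's master seed, so a rerun with the same config reproduces every
#' output.
#'
#' @param config a [gen_config()] object.
#' @param n_permutations permutations per test (default 1000).
#' @param metric a [similarity_metric()] for the personality predictor.
#' @param stages character subset of `c("fmri", "eeg", "gaze")`.
#' @param out_dir optional directory; when given, CSV/JSON artifacts and a
#'   manifest are written there.
#' @return A list of class `"dyadsync_run"` with elements `config`,
#'   `profiles`, `dyad_table`, `region_results` (per region/measure beta,
#'   p, permutation p, FDR flag), `network_tests`, `eeg_result`,
#'   `mediation`, `reliability`, `per_subject`, and `manifest`.
#' @export
run_pipeline <- function(config, n_permutations = 1000L,
                         metric = similarity_metric("euclidean"),
                         stages = c("fmri", "eeg", "gaze"),
                         out_dir = NULL) {
  stages <- match.arg(stages, c("fmri", "eeg", "gaze"), several.ok = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timing[[name]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }

  profiles <- generate_profiles(config)
  tick("profiles")

  synchrony <- isc <- gaze <- NULL
  reliability <- list()
  if ("fmri" %in% stages) {
    fmri <- generate_fmri_dataset(profiles, config)
    synchrony <- dyadic_synchrony_table(fmri)
    if (config$n_runs >= 4L) {
      reliability$nm_split_half <- synchrony_split_half(fmri, measure = "NM")
      reliability$np_split_half <- synchrony_split_half(fmri, measure = "NP")
    }
    tick("fmri")
  }
  if ("eeg" %in% stages) {
    eeg <- generate_eeg_dataset(profiles, config)
    isc <- eeg_isc_table(eeg)
    if (config$n_images >= 4L)
      reliability$isc_split_half <- isc_split_half(eeg)
    tick("eeg")
  }
  if ("gaze" %in% stages) {
    gz <- generate_gaze_dataset(profiles, config)
    gaze <- gaze_similarity_table(gz)
    tick("gaze")
  }
  reliability$personality_split_half <- split_half_reliability(
    profiles$item_responses, profiles$keying,
    profiles$scale[1], profiles$scale[2], metric)

  include_facets <- length(unique(profiles$keying$facet)) >
    length(unique(profiles$keying$trait))
  tab <- build_dyad_table(profiles, synchrony = synchrony, isc = isc,
                          gaze = gaze, metric = metric,
                          include_facets = include_facets)
  tick("dyad_table")

  covars <- c("gender_similarity", "age_similarity",
              "handedness_similarity", "nationality_similarity",
              "ethnicity_similarity")
  if (!is.null(isc)) covars <- c(covars, "politics_similarity")
  covars <- covars[vapply(covars, function(cl)
    stats::sd(tab[[cl]], na.rm = TRUE) > 0, logical(1))]
  if (length(covars) < 5L)
    message("dropping zero-variance covariate(s) at this sample size")

  seed_perm <- substream_seed(config, 10L)

  region_results <- NULL
  network_tests <- NULL
  if (!is.null(synchrony)) {
    combos <- unique(as.data.frame(synchrony)[, c("region", "measure")])
    rows <- lapply(seq_len(nrow(combos)), function(k) {
      col <- paste(combos$measure[k], combos$region[k], sep = "_")
      pr <- subject_permutation_test(tab, col, "personality_similarity",
                                     covariates = covars,
                                     n_permutations = n_permutations,
                                     seed = seed_perm + k)
      data.frame(region = combos$region[k], measure = combos$measure[k],
                 beta = pr$beta_obs, se = pr$se,
                 p_parametric = pr$p_parametric,
                 p_permutation = pr$p_permutation,
                 stringsAsFactors = FALSE)
    })
    region_results <- do.call(rbind, rows)
    for (msr in unique(region_results$measure)) {
      sel <- region_results$measure == msr
      fdr <- fdr_bh(region_results$p_permutation[sel])
      region_results$p_fdr[sel] <- fdr$p_adjusted
      region_results$significant_fdr[sel] <- fdr$rejected
    }
    meta <- if ("fmri" %in% stages) fmri$region_meta else NULL
    if (!is.null(meta)) {
      network_tests <- lapply(unique(region_results$measure), function(msr) {
        sel <- region_results[region_results$measure == msr, ]
        nets <- meta$network[match(sel$region, meta$region)]
        keep <- nets %in% names(which(table(nets) >= 2))
        if (!any(keep)) return(NULL)
        cbind(data.frame(measure = msr, stringsAsFactors = FALSE),
              network_coefficient_test(sel$beta[keep], nets[keep]))
      })
      network_tests <- do.call(rbind, network_tests)
    }
    tick("fmri_inference")
  }

  eeg_result <- NULL
  facet_results <- NULL
  if (!is.null(isc)) {
    eeg_result <- subject_permutation_test(tab, "eeg_isc",
                                           "personality_similarity",
                                           covariates = covars,
                                           n_permutations = n_permutations,
                                           seed = seed_perm)
    if (include_facets) {
      facet_cols <- grep("^facet_", names(tab), value = TRUE)
      facet_results <- do.call(rbind, lapply(facet_cols, function(fc) {
        pr <- subject_permutation_test(tab, "eeg_isc", fc,
                                       n_permutations = n_permutations,
                                       seed = seed_perm + 1L)
        data.frame(facet = sub("^facet_", "", fc), beta = pr$beta_obs,
                   se = pr$se, p_parametric = pr$p_parametric,
                   p_permutation = pr$p_permutation,
                   stringsAsFactors = FALSE)
      }))
    }
    tick("eeg_inference")
  }

  mediation <- NULL
  if (!is.null(gaze) && !is.null(isc)) {
    mediation <- mediation_analysis(tab, "personality_similarity",
                                    "gaze_similarity", "eeg_isc",
                                    n_permutations = n_permutations,
                                    seed = seed_perm + 2L)
    tick("mediation")
  }

  per_subject <- NULL
  outcome_main <- if (!is.null(isc)) "eeg_isc" else if (!is.null(synchrony))
    paste(region_results$measure[1], region_results$region[1], sep = "_")
  if (!is.null(outcome_main)) {
    per_subject <- per_subject_effects(tab, outcome_main,
                                       "personality_similarity",
                                       covariates = covars)
    tick("per_subject")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dyadsync")),
    master_seed = config$seed,
    n_subjects = config$n_subjects,
    n_dyads = nrow(tab),
    metric = metric$name,
    n_permutations = n_permutations,
    stages = stages,
    wall_time_s = timing
  )

  run <- structure(list(config = config, profiles = profiles,
                        dyad_table = tab, region_results = region_results,
                        network_tests = network_tests,
                        eeg_result = eeg_result,
                        facet_results = facet_results,
                        mediation = mediation, reliability = reliability,
                        per_subject = per_subject, manifest = manifest),
                   class = "dyadsync_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    wr <- function(obj, name) {
      path <- file.path(out_dir, name)
      utils::write.csv(obj, path, row.names = FALSE)
      files <<- c(files, path)
    }
    wr(as.data.frame(profiles$item_responses), "item_responses.csv")
    wr(profiles$demographics, "demographics.csv")
    wr(as.data.frame(tab), "dyad_table.csv")
    if (!is.null(region_results)) wr(region_results, "region_results.csv")
    if (!is.null(network_tests)) wr(network_tests, "network_tests.csv")
    if (!is.null(facet_results)) wr(facet_results, "facet_results.csv")
    manifest$files <- files
    run$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  run
}

#' Summarize a pipeline run
#'
#' Prints a human-readable report: per-region coefficient table (sorted by
#' absolute effect size within measure), facet table, EEG main effect,
#' mediation paths, reliability estimates, and the per-subject
#' fraction-positive.
#'
#' @param run a `"dyadsync_run"` from [run_pipeline()].
#' @param max_regions cap on printed region rows per measure.
#' @return `run`, invisibly.
#' @export
summarize_run <- function(run, max_regions = 10L) {
  stopifnot(inherits(run, "dyadsync_run"))
  m <- run$manifest
  cat(sprintf("Dyadic synchrony run: %d subjects, %d dyads, metric = %s, %d permutations\n",
              m$n_subjects, m$n_dyads, m$metric, m$n_permutations))
  if (!is.null(run$region_results)) {
    if (nrow(run$region_results) == 0L)
      stop("empty region result set", call. = FALSE)
    for (msr in unique(run$region_results$measure)) {
      sel <- run$region_results[run$region_results$measure == msr, ]
      sel <- sel[order(-abs(sel$beta)), ]
      cat(sprintf("\n%s-synchrony ~ personality similarity (top %d regions by |beta|):\n",
                  msr, min(max_regions, nrow(sel))))
      print(utils::head(format(sel, digits = 3), max_regions),
            row.names = FALSE)
      cat(sprintf("  FDR-significant regions: %d of %d\n",
                  sum(sel$significant_fdr), nrow(sel)))
    }
  }
  if (!is.null(run$network_tests)) {
    cat("\nPer-network coefficient tests:\n")
    print(format(run$network_tests, digits = 3), row.names = FALSE)
  }
  if (!is.null(run$eeg_result)) {
    cat("\nEEG ISC ~ personality similarity: ")
    print(run$eeg_result)
  }
  if (!is.null(run$facet_results)) {
    sel <- run$facet_results[order(-abs(run$facet_results$beta)), ]
    cat("\nFacet-level effects on EEG ISC (sorted by |beta|):\n")
    print(format(sel, digits = 3), row.names = FALSE)
  }
  if (!is.null(run$mediation)) {
    cat("\n")
    print(run$mediation)
  }
  if (length(run$reliability)) {
    cat("\nSplit-half reliabilities:\n")
    for (nm in names(run$reliability))
      cat(sprintf("  %s: r = %.3f\n", nm, run$reliability[[nm]]))
  }
  if (!is.null(run$per_subject)) {
    cat(sprintf("\nPer-subject effects: %.0f%% positive (n_obs/person = %s)\n",
                100 * run$per_subject$fraction_positive,
                paste(run$per_subject$n_obs_per_subject, collapse = ", ")))
  }
  invisible(run)
}

#' @export
print.dyadsync_run <- function(x, ...) summarize_run(x, ...)
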