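#' Concatenate a subject's runs, dropping excluded runs
#'
#' Runs are concatenated in acquisition order; runs flagged in the
#' dataset's `exclusion_mask` (e.g. excess motion, sleep) are dropped for
#' that subject.
#'
#' @param dataset an `"fmri_dataset"`.
#' @param subject subject id (label) or index.
#' @param runs optional subset of run indices to consider (default: all).
#' @return A list with `magnitude` (region x time), `patterns` (region x
#'   voxel x time) and `runs_used` (integer vector).
#' @export
concatenate_runs <- function(dataset, subject, runs = NULL) {
  stopifnot(inherits(dataset, "fmri_dataset"))
  i <- subject_index(dataset, subject)
  n_runs <- ncol(dataset$exclusion_mask)
  if (is.null(runs)) runs <- seq_len(n_runs)
  keep <- runs[!dataset$exclusion_mask[i, runs]]
  if (length(keep) == 0L)
    stop("all runs excluded for subject ", subject, call. = FALSE)
  idx <- run_time_index(dataset, keep)
  mag <- dataset$magnitude[i, , idx, drop = FALSE]
  mag <- array(mag, dim = dim(mag)[-1])
  pat <- dataset$patterns[i, , , idx, drop = FALSE]
  pat <- array(pat, dim = dim(pat)[-1])
  list(magnitude = mag, patterns = pat, runs_used = keep)
}

subject_index <- function(dataset, subject) {
  if (is.character(subject)) {
    i <- match(subject, dataset$subject_id)
    if (is.na(i)) stop("unknown subject: ", subject, call. = FALSE)
    i
  } else as.integer(subject)
}

# Time indices covered by the given runs.
run_time_index <- function(dataset, runs) {
  tp <- dataset$n_timepoints_per_run
  unlist(lapply(sort(runs), function(r) ((r - 1L) * tp + 1L):(r * tp)))
}

# Runs retained by BOTH subjects of a dyad (run-intersection rule).
shared_runs <- function(dataset, i, j, runs = NULL) {
  n_runs <- ncol(dataset$exclusion_mask)
  if (is.null(runs)) runs <- seq_len(n_runs)
  keep <- runs[!dataset$exclusion_mask[i, runs] &
                 !dataset$exclusion_mask[j, runs]]
  if (length(keep) == 0L)
    stop("no shared runs for subjects ", i, " and ", j, call. = FALSE)
  keep
}

#' Neural magnitude synchrony (NM-synchrony)
#'
#' Pearson correlation between two subjects' spatially-averaged response
#' magnitude time series within a region.
#'
#' @param ts_i,ts_j numeric time series of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
nm_synchrony <- function(ts_i, ts_j) {
  if (length(ts_i) != length(ts_j))
    stop("time series differ in length", call. = FALSE)
  if (length(ts_i) < 3L)
    stop("time series must have length >= 3", call. = FALSE)
  if (stats::sd(ts_i) == 0 || stats::sd(ts_j) == 0)
    stop("zero-variance time series; synchrony undefined", call. = FALSE)
  stats::cor(ts_i, ts_j)
}

#' Neural pattern synchrony (NP-synchrony)
#'
#' Similarity of two subjects' spatially distributed response patterns over
#' time: at each timepoint the Pearson correlation across voxels between
#' the two subjects' spatial patterns is computed, Fisher-z transformed,
#' averaged over timepoints, and transformed back. Correlations are clipped
#' to +/-(1 - 1e-7) before the z-transform so that identical patterns
#' average finitely. Timepoints where either subject has zero spatial
#' variance are dropped with a warning.
#'
#' @param pat_i,pat_j voxel x time matrices with matching dimensions
#'   (>= 3 voxels, >= 2 timepoints).
#' @param method `"timepoint"` (default; spatial correlation per timepoint)
#'   or `"voxel"` (per-voxel temporal correlation averaged over voxels on
#'   the Fisher-z scale) — two defensible readings of pattern synchrony.
#' @return Correlation-scale value in `(-1, 1)`.
#' @export
np_synchrony <- function(pat_i, pat_j, method = c("timepoint", "voxel")) {
  method <- match.arg(method)
  if (!all(dim(pat_i) == dim(pat_j)))
    stop("pattern arrays differ in dimension", call. = FALSE)
  if (nrow(pat_i) < 3L) stop("need >= 3 voxels", call. = FALSE)
  if (ncol(pat_i) < 2L) stop("need >= 2 timepoints", call. = FALSE)
  if (method == "timepoint") {
    sd_i <- apply(pat_i, 2, stats::sd)
    sd_j <- apply(pat_j, 2, stats::sd)
    ok <- sd_i > 0 & sd_j > 0
    if (!all(ok))
      warning(sum(!ok), " timepoint(s) with zero spatial variance dropped")
    if (!any(ok))
      stop("all timepoints have zero spatial variance", call. = FALSE)
    r <- vapply(which(ok), function(t) stats::cor(pat_i[, t], pat_j[, t]),
                numeric(1))
  } else {
    sd_i <- apply(pat_i, 1, stats::sd)
    sd_j <- apply(pat_j, 1, stats::sd)
    ok <- sd_i > 0 & sd_j > 0
    if (!all(ok))
      warning(sum(!ok), " voxel(s) with zero temporal variance dropped")
    if (!any(ok))
      stop("all voxels have zero temporal variance", call. = FALSE)
    r <- vapply(which(ok), function(v) stats::cor(pat_i[v, ], pat_j[v, ]),
                numeric(1))
  }
  fisher_z_mean(r)
}

# Average correlations on the Fisher-z scale; clip r = +/-1 for finiteness.
fisher_z_mean <- function(r, clip = 1 - 1e-7) {
  r <- pmin(clip, pmax(-clip, r))
  tanh(mean(atanh(r)))
}

#' Dyadic synchrony table for all subject pairs and regions
#'
#' Computes NM- and NP-synchrony for every unordered pair of subjects in
#' every region, after concatenating each subject's retained runs and
#' restricting each dyad to the runs retained by both subjects. Per-pair
#' failures (e.g. zero variance) yield `NA` values with a warning rather
#' than aborting the table.
#'
#' @param dataset an `"fmri_dataset"`.
#' @param measures subset of `c("NM", "NP")`.
#' @param runs optional run subset (used by split-half reliability).
#' @return A long-format data frame of class `"synchrony_table"` with
#'   columns `subject_a`, `subject_b`, `region`, `measure`, `value`;
#'   exactly `n(n-1)/2` dyads.
#' @export
dyadic_synchrony_table <- function(dataset, measures = c("NM", "NP"),
                                   runs = NULL) {
  stopifnot(inherits(dataset, "fmri_dataset"))
  measures <- match.arg(measures, c("NM", "NP"), several.ok = TRUE)
  n <- length(dataset$subject_id)
  if (n < 2L) stop("need >= 2 subjects", call. = FALSE)
  R <- dim(dataset$magnitude)[2]
  pairs <- dyad_pairs(n)
  regions <- dataset$region_meta$region

  out <- vector("list", nrow(pairs))
  for (d in seq_len(nrow(pairs))) {
    i <- pairs$a[d]; j <- pairs$b[d]
    keep <- shared_runs(dataset, i, j, runs)
    idx <- run_time_index(dataset, keep)
    rows <- expand.grid(region = regions, measure = measures,
                        stringsAsFactors = FALSE)
    rows$subject_a <- dataset$subject_id[i]
    rows$subject_b <- dataset$subject_id[j]
    rows$value <- NA_real_
    for (r in seq_len(R)) {
      if ("NM" %in% measures) {
        v <- tryCatch(nm_synchrony(dataset$magnitude[i, r, idx],
                                   dataset$magnitude[j, r, idx]),
                      error = function(e) {
                        warning("NM dyad (", i, ",", j, ") region ", r, ": ",
                                conditionMessage(e)); NA_real_
                      })
        rows$value[rows$region == regions[r] & rows$measure == "NM"] <- v
      }
      if ("NP" %in% measures) {
        v <- tryCatch(np_synchrony(dataset$patterns[i, r, , idx],
                                   dataset$patterns[j, r, , idx]),
                      error = function(e) {
                        warning("NP dyad (", i, ",", j, ") region ", r, ": ",
                                conditionMessage(e)); NA_real_
                      })
        rows$value[rows$region == regions[r] & rows$measure == "NP"] <- v
      }
    }
    out[[d]] <- rows
  }
  res <- do.call(rbind, out)
  res <- res[, c("subject_a", "subject_b", "region", "measure", "value")]
  class(res) <- c("synchrony_table", "data.frame")
  res
}

#' Split-half reliability of dyadic synchrony
#'
#' Computes synchrony per dyad separately on two disjoint halves of the
#' runs (default: runs 1 and 3 vs runs 2 and 4), averages across regions
#' within each dyad, and returns the Pearson correlation of the two
#' half-based dyad vectors. Region-averaging is the minimal-variance
#' summary; set `per_region = TRUE` to correlate region-wise values
#' instead.
#'
#' @param dataset an `"fmri_dataset"`.
#' @param partition list of two integer vectors of run indices.
#' @param measure `"NM"` or `"NP"`.
#' @param per_region if `TRUE`, correlate dyad-by-region values rather than
#'   dyad-level region averages.
#' @return Pearson correlation across dyads.
#' @export
synchrony_split_half <- function(dataset,
                                 partition = list(c(1L, 3L), c(2L, 4L)),
                                 measure = c("NM", "NP"),
                                 per_region = FALSE) {
  measure <- match.arg(measure)
  n_runs <- ncol(dataset$exclusion_mask)
  if (length(partition) != 2L)
    stop("partition must list two run sets", call. = FALSE)
  if (any(unlist(partition) > n_runs))
    stop("partition names runs beyond the dataset; supply a custom partition",
         call. = FALSE)
  halves <- lapply(partition, function(runs) {
    tab <- dyadic_synchrony_table(dataset, measures = measure, runs = runs)
    if (per_region) {
      tab$value
    } else {
      agg <- stats::aggregate(value ~ subject_a + subject_b, tab, mean)
      agg <- agg[order(agg$subject_a, agg$subject_b), ]
      agg$value
    }
  })
  if (stats::sd(halves[[1]]) == 0 || stats::sd(halves[[2]]) == 0)
    stop("constant synchrony vector in one half", call. = FALSE)
  stats::cor(halves[[1]], halves[[2]])
}
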