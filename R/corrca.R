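#' Correlated components analysis for a dyad
#'
#' Finds channel-space projections that maximize the correlation between
#' two subjects' multichannel recordings (rather than variance, as PCA
#' would). With channel-centered data, let \eqn{R_{11}, R_{22}} be the
#' within-subject covariances and \eqn{R_{12}, R_{21}} the cross-subject
#' covariances. Components are eigenvectors of
#' \eqn{R_w^{-1} R_b} with \eqn{R_w = R_{11} + R_{22}} and
#' \eqn{R_b = R_{12} + R_{21}}; the ranked eigenvalues reflect the strength
#' of correlation captured by each component. `shrinkage` regularizes
#' \eqn{R_w} toward a scaled identity:
#' \eqn{(1-s) R_w + s\,\overline{\mathrm{diag}(R_w)} I}.
#'
#' The product \eqn{R_w^{-1} R_b} is not symmetric, so eigenpairs can come
#' out complex in degenerate cases; real parts are taken and re-sorted
#' (standard practice for this eigenproblem).
#'
#' @param X1,X2 channel x time matrices with matching dimensions.
#' @param shrinkage regularization weight in `[0, 1]` (default 0.05).
#' @return A list of class `"corrca"`: `eigenvalues` (descending),
#'   `weights` (channels x components), `component_isc` (Pearson
#'   correlation of the two subjects' projected time courses per
#'   component).
#' @export
corrca_fit <- function(X1, X2, shrinkage = 0.05) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (!all(dim(X1) == dim(X2)))
    stop("epoch matrices differ in dimension", call. = FALSE)
  if (shrinkage < 0 || shrinkage > 1)
    stop("shrinkage must lie in [0, 1]", call. = FALSE)
  C <- nrow(X1); Tt <- ncol(X1)
  if (Tt < C)
    warning("fewer timepoints than channels; covariance estimates are rank-deficient")

  X1c <- X1 - rowMeans(X1)
  X2c <- X2 - rowMeans(X2)
  R11 <- tcrossprod(X1c) / (Tt - 1)
  R22 <- tcrossprod(X2c) / (Tt - 1)
  R12 <- tcrossprod(X1c, X2c) / (Tt - 1)
  Rw <- R11 + R22
  Rb <- R12 + t(R12)
  if (shrinkage > 0)
    Rw <- (1 - shrinkage) * Rw + shrinkage * mean(diag(Rw)) * diag(C)

  M <- tryCatch(solve(Rw, Rb), error = function(e)
    stop("within-subject covariance is singular; use nonzero shrinkage",
         call. = FALSE))
  eig <- eigen(M)
  vals <- Re(eig$values)
  vecs <- Re(eig$vectors)
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]

  isc <- vapply(seq_len(ncol(vecs)), function(k) {
    y1 <- drop(crossprod(vecs[, k], X1c))
    y2 <- drop(crossprod(vecs[, k], X2c))
    if (stats::sd(y1) == 0 || stats::sd(y2) == 0) return(0)
    stats::cor(y1, y2)
  }, numeric(1))

  structure(list(eigenvalues = vals, weights = vecs, component_isc = isc),
            class = "corrca")
}

#' Dyadic EEG inter-subject correlation (ISC)
#'
#' For each image, fits [corrca_fit()] on the dyad's two epochs and
#' averages the projected-time-course correlations of the top
#' `n_components` components; the dyad's ISC is the mean over images.
#' With a single channel this reduces exactly to the mean per-image
#' Pearson correlation.
#'
#' @param epochs_i,epochs_j image x channel x time arrays (same image set).
#' @param n_components number of top components to average (default 3).
#' @param shrinkage passed to [corrca_fit()].
#' @param use one of `"component_isc"` (default: average the projection
#'   correlations) or `"eigenvalues"` (average the top eigenvalues); the
#'   two coincide when the subjects' projected variances are equal.
#' @return A single ISC value.
#' @export
dyad_isc <- function(epochs_i, epochs_j, n_components = 3L, shrinkage = 0.05,
                     use = c("component_isc", "eigenvalues")) {
  use <- match.arg(use)
  if (!all(dim(epochs_i) == dim(epochs_j)))
    stop("epoch arrays differ in dimension", call. = FALSE)
  n_channels <- dim(epochs_i)[2]
  if (n_components > n_channels)
    stop("n_components exceeds the number of channels", call. = FALSE)
  M <- dim(epochs_i)[1]
  per_image <- vapply(seq_len(M), function(m) {
    fit <- corrca_fit(matrix(epochs_i[m, , ], nrow = n_channels),
                      matrix(epochs_j[m, , ], nrow = n_channels), shrinkage)
    k <- seq_len(n_components)
    if (use == "component_isc") mean(fit$component_isc[k])
    else mean(fit$eigenvalues[k])
  }, numeric(1))
  mean(per_image)
}

#' Dyadic ISC table for all subject pairs
#'
#' @param dataset an `"eeg_dataset"`.
#' @param images optional subset of image indices.
#' @inheritParams dyad_isc
#' @return A data frame with columns `subject_a`, `subject_b`, `value`;
#'   one row per unordered dyad.
#' @export
eeg_isc_table <- function(dataset, n_components = 3L, shrinkage = 0.05,
                          images = NULL) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  n <- length(dataset$subject_id)
  if (is.null(images)) images <- seq_len(dim(dataset$epochs)[2])
  pairs <- dyad_pairs(n)
  take <- function(i) {
    e <- dataset$epochs[i, images, , , drop = FALSE]
    array(e, dim = dim(e)[-1])
  }
  value <- vapply(seq_len(nrow(pairs)), function(d) {
    dyad_isc(take(pairs$a[d]), take(pairs$b[d]), n_components, shrinkage)
  }, numeric(1))
  data.frame(subject_a = dataset$subject_id[pairs$a],
             subject_b = dataset$subject_id[pairs$b],
             value = value, stringsAsFactors = FALSE)
}

#' Split-half reliability of dyadic EEG ISC
#'
#' Splits the stimulus set into odd- and even-indexed images, computes the
#' dyad ISC separately on each half, and correlates the two dyad vectors.
#'
#' @inheritParams eeg_isc_table
#' @param partition list of two image-index vectors; defaults to odd vs
#'   even images.
#' @return Pearson correlation across dyads.
#' @export
isc_split_half <- function(dataset, n_components = 3L, shrinkage = 0.05,
                           partition = NULL) {
  M <- dim(dataset$epochs)[2]
  if (is.null(partition))
    partition <- list(seq(1L, M, by = 2L), seq(2L, M, by = 2L))
  if (length(partition[[1]]) < 2L || length(partition[[2]]) < 2L)
    stop("need >= 2 images per half", call. = FALSE)
  halves <- lapply(partition, function(imgs)
    eeg_isc_table(dataset, n_components, shrinkage, images = imgs)$value)
  if (stats::sd(halves[[1]]) == 0 || stats::sd(halves[[2]]) == 0)
    stop("constant ISC vector in one half", call. = FALSE)
  stats::cor(halves[[1]], halves[[2]])
}
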