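#' Assemble the dyad table
#'
#' One row per unordered subject pair, carrying all similarity predictors
#' (personality, socio-demographic, optionally per-facet) and any supplied
#' synchrony outcomes. The table keeps a record of the subject labels and
#' of each predictor's subject-level provenance, which is what the
#' subject-shuffling permutation tests permute.
#'
#' @param profiles a `"profile_set"`.
#' @param synchrony optional `"synchrony_table"` from
#'   [dyadic_synchrony_table()]; spread into one outcome column per
#'   region/measure, named `"NM_R001"`, `"NP_R001"`, ....
#' @param isc optional EEG ISC table from [eeg_isc_table()] (column
#'   `eeg_isc`).
#' @param gaze optional gaze table from [gaze_similarity_table()] (column
#'   `gaze_similarity`).
#' @param metric a [similarity_metric()] for the overall personality
#'   predictor.
#' @param level `"trait"` or `"facet"`: score level for the overall
#'   personality similarity.
#' @param include_facets if `TRUE`, adds one predictor per facet
#'   (`facet_<name>`), coded as the negated absolute difference of the two
#'   subjects' facet scores.
#' @return A data frame of class `"dyad_table"` with `n(n-1)/2` rows and
#'   attributes used by the permutation machinery.
#' @export
build_dyad_table <- function(profiles, synchrony = NULL, isc = NULL,
                             gaze = NULL,
                             metric = similarity_metric("euclidean"),
                             level = c("trait", "facet"),
                             include_facets = FALSE) {
  stopifnot(inherits(profiles, "profile_set"))
  level <- match.arg(level)
  ids <- profiles$subject_id
  n <- length(ids)
  pairs <- dyad_pairs(n)
  scores <- score_traits(profiles$item_responses, profiles$keying,
                         profiles$scale[1], profiles$scale[2])
  score_mat <- if (level == "trait") scores$traits else scores$facets

  tab <- data.frame(subject_a = ids[pairs$a], subject_b = ids[pairs$b],
                    stringsAsFactors = FALSE)
  tab$personality_similarity <- pairwise_similarity(score_mat, metric)

  demo <- profiles$demographics
  demo_sims <- lapply(seq_len(nrow(pairs)), function(r)
    demographic_similarity(demo[pairs$a[r], ], demo[pairs$b[r], ]))
  for (f in names(demo_sims[[1]]))
    tab[[f]] <- vapply(demo_sims, function(x) as.numeric(x[[f]]), numeric(1))

  if (include_facets) {
    for (fc in colnames(scores$facets)) {
      tab[[paste0("facet_", fc)]] <-
        -abs(scores$facets[pairs$a, fc] - scores$facets[pairs$b, fc])
    }
  }

  merge_outcome <- function(tab, extra, value_cols) {
    key_t <- paste(tab$subject_a, tab$subject_b)
    key_e <- paste(extra$subject_a, extra$subject_b)
    mi <- match(key_t, key_e)
    if (anyNA(mi))
      stop("outcome table subject labels inconsistent with profiles",
           call. = FALSE)
    for (vc in names(value_cols)) tab[[vc]] <- value_cols[[vc]][mi]
    tab
  }

  if (!is.null(synchrony)) {
    if (!all(unique(c(synchrony$subject_a, synchrony$subject_b)) %in% ids))
      stop("synchrony table subject labels inconsistent with profiles",
           call. = FALSE)
    syn <- as.data.frame(synchrony)
    syn$col <- paste(syn$measure, syn$region, sep = "_")
    for (cl in unique(syn$col)) {
      sub <- syn[syn$col == cl, c("subject_a", "subject_b", "value")]
      tab <- merge_outcome(tab, sub, stats::setNames(list(sub$value), cl))
    }
  }
  if (!is.null(isc))
    tab <- merge_outcome(tab, isc,
                         stats::setNames(list(isc$value), "eeg_isc"))
  if (!is.null(gaze))
    tab <- merge_outcome(tab, gaze,
                         stats::setNames(list(gaze$value), "gaze_similarity"))

  attr(tab, "subject_id") <- ids
  attr(tab, "pair_index") <- pairs
  class(tab) <- c("dyad_table", "data.frame")
  tab
}

# Lookup matrix: row index of the dyad (i, j) in the table.
pair_lookup <- function(n, pairs) {
  M <- matrix(NA_integer_, n, n)
  M[cbind(pairs$a, pairs$b)] <- seq_len(nrow(pairs))
  M[cbind(pairs$b, pairs$a)] <- seq_len(nrow(pairs))
  M
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance column", call. = FALSE)
  (x - mean(x)) / s
}

#' Standardized OLS on the dyad table
#'
#' z-scores the outcome and every predictor across dyads and fits ordinary
#' least squares, so every coefficient is a standardized beta.
#'
#' @param table a `"dyad_table"` (or any data frame).
#' @param outcome outcome column name.
#' @param predictors character vector of focal predictor column names.
#' @param covariates optional character vector of control column names.
#' @return A list of class `"std_ols"`: `coefficients` (a data frame with
#'   `term`, `beta`, `se`, `t`, `p` for predictors and covariates),
#'   `vcov`, `n`, `residuals`.
#' @export
standardized_ols <- function(table, outcome, predictors,
                             covariates = NULL) {
  cols <- c(outcome, predictors, covariates)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("columns not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dat <- table[, cols, drop = FALSE]
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  p <- length(predictors) + length(covariates)
  if (nrow(dat) < p + 2L)
    stop("too few complete dyads for the design", call. = FALSE)
  Z <- vapply(cols, function(cl) zscore(dat[[cl]]), numeric(nrow(dat)))
  y <- Z[, 1]
  X <- cbind(`(Intercept)` = 1, Z[, -1, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  vc <- sigma2 * XtXinv
  dimnames(vc) <- list(colnames(X), colnames(X))
  beta <- fit$coefficients
  se <- sqrt(diag(vc))
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  coefs <- data.frame(term = colnames(X), beta = beta, se = se, t = tstat,
                      p = pval, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs[-1, , drop = FALSE], vcov = vc,
                 n = nrow(X), df = df, residuals = res),
            class = "std_ols")
}

#' @export
print.std_ols <- function(x, ...) {
  cat(sprintf("Standardized OLS (n = %d dyads)\n", x$n))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}

# Extract one predictor's row from a std_ols fit.
ols_beta <- function(fit, term) {
  row <- fit$coefficients[fit$coefficients$term == term, ]
  if (nrow(row) != 1L) stop("term not found: ", term, call. = FALSE)
  row
}

#' Subject-shuffling (Mantel-style) permutation test
#'
#' Tests a dyadic predictor's standardized OLS coefficient against a null
#' built by randomly permuting subject identities. Because every dyadic
#' predictor is a symmetric function of the two subjects' attributes,
#' permuting subject labels and re-indexing the dyadic predictor is
#' exactly equivalent to recomputing it from permuted subject-level
#' attributes, while respecting the dyadic dependence structure that makes
#' ordinary row shuffles invalid. Covariates stay fixed, so the test
#' targets the partial effect of the shuffled predictor.
#'
#' @inheritParams standardized_ols
#' @param predictor single predictor column to permute and test.
#' @param n_permutations number of random subject permutations (default
#'   1000, resolving p down to about 0.001).
#' @param seed integer seed for the permutation stream.
#' @return A list of class `"permutation_result"`: `beta_obs`, `se`,
#'   `p_parametric`, `p_permutation` (two-sided, with the +1 correction),
#'   `n_permutations`, `seed`, `null_quantiles`.
#' @export
subject_permutation_test <- function(table, outcome, predictor,
                                     covariates = NULL,
                                     n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(table, "dyad_table"))
  ids <- attr(table, "subject_id")
  pairs <- attr(table, "pair_index")
  n <- length(ids)
  lookup <- pair_lookup(n, pairs)

  obs <- standardized_ols(table, outcome, predictor, covariates)
  brow <- ols_beta(obs, predictor)

  keep <- stats::complete.cases(table[, c(outcome, predictor, covariates),
                                      drop = FALSE])
  perm_tab <- table[keep, , drop = FALSE]
  x <- table[[predictor]]

  set.seed(as.integer(seed))
  beta_null <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    new_rows <- lookup[cbind(perm[pairs$a], perm[pairs$b])]
    perm_tab[[predictor]] <- x[new_rows][keep]
    fit <- tryCatch(standardized_ols(perm_tab, outcome, predictor,
                                     covariates),
                    error = function(e) NULL)
    beta_null[b] <- if (is.null(fit)) NA_real_ else
      ols_beta(fit, predictor)$beta
  }
  beta_null <- beta_null[is.finite(beta_null)]
  p_perm <- (1 + sum(abs(beta_null) >= abs(brow$beta))) /
    (length(beta_null) + 1)
  structure(list(beta_obs = brow$beta, se = brow$se,
                 p_parametric = brow$p, p_permutation = p_perm,
                 n_permutations = length(beta_null), seed = as.integer(seed),
                 null_quantiles = stats::quantile(
                   beta_null, c(0.025, 0.25, 0.5, 0.75, 0.975))),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "beta = %.4f (SE %.4f), p = %.3g, p_permutation = %.4g (%d permutations)\n",
    x$beta_obs, x$se, x$p_parametric, x$p_permutation, x$n_permutations))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR control at level `q` across a family of p-values (e.g. all
#' brain regions of one synchrony measure). Adjusted p-values come from
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A data frame with `p`, `p_adjusted`, `rejected`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p_values, method = "BH")
  data.frame(p = p_values, p_adjusted = adj, rejected = adj <= q)
}

#' Per-network one-sample t-tests on regional coefficients
#'
#' For each network, tests whether the distribution of its regions' betas
#' differs from zero. Regional coefficients share dyads and are therefore
#' not independent; the tests are descriptive summaries of the coefficient
#' distributions, not independent-sample inference.
#'
#' @param region_betas numeric vector of per-region standardized betas.
#' @param network_labels network label per region.
#' @return A data frame with one row per network: `network`, `n_regions`,
#'   `mean_beta`, `t`, `df`, `p`.
#' @export
network_coefficient_test <- function(region_betas, network_labels) {
  stopifnot(length(region_betas) == length(network_labels))
  nets <- unique(network_labels)
  rows <- lapply(nets, function(nw) {
    b <- region_betas[network_labels == nw]
    if (length(b) < 2L)
      stop("network '", nw, "' has fewer than 2 regions", call. = FALSE)
    if (stats::sd(b) == 0)
      stop("zero-variance coefficient vector in network '", nw, "'",
           call. = FALSE)
    tt <- stats::t.test(b, mu = 0)
    data.frame(network = nw, n_regions = length(b), mean_beta = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-subject effect distribution
#'
#' Re-runs the standardized regression restricted to the dyads containing
#' each single subject (n - 1 observations per subject) and reports the
#' per-subject coefficient for the focal predictor plus the fraction of
#' subjects with a positive coefficient.
#'
#' @inheritParams standardized_ols
#' @param predictor focal predictor column.
#' @return A list: `betas` (named per-subject vector), `fraction_positive`,
#'   `n_obs_per_subject`.
#' @export
per_subject_effects <- function(table, outcome, predictor,
                                covariates = NULL) {
  stopifnot(inherits(table, "dyad_table"))
  ids <- attr(table, "subject_id")
  p <- 1L + length(covariates)
  betas <- stats::setNames(rep(NA_real_, length(ids)), ids)
  n_obs <- integer(0)
  for (s in ids) {
    rows <- table$subject_a == s | table$subject_b == s
    sub <- table[rows, , drop = FALSE]
    if (sum(stats::complete.cases(
      sub[, c(outcome, predictor, covariates), drop = FALSE])) < p + 2L) {
      warning("subject ", s, " has too few dyads; excluded")
      next
    }
    # a covariate can be constant within one subject's dyads; drop it there
    covs_s <- covariates[vapply(covariates, function(cl)
      stats::sd(sub[[cl]], na.rm = TRUE) > 0, logical(1))]
    fit <- standardized_ols(sub, outcome, predictor, covs_s)
    betas[s] <- ols_beta(fit, predictor)$beta
    n_obs <- c(n_obs, fit$n)
  }
  ok <- is.finite(betas)
  list(betas = betas[ok],
       fraction_positive = mean(betas[ok] > 0),
       n_obs_per_subject = unique(n_obs))
}

#' Mediation analysis with subject-shuffling permutation tests
#'
#' Estimates the classical OLS path decomposition on standardized
#' variables: `a` (X -> M), `b` (M -> Y given X), total `c` (X -> Y),
#' direct `c'` (X -> Y given M), and the indirect effect `a * b`
#' (= `c - c'` for linear OLS on the same sample). Permutation p-values
#' relabel subjects: for path `a` the X attribute is shuffled; for path
#' `b`, M; for the indirect effect, X and M are shuffled independently and
#' the product `a* x b*` forms the null.
#'
#' @param table a `"dyad_table"`.
#' @param x,mediator,outcome column names.
#' @param n_permutations,seed permutation stream controls.
#' @return A list of class `"mediation_result"` with elements `path_a`,
#'   `path_b`, `total_c`, `direct_c_prime`, `indirect` (each carrying
#'   `beta`, `se`, `p_parametric`, and for a/b/indirect `p_permutation`).
#' @export
mediation_analysis <- function(table, x, mediator, outcome,
                               n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(table, "dyad_table"))
  ids <- attr(table, "subject_id")
  pairs <- attr(table, "pair_index")
  n <- length(ids)
  lookup <- pair_lookup(n, pairs)

  fit_paths <- function(tab) {
    fa <- standardized_ols(tab, mediator, x)
    fb <- standardized_ols(tab, outcome, c(mediator, x))
    fc <- standardized_ols(tab, outcome, x)
    fcp <- standardized_ols(tab, outcome, c(x, mediator))
    list(a = ols_beta(fa, x), b = ols_beta(fb, mediator),
         c = ols_beta(fc, x), c_prime = ols_beta(fcp, x))
  }
  obs <- fit_paths(table)
  indirect_obs <- obs$a$beta * obs$b$beta

  keep <- stats::complete.cases(table[, c(x, mediator, outcome),
                                      drop = FALSE])
  base <- table[keep, , drop = FALSE]
  xv <- table[[x]]; mv <- table[[mediator]]

  set.seed(as.integer(seed))
  a_null <- b_null <- numeric(n_permutations)
  for (bb in seq_len(n_permutations)) {
    px <- sample.int(n); pm <- sample.int(n)
    tab_x <- base
    tab_x[[x]] <- xv[lookup[cbind(px[pairs$a], px[pairs$b])]][keep]
    tab_m <- base
    tab_m[[mediator]] <- mv[lookup[cbind(pm[pairs$a], pm[pairs$b])]][keep]
    a_null[bb] <- ols_beta(standardized_ols(tab_x, mediator, x), x)$beta
    b_null[bb] <- ols_beta(standardized_ols(tab_m, outcome,
                                            c(mediator, x)), mediator)$beta
  }
  perm_p <- function(null, observed)
    (1 + sum(abs(null) >= abs(observed))) / (length(null) + 1)

  mk <- function(row, p_perm = NULL) {
    out <- list(beta = row$beta, se = row$se, p_parametric = row$p)
    if (!is.null(p_perm)) out$p_permutation <- p_perm
    out
  }
  structure(list(
    path_a = mk(obs$a, perm_p(a_null, obs$a$beta)),
    path_b = mk(obs$b, perm_p(b_null, obs$b$beta)),
    total_c = mk(obs$c),
    direct_c_prime = mk(obs$c_prime),
    indirect = list(beta = indirect_obs,
                    p_permutation = perm_p(a_null * b_null, indirect_obs)),
    n_permutations = n_permutations, seed = as.integer(seed)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation (standardized OLS paths)\n")
  cat(sprintf("  a (X->M):      beta = %.4f, p_perm = %.4g\n",
              x$path_a$beta, x$path_a$p_permutation))
  cat(sprintf("  b (M->Y|X):    beta = %.4f, p_perm = %.4g\n",
              x$path_b$beta, x$path_b$p_permutation))
  cat(sprintf("  c (total):     beta = %.4f\n", x$total_c$beta))
  cat(sprintf("  c' (direct):   beta = %.4f\n", x$direct_c_prime$beta))
  cat(sprintf("  a*b (indirect): beta = %.4g, p_perm = %.4g\n",
              x$indirect$beta, x$indirect$p_permutation))
  invisible(x)
}

#' Compare two predictors' effect sizes across focal effects
#'
#' Pooled-variance two-sample t-test comparing predictor A's coefficients
#' against predictor B's across the same `k` focal effects (df = 2k - 2;
#' six focal effects give df = 10).
#'
#' @param coefficient_matrix numeric matrix, focal effects x predictors.
#' @param predictor_a,predictor_b column names (or indices) to compare.
#' @return A list with `t`, `df`, `p`, and the two mean coefficients.
#' @export
compare_effect_sizes <- function(coefficient_matrix, predictor_a,
                                 predictor_b) {
  A <- coefficient_matrix[, predictor_a]
  B <- coefficient_matrix[, predictor_b]
  if (length(A) != length(B) || length(A) < 2L)
    stop("need the same >= 2 focal effects for both predictors",
         call. = FALSE)
  tt <- stats::t.test(A, B, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(A), mean_b = mean(B))
}

#' Wald contrast between two coefficients of one standardized model
#'
#' Tests whether two standardized coefficients from the same fitted model
#' differ, using the fitted coefficient covariance:
#' z = (b1 - b2) / sqrt(v11 + v22 - 2 v12).
#'
#' @param fit a `"std_ols"` object.
#' @param term_a,term_b coefficient names.
#' @return A list with `difference`, `se`, `z`, `p`.
#' @export
coefficient_contrast <- function(fit, term_a, term_b) {
  stopifnot(inherits(fit, "std_ols"))
  b <- stats::setNames(fit$coefficients$beta, fit$coefficients$term)
  v <- fit$vcov
  d <- b[[term_a]] - b[[term_b]]
  se <- sqrt(v[term_a, term_a] + v[term_b, term_b] - 2 * v[term_a, term_b])
  z <- d / se
  list(difference = unname(d), se = unname(se), z = unname(z),
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}
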