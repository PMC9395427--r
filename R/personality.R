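#' Score traits and facets from item responses
#'
#' Facet scores are the mean of their keyed items, with reverse-keyed items
#' reflected as `scale_min + scale_max - response` before averaging; trait
#' scores are the mean of their facet scores. Missing responses are an
#' error: with short inventories there is no defensible imputation.
#'
#' @param item_responses numeric subjects x items matrix; column names must
#'   match `keying$item`.
#' @param keying data frame with columns `item`, `trait`, `facet`,
#'   `reverse` (logical).
#' @param scale_min,scale_max Likert bounds used to reflect reverse-keyed
#'   items.
#' @return A list with `traits` (subjects x traits) and `facets`
#'   (subjects x facets), both numeric matrices. Facet columns are named
#'   as in `keying$facet`; trait columns as in `keying$trait` (first-use
#'   order).
#' @examples
#' keying <- data.frame(item = c("a1", "a2"), trait = "agreeableness",
#'                      facet = "agreeableness_f1", reverse = c(FALSE, TRUE))
#' resp <- matrix(c(7, 1), 1, 2, dimnames = list("S1", c("a1", "a2")))
#' score_traits(resp, keying, 1, 7)$traits  # reflected to (7, 7) -> 7
#' @export
score_traits <- function(item_responses, keying, scale_min, scale_max) {
  item_responses <- as.matrix(item_responses)
  if (anyNA(item_responses))
    stop("missing item responses; no imputation is performed", call. = FALSE)
  if (is.null(colnames(item_responses)))
    stop("item_responses must have item names as column names", call. = FALSE)
  missing_key <- setdiff(colnames(item_responses), keying$item)
  if (length(missing_key))
    stop("unkeyed items: ", paste(missing_key, collapse = ", "),
         call. = FALSE)
  keying <- keying[match(colnames(item_responses), keying$item), ]

  scored <- item_responses
  rev <- which(keying$reverse)
  if (length(rev))
    scored[, rev] <- (scale_min + scale_max) - scored[, rev]

  facet_levels <- unique(keying$facet)
  facets <- vapply(facet_levels, function(f) {
    cols <- which(keying$facet == f)
    rowMeans(scored[, cols, drop = FALSE])
  }, numeric(nrow(scored)))
  facets <- matrix(facets, nrow = nrow(scored),
                   dimnames = list(rownames(item_responses), facet_levels))

  trait_levels <- unique(keying$trait)
  facet_trait <- keying$trait[match(facet_levels, keying$facet)]
  traits <- vapply(trait_levels, function(tr) {
    rowMeans(facets[, facet_trait == tr, drop = FALSE])
  }, numeric(nrow(scored)))
  traits <- matrix(traits, nrow = nrow(scored),
                   dimnames = list(rownames(item_responses), trait_levels))

  list(traits = traits, facets = facets)
}

#' Cronbach's alpha internal consistency
#'
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j
#'   \mathrm{Var}(x_j)}{\mathrm{Var}(\sum_j x_j)}\right)}
#' over the `k` item columns. Reverse-keyed items should be reflected
#' before calling (as [score_traits()] does internally).
#'
#' @param items numeric subjects x items matrix (>= 2 items, >= 2 subjects).
#' @return Alpha (can be negative for incoherent scales).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("alpha requires >= 2 items", call. = FALSE)
  if (nrow(items) < 2L) stop("alpha requires >= 2 subjects", call. = FALSE)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero total-score variance", call. = FALSE)
  k <- ncol(items)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Similarity metric specification
#'
#' @param name one of `"euclidean"`, `"manhattan"`, `"canberra"`,
#'   `"supremum"`.
#' @param invert if `TRUE` (default) the distance is subtracted from zero so
#'   that higher values mean more similar profiles.
#' @return A list of class `"similarity_metric"`.
#' @export
similarity_metric <- function(name = c("euclidean", "manhattan", "canberra",
                                       "supremum"),
                              invert = TRUE) {
  name <- match.arg(name)
  structure(list(name = name, invert = isTRUE(invert)),
            class = "similarity_metric")
}

#' Dyadic personality similarity (negated profile distance)
#'
#' Distance between two trait (or facet) score vectors:
#' Euclidean \eqn{\sqrt{\sum_i (x_i - y_i)^2}}, Manhattan
#' \eqn{\sum_i |x_i - y_i|}, Canberra
#' \eqn{\sum_i |x_i - y_i| / |x_i + y_i|}, or supremum
#' \eqn{\max_i |x_i - y_i|}. With `invert = TRUE` the negated distance is
#' returned so that larger values indicate more similar profiles.
#'
#' @param p_i,p_j numeric score vectors of equal length.
#' @param spec a [similarity_metric()].
#' @return A single number (<= 0 when inverted).
#' @export
personality_similarity <- function(p_i, p_j,
                                   spec = similarity_metric("euclidean")) {
  if (length(p_i) != length(p_j))
    stop("score vectors differ in length", call. = FALSE)
  if (!all(is.finite(p_i)) || !all(is.finite(p_j)))
    stop("score vectors must be finite", call. = FALSE)
  d <- switch(spec$name,
    euclidean = sqrt(sum((p_i - p_j)^2)),
    manhattan = sum(abs(p_i - p_j)),
    canberra = {
      den <- abs(p_i + p_j)
      if (any(den == 0 & abs(p_i - p_j) >= 0))
        stop("canberra distance undefined: coordinate pair with x + y = 0",
             call. = FALSE)
      sum(abs(p_i - p_j) / den)
    },
    supremum = max(abs(p_i - p_j))
  )
  if (spec$invert) 0 - d else d
}

# All unordered pairs of n subjects, subject_a index < subject_b index.
dyad_pairs <- function(n) {
  stopifnot(n >= 2L)
  idx <- utils::combn(n, 2L)
  data.frame(a = idx[1, ], b = idx[2, ])
}

# Similarity vector over all dyads for a score matrix.
pairwise_similarity <- function(scores, spec) {
  pairs <- dyad_pairs(nrow(scores))
  vapply(seq_len(nrow(pairs)), function(r) {
    personality_similarity(scores[pairs$a[r], ], scores[pairs$b[r], ], spec)
  }, numeric(1))
}

#' Dyadic socio-demographic similarity codings
#'
#' Binary codings: 1 if the two subjects share the attribute (gender,
#' handedness, nationality), 1 if their ethnicity sets overlap.
#' Age and political-ideology similarity are negated absolute differences,
#' so every similarity points in the direction "higher = more similar".
#'
#' @param profile_i,profile_j single-row data frames (or lists) with fields
#'   `gender`, `age`, `handedness`, `nationality`, `ethnicity`
#'   (`;`-separated set of labels) and optionally `political_ideology`
#'   (1-7).
#' @return A named list: `gender_similarity`, `age_similarity`,
#'   `handedness_similarity`, `nationality_similarity`,
#'   `ethnicity_similarity`, and `politics_similarity` (`NA` if ideology is
#'   missing from either profile).
#' @export
demographic_similarity <- function(profile_i, profile_j) {
  need <- c("gender", "age", "handedness", "nationality", "ethnicity")
  for (f in need) {
    if (is.null(profile_i[[f]]) || is.null(profile_j[[f]]))
      stop("missing demographic field: ", f, call. = FALSE)
  }
  eth_i <- strsplit(as.character(profile_i[["ethnicity"]]), ";", fixed = TRUE)[[1]]
  eth_j <- strsplit(as.character(profile_j[["ethnicity"]]), ";", fixed = TRUE)[[1]]
  pol <- if (!is.null(profile_i[["political_ideology"]]) &&
             !is.null(profile_j[["political_ideology"]])) {
    -abs(profile_i[["political_ideology"]] - profile_j[["political_ideology"]])
  } else NA_real_
  list(
    gender_similarity = as.numeric(profile_i[["gender"]] == profile_j[["gender"]]),
    age_similarity = -abs(profile_i[["age"]] - profile_j[["age"]]),
    handedness_similarity = as.numeric(profile_i[["handedness"]] ==
                                         profile_j[["handedness"]]),
    nationality_similarity = as.numeric(profile_i[["nationality"]] ==
                                          profile_j[["nationality"]]),
    ethnicity_similarity = as.numeric(length(intersect(eth_i, eth_j)) > 0L),
    politics_similarity = pol
  )
}

#' Split-half reliability of dyadic personality similarity
#'
#' Splits the inventory into two halves (odd- vs even-positioned items
#' within each facet — balanced and deterministic), scores each half,
#' computes the dyadic similarity vector per half, and returns the Pearson
#' correlation of the two similarity vectors across all dyads.
#'
#' @param item_responses subjects x items matrix.
#' @param keying item keying as for [score_traits()].
#' @param scale_min,scale_max Likert bounds.
#' @param spec a [similarity_metric()].
#' @param level `"trait"` (default) or `"facet"`: which score level the
#'   similarity is computed over.
#' @return Pearson correlation between the two half-based similarity
#'   vectors.
#' @export
split_half_reliability <- function(item_responses, keying, scale_min,
                                   scale_max,
                                   spec = similarity_metric("euclidean"),
                                   level = c("trait", "facet")) {
  level <- match.arg(level)
  item_responses <- as.matrix(item_responses)
  if (ncol(item_responses) < 4L)
    stop("split-half reliability requires >= 4 items", call. = FALSE)
  if (nrow(item_responses) < 3L)
    stop("split-half reliability requires >= 3 subjects", call. = FALSE)
  keying <- keying[match(colnames(item_responses), keying$item), ]

  in_half1 <- logical(ncol(item_responses))
  for (f in unique(keying$facet)) {
    cols <- which(keying$facet == f)
    in_half1[cols[seq_along(cols) %% 2L == 1L]] <- TRUE
  }
  halves <- list(which(in_half1), which(!in_half1))
  sims <- lapply(halves, function(cols) {
    sc <- score_traits(item_responses[, cols, drop = FALSE],
                       keying[cols, ], scale_min, scale_max)
    mat <- if (level == "trait") sc$traits else sc$facets
    pairwise_similarity(mat, spec)
  })
  if (stats::sd(sims[[1]]) == 0 || stats::sd(sims[[2]]) == 0)
    stop("constant similarity vector in one half; reliability undefined",
         call. = FALSE)
  stats::cor(sims[[1]], sims[[2]])
}
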