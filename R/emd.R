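#' Dwell-time-weighted fixation histogram
#'
#' Converts a fixation sequence into a probability distribution over an
#' `grid_dims[1] x grid_dims[2]` grid covering the unit square. Coordinates
#' are normalized by the screen dimensions (`x / width`, `y / height`,
#' origin top-left); each fixation contributes mass proportional to its
#' duration to the cell containing it. Cells are half-open `[lo, hi)`
#' except the last row/column, which is closed so edge fixations are kept.
#'
#' @param fixations data frame with columns `x`, `y` (pixels) and
#'   `duration` (ms); at least one row.
#' @param screen_dims `c(width, height)` in pixels.
#' @param grid_dims `c(n_rows, n_cols)` (default `c(32, 32)`).
#' @return An object of class `"fixation_distribution"`: a list with
#'   `mass` (rows x cols matrix summing to 1) and `grid_dims`.
#' @export
fixation_histogram <- function(fixations, screen_dims,
                               grid_dims = c(32L, 32L)) {
  if (is.null(fixations) || nrow(fixations) == 0L)
    stop("empty fixation list", call. = FALSE)
  if (any(fixations$duration <= 0))
    stop("fixation durations must be positive", call. = FALSE)
  if (any(fixations$x < 0 | fixations$x >= screen_dims[1]) ||
      any(fixations$y < 0 | fixations$y >= screen_dims[2]))
    stop("fixation coordinates out of screen bounds", call. = FALSE)
  H <- as.integer(grid_dims[1]); W <- as.integer(grid_dims[2])
  stopifnot(H >= 1L, W >= 1L)
  u <- fixations$x / screen_dims[1]
  v <- fixations$y / screen_dims[2]
  col <- pmin(W, floor(u * W) + 1L)   # last column closed
  row <- pmin(H, floor(v * H) + 1L)   # last row closed
  mass <- matrix(0, H, W)
  for (k in seq_along(u))
    mass[row[k], col[k]] <- mass[row[k], col[k]] + fixations$duration[k]
  mass <- mass / sum(mass)
  structure(list(mass = mass, grid_dims = c(H, W)),
            class = "fixation_distribution")
}

# Exact transportation problem (supplies a, demands b, cost C) solved with
# the transportation simplex (northwest-corner start, MODI pivoting).
# Returns the optimal cost and the dual potentials (u, v), which certify
# optimality via c_ij - u_i - v_j >= 0.
transport_simplex <- function(a, b, C, tol = 1e-10, max_iter = 100000L) {
  m <- length(a); n <- length(b)
  stopifnot(nrow(C) == m, ncol(C) == n)
  if (abs(sum(a) - sum(b)) > 1e-8)
    stop("supplies and demands must balance", call. = FALSE)

  # Northwest-corner initial basis: exactly m + n - 1 basic cells,
  # degenerate cells carry zero flow.
  bi <- integer(m + n - 1L); bj <- integer(m + n - 1L)
  bf <- numeric(m + n - 1L)
  ra <- a; rb <- b
  i <- 1L; j <- 1L
  for (k in seq_len(m + n - 1L)) {
    f <- min(ra[i], rb[j])
    bi[k] <- i; bj[k] <- j; bf[k] <- f
    ra[i] <- ra[i] - f; rb[j] <- rb[j] - f
    if (i < m && (ra[i] <= rb[j] || j == n)) i <- i + 1L else j <- j + 1L
  }

  for (iter in seq_len(max_iter)) {
    # Dual potentials from the basis tree (u[1] = 0).
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1] <- 0
    repeat {
      progressed <- FALSE
      for (k in seq_along(bi)) {
        if (!is.na(u[bi[k]]) && is.na(v[bj[k]])) {
          v[bj[k]] <- C[bi[k], bj[k]] - u[bi[k]]; progressed <- TRUE
        } else if (is.na(u[bi[k]]) && !is.na(v[bj[k]])) {
          u[bi[k]] <- C[bi[k], bj[k]] - v[bj[k]]; progressed <- TRUE
        }
      }
      if (!progressed) break
    }
    if (anyNA(u) || anyNA(v))
      stop("degenerate basis: disconnected basis tree", call. = FALSE)

    red <- C - outer(u, v, "+")
    red[cbind(bi, bj)] <- 0
    enter <- which.min(red)
    if (red[enter] >= -tol) {
      cost <- sum(bf * C[cbind(bi, bj)])
      return(list(cost = cost, u = u, v = v,
                  basis = data.frame(i = bi, j = bj, flow = bf)))
    }
    ei <- (enter - 1L) %% m + 1L
    ej <- (enter - 1L) %/% m + 1L

    # Find the unique alternating cycle through the entering cell: in the
    # basis graph (rows and columns as nodes, basic cells as edges), BFS
    # for a path from row ei to column ej.
    via_col <- integer(n)   # basis cell that first reached each column
    via_row <- integer(m)   # basis cell that first reached each row
    via_row[ei] <- -1L      # sentinel: search root
    frontier_rows <- ei
    found <- FALSE
    while (length(frontier_rows) && !found) {
      new_cols <- integer(0)
      for (r in frontier_rows) {
        for (k in which(bi == r)) {
          cc <- bj[k]
          if (via_col[cc] == 0L) {
            via_col[cc] <- k
            new_cols <- c(new_cols, cc)
            if (cc == ej) { found <- TRUE; break }
          }
        }
        if (found) break
      }
      if (found) break
      frontier_rows <- integer(0)
      for (cc in new_cols) {
        for (k in which(bj == cc)) {
          rr <- bi[k]
          if (via_row[rr] == 0L) {
            via_row[rr] <- k
            frontier_rows <- c(frontier_rows, rr)
          }
        }
      }
    }
    if (!found)
      stop("internal error: no pivot cycle found", call. = FALSE)

    # Walk back from column ej to row ei collecting the path of basis
    # cells (ordered from ei's end to ej's end).
    path <- integer(0)
    cc <- ej
    repeat {
      k <- via_col[cc]
      path <- c(k, path)
      rr <- bi[k]
      if (rr == ei) break
      k2 <- via_row[rr]
      path <- c(k2, path)
      cc <- bj[k2]
    }
    # Cycle: entering cell (+), then alternating -,+ along the path back.
    signs <- rep_len(c(-1, 1), length(path))
    neg <- path[signs < 0]
    theta <- min(bf[neg])
    leave <- neg[which.min(bf[neg])]
    bf[path] <- bf[path] + signs * theta
    bi[leave] <- ei; bj[leave] <- ej; bf[leave] <- theta
  }
  stop("transportation simplex failed to converge", call. = FALSE)
}

#' Earth mover's distance between two fixation distributions
#'
#' Exact optimal-transport cost between the two cell-mass distributions,
#' with ground metric the Euclidean distance between cell centers in
#' unit-square coordinates. Solved as an exact transportation linear
#' program restricted to cells with positive mass; the result is bounded
#' by the grid diagonal (sqrt(2)).
#'
#' @param P,Q `"fixation_distribution"` objects on identical grids.
#' @return Nonnegative transport cost.
#' @export
emd <- function(P, Q) {
  stopifnot(inherits(P, "fixation_distribution"),
            inherits(Q, "fixation_distribution"))
  if (!all(P$grid_dims == Q$grid_dims))
    stop("distributions live on different grids", call. = FALSE)
  H <- P$grid_dims[1]; W <- P$grid_dims[2]
  ip <- which(P$mass > 0); iq <- which(Q$mass > 0)
  a <- P$mass[ip]; b <- Q$mass[iq]
  a <- a / sum(a); b <- b / sum(b)
  centers <- function(idx) {
    r <- (idx - 1L) %% H + 1L
    c <- (idx - 1L) %/% H + 1L
    cbind((c - 0.5) / W, (r - 0.5) / H)
  }
  cp <- centers(ip); cq <- centers(iq)
  C <- sqrt(outer(cp[, 1], cq[, 1], "-")^2 + outer(cp[, 2], cq[, 2], "-")^2)
  transport_simplex(a, b, C)$cost
}

#' Dyadic gaze similarity (negated mean EMD over shared images)
#'
#' Builds dwell-time histograms for each image viewed by both subjects,
#' computes the EMD per image, averages across images, and negates the
#' result so that — as for all other predictors — higher values mean more
#' similar viewing.
#'
#' @param subject_i,subject_j subject ids or indices.
#' @param dataset a `"gaze_dataset"`.
#' @param grid_dims histogram grid (default 32 x 32).
#' @return Negated mean EMD (a nonpositive number).
#' @export
dyad_gaze_similarity <- function(subject_i, subject_j, dataset,
                                 grid_dims = c(32L, 32L)) {
  stopifnot(inherits(dataset, "gaze_dataset"))
  gi <- gaze_subject(dataset, subject_i)
  gj <- gaze_subject(dataset, subject_j)
  shared <- which(!vapply(gi, is.null, logical(1)) &
                    !vapply(gj, is.null, logical(1)))
  if (length(shared) == 0L)
    stop("no shared images between subjects", call. = FALSE)
  d <- vapply(shared, function(m) {
    emd(fixation_histogram(gi[[m]], dataset$screen_dims, grid_dims),
        fixation_histogram(gj[[m]], dataset$screen_dims, grid_dims))
  }, numeric(1))
  -mean(d)
}

gaze_subject <- function(dataset, subject) {
  if (is.character(subject)) {
    i <- match(subject, dataset$subject_id)
    if (is.na(i)) stop("unknown subject: ", subject, call. = FALSE)
  } else i <- as.integer(subject)
  dataset$fixations[[i]]
}

#' Dyadic gaze-similarity table for all subject pairs
#'
#' @param dataset a `"gaze_dataset"`.
#' @param grid_dims histogram grid passed to [dyad_gaze_similarity()].
#' @return Data frame with `subject_a`, `subject_b`, `value` (negated mean
#'   EMD); one row per unordered dyad.
#' @export
gaze_similarity_table <- function(dataset, grid_dims = c(32L, 32L)) {
  n <- length(dataset$subject_id)
  pairs <- dyad_pairs(n)
  value <- vapply(seq_len(nrow(pairs)), function(d) {
    dyad_gaze_similarity(pairs$a[d], pairs$b[d], dataset, grid_dims)
  }, numeric(1))
  data.frame(subject_a = dataset$subject_id[pairs$a],
             subject_b = dataset$subject_id[pairs$b],
             value = value, stringsAsFactors = FALSE)
}
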