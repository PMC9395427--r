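#' Read fixation sequences from CSV
#'
#' Expects columns `subject`, `image`, `x`, `y`, `duration` (ms). Rows are
#' grouped into per-subject, per-image fixation data frames in file order
#' (assumed temporal order).
#'
#' @param path CSV file path.
#' @param screen_dims `c(width, height)` in pixels.
#' @return A `"gaze_dataset"`.
#' @export
read_fixations_csv <- function(path, screen_dims) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "image", "x", "y", "duration")
  if (!all(need %in% names(d)))
    stop("fixation CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  subjects <- unique(d$subject)
  images <- unique(d$image)
  fixations <- lapply(subjects, function(s) {
    lapply(images, function(im) {
      sub <- d[d$subject == s & d$image == im, c("x", "y", "duration")]
      if (nrow(sub) == 0L) NULL else sub
    })
  })
  names(fixations) <- subjects
  structure(list(fixations = fixations, screen_dims = screen_dims,
                 image_meta = data.frame(image = images,
                                         stringsAsFactors = FALSE),
                 subject_id = subjects),
            class = "gaze_dataset")
}

#' Write a synchrony table to long-format CSV
#'
#' @param table a `"synchrony_table"` (columns `subject_a`, `subject_b`,
#'   `region`, `measure`, `value`).
#' @param path output CSV path.
#' @export
write_synchrony_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format synchrony CSV
#'
#' @param path CSV with columns `subject_a`, `subject_b`, `region`,
#'   `measure`, `value`.
#' @return A `"synchrony_table"` data frame.
#' @export
read_synchrony_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_a", "subject_b", "region", "measure", "value")
  if (!all(need %in% names(d)))
    stop("synchrony CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  class(d) <- c("synchrony_table", "data.frame")
  d
}
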