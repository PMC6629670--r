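## Aorta localization, peak-flow detection, and crop/alignment.
##
## Localization follows the temporal-variance heuristic: the per-pixel
## standard deviation of the MAG channel over time is largest inside the
## aortic flow region, and the frame of maximal spatial standard deviation is
## the frame of peak flow. Crops are exact pixel copies (no interpolation).

#' Per-pixel temporal standard deviation of the MAG channel
#'
#' @param seq A `frame_sequence` (needs >= 2 frames).
#' @return Object of class `variation_map`: list with `values`
#'   (height x width matrix, >= 0) and `source_id`.
#' @export
pixel_variation_map <- function(seq) {
  d <- dim(seq$frames)
  if (d[1] < 2) stop("need at least 2 frames to compute temporal variation",
                     call. = FALSE)
  mag <- matrix(seq$frames[, , , 1], nrow = d[1])  # frames x pixels
  n <- d[1]
  mu <- colMeans(mag)
  v <- (colSums(mag^2) - n * mu^2) / (n - 1)
  values <- matrix(sqrt(pmax(v, 0)), d[2], d[3])
  structure(list(values = values, source_id = seq$patient_id),
            class = "variation_map")
}

#' Localize the aorta as the window of maximal total variation
#'
#' Exhaustive search (via summed-area table, equivalent to sliding every
#' window position) for the `size` x `size` window maximizing the sum of the
#' variation map. Ties are broken by the smallest (top, left) position in
#' lexicographic order.
#'
#' @param varmap A [pixel_variation_map()] result, or a plain matrix.
#' @param size Window edge in pixels (default 32).
#' @return Object of class `crop_window`: list with 0-based inclusive `top`,
#'   `left`, and `size`.
#' @export
localize_aorta <- function(varmap, size = 32) {
  vals <- if (inherits(varmap, "variation_map")) varmap$values else varmap
  nr <- nrow(vals); nc <- ncol(vals)
  if (size > nr || size > nc) stop("crop size exceeds frame dimensions",
                                   call. = FALSE)
  ## summed-area table with zero padding
  S <- matrix(0, nr + 1, nc + 1)
  cs <- apply(vals, 2, cumsum)          # cumulative over rows
  S[-1, -1] <- t(apply(cs, 1, cumsum))  # then over cols
  tops <- seq_len(nr - size + 1)
  lefts <- seq_len(nc - size + 1)
  W <- S[tops + size, lefts + size, drop = FALSE] -
    S[tops, lefts + size, drop = FALSE] -
    S[tops + size, lefts, drop = FALSE] + S[tops, lefts, drop = FALSE]
  best <- which(W >= max(W) - 1e-12)
  r <- (best - 1) %% nrow(W) + 1
  c <- (best - 1) %/% nrow(W) + 1
  pick <- order(r, c)[1]
  structure(list(top = as.integer(r[pick] - 1L),
                 left = as.integer(c[pick] - 1L),
                 size = as.integer(size)),
            class = "crop_window")
}

#' Find the frame of peak blood flow
#'
#' Returns the 0-based index of the frame whose MAG-channel spatial standard
#' deviation is maximal; ties go to the lowest index.
#'
#' @param seq A `frame_sequence`.
#' @return Integer 0-based frame index.
#' @export
find_peak_frame <- function(seq) {
  d <- dim(seq$frames)
  mag <- matrix(seq$frames[, , , 1], nrow = d[1])
  np <- ncol(mag)
  mu <- rowMeans(mag)
  v <- (rowSums(mag^2) - np * mu^2) / (np - 1)
  as.integer(which.max(v) - 1L)
}

#' Crop all channels and align to the peak frame
#'
#' Keeps frames `[peak - half_width, peak + half_width]` intersected with the
#' valid range (boundary clipping, no padding) and crops every channel to the
#' given window. Pixel values are copied exactly.
#'
#' @param seq A `frame_sequence`.
#' @param crop A [localize_aorta()] `crop_window`.
#' @param peak 0-based peak frame index.
#' @param half_width Frames kept on each side of the peak (default 7, i.e., a
#'   15-frame subsequence away from sequence boundaries).
#' @return Object of class `aligned_sequence`: list with `frames`
#'   (`window_len x size x size x channels`), `frame_indices` (0-based
#'   original indices), `peak_frame_original`, `crop`, `patient_id`, `sex`,
#'   and `truth` carried over.
#' @export
crop_and_align <- function(seq, crop, peak, half_width = 7) {
  d <- dim(seq$frames)
  if (crop$top < 0 || crop$left < 0 ||
      crop$top + crop$size > d[2] || crop$left + crop$size > d[3]) {
    stop("crop window outside frame bounds", call. = FALSE)
  }
  if (peak < 0 || peak >= d[1]) stop("invalid peak frame", call. = FALSE)
  idx0 <- max(0L, peak - half_width):min(d[1] - 1L, peak + half_width)
  rows <- (crop$top + 1L):(crop$top + crop$size)
  cols <- (crop$left + 1L):(crop$left + crop$size)
  frames <- seq$frames[idx0 + 1L, rows, cols, , drop = FALSE]
  structure(list(frames = frames,
                 frame_indices = as.integer(idx0),
                 peak_frame_original = as.integer(peak),
                 crop = crop,
                 patient_id = seq$patient_id,
                 sex = seq$sex,
                 truth = seq$truth),
            class = "aligned_sequence")
}

#' Preprocess one sequence end to end
#'
#' Variation map, localization, peak detection, crop and alignment in one
#' call.
#'
#' @inheritParams crop_and_align
#' @param crop_size Crop edge in pixels.
#' @return An `aligned_sequence`.
#' @export
preprocess_sequence <- function(seq, crop_size = 32, half_width = 7) {
  vm <- pixel_variation_map(seq)
  cw <- localize_aorta(vm, size = crop_size)
  pk <- find_peak_frame(seq)
  crop_and_align(seq, cw, pk, half_width = half_width)
}

#' Render and preprocess a cohort one patient at a time
#'
#' Streams [render_patient()] through [preprocess_sequence()] so that only
#' the aligned crops (not the full-resolution stacks) are retained.
#'
#' @param specs A [sample_cohort_specs()] table.
#' @param crop_size,half_width Passed to [preprocess_sequence()].
#' @param channels Channel names to retain in the aligned output (default
#'   all three; `"MAG"` keeps memory low for large cohorts).
#' @return List of `aligned_sequence` objects, named by patient id.
#' @export
preprocess_cohort <- function(specs, crop_size = 32, half_width = 7,
                              channels = c("MAG", "CINE", "VENC")) {
  keep <- match(channels, c("MAG", "CINE", "VENC"))
  if (anyNA(keep)) stop("unknown channel name", call. = FALSE)
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    seq_i <- render_patient(specs, i)
    al <- preprocess_sequence(seq_i, crop_size = crop_size,
                              half_width = half_width)
    al$frames <- al$frames[, , , keep, drop = FALSE]
    al$channel_names <- c("MAG", "CINE", "VENC")[keep]
    out[[i]] <- al
  }
  names(out) <- specs$patient_id
  out
}

#' @export
print.aligned_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<aligned_sequence> %s: %d frames %dx%d, peak %d, crop (%d, %d) size %d\n",
    x$patient_id, d[1], d[2], d[3], x$peak_frame_original,
    x$crop$top, x$crop$left, x$crop$size))
  invisible(x)
}
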