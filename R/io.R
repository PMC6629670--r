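## Cohort and aligned-sequence I/O: multi-page TIFF stacks plus plain-text
## sidecars (CSV manifest, JSON crop/peak metadata).

#' Write a cohort as multi-page TIFFs plus a manifest
#'
#' One TIFF per patient per channel (pages = frames) and `manifest.csv`
#' with patient_id, sex, truth, peak_frame, center_row, center_col.
#'
#' @param cohort List of `frame_sequence`, or a [sample_cohort_specs()]
#'   table (rendered one patient at a time).
#' @param dir Output directory (created if missing).
#' @param bits `"float"` (32-bit float TIFF) or `"12bit"` (intensities
#'   quantized to 4096 levels in 16-bit storage).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, bits = c("float", "12bit")) {
  bits <- match.arg(bits)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_specs <- inherits(cohort, "cohort_spec")
  n <- if (is_specs) nrow(cohort) else length(cohort)
  manifest <- if (is_specs) cohort_manifest(cohort) else
    attr(cohort, "manifest")
  for (i in seq_len(n)) {
    s <- if (is_specs) render_patient(cohort, i) else cohort[[i]]
    for (ch in seq_along(s$channel_names)) {
      pages <- lapply(seq_len(dim(s$frames)[1]), function(t) {
        fr <- s$frames[t, , , ch]
        if (bits == "12bit") fr <- round(fr * 4095) / 4095
        fr
      })
      path <- file.path(dir, sprintf("%s_%s.tiff", s$patient_id,
                                     s$channel_names[ch]))
      if (bits == "float") {
        tiff::writeTIFF(pages, path, bits.per.sample = 32)
      } else {
        tiff::writeTIFF(pages, path, bits.per.sample = 16)
      }
    }
  }
  if (is.null(manifest)) {
    manifest <- data.frame(
      patient_id = vapply(seq_len(n), function(i) {
        if (is_specs) cohort$patient_id[i] else cohort[[i]]$patient_id
      }, ""))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List of `frame_sequence` with a `manifest` attribute.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  channels <- c("MAG", "CINE", "VENC")
  cohort <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$patient_id[i]
    stacks <- lapply(channels, function(ch) {
      path <- file.path(dir, sprintf("%s_%s.tiff", id, ch))
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      pages
    })
    nt <- length(stacks[[1]])
    nr <- nrow(stacks[[1]][[1]]); nc <- ncol(stacks[[1]][[1]])
    frames <- array(0, c(nt, nr, nc, 3))
    for (ch in 1:3) {
      for (t in seq_len(nt)) frames[t, , , ch] <- stacks[[ch]][[t]]
    }
    truth <- NULL
    if (all(c("truth", "peak_frame", "center_row", "center_col") %in%
            names(manifest))) {
      truth <- list(class_label = manifest$truth[i],
                    center = c(manifest$center_row[i],
                               manifest$center_col[i]),
                    peak_frame = manifest$peak_frame[i])
    }
    structure(list(patient_id = id, frames = frames,
                   channel_names = channels,
                   sex = if ("sex" %in% names(manifest)) manifest$sex[i]
                         else "unknown",
                   truth = truth),
              class = "frame_sequence")
  })
  attr(cohort, "manifest") <- manifest
  cohort
}

#' Write an aligned sequence as TIFF + JSON sidecar
#'
#' @param aligned An `aligned_sequence`.
#' @param dir Output directory.
#' @return The TIFF path, invisibly.
#' @export
write_aligned <- function(aligned, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nch <- dim(aligned$frames)[4]
  chn <- aligned$channel_names %||% c("MAG", "CINE", "VENC")[seq_len(nch)]
  for (ch in seq_len(nch)) {
    pages <- lapply(seq_len(dim(aligned$frames)[1]),
                    function(t) aligned$frames[t, , , ch])
    tiff::writeTIFF(pages, file.path(dir, sprintf("%s_%s.tiff",
                                                  aligned$patient_id,
                                                  chn[ch])),
                    bits.per.sample = 32)
  }
  side <- list(patient_id = aligned$patient_id,
               peak_frame_original = aligned$peak_frame_original,
               frame_indices = aligned$frame_indices,
               crop = aligned$crop[c("top", "left", "size")],
               sex = aligned$sex)
  jsonlite::write_json(side,
                       file.path(dir, sprintf("%s.json", aligned$patient_id)),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, sprintf("%s_%s.tiff", aligned$patient_id,
                                   chn[1])))
}
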