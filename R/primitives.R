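## Otsu-mask shape/intensity primitives.
##
## Five per-frame features are computed from an Otsu-binarized MAG frame
## restricted to its largest 8-connected component: area, perimeter,
## eccentricity, mean intensity, and area/perimeter^2. Degenerate inputs
## (constant frames, empty masks, zero perimeters) propagate `defined = FALSE`
## flags instead of errors, and all downstream labeling functions abstain on
## undefined primitives.

#' Otsu-binarize a grayscale frame
#'
#' Thresholds the intensity histogram with Otsu's method; pixels strictly
#' above the threshold are foreground. A constant frame has no valid
#' threshold and yields an empty mask (with an attribute `defined = FALSE`)
#' rather than an error.
#'
#' @param frame Numeric matrix with values in [0, 1].
#' @return Integer 0/1 matrix with attributes `threshold` and `defined`.
#' @export
binarize <- function(frame) {
  if (!is.matrix(frame) || length(frame) == 0) {
    stop("`frame` must be a non-empty matrix", call. = FALSE)
  }
  rng <- range(frame)
  if (!all(is.finite(rng)) || diff(rng) < 1e-12) {
    mask <- matrix(0L, nrow(frame), ncol(frame))
    attr(mask, "threshold") <- NA_real_
    attr(mask, "defined") <- FALSE
    return(mask)
  }
  th <- EBImage::otsu(EBImage::as.Image(frame), range = c(0, 1))
  mask <- matrix(as.integer(frame > th), nrow(frame), ncol(frame))
  attr(mask, "threshold") <- as.numeric(th)
  attr(mask, "defined") <- TRUE
  mask
}

#' Keep only the largest 8-connected component
#'
#' Components are labeled with 8-connectivity (4-connected labels merged
#' across diagonal adjacencies). Ties in size are broken by the component
#' containing the smallest (row, col) pixel in row-major scan order. Empty
#' masks pass through unchanged.
#'
#' @param mask Binary matrix.
#' @return Binary integer matrix with only the winning component.
#' @export
largest_component <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(m)
  lab <- EBImage::bwlabel(m)            # 4-connected labels
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(m); nc <- ncol(m)
  if (nlab > 1L && nr > 1L && nc > 1L) {
    ## merge labels touching diagonally (both diagonal directions)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      for (i in seq_len(nrow(pairs))) union2(pairs[i, 1], pairs[i, 2])
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  lab8 <- matrix(0L, nr, nc)
  lab8[lab > 0] <- roots[lab[lab > 0]]
  sizes <- tabulate(lab8[lab8 > 0], nbins = nlab)
  winners <- which(sizes == max(sizes))
  if (length(winners) > 1L) {
    ## row-major scan order: first touched pixel decides
    rm_index <- function(l) {
      px <- which(lab8 == l, arr.ind = TRUE)
      min((px[, 1] - 1) * nc + (px[, 2] - 1))
    }
    winners <- winners[order(vapply(winners, rm_index, numeric(1)))][1]
  }
  matrix(as.integer(lab8 == winners[1]), nr, nc)
}

## Perimeter: boundary contour chain length with diagonal steps weighted
## sqrt(2). Sums over all contours present in the mask.
mask_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask))
  if (length(oc) == 0) return(0)
  total <- 0
  for (p in oc) {
    if (nrow(p) < 2) next
    d <- rbind(diff(p), p[1, , drop = FALSE] - p[nrow(p), , drop = FALSE])
    total <- total + sum(sqrt(rowSums(d^2)))
  }
  total
}

## Eccentricity of the ellipse with matching normalized second central
## moments; the 1/12 term is the moment of a unit pixel, which keeps thin
## components strictly below 1.
mask_eccentricity <- function(mask) {
  px <- which(mask != 0, arr.ind = TRUE)
  r <- px[, 1]; c <- px[, 2]
  mu20 <- mean((r - mean(r))^2) + 1 / 12
  mu02 <- mean((c - mean(c))^2) + 1 / 12
  mu11 <- mean((r - mean(r)) * (c - mean(c)))
  t1 <- (mu20 + mu02) / 2
  t2 <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- t1 + t2; l2 <- t1 - t2
  if (l1 <= 0) return(0)
  sqrt(clamp(1 - l2 / l1, 0, 1 - 1e-12))
}

#' Shape and intensity primitives of a binary mask
#'
#' @param mask Binary matrix (ideally a single component from
#'   [largest_component()]).
#' @param frame The un-normalized grayscale frame the mask was derived from
#'   (same shape); mean intensity is taken over mask pixels.
#' @return A one-row data.frame with columns `area`, `perimeter`,
#'   `eccentricity`, `intensity`, `ratio` and logical `defined_*` flags.
#'   Empty masks have all flags `FALSE`; a zero perimeter leaves only
#'   `ratio` undefined.
#' @export
shape_stats <- function(mask, frame) {
  if (!all(dim(mask) == dim(frame))) {
    stop("mask and frame must have the same shape", call. = FALSE)
  }
  area <- sum(mask != 0)
  if (area == 0) {
    return(data.frame(area = 0, perimeter = NA_real_,
                      eccentricity = NA_real_, intensity = NA_real_,
                      ratio = NA_real_,
                      defined_area = FALSE, defined_perimeter = FALSE,
                      defined_eccentricity = FALSE, defined_intensity = FALSE,
                      defined_ratio = FALSE))
  }
  per <- mask_perimeter(mask)
  ecc <- mask_eccentricity(mask)
  intens <- mean(frame[mask != 0])
  ratio <- if (per > 0) area / per^2 else NA_real_
  data.frame(area = area, perimeter = per, eccentricity = ecc,
             intensity = intens, ratio = ratio,
             defined_area = TRUE, defined_perimeter = TRUE,
             defined_eccentricity = TRUE, defined_intensity = TRUE,
             defined_ratio = per > 0)
}

PRIMITIVE_NAMES <- c("area", "perimeter", "eccentricity", "intensity", "ratio")

#' Per-frame primitive table for aligned sequences
#'
#' Binarizes each MAG frame, keeps the largest 8-connected component, and
#' computes [shape_stats()].
#'
#' @param aligned One `aligned_sequence` or a list of them.
#' @return data.frame with `patient_id`, `sex`, `frame_index` (0-based,
#'   original indices), the five primitives, and `defined_*` flags.
#' @export
compute_primitives <- function(aligned) {
  if (inherits(aligned, "aligned_sequence")) aligned <- list(aligned)
  out <- vector("list", length(aligned))
  for (i in seq_along(aligned)) {
    a <- aligned[[i]]
    nt <- dim(a$frames)[1]
    recs <- vector("list", nt)
    for (t in seq_len(nt)) {
      fr <- a$frames[t, , , 1]
      mk <- largest_component(binarize(fr))
      recs[[t]] <- shape_stats(mk, fr)
    }
    tab <- do.call(rbind, recs)
    tab <- cbind(data.frame(patient_id = a$patient_id,
                            sex = a$sex %||% "unknown",
                            frame_index = a$frame_indices,
                            stringsAsFactors = FALSE),
                 tab)
    out[[i]] <- tab
  }
  do.call(rbind, out)
}

#' Sex-stratified normalization of primitives
#'
#' Divides each defined primitive by the mean of that primitive within the
#' patient's sex stratum (computed over the defined entries of the unlabeled
#' cohort when `population_means` is not supplied). Patients of unknown sex
#' are normalized by the pooled overall mean.
#'
#' @param records A [compute_primitives()] table (must contain a `sex`
#'   column).
#' @param population_means Optional list with elements `F`, `M`, `pooled`,
#'   each a named numeric vector of per-primitive means.
#' @return The table with primitives rescaled; the means used are attached
#'   as attribute `population_means`.
#' @export
normalize_primitives <- function(records, population_means = NULL) {
  if (is.null(population_means)) {
    mean_of <- function(rows) {
      vapply(PRIMITIVE_NAMES, function(p) {
        ok <- rows[[paste0("defined_", p)]]
        mean(rows[[p]][ok])
      }, numeric(1))
    }
    population_means <- list(
      F = mean_of(records[records$sex == "F", , drop = FALSE]),
      M = mean_of(records[records$sex == "M", , drop = FALSE]),
      pooled = mean_of(records)
    )
  }
  for (stratum in c("F", "M", "pooled")) {
    mu <- population_means[[stratum]]
    if (is.null(mu)) next
    rows <- if (stratum == "pooled") {
      !(records$sex %in% c("F", "M"))
    } else {
      records$sex == stratum
    }
    if (!any(rows)) next
    for (p in PRIMITIVE_NAMES) {
      if (!is.finite(mu[[p]]) || mu[[p]] <= 0) {
        stop(sprintf("population mean for %s (%s) must be positive",
                     p, stratum), call. = FALSE)
      }
      records[[p]][rows] <- records[[p]][rows] / mu[[p]]
    }
  }
  attr(records, "population_means") <- population_means
  records
}
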