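## Data augmentation: label-invariant affine transforms of aligned
## sequences. One transform is drawn per sequence and applied identically to
## every frame and channel, so the class label never changes.

#' Augmentation configuration
#'
#' @param translate Maximum absolute shift in pixels (rows and cols).
#' @param rotate Maximum absolute rotation in degrees.
#' @param scale Range of isotropic scale factors.
#' @return List of class `augment_config`.
#' @export
augment_config <- function(translate = 2, rotate = 10, scale = c(0.9, 1.1)) {
  structure(list(translate = translate, rotate = rotate, scale = scale),
            class = "augment_config")
}

## Precompute the bilinear sampling map for one affine transform; the map
## is shared by every frame and channel of a sequence.
warp_map <- function(n, shift, angle_rad, scale_f) {
  c0 <- (n + 1) / 2
  out_r <- matrix(seq_len(n), n, n)
  out_c <- matrix(seq_len(n), n, n, byrow = TRUE)
  ## inverse map: rotate by -angle, scale by 1/s, then undo the shift
  dr <- out_r - c0 - shift[1]
  dc <- out_c - c0 - shift[2]
  sr <- (cos(-angle_rad) * dr - sin(-angle_rad) * dc) / scale_f + c0
  sc <- (sin(-angle_rad) * dr + cos(-angle_rad) * dc) / scale_f + c0
  r0 <- as.vector(floor(sr)); c0i <- as.vector(floor(sc))
  fr <- as.vector(sr) - r0; fc <- as.vector(sc) - c0i
  lin <- function(rr, cc) {
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
    idx <- (cc - 1) * n + rr
    idx[!ok] <- n * n + 1       # out-of-frame sentinel (reads the padded 0)
    idx
  }
  list(n = n,
       i00 = lin(r0, c0i), i01 = lin(r0, c0i + 1),
       i10 = lin(r0 + 1, c0i), i11 = lin(r0 + 1, c0i + 1),
       w00 = (1 - fr) * (1 - fc), w01 = (1 - fr) * fc,
       w10 = fr * (1 - fc), w11 = fr * fc)
}

warp_apply <- function(img, map) {
  v <- c(as.vector(img), 0)     # padded 0 for out-of-frame reads
  matrix(map$w00 * v[map$i00] + map$w01 * v[map$i01] +
           map$w10 * v[map$i10] + map$w11 * v[map$i11], map$n, map$n)
}

## Integer translation without interpolation (exact pixel copy).
shift_frame <- function(img, shift) {
  n <- nrow(img)
  out <- matrix(0, n, n)
  src_r <- (1:n) - shift[1]
  src_c <- (1:n) - shift[2]
  ok_r <- src_r >= 1 & src_r <= n
  ok_c <- src_c >= 1 & src_c <= n
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Augment an aligned sequence with one random affine transform
#'
#' Draws a translation, rotation, and scale within the configured ranges and
#' applies the same transform to every frame and channel. Pure integer
#' translations are exact pixel copies; rotations/scales use bilinear
#' interpolation. A transform that pushes essentially all content outside
#' the frame (MAG mass below 10% of the original) is rejected and
#' resampled.
#'
#' @param seq An `aligned_sequence`.
#' @param config An [augment_config()]; the identity config
#'   (`translate = 0, rotate = 0, scale = c(1, 1)`) returns the input
#'   unchanged.
#' @param seed Integer seed.
#' @param max_tries Resampling attempts before erroring.
#' @return The augmented `aligned_sequence` (same dimensions).
#' @export
augment <- function(seq, config = augment_config(), seed = 1L,
                    max_tries = 10L) {
  d <- dim(seq$frames)
  ref_mass <- sum(seq$frames[, , , 1])
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      shift <- round(stats::runif(2, -config$translate, config$translate))
      ang <- stats::runif(1, -config$rotate, config$rotate) * pi / 180
      sc <- stats::runif(1, config$scale[1], config$scale[2])
      identity_tf <- all(shift == 0) && ang == 0 && sc == 1
      pure_shift <- ang == 0 && sc == 1
      out <- seq
      if (identity_tf) return(out)
      map <- if (!pure_shift) warp_map(dim(seq$frames)[2], shift, ang, sc)
      for (t in seq_len(d[1])) {
        for (ch in seq_len(d[4])) {
          img <- seq$frames[t, , , ch]
          out$frames[t, , , ch] <- if (pure_shift) shift_frame(img, shift)
                                   else warp_apply(img, map)
        }
      }
      if (sum(out$frames[, , , 1]) >= 0.1 * ref_mass) {
        attr(out, "transform") <- list(shift = shift, angle = ang,
                                       scale = sc)
        return(out)
      }
    }
    stop("could not draw a content-preserving transform", call. = FALSE)
  })
}
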