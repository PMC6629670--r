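## Synthetic phase-contrast-like MRI phantoms.
##
## The generator emulates the statistical structure the downstream pipeline
## assumes: a bright quasi-elliptical flow region (the aortic valve seen en
## face) whose intensity peaks at one frame of the cardiac cycle, a
## low-variance background, a time-constant anatomical (CINE-like) channel,
## and a signed-flow (VENC-like) channel. BAV-class phantoms receive more
## eccentric, more irregular flow regions than TAV-class phantoms.
##
## Conventions: pixel coordinates and frame indices are 0-based everywhere in
## the public interface; intensities are floating point in [0, 1] (a 12-bit
## quantized export is available at the I/O layer).

#' Specification of one synthetic phase-contrast MRI sequence
#'
#' @param class_label `"BAV"` or `"TAV"`; controls nothing directly in
#'   [render_sequence()] (shape is set by `eccentricity_target` and
#'   `irregularity`) but is recorded as ground truth.
#' @param center Numeric length-2, planted flow-region center as
#'   (row, col) in 0-based pixel coordinates.
#' @param base_radius Flow-region radius in pixels; the rendered ellipse has
#'   the same area as a circle of this radius.
#' @param eccentricity_target Ellipse eccentricity in [0, 1) planted for the
#'   flow region (0 = circle).
#' @param irregularity Amplitude (>= 0, relative units) of the low-order
#'   angular boundary perturbation; BAV-like regions use larger values.
#' @param peak_frame 0-based index of the frame of peak flow.
#' @param flow_amplitude Peak flow intensity above background, in [0, 1]
#'   intensity units.
#' @param noise_sd Standard deviation of background pixel noise.
#' @param n_frames Number of frames (default 30, matching raw acquisitions).
#' @param frame_size Square frame edge in pixels (default 192).
#' @param sex `"F"` or `"M"`; recorded for sex-stratified normalization.
#' @param flow_width Half-width (frames) of the raised-cosine temporal flow
#'   profile.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label = "TAV",
                         center = NULL,
                         base_radius = 12,
                         eccentricity_target = 0.40,
                         irregularity = 0.10,
                         peak_frame = 9,
                         flow_amplitude = 0.78,
                         noise_sd = 0.05,
                         n_frames = 30,
                         frame_size = 192,
                         sex = "F",
                         flow_width = 8) {
  if (is.null(center)) center <- c(frame_size, frame_size) / 2
  spec <- structure(list(
    class_label = match.arg(class_label, c("TAV", "BAV")),
    center = as.numeric(center),
    base_radius = as.numeric(base_radius),
    eccentricity_target = as.numeric(eccentricity_target),
    irregularity = as.numeric(irregularity),
    peak_frame = as.integer(peak_frame),
    flow_amplitude = as.numeric(flow_amplitude),
    noise_sd = as.numeric(noise_sd),
    n_frames = as.integer(n_frames),
    frame_size = as.integer(frame_size),
    sex = match.arg(sex, c("F", "M")),
    flow_width = as.numeric(flow_width)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (eccentricity_target < 0 || eccentricity_target >= 1)
      stop("eccentricity_target must lie in [0, 1)", call. = FALSE)
    if (peak_frame < 0 || peak_frame >= n_frames)
      stop("peak_frame must satisfy 0 <= peak_frame < n_frames", call. = FALSE)
    if (base_radius >= frame_size / 2)
      stop("base_radius must be smaller than frame_size / 2", call. = FALSE)
    if (irregularity < 0) stop("irregularity must be >= 0", call. = FALSE)
    if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
    if (flow_amplitude < 0) stop("flow_amplitude must be >= 0", call. = FALSE)
    if (n_frames < 1 || frame_size < 8)
      stop("n_frames >= 1 and frame_size >= 8 required", call. = FALSE)
  })
  invisible(spec)
}

## Raised-cosine temporal bump, maximal (=1) at `peak`, support peak +/- width.
flow_profile <- function(n_frames, peak, width) {
  t <- seq_len(n_frames) - 1
  p <- 0.5 * (1 + cos(pi * (t - peak) / width))
  p[abs(t - peak) > width] <- 0
  p
}

## Soft membership [0,1] of a perturbed ellipse on the pixel grid.
## fourier: list(k, a, phi) of boundary-perturbation harmonics.
region_profile <- function(frame_size, center, base_radius, ecc, orientation,
                           fourier, edge = 0.12) {
  n <- frame_size
  stretch <- (1 - ecc^2)^0.25        # a = r/stretch, b = r*stretch: ab = r^2
  a <- base_radius / stretch
  b <- base_radius * stretch
  rows <- matrix(seq_len(n) - 1, n, n)          # 0-based coordinates
  cols <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  dx <- rows - center[1]
  dy <- cols - center[2]
  u <- (dx * cos(orientation) + dy * sin(orientation)) / a
  v <- (-dx * sin(orientation) + dy * cos(orientation)) / b
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  boundary <- 1
  if (length(fourier$k)) {
    pert <- 0
    for (i in seq_along(fourier$k)) {
      pert <- pert + fourier$a[i] * cos(fourier$k[i] * theta + fourier$phi[i])
    }
    boundary <- pmax(0.2, 1 + pert)
  }
  ## edge width measured in units of the local boundary radius
  clamp((boundary - rho) / (edge * boundary) + 0.5, 0, 1)
}

#' Render one synthetic phase-contrast MRI sequence
#'
#' Produces a three-channel frame stack. The MAG channel carries a bright
#' quasi-elliptical flow region at `spec$center` whose intensity follows a
#' raised-cosine temporal profile maximal at `spec$peak_frame` over a
#' noisy background; the CINE channel is time-constant anatomy; the VENC
#' channel is a signed-flow-like transform of MAG (sign flipped inside a
#' random sub-region, re-centered on mid-gray).
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; identical (`spec`, `seed`) pairs render
#'   identical arrays.
#' @return An object of class `frame_sequence`: list with `patient_id`,
#'   `frames` (array `n_frames x size x size x 3`), `channel_names`
#'   (`MAG`, `CINE`, `VENC`), `sex`, and `truth` (class, planted center,
#'   planted peak frame).
#' @export
render_sequence <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  n <- spec$frame_size
  nt <- spec$n_frames
  with_seed(seed, {
    ## boundary perturbation: harmonics k = 2..4, total amplitude
    ## = spec$irregularity
    k <- 2:4
    w <- abs(stats::rnorm(3)) + 0.1
    fourier <- list(k = k,
                    a = spec$irregularity * w / sum(w),
                    phi = stats::runif(3, 0, 2 * pi))
    orientation <- stats::runif(1, 0, 2 * pi)
    S <- region_profile(n, spec$center, spec$base_radius,
                        spec$eccentricity_target, orientation, fourier)
    prof <- flow_profile(nt, spec$peak_frame, spec$flow_width)

    frames <- array(0, dim = c(nt, n, n, 3))
    bg_level <- 0.08
    inside <- which(S > 0)
    mag <- render_mag_cpp(as.vector(S), inside, prof, spec$flow_amplitude,
                          spec$noise_sd, bg_level)
    frames[, , , 1] <- t(mag)

    ## CINE: time-constant anatomy (vessel wall + smooth blobs + frozen noise)
    blobs <- matrix(0, n, n)
    rows <- matrix(seq_len(n) - 1, n, n)
    cols <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
    for (b in seq_len(3)) {
      bc <- stats::runif(2, 0.15 * n, 0.85 * n)
      br <- stats::runif(1, 0.08 * n, 0.2 * n)
      blobs <- blobs + stats::runif(1, 0.1, 0.3) *
        exp(-((rows - bc[1])^2 + (cols - bc[2])^2) / (2 * br^2))
    }
    cine <- clamp(0.15 + 0.35 * S + blobs +
                    matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n), 0, 1)
    frames[, , , 2] <- rep(as.vector(cine), each = nt)

    ## VENC: MAG re-centered on mid-gray with sign flipped in a random
    ## half-plane (low-stakes channel; only MAG feeds the pipeline defaults)
    ang <- stats::runif(1, 0, 2 * pi)
    sgn <- ifelse((rows - spec$center[1]) * cos(ang) +
                    (cols - spec$center[2]) * sin(ang) > 0, -1, 1)
    for (t in seq_len(nt)) {
      frames[t, , , 3] <- clamp(0.5 + 0.5 * sgn * (frames[t, , , 1] - bg_level),
                                0, 1)
    }

    structure(list(
      patient_id = sprintf("phantom_%08d", seed %% 1e8),
      frames = frames,
      channel_names = c("MAG", "CINE", "VENC"),
      sex = spec$sex,
      truth = list(class_label = spec$class_label,
                   center = spec$center,
                   peak_frame = spec$peak_frame)
    ), class = "frame_sequence")
  })
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %s: %d frames of %dx%d, channels %s, sex %s\n",
              x$patient_id, d[1], d[2], d[3],
              paste(x$channel_names, collapse = "/"), x$sex))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: %s, center (%g, %g), peak frame %d\n",
                x$truth$class_label, x$truth$center[1], x$truth$center[2],
                x$truth$peak_frame))
  }
  invisible(x)
}

## Class-conditional cohort defaults (frozen study conditions; rationale in
## the methods vignette). BAV flow regions are smaller, more eccentric, more
## irregular, and slightly dimmer than TAV ones, with overlapping
## distributions ("hard but learnable").
cohort_class_params <- function() {
  list(
    TAV = list(ecc = 0.40, ecc_sd = 0.10, irr = 0.10, irr_sd = 0.05,
               radius = 12, amp = 0.78),
    BAV = list(ecc = 0.72, ecc_sd = 0.10, irr = 0.32, irr_sd = 0.06,
               radius = 11.5, amp = 0.70),
    radius_sd = 1.2, amp_sd = 0.06,
    center_jitter = 10, peak_range = c(5L, 14L),
    sex_radius_factor = c(F = 0.93, M = 1.07)
  )
}

#' Draw per-patient cohort parameters without rendering
#'
#' Each patient is independently BAV with probability `prevalence`; shape
#' parameters (eccentricity, irregularity, radius, flow amplitude), the
#' planted center, the peak frame, and sex are jittered around
#' class-conditional defaults. The returned table drives [render_patient()],
#' so cohorts of any size can be rendered one patient at a time (a full
#' 30-frame 192x192 3-channel stack is ~27 MB, which makes materializing
#' thousands of patients at once impractical).
#'
#' @param n Number of patients.
#' @param prevalence Probability of the BAV (positive) class; the study
#'   condition is ~6 BAV per 100.
#' @param base_spec Optional [phantom_spec()] giving shared acquisition
#'   settings (frame size, frame count, noise level, flow width).
#' @param seed Integer seed.
#' @return data.frame of class `cohort_spec` with one row per patient:
#'   identity, truth, sex, all jittered shape parameters, and the render
#'   seed.
#' @export
sample_cohort_specs <- function(n, prevalence = 0.06, base_spec = NULL,
                                seed = 1L) {
  stopifnot(n >= 1)
  stopifnot_prob(prevalence, "prevalence")
  if (is.null(base_spec)) base_spec <- phantom_spec()
  pars <- cohort_class_params()
  draws <- with_seed(seed, {
    list(cls = ifelse(stats::runif(n) < prevalence, "BAV", "TAV"),
         sex = ifelse(stats::runif(n) < 0.5, "F", "M"),
         sub = vapply(seq_len(n), function(i) derive_seed(seed, i),
                      integer(1)))
  })
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cp <- pars[[draws$cls[i]]]
    rows[[i]] <- with_seed(derive_seed(seed, i, salt = 1L), {
      data.frame(
        patient_id = sprintf("P%05d", i),
        truth = draws$cls[i],
        sex = draws$sex[i],
        eccentricity_target = clamp(stats::rnorm(1, cp$ecc, cp$ecc_sd),
                                    0.02, 0.92),
        irregularity = clamp(stats::rnorm(1, cp$irr, cp$irr_sd), 0, 0.6),
        base_radius = clamp(stats::rnorm(1, cp$radius, pars$radius_sd), 7,
                            base_spec$frame_size / 2 - 1) *
          pars$sex_radius_factor[[draws$sex[i]]],
        flow_amplitude = clamp(stats::rnorm(1, cp$amp, pars$amp_sd),
                               0.35, 0.95),
        center_row = base_spec$frame_size / 2 +
          stats::runif(1, -pars$center_jitter, pars$center_jitter),
        center_col = base_spec$frame_size / 2 +
          stats::runif(1, -pars$center_jitter, pars$center_jitter),
        peak_frame = {
          hi <- min(pars$peak_range[2], base_spec$n_frames - 1L)
          lo <- min(pars$peak_range[1], hi)
          sample(seq(lo, hi), 1)
        },
        render_seed = draws$sub[i],
        stringsAsFactors = FALSE
      )
    })
  }
  specs <- do.call(rbind, rows)
  attr(specs, "base_spec") <- base_spec
  class(specs) <- c("cohort_spec", "data.frame")
  specs
}

#' Render one patient from a cohort specification table
#'
#' @param specs A [sample_cohort_specs()] table.
#' @param i Patient row index.
#' @return A `frame_sequence`.
#' @export
render_patient <- function(specs, i) {
  base_spec <- attr(specs, "base_spec")
  row <- specs[i, ]
  sp <- phantom_spec(class_label = row$truth,
                     center = c(row$center_row, row$center_col),
                     base_radius = row$base_radius,
                     eccentricity_target = row$eccentricity_target,
                     irregularity = row$irregularity,
                     peak_frame = row$peak_frame,
                     flow_amplitude = row$flow_amplitude,
                     noise_sd = base_spec$noise_sd,
                     n_frames = base_spec$n_frames,
                     frame_size = base_spec$frame_size,
                     sex = row$sex, flow_width = base_spec$flow_width)
  out <- render_sequence(sp, seed = row$render_seed)
  out$patient_id <- row$patient_id
  out
}

#' Extract the cohort manifest from a specification table
#'
#' @param specs A [sample_cohort_specs()] table.
#' @return data.frame: patient_id, sex, truth, peak_frame, center_row,
#'   center_col.
#' @export
cohort_manifest <- function(specs) {
  data.frame(specs)[, c("patient_id", "sex", "truth", "peak_frame",
                        "center_row", "center_col")]
}

#' Sample and render a full synthetic cohort
#'
#' Materializes every patient of [sample_cohort_specs()]; reproducible and
#' byte-identical under the same (`n`, `prevalence`, `seed`). Intended for
#' small cohorts; stream with [render_patient()] for large `n`.
#'
#' @inheritParams sample_cohort_specs
#' @return List of `frame_sequence` objects with a `manifest` attribute.
#' @export
sample_cohort <- function(n, prevalence = 0.06, base_spec = NULL, seed = 1L) {
  specs <- sample_cohort_specs(n, prevalence, base_spec, seed)
  cohort <- lapply(seq_len(n), function(i) render_patient(specs, i))
  attr(cohort, "manifest") <- cohort_manifest(specs)
  cohort
}

#' Simulation parameters for one synthetic labeling function
#'
#' @param accuracy P(vote = truth | vote != abstain).
#' @param propensity P(vote != abstain).
#' @param polarity `"symmetric"` (votes both classes), `"positive-only"`, or
#'   `"negative-only"` (votes of the excluded sign become abstains, which
#'   lowers the effective propensity).
#' @return Object of class `lf_sim_params`.
#' @export
lf_sim_params <- function(accuracy, propensity = 1,
                          polarity = c("symmetric", "positive-only",
                                       "negative-only")) {
  stopifnot_prob(accuracy, "accuracy")
  stopifnot_prob(propensity, "propensity")
  structure(list(accuracy = accuracy, propensity = propensity,
                 polarity = match.arg(polarity)),
            class = "lf_sim_params")
}

#' Sample a synthetic label matrix under conditional independence
#'
#' Simulates the generative assumption of the label model: each labeling
#' function's vote is conditionally independent given the true label, voting
#' with its propensity and agreeing with the truth with its accuracy.
#'
#' @param m Number of items (frames).
#' @param lf_params List of [lf_sim_params()].
#' @param class_balance P(y = +1).
#' @param seed Integer seed.
#' @return List with `L` (m x n matrix in {-1, 0, 1}, columns named LF1..)
#'   and `truth` (vector in {-1, 1}).
#' @export
sample_label_matrix <- function(m, lf_params, class_balance = 0.5, seed = 1L) {
  stopifnot(m >= 1)
  if (length(lf_params) < 1) stop("need at least one labeling function",
                                  call. = FALSE)
  stopifnot_prob(class_balance, "class_balance")
  with_seed(seed, {
    y <- ifelse(stats::runif(m) < class_balance, 1L, -1L)
    n <- length(lf_params)
    L <- matrix(0L, m, n, dimnames = list(NULL, paste0("LF", seq_len(n))))
    for (j in seq_len(n)) {
      p <- lf_params[[j]]
      votes <- stats::runif(m) < p$propensity
      agree <- stats::runif(m) < p$accuracy
      v <- ifelse(votes, ifelse(agree, y, -y), 0L)
      if (p$polarity == "positive-only") v[v == -1L] <- 0L
      if (p$polarity == "negative-only") v[v == 1L] <- 0L
      L[, j] <- v
    }
    list(L = L, truth = y)
  })
}
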