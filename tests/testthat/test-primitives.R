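test_that("Otsu binarization separates bimodal images and flags constants", {
  disk <- raster_ellipse(32, 8, 8)
  img <- matrix(0.1, 32, 32); img[disk == 1] <- 0.9
  mask <- binarize(img)
  expect_equal(mask, disk, ignore_attr = TRUE)
  expect_true(attr(mask, "defined"))

  const <- binarize(matrix(0.4, 16, 16))
  expect_true(all(const == 0))
  expect_false(attr(const, "defined"))
})

test_that("largest_component keeps one 8-connected blob with tie-breaks", {
  m <- matrix(0L, 20, 20)
  m[5:11, 5:11] <- 1L                     # 49-pixel blob
  m[2, 18] <- 1L; m[18, 2] <- 1L; m[18, 18] <- 1L
  out <- largest_component(m)
  expect_equal(sum(out), 49)
  expect_true(all(out[5:11, 5:11] == 1L))

  expect_true(all(largest_component(matrix(0L, 5, 5)) == 0L))

  ## diagonal pixels are one component under 8-connectivity
  d <- matrix(0L, 6, 6); d[2, 2] <- 1L; d[3, 3] <- 1L; d[4, 4] <- 1L
  expect_equal(sum(largest_component(d)), 3)

  ## equal-size components: first pixel in row-major order wins
  t2 <- matrix(0L, 8, 8); t2[6, 2] <- 1L; t2[2, 6] <- 1L
  out2 <- largest_component(t2)
  expect_equal(which(out2 == 1L, arr.ind = TRUE)[1, ], c(row = 2, col = 6))
})

test_that("shape statistics match closed forms on rasterized shapes", {
  disk <- raster_ellipse(32, 8, 8)
  rec <- shape_stats(disk, disk * 0.9)
  expect_equal(rec$area, sum(disk))
  expect_lt(rec$eccentricity, 0.1)
  expect_lt(abs(rec$ratio - 1 / (4 * pi)) / (1 / (4 * pi)), 0.15)
  expect_equal(rec$intensity, 0.9)

  ell <- raster_ellipse(48, 16, 8)
  rec2 <- shape_stats(ell, ell)
  expect_lt(abs(rec2$eccentricity - sqrt(1 - 8^2 / 16^2)), 0.05)

  rot <- raster_ellipse(48, 16, 8, theta = pi / 5)
  rec3 <- shape_stats(rot, rot)
  expect_lt(abs(rec3$eccentricity - 0.866), 0.05)

  empty <- shape_stats(matrix(0L, 8, 8), matrix(0.5, 8, 8))
  expect_false(any(unlist(empty[grep("defined", names(empty))])))
})

test_that("doubling a disk's radius quadruples area and preserves ratio", {
  small <- raster_ellipse(64, 8, 8)
  big <- raster_ellipse(64, 16, 16)
  rs <- shape_stats(small, small)
  rb <- shape_stats(big, big)
  expect_lt(abs(rb$area / rs$area - 4), 4 * 0.05)
  expect_lt(abs(rb$ratio - rs$ratio) / rs$ratio, 0.10)
})

test_that("ratio respects the isoperimetric bound on random convex masks", {
  set.seed(31)
  worst <- -Inf
  for (i in 1:500) {
    r <- runif(1, 7, 15)   # phantom-scale radii
    e <- runif(1, 0, 0.9)
    st <- (1 - e^2)^0.25
    m <- raster_ellipse(48, r / st, r * st, theta = runif(1, 0, pi))
    rec <- shape_stats(m, m)
    if (isTRUE(rec$defined_ratio)) worst <- max(worst, rec$ratio)
  }
  expect_lte(worst, 1 / (4 * pi) + 0.01)
})

test_that("sex-stratified normalization divides by the right means", {
  tab <- data.frame(
    patient_id = c("a", "a", "b", "c"),
    sex = c("F", "F", "M", "unknown"),
    frame_index = c(0L, 1L, 0L, 0L),
    area = c(100, 200, 300, 150), perimeter = c(40, 50, 60, 45),
    eccentricity = c(0.5, 0.7, 0.6, 0.55), intensity = c(0.8, 0.6, 0.7, 0.7),
    ratio = c(0.06, 0.08, 0.08, 0.07),
    defined_area = TRUE, defined_perimeter = TRUE,
    defined_eccentricity = TRUE, defined_intensity = TRUE,
    defined_ratio = TRUE)
  out <- normalize_primitives(tab)
  mu <- attr(out, "population_means")
  expect_equal(mu$F[["area"]], 150)
  expect_equal(out$area[1:2], c(100, 200) / 150)
  expect_equal(out$area[3], 1)               # M stratum mean is itself
  expect_equal(out$area[4], 150 / mean(c(100, 200, 300, 150)))  # pooled

  ## same raw primitives, different sexes -> different normalized values
  two <- tab[c(1, 3), ]; two$area <- c(120, 120)
  mu2 <- list(F = c(area = 100, perimeter = 40, eccentricity = 0.5,
                    intensity = 0.7, ratio = 0.07),
              M = c(area = 200, perimeter = 50, eccentricity = 0.6,
                    intensity = 0.7, ratio = 0.07))
  out2 <- normalize_primitives(two, population_means = mu2)
  expect_false(out2$area[1] == out2$area[2])

  ## rank order within a stratum is preserved
  expect_equal(order(out$area[1:2]), order(tab$area[1:2]))

  bad <- list(F = c(area = 0, perimeter = 1, eccentricity = 1,
                    intensity = 1, ratio = 1))
  expect_error(normalize_primitives(tab[1, ], population_means = bad),
               "positive")
})

test_that("phantom peak-frame masks overlap the planted region", {
  specs <- mini_cohort()$specs
  base <- attr(specs, "base_spec")
  ious <- numeric(10)
  for (i in 1:10) {
    s <- render_patient(specs, i)
    t_peak <- s$truth$peak_frame + 1
    fr <- s$frames[t_peak, , , 1]
    mask <- largest_component(binarize(fr))
    ## planted region: the same geometry rendered without noise (the RNG
    ## draws for the region shape precede the noise draws, so geometry is
    ## identical under the same seed)
    clean_specs <- specs
    attr(clean_specs, "base_spec") <- phantom_spec(
      noise_sd = 0, frame_size = base$frame_size, n_frames = base$n_frames)
    clean <- render_patient(clean_specs, i)
    planted <- clean$frames[t_peak, , , 1] > 0.3
    inter <- sum(mask & planted); uni <- sum(mask | planted)
    ious[i] <- inter / uni
  }
  expect_true(all(ious >= 0.5))
})
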