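test_that("bank construction converts scales and validates resolution", {
  bank <- build_gabor_bank(c(0.25, 0.5, 1.0), px_per_cm = 100)
  expect_equal(bank$lambda_px, c(25, 50, 100))
  expect_error(build_gabor_bank(c(0.01, 0.02), px_per_cm = 64), "below 2 px")
  expect_error(build_gabor_bank(c(0.5, 0.25)), "strictly increasing")
})

test_that("kernels are DC-free quadrature pairs with rotational structure", {
  for (th in c(0, 45, 90, 135)) {
    k <- gabor_kernel(8, th)
    expect_lt(abs(sum(Re(k))), 1e-6)        # even part zero-mean
    expect_lt(abs(sum(Im(k))), 1e-6)        # odd part antisymmetric
  }
  # rotating the grid by 90 degrees gives the kernel built at theta + 90
  k0 <- gabor_kernel(8, 0)
  k90 <- gabor_kernel(8, 90)
  rot <- t(k0)[, rev(seq_len(ncol(k0)))]    # 90-degree grid rotation
  expect_true(max(Mod(rot - k90)) < 1e-12 || max(Mod(rot - Conj(k90))) < 1e-12)
})

test_that("constant input yields zero energy at every scale and orientation", {
  bank <- profile_bank()
  E <- gabor_energy(matrix(0.7, 30, 40), matrix(TRUE, 30, 40), bank)
  expect_true(all(E < 1e-10))
})

test_that("FFT energy path matches direct spatial convolution", {
  set.seed(5)
  map <- matrix(runif(18 * 20), 18, 20)
  mask <- matrix(FALSE, 18, 20); mask[3:16, 3:18] <- TRUE
  bank <- build_gabor_bank(c(0.03125, 0.0625), px_per_cm = 64)
  expect_equal(gabor_energy(map, mask, bank),
               gabor_energy_direct(map, mask, bank),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sinusoidal gratings peak at their generating scale with V > 0", {
  bank <- profile_bank()
  n <- 128
  mask <- matrix(TRUE, n, n)
  for (s in bank$scales_cm) {
    g <- matrix(sin(2 * pi * outer(rep(1, n), seq_len(n)) / (s * 64)), n, n)
    st <- orientation_stats(gabor_energy(g, mask, bank))
    expect_equal(st$scale_cm[which.max(st$Emean)], s)
    expect_gt(st$V[st$scale_cm == s], 0)     # vertical stripes
  }
})

test_that("isotropic noise has directionality near 1 at well-sampled scales", {
  set.seed(3)
  nz <- matrix(rnorm(256 * 256), 256)
  bank <- build_gabor_bank(c(0.0625, 0.125), px_per_cm = 64)
  st <- orientation_stats(gabor_energy(nz, matrix(TRUE, 256, 256), bank))
  expect_true(all(st$D < 1.1))
  expect_true(all(st$D >= 1))
})

test_that("rotating the image by 90 degrees swaps the orientation energies", {
  img <- generate_specimen(default_spec(9), effect_config(), c(48, 48))
  st <- channel_stack(img)
  bank <- profile_bank()
  E <- gabor_energy(st$Lum, st$mask, bank)
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m)))]
  E2 <- gabor_energy(rot90(st$Lum), rot90(st$mask), bank)
  expect_equal(unname(E[, "0"]), unname(E2[, "90"]), tolerance = 1e-6)
  expect_equal(unname(E[, "90"]), unname(E2[, "0"]), tolerance = 1e-6)
  expect_equal(unname(E[, "45"]), unname(E2[, "135"]), tolerance = 1e-6)
})

test_that("orientation statistics follow their definitions", {
  grid <- matrix(c(1, 1, 1, 1), 1, 4,
                 dimnames = list("0.25", c("0", "45", "90", "135")))
  st <- orientation_stats(grid)
  expect_equal(c(st$Emean, st$V, st$D), c(1, 0, 1))
  grid[1, ] <- c(1, 2, 3, 2)
  st <- orientation_stats(grid)
  expect_equal(c(st$Emean, st$V, st$D), c(2, 2, 1.5))
  grid[1, ] <- 0
  st <- orientation_stats(grid)
  expect_equal(c(st$Emean, st$V, st$D), c(0, 0, 1))
})

test_that("scale summary sums, finds the peak and breaks ties downward", {
  st <- data.frame(scale_cm = c(0.1, 0.2, 0.4),
                   Emean = c(0.1, 0.5, 0.2), V = c(0, 1, 2), D = c(1, 2, 3))
  sm <- scale_summary(st)
  expect_equal(sm$Esum, 0.8)
  expect_equal(sm$max_scale_cm, 0.2)
  expect_equal(sm$E_at_max, 0.5)
  st$Emean <- c(0.5, 0.5, 0.2)
  expect_equal(scale_summary(st)$max_scale_cm, 0.1)   # tie -> smaller scale
  one <- data.frame(scale_cm = 0.3, Emean = 2, V = 1, D = 1.2)
  expect_equal(scale_summary(one)$Dsum, 1.2)
})

test_that("a mask that vanishes under erosion names the offending scale", {
  mask <- matrix(FALSE, 40, 40); mask[16:25, 16:25] <- TRUE
  bank <- build_gabor_bank(c(0.03125, 0.5), px_per_cm = 64)
  expect_error(gabor_energy(matrix(1, 40, 40), mask, bank), "0.5 cm")
})

test_that("feature vectors have the canonical 203-column schema", {
  bank <- full_bank()
  expect_length(feature_schema(bank), 203)
  img <- generate_specimen(default_spec(10), effect_config())
  st <- channel_stack(img)
  fv <- extract_features(st, bank, wing_size(img$mask, img$px_per_cm))
  expect_identical(names(fv), feature_schema(bank))
  expect_false(anyNA(fv))
  fv2 <- extract_features(st, bank, wing_size(img$mask, img$px_per_cm))
  expect_identical(fv, fv2)
})
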