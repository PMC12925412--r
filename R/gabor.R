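# --- small FFT utilities -----------------------------------------------------

# smallest size >= n whose prime factors are all in {2, 3, 5}
next_fast_size <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
    m <- m + 1
  }
}

fft2 <- function(m) stats::fft(m)

# inverse 2D FFT of each slice of an nr x nc x K complex array, in two
# batched mvfft passes (one per dimension) instead of K separate calls
ifft2_batch <- function(a) {
  d <- dim(a)
  if (length(d) == 2L) d <- c(d, 1L)
  nr <- d[1]; nc <- d[2]; K <- d[3]
  m <- stats::mvfft(matrix(a, nr, nc * K), inverse = TRUE)
  a <- aperm(array(m, c(nr, nc, K)), c(2, 1, 3))
  m <- stats::mvfft(matrix(a, nc, nr * K), inverse = TRUE)
  aperm(array(m, c(nc, nr, K)), c(2, 1, 3)) / (nr * nc)
}

# embed kernel (odd-sized, centered) at the origin of a P1 x P2 plane with
# wraparound, so FFT convolution leaves responses aligned with the image
embed_kernel <- function(k, P1, P2) {
  r1 <- (nrow(k) - 1L) / 2L; r2 <- (ncol(k) - 1L) / 2L
  out <- matrix(0 + 0i, P1, P2)
  idx1 <- ((-r1:r1) %% P1) + 1L
  idx2 <- ((-r2:r2) %% P2) + 1L
  out[idx1, idx2] <- k
  out
}

# --- Gabor kernels and bank --------------------------------------------------

#' Complex Gabor kernel
#'
#' Quadrature pair packed as one complex kernel: the real part is the even
#' (cosine) component, DC-corrected so it sums to zero; the imaginary part is
#' the odd (sine) component. `theta_deg` is the orientation of the filter's
#' *stripes* -- bars aligned with `theta_deg` give the maximal response -- so
#' the carrier wave runs along `theta_deg - 90`. The Gaussian envelope is
#' isotropic with `sigma = sigma_factor * lambda` (aspect ratio 1) and the
#' kernel is truncated at `trunc_sigmas` envelope sds.
#'
#' @param lambda_px carrier wavelength in pixels (>= 2).
#' @param theta_deg stripe orientation in degrees (0 = horizontal stripes,
#'   90 = vertical).
#' @param sigma_factor envelope sd as a fraction of the wavelength.
#' @param trunc_sigmas truncation radius in envelope sds.
#' @return Complex matrix of odd size.
#' @export
gabor_kernel <- function(lambda_px, theta_deg, sigma_factor = 0.5,
                         trunc_sigmas = 3) {
  if (lambda_px < 2) stop("wavelength below 2 px is not representable")
  sigma <- sigma_factor * lambda_px
  r <- ceiling(trunc_sigmas * sigma)
  x <- matrix(-r:r, 2 * r + 1, 2 * r + 1, byrow = TRUE)  # column offset
  y <- matrix(-r:r, 2 * r + 1, 2 * r + 1)                # row offset
  phi <- (theta_deg - 90) * pi / 180                     # carrier direction
  u <- x * cos(phi) + y * sin(phi)
  env <- exp(-(x^2 + y^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * u / lambda_px)
  odd <- env * sin(2 * pi * u / lambda_px)
  even <- even - env * (sum(even) / sum(env))            # zero mean
  (even + 1i * odd) / sum(env)
}

#' Build a Gabor filter bank
#'
#' Quadrature Gabor kernels at every combination of spatial scale and stripe
#' orientation. Defaults follow octave spacing from 0.03125 cm up to 1 cm and
#' orientations 0, 45, 90 and 135 degrees. The wavelength of the filter at
#' scale `s` is `s * px_per_cm` pixels; boundary handling later erodes the
#' wing mask by a quarter wavelength per scale.
#'
#' @param scales_cm strictly increasing spatial scales in cm.
#' @param orientations_deg stripe orientations in degrees.
#' @param px_per_cm image scale; the smallest wavelength must be >= 2 px.
#' @param sigma_factor,trunc_sigmas kernel shape, see [gabor_kernel()].
#' @return An object of class `gabor_bank`.
#' @export
build_gabor_bank <- function(scales_cm = c(0.03125, 0.0625, 0.125, 0.25, 0.5, 1.0),
                             orientations_deg = c(0, 45, 90, 135),
                             px_per_cm = 64,
                             sigma_factor = 0.5, trunc_sigmas = 3) {
  if (is.unsorted(scales_cm, strictly = TRUE))
    stop("scales_cm must be strictly increasing")
  lambda <- scales_cm * px_per_cm
  if (min(lambda) < 2)
    stop(sprintf("smallest scale %.5g cm is below 2 px at %.4g px/cm",
                 min(scales_cm), px_per_cm))
  kernels <- lapply(lambda, function(l)
    lapply(orientations_deg, function(th)
      gabor_kernel(l, th, sigma_factor, trunc_sigmas)))
  structure(list(scales_cm = scales_cm,
                 orientations_deg = orientations_deg,
                 px_per_cm = px_per_cm,
                 lambda_px = lambda,
                 erosion_px = ceiling(lambda / 4),
                 radius_px = vapply(kernels, function(ks) (nrow(ks[[1]]) - 1L) %/% 2L,
                                    integer(1)),
                 sigma_factor = sigma_factor, trunc_sigmas = trunc_sigmas,
                 kernels = kernels,
                 cache = new.env(parent = emptyenv())),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("gabor_bank: %d scales (%s cm) x %d orientations (%s deg) at %.4g px/cm\n",
              length(x$scales_cm), paste(signif(x$scales_cm, 4), collapse = ", "),
              length(x$orientations_deg),
              paste(x$orientations_deg, collapse = ", "), x$px_per_cm))
  invisible(x)
}

# FFTs of all bank kernels at padded size P1 x P2, cached on the bank
bank_kernel_ffts <- function(bank, P1, P2) {
  key <- paste0("k", P1, "x", P2)
  if (!is.null(bank$cache[[key]])) return(bank$cache[[key]])
  ns <- length(bank$scales_cm); no <- length(bank$orientations_deg)
  out <- array(0 + 0i, c(P1, P2, ns * no))
  for (s in seq_len(ns)) for (o in seq_len(no))
    out[, , (s - 1L) * no + o] <- fft2(embed_kernel(bank$kernels[[s]][[o]], P1, P2))
  bank$cache[[key]] <- out
  out
}

# disc-kernel FFTs used for mask erosion, cached
bank_disc_ffts <- function(bank, P1, P2) {
  key <- paste0("d", P1, "x", P2)
  if (!is.null(bank$cache[[key]])) return(bank$cache[[key]])
  out <- lapply(bank$erosion_px, function(r) {
    x <- matrix(-r:r, 2 * r + 1, 2 * r + 1, byrow = TRUE)
    y <- matrix(-r:r, 2 * r + 1, 2 * r + 1)
    disc <- (x^2 + y^2 <= r^2) + 0i
    fft2(embed_kernel(disc, P1, P2))
  })
  bank$cache[[key]] <- out
  out
}

padded_dims <- function(nr, nc, bank) {
  r <- max(bank$radius_px)
  c(next_fast_size(nr + 2 * r), next_fast_size(nc + 2 * r))
}

# per-scale eroded masks (quarter-wavelength erosion, exact Euclidean disc)
eroded_masks <- function(mask, bank) {
  nr <- nrow(mask); nc <- ncol(mask)
  P <- padded_dims(nr, nc, bank)
  bg <- matrix(1, P[1], P[2])          # everything outside the image is background
  bg[seq_len(nr), seq_len(nc)] <- 1 - mask
  Fbg <- fft2(bg)
  discs <- bank_disc_ffts(bank, P[1], P[2])
  lapply(seq_along(bank$scales_cm), function(s) {
    ov <- Re(ifft2_batch(array(Fbg * discs[[s]], c(P[1], P[2], 1)))[, , 1])
    mask & (ov[seq_len(nr), seq_len(nc)] < 0.5)
  })
}

# shared driver: complex filter responses for one channel, all scales/orients
gabor_responses <- function(map, mask, bank) {
  nr <- nrow(map); nc <- ncol(map)
  P <- padded_dims(nr, nc, bank)
  mu <- mean(map[mask])
  padded <- matrix(mu, P[1], P[2])
  filled <- map; filled[!mask] <- mu     # suppress silhouette edges
  padded[seq_len(nr), seq_len(nc)] <- filled
  Fimg <- fft2(padded)
  Kf <- bank_kernel_ffts(bank, P[1], P[2])
  resp <- ifft2_batch(Kf * as.vector(Fimg))
  resp[seq_len(nr), seq_len(nc), , drop = FALSE]
}

#' Gabor pattern energy grid
#'
#' Convolves one channel with every quadrature pair of the bank and averages
#' the response magnitude `sqrt(even^2 + odd^2)` over the wing mask eroded by
#' a quarter wavelength at each scale (pixels outside the mask are filled
#' with the in-mask mean before filtering, so the wing silhouette contributes
#' no spurious energy).
#'
#' @param map numeric matrix (one analysis channel).
#' @param mask logical wing mask.
#' @param bank a [build_gabor_bank()].
#' @return Matrix `E` of mean magnitudes, scales x orientations, with
#'   dimnames giving scales in cm and orientations in degrees.
#' @export
gabor_energy <- function(map, mask, bank) {
  stopifnot(inherits(bank, "gabor_bank"))
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("empty mask")
  em <- eroded_masks(mask, bank)
  empty <- !vapply(em, any, logical(1))
  if (any(empty))
    stop(sprintf("mask vanishes after erosion at scale %.5g cm",
                 bank$scales_cm[which(empty)[1]]))
  resp <- gabor_responses(map, mask, bank)
  ns <- length(bank$scales_cm); no <- length(bank$orientations_deg)
  E <- matrix(0, ns, no,
              dimnames = list(scale = signif(bank$scales_cm, 6),
                              orientation = bank$orientations_deg))
  for (s in seq_len(ns)) for (o in seq_len(no))
    E[s, o] <- mean(Mod(resp[, , (s - 1L) * no + o])[em[[s]]])
  E
}

# energy grids for all four channels of a stack, sharing mask erosions
gabor_energy_stack <- function(stack, bank) {
  stopifnot(inherits(stack, "channel_stack"), inherits(bank, "gabor_bank"))
  mask <- stack$mask
  em <- eroded_masks(mask, bank)
  empty <- !vapply(em, any, logical(1))
  if (any(empty))
    stop(sprintf("mask vanishes after erosion at scale %.5g cm",
                 bank$scales_cm[which(empty)[1]]))
  ns <- length(bank$scales_cm); no <- length(bank$orientations_deg)
  out <- lapply(channel_names(), function(ch) {
    resp <- gabor_responses(stack[[ch]], mask, bank)
    E <- matrix(0, ns, no,
                dimnames = list(scale = signif(bank$scales_cm, 6),
                                orientation = bank$orientations_deg))
    for (s in seq_len(ns)) for (o in seq_len(no))
      E[s, o] <- mean(Mod(resp[, , (s - 1L) * no + o])[em[[s]]])
    E
  })
  names(out) <- channel_names()
  out
}

#' Per-scale orientation statistics
#'
#' For each scale of an energy grid: `Emean`, the mean energy across
#' orientations; `V` (verticality), energy at the 90-degree (vertical
#' stripes) orientation minus energy at 0 degrees (horizontal); and `D`
#' (directionality), maximum over mean energy across orientations, defined
#' as 1 when `Emean` is 0 (isotropy limit).
#'
#' @param grid energy matrix from [gabor_energy()] (orientations must
#'   include 0 and 90).
#' @return Data frame with columns `scale_cm`, `Emean`, `V`, `D`.
#' @export
orientation_stats <- function(grid) {
  on <- colnames(grid)
  if (!all(c("0", "90") %in% on))
    stop("energy grid must include 0 and 90 degree orientations")
  Emean <- rowMeans(grid)
  V <- grid[, "90"] - grid[, "0"]
  D <- ifelse(Emean > 0, apply(grid, 1, max) / Emean, 1)
  data.frame(scale_cm = as.numeric(rownames(grid)),
             Emean = Emean, V = V, D = D, row.names = NULL)
}

#' Across-scale summary of the granularity statistics
#'
#' Sums `Emean`, `V` and `D` over scales, and reports the scale with the
#' highest mean energy (`maxEnergy`; ties broken toward the smaller scale)
#' together with the energy, verticality and directionality at that scale.
#'
#' @param stats per-scale data frame from [orientation_stats()].
#' @return Named list: `Esum`, `Vsum`, `Dsum`, `max_scale_cm`, `E_at_max`,
#'   `V_at_max`, `D_at_max`.
#' @export
scale_summary <- function(stats) {
  if (nrow(stats) < 1) stop("need at least one scale")
  i <- which.max(stats$Emean)   # first max = smallest scale on ties
  list(Esum = sum(stats$Emean), Vsum = sum(stats$V), Dsum = sum(stats$D),
       max_scale_cm = stats$scale_cm[i], E_at_max = stats$Emean[i],
       V_at_max = stats$V[i], D_at_max = stats$D[i])
}
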