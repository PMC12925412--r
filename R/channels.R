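#' Cone-catch image
#'
#' Container for one calibrated specimen photograph: a 3-channel stack of
#' modelled photoreceptor quantum catches (longwave, midwave, shortwave;
#' reflectance-scaled, so values lie in (0, 1]), a binary wing mask and the
#' image scale in pixels per centimetre. Masked catches are floored at
#' `1e-6`: the RNL model takes logarithms, so zero is illegal.
#'
#' @param q numeric array `nrow x ncol x 3` of cone catches (L, M, S).
#' @param mask logical or 0/1 matrix of the wing region, same `nrow`/`ncol`.
#' @param px_per_cm positive scalar, pixels per centimetre.
#' @return An object of class `cone_catch_image` with elements `q`, `mask`,
#'   `px_per_cm`.
#' @export
cone_catch_image <- function(q, mask, px_per_cm) {
  if (length(dim(q)) != 3L || dim(q)[3] != 3L)
    stop("`q` must be an nrow x ncol x 3 array of cone catches")
  mask <- as.matrix(mask) > 0
  if (!all(dim(mask) == dim(q)[1:2]))
    stop("mask dimensions do not match the image")
  if (!is.numeric(px_per_cm) || length(px_per_cm) != 1L || px_per_cm <= 0)
    stop("`px_per_cm` must be a positive scalar")
  q <- pmin(pmax(q, 1e-6), 1)
  structure(list(q = q, mask = mask, px_per_cm = px_per_cm),
            class = "cone_catch_image")
}

#' @export
print.cone_catch_image <- function(x, ...) {
  d <- dim(x$q)
  cat(sprintf("cone_catch_image: %d x %d px, %d channels, %.1f px/cm, %d mask px\n",
              d[1], d[2], d[3], x$px_per_cm, sum(x$mask)))
  invisible(x)
}

#' Receptor-noise-limited model parameters
#'
#' Weber fractions (noise-to-signal ratios) for the three receptor channels
#' of the trichromatic RNL model. One unit of the resulting chromatic
#' coordinates corresponds to roughly one just-noticeable difference. The
#' default applies a single Weber fraction of 0.05 to all receptors.
#'
#' @param weber numeric length-1 or length-3 vector of Weber fractions
#'   (L, M, S); all must be > 0.
#' @return An object of class `rnl_params`.
#' @export
rnl_params <- function(weber = 0.05) {
  if (length(weber) == 1L) weber <- rep(weber, 3L)
  if (length(weber) != 3L || any(weber <= 0))
    stop("`weber` must be 1 or 3 positive values")
  structure(list(weber = as.numeric(weber)), class = "rnl_params")
}

#' Luminance channel
#'
#' Averages the longwave and midwave catches (the "X" and "Y" receptors of a
#' chart-calibrated human XYZ camera model) pixelwise.
#'
#' @param img a [cone_catch_image()].
#' @return Numeric matrix `Lum = (q_L + q_M) / 2`.
#' @export
compute_luminance <- function(img) {
  stopifnot(inherits(img, "cone_catch_image"))
  if (any(img$q[, , 1][img$mask] <= 0) || any(img$q[, , 2][img$mask] <= 0))
    stop("non-positive cone catch inside mask")
  (img$q[, , 1] + img$q[, , 2]) / 2
}

#' RNL chromaticity maps
#'
#' Converts cone catches to the standard trichromatic receptor-noise-limited
#' chromatic coordinates (log-linear form). With `f_i = log(q_i)` and Weber
#' fractions `w = (wL, wM, wS)`:
#' \deqn{X = (f_L - f_M) / \sqrt{w_L^2 + w_M^2}}
#' \deqn{Y = \left(f_S - \frac{w_M^2 f_L + w_L^2 f_M}{w_L^2 + w_M^2}\right)
#'   \sqrt{\frac{w_L^2 + w_M^2}{w_L^2 w_M^2 + w_L^2 w_S^2 + w_M^2 w_S^2}}}
#' X is the red--green (L vs M) opponent axis and Y the blue--yellow
#' (S vs L,M) axis, in JND units. Both are invariant to scaling all catches
#' by a common factor, and vanish for achromatic pixels.
#'
#' @param img a [cone_catch_image()].
#' @param params an [rnl_params()].
#' @return List with matrices `X` and `Y`.
#' @export
rnl_chromaticity <- function(img, params = rnl_params()) {
  stopifnot(inherits(img, "cone_catch_image"), inherits(params, "rnl_params"))
  q <- pmax(img$q, 1e-6)
  if (any(img$q[, , 1][img$mask] <= 0))
    stop("non-positive cone catch inside mask")
  w <- params$weber
  fL <- log(q[, , 1]); fM <- log(q[, , 2]); fS <- log(q[, , 3])
  wl2 <- w[1]^2; wm2 <- w[2]^2; ws2 <- w[3]^2
  X <- (fL - fM) / sqrt(wl2 + wm2)
  A <- sqrt((wl2 + wm2) / (wl2 * wm2 + wl2 * ws2 + wm2 * ws2))
  Y <- (fS - (wm2 * fL + wl2 * fM) / (wl2 + wm2)) * A
  list(X = X, Y = Y)
}

#' Saturation map
#'
#' Euclidean distance of the (X, Y) chromaticity from the achromatic origin,
#' pixelwise: `Sat = sqrt(X^2 + Y^2)`.
#'
#' @param X,Y chromaticity matrices of identical shape.
#' @return Numeric matrix of saturations (JND units, >= 0).
#' @export
saturation_map <- function(X, Y) {
  if (!all(dim(X) == dim(Y))) stop("X and Y maps differ in shape")
  sqrt(X^2 + Y^2)
}

#' Build the four analysis channels for one specimen
#'
#' Derives the Lum, X, Y and Sat maps from a cone-catch image; the channel
#' stack shares the image's mask and scale.
#'
#' @param img a [cone_catch_image()].
#' @param params an [rnl_params()].
#' @return An object of class `channel_stack` with elements `Lum`, `X`, `Y`,
#'   `Sat`, `mask`, `px_per_cm`.
#' @export
channel_stack <- function(img, params = rnl_params()) {
  Lum <- compute_luminance(img)
  xy <- rnl_chromaticity(img, params)
  structure(list(Lum = Lum, X = xy$X, Y = xy$Y,
                 Sat = saturation_map(xy$X, xy$Y),
                 mask = img$mask, px_per_cm = img$px_per_cm),
            class = "channel_stack")
}

#' Mean channel values over the wing
#'
#' Arithmetic mean of each of the four channels over masked pixels only.
#'
#' @param stack a [channel_stack()].
#' @return Named numeric vector `c(Lum, X, Y, Sat)`.
#' @export
channel_means <- function(stack) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!any(stack$mask)) stop("empty mask")
  vapply(c("Lum", "X", "Y", "Sat"),
         function(ch) mean(stack[[ch]][stack$mask]), numeric(1))
}

channel_names <- function() c("Lum", "X", "Y", "Sat")
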