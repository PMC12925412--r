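#' Specimen description for the synthetic generator
#'
#' One row of the simulated collection: the covariates the downstream mixed
#' models use, plus the seed that fully determines the rendered image.
#'
#' @param sex `"male"` or `"female"`.
#' @param taxon `"badiata"`, `"fennokarelica"` or `"none"` (no subspecific
#'   annotation).
#' @param wear integer wear class 1 (little scale loss) to 3 (severe).
#' @param collection_year integer year of capture (not in the future).
#' @param latitude,longitude collection coordinates in decimal degrees.
#' @param collection_group label combining location and year; the random
#'   effect grouping of the mixed models.
#' @param seed integer; fully determines the generated image.
#' @return An object of class `wing_spec`.
#' @export
wing_spec <- function(sex, taxon = "none", wear = 1L,
                      collection_year = 2000L,
                      latitude = 60, longitude = 25,
                      collection_group = "sim_2000", seed = 1L) {
  sex <- match.arg(sex, c("male", "female"))
  taxon <- match.arg(taxon, c("badiata", "fennokarelica", "none"))
  wear <- as.integer(wear)
  if (!wear %in% 1:3) stop("wear must be 1, 2 or 3")
  collection_year <- as.integer(collection_year)
  if (collection_year > as.integer(format(Sys.Date(), "%Y")))
    stop("collection_year is in the future")
  structure(list(sex = sex, taxon = taxon, wear = wear,
                 collection_year = collection_year,
                 latitude = latitude, longitude = longitude,
                 collection_group = collection_group,
                 seed = as.integer(seed)),
            class = "wing_spec")
}

#' Effect magnitudes of the synthetic wing generator
#'
#' The generator's stated world. Each argument injects one of the effects the
#' analysis is designed to recover: a sex effect on darkness and contrast, a
#' taxon effect on contrast, stochastic scale loss increasing with wear
#' class, and fading (desaturation) with specimen age.
#'
#' @param sex_luminance_offset additive reflectance shift of the L and M
#'   catches for males (default -0.10: males darker).
#' @param sex_contrast_scale multiplier on pattern contrast for males
#'   (default 0.8: males less contrasting).
#' @param taxon_contrast_scale contrast multiplier for `fennokarelica`
#'   (default 0.85: paler, less contrasting pattern).
#' @param wear_loss_fraction length-3 vector, fraction of in-mask pixels
#'   replaced by scale-loss speckle per wear class (default 0.02/0.10/0.30);
#'   must be non-decreasing and in \[0, 1\].
#' @param fading_rate fractional relaxation of each channel toward its mean
#'   per year of specimen age (default 0.002/yr).
#' @param noise_sd per-pixel Gaussian noise sd on each catch (default 0.01).
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(sex_luminance_offset = -0.10,
                          sex_contrast_scale = 0.8,
                          taxon_contrast_scale = 0.85,
                          wear_loss_fraction = c(0.02, 0.10, 0.30),
                          fading_rate = 0.002,
                          noise_sd = 0.01) {
  if (sex_contrast_scale <= 0 || taxon_contrast_scale <= 0)
    stop("contrast multipliers must be > 0")
  if (length(wear_loss_fraction) != 3L ||
      any(wear_loss_fraction < 0) || any(wear_loss_fraction > 1) ||
      is.unsorted(wear_loss_fraction))
    stop("wear_loss_fraction must be 3 non-decreasing values in [0, 1]")
  if (noise_sd < 0 || fading_rate < 0)
    stop("noise_sd and fading_rate must be >= 0")
  structure(list(sex_luminance_offset = sex_luminance_offset,
                 sex_contrast_scale = sex_contrast_scale,
                 taxon_contrast_scale = taxon_contrast_scale,
                 wear_loss_fraction = wear_loss_fraction,
                 fading_rate = fading_rate, noise_sd = noise_sd),
            class = "effect_config")
}

#' Null effect configuration
#'
#' All systematic effects zeroed (no sex, taxon, wear or fading signal);
#' per-pixel noise is retained so specimens still differ stochastically.
#' Used for type-I-error simulations.
#'
#' @param noise_sd per-pixel noise sd (default 0.01).
#' @return An `effect_config`.
#' @export
null_effect_config <- function(noise_sd = 0.01) {
  effect_config(sex_luminance_offset = 0, sex_contrast_scale = 1,
                taxon_contrast_scale = 1, wear_loss_fraction = c(0, 0, 0),
                fading_rate = 0, noise_sd = noise_sd)
}

# Half-ellipse wing silhouette: straight trailing (lower) edge along the
# major axis, elliptical leading edge, apex at the right tip.
wing_outline_mask <- function(size_px, margin_px = 4L) {
  nr <- size_px[1]; nc <- size_px[2]
  a <- (nc - 2 * margin_px) / 2            # semi-major (half length), px
  b <- nr - 2 * margin_px                  # breadth, px
  cx <- (nc + 1) / 2
  y0 <- nr - margin_px                     # trailing edge row
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  row <- matrix(seq_len(nr), nr, nc)
  u2 <- ((col - cx) / a)^2
  height <- ifelse(u2 <= 1, b * sqrt(pmax(0, 1 - u2)), -1)
  (row <= y0) & (row >= y0 - height)
}

# Position of each pixel along the wing axis, 0 at the root, 1 at the apex.
wing_axis_fraction <- function(mask) {
  cols <- which(mask, arr.ind = TRUE)[, 2]
  rng <- range(cols)
  frac <- matrix(0, nrow(mask), ncol(mask))
  col <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  frac[] <- (col - rng[1]) / max(1, diff(rng))
  frac
}

# Base reflectances per transverse band (L, M, S): mid-brown basal field,
# darker red-brown median fascia, pale terminal field.
wing_band_palette <- function() {
  list(basal    = c(0.30, 0.26, 0.18),
       fascia   = c(0.16, 0.12, 0.08),
       terminal = c(0.46, 0.42, 0.34),
       breaks   = c(0.45, 0.65))
}

# Smooth Gaussian random field used to place scale-loss patches.
smooth_field <- function(nr, nc, sigma_px = 4) {
  m <- matrix(rnorm(nr * nc), nr, nc)
  r <- max(1L, min(ceiling(3 * sigma_px), (min(nr, nc) - 1L) %/% 2L))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2)); k <- k / sum(k)
  m <- apply(m, 2, function(x) as.numeric(stats::filter(x, k, circular = TRUE)))
  m <- t(apply(m, 1, function(x) as.numeric(stats::filter(x, k, circular = TRUE))))
  m
}

#' Render one synthetic wing specimen
#'
#' Draws a half-ellipse wing with three transverse bands (basal field, darker
#' median fascia, pale terminal field) in cone-catch space, then applies the
#' configured effects in order: taxon and sex contrast scaling about the
#' in-wing channel means, the male luminance offset on the L and M catches,
#' age fading (relaxation of every channel toward its mean by
#' `fading_rate * (reference_year - collection_year)`), scale loss on a
#' `wear_loss_fraction[wear]` share of in-mask pixels (feathered patches cut
#' from a smoothed random field, attenuated to the mean wing tone so wear
#' erodes pattern contrast), per-pixel Gaussian noise, and
#' clipping to `[1e-6, 1]`. The same `(spec, cfg, size)` always yields a
#' bit-identical image; sex and taxon enter only through the effects, so with
#' all effects zeroed specimens differing only in those labels are identical.
#'
#' @param spec a [wing_spec()].
#' @param cfg an [effect_config()].
#' @param size_px integer `c(rows, cols)` of the rendered image.
#' @param px_per_cm image scale (default 64, so the default 64 x 128 image
#'   holds a 1.9 cm x 0.9 cm wing).
#' @param reference_year year against which specimen age is measured
#'   (conventionally the newest collection year in the dataset); defaults to
#'   the specimen's own year, i.e. age 0.
#' @return A [cone_catch_image()].
#' @export
generate_specimen <- function(spec, cfg = effect_config(),
                              size_px = c(64L, 128L), px_per_cm = 64,
                              reference_year = NULL) {
  stopifnot(inherits(spec, "wing_spec"), inherits(cfg, "effect_config"))
  size_px <- as.integer(size_px)
  if (length(size_px) != 2L || any(size_px < 12L))
    stop("size_px must be two integers >= 12")
  reference_year <- reference_year %||% spec$collection_year
  age <- max(0, reference_year - spec$collection_year)

  mask <- wing_outline_mask(size_px)
  frac <- wing_axis_fraction(mask)
  pal <- wing_band_palette()
  band <- matrix(1L, size_px[1], size_px[2])
  band[frac >= pal$breaks[1]] <- 2L
  band[frac >= pal$breaks[2]] <- 3L

  q <- array(0.5, c(size_px, 3L))   # background: neutral grey card
  for (ch in 1:3) {
    plane <- q[, , ch]
    vals <- c(pal$basal[ch], pal$fascia[ch], pal$terminal[ch])
    plane[mask] <- vals[band[mask]]
    q[, , ch] <- plane
  }

  with_seed(spec$seed, {
    # broadband wing texture: transverse striation plus correlated speckle,
    # shared across channels (real wings are textured at all scales; wear
    # attenuates this texture, which is what erodes pattern energy)
    phase <- runif(1, 0, 2 * pi)
    col <- matrix(seq_len(size_px[2]), size_px[1], size_px[2], byrow = TRUE)
    stri <- sin(2 * pi * col / (0.1 * px_per_cm) + phase)
    spk <- smooth_field(size_px[1], size_px[2], sigma_px = max(1, px_per_cm / 32))
    spk <- spk / max(sd(spk[mask]), 1e-12)
    tex <- 0.03 * stri + 0.025 * spk
    tex_amp <- c(1, 0.9, 0.7)   # weaker texture in the shortwave catch
    for (ch in 1:3) {
      plane <- q[, , ch]
      plane[mask] <- plane[mask] + tex_amp[ch] * tex[mask]
      q[, , ch] <- plane
    }
    # contrast scaling about the in-wing mean; mean itself is preserved
    cscale <- 1
    if (spec$taxon == "fennokarelica") cscale <- cscale * cfg$taxon_contrast_scale
    if (spec$sex == "male") cscale <- cscale * cfg$sex_contrast_scale
    for (ch in 1:3) {
      plane <- q[, , ch]
      mu <- mean(plane[mask])
      plane[mask] <- mu + cscale * (plane[mask] - mu)
      q[, , ch] <- plane
    }
    if (spec$sex == "male") {
      for (ch in 1:2) {  # L and M carry luminance
        plane <- q[, , ch]
        plane[mask] <- plane[mask] + cfg$sex_luminance_offset
        q[, , ch] <- plane
      }
    }
    fade <- min(1, cfg$fading_rate * age)
    if (fade > 0) {
      for (ch in 1:3) {
        plane <- q[, , ch]
        mu <- mean(plane[mask])
        plane[mask] <- mu + (1 - fade) * (plane[mask] - mu)
        q[, , ch] <- plane
      }
    }
    # scale loss: contiguous patches where the pattern is replaced by the
    # pale exposed-membrane tone; patch borders are feathered (scale cover
    # thins gradually), so wear erodes pattern contrast instead of cutting
    # new high-contrast edges into the wing
    loss <- cfg$wear_loss_fraction[spec$wear]
    field <- smooth_field(size_px[1], size_px[2], sigma_px = px_per_cm / 12)
    if (loss > 0) {
      idx <- which(mask)
      k <- round(loss * length(idx))
      if (k > 0) {
        thr <- sort(field[idx])[k]
        soft <- 0.5 * sd(field[idx])
        keep <- pmin(1, pmax(0, (field - thr) / soft))   # 0 = bare membrane
        for (ch in 1:3) {
          plane <- q[, , ch]
          speckle <- mean(plane[mask])   # bare membrane at the mean wing tone
          plane[idx] <- keep[idx] * plane[idx] + (1 - keep[idx]) * speckle
          q[, , ch] <- plane
        }
      }
    }
    if (cfg$noise_sd > 0)
      q <- q + array(rnorm(length(q), sd = cfg$noise_sd), dim(q))
  })
  cone_catch_image(q, mask, px_per_cm)
}

# Largest-remainder allocation of n among categories with given proportions.
allocate_counts <- function(n, props) {
  raw <- n * props / sum(props)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

sim_locations <- function() {
  data.frame(
    location = c("FI_SW_Turku", "FI_S_Helsinki", "SE_Skane", "HU_Pest",
                 "FI_NK_Joensuu", "RU_Kar_Petrozavodsk", "RU_Kar_Sortavala",
                 "RU_Buryatia", "CN_NE_Harbin"),
    taxon = c("badiata", "badiata", "badiata", "badiata",
              "fennokarelica", "fennokarelica", "fennokarelica",
              "none", "none"),
    latitude = c(60.45, 60.17, 55.7, 47.4, 62.6, 61.8, 61.7, 51.8, 45.8),
    longitude = c(22.27, 24.94, 13.2, 19.3, 29.8, 34.3, 30.7, 107.6, 126.5),
    stringsAsFactors = FALSE)
}

#' Default sampling design of the synthetic collection
#'
#' Reproduces the composition of a typical museum series: for `n = 72`,
#' 40 males / 32 females, 29 specimens annotated *badiata* /
#' 41 *fennokarelica* / 2 unannotated, and wear classes 28/37/7. Other `n`
#' use the same proportions (largest-remainder rounding). Collection groups
#' are location x campaign-year labels; coordinates follow the location with
#' small jitter, so taxon and geography are confounded just as in real
#' museum material.
#'
#' @param n number of specimens (>= 2).
#' @param seed integer seed for the design draw.
#' @return Data frame with one row per specimen: `id`, `sex`, `taxon`,
#'   `wear`, `collection_year`, `latitude`, `longitude`, `collection_group`,
#'   `seed`.
#' @export
default_design <- function(n = 72L, seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  with_seed(seed, {
    sex <- sample(rep(c("male", "female"), allocate_counts(n, c(40, 32))))
    taxon <- sample(rep(c("badiata", "fennokarelica", "none"),
                        allocate_counts(n, c(29, 41, 2))))
    wear <- sample(rep(1:3, allocate_counts(n, c(28, 37, 7))))
    locs <- sim_locations()
    years <- lapply(seq_len(nrow(locs)),
                    function(i) sample(seq(1945, 2020, by = 5), 3))
    loc_idx <- integer(n); year <- integer(n)
    for (i in seq_len(n)) {
      cand <- which(locs$taxon == taxon[i])
      loc_idx[i] <- if (length(cand) > 1) sample(cand, 1) else cand
      year[i] <- sample(years[[loc_idx[i]]], 1)
    }
    data.frame(
      id = sprintf("sim%03d", seq_len(n)),
      sex = sex, taxon = taxon, wear = wear,
      collection_year = year,
      latitude = locs$latitude[loc_idx] + runif(n, -0.2, 0.2),
      longitude = locs$longitude[loc_idx] + runif(n, -0.2, 0.2),
      collection_group = paste0(locs$location[loc_idx], "_", year),
      seed = derive_seeds(seed + 1L, n),
      stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic wing-image dataset
#'
#' Renders `n` specimens under a sampling design (default:
#' [default_design()]) and an effect
#' configuration. Fading is measured against the newest collection year in
#' the design, so "specimen age" is relative within the dataset.
#'
#' @param n number of specimens (>= 2).
#' @param cfg an [effect_config()].
#' @param design optional design data frame as from [default_design()]; must
#'   have `n` rows. A `seed` column is derived from `seed` if absent.
#' @param seed integer; seeds the design and, through it, every image.
#' @param size_px,px_per_cm image geometry passed to [generate_specimen()].
#' @return List with `images` (list of [cone_catch_image()]) and `meta`
#'   (the design data frame plus `px_per_cm`).
#' @export
generate_dataset <- function(n = 72L, cfg = effect_config(), design = NULL,
                             seed = 1L, size_px = c(64L, 128L),
                             px_per_cm = 64) {
  if (n < 2) stop("n must be >= 2")
  design <- design %||% default_design(n, seed)
  if (nrow(design) != n) stop("design has ", nrow(design), " rows but n = ", n)
  if (is.null(design$seed)) design$seed <- derive_seeds(seed + 1L, n)
  ref_year <- max(design$collection_year)
  images <- lapply(seq_len(n), function(i) {
    sp <- wing_spec(sex = design$sex[i], taxon = design$taxon[i],
                    wear = design$wear[i],
                    collection_year = design$collection_year[i],
                    latitude = design$latitude[i],
                    longitude = design$longitude[i],
                    collection_group = design$collection_group[i],
                    seed = design$seed[i])
    generate_specimen(sp, cfg, size_px = size_px, px_per_cm = px_per_cm,
                      reference_year = ref_year)
  })
  design$px_per_cm <- px_per_cm
  list(images = images, meta = design)
}
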