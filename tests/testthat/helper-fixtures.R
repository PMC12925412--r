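# Shared fixtures, built once per test run. The "profile" geometry keeps
# simulation-heavy tests inside the time budget: a 24 x 48 px wing at
# 64 px/cm analysed with the three smallest default Gabor scales.

profile_size <- c(24L, 48L)
profile_px_per_cm <- 64

profile_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- build_gabor_bank(c(0.03125, 0.0625, 0.125),
                                                 px_per_cm = profile_px_per_cm)
    bank
  }
})

full_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- build_gabor_bank(px_per_cm = 64)
    bank
  }
})

# one full pipeline replicate on the profile geometry
profile_replicate <- function(seed, cfg) {
  ds <- generate_dataset(72, cfg, seed = seed, size_px = profile_size,
                         px_per_cm = profile_px_per_cm)
  ft <- dataset_features(ds$images, profile_bank(), ids = ds$meta$id)
  list(features = ft, meta = ds$meta)
}

# flat-ish cone-catch image with constant catches
constant_image <- function(qvals = c(0.5, 0.5, 0.5), nr = 20, nc = 30,
                           mask = NULL, px_per_cm = 64) {
  q <- array(rep(qvals, each = nr * nc), c(nr, nc, 3))
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  cone_catch_image(q, mask, px_per_cm)
}

default_spec <- function(seed = 1L, ...) {
  args <- modifyList(list(sex = "female", taxon = "badiata", wear = 1L,
                          collection_year = 2000L, latitude = 60.4,
                          longitude = 22.3, collection_group = "FI_SW_2000",
                          seed = seed), list(...))
  do.call(wing_spec, args)
}
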