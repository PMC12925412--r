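#' Canonical feature schema
#'
#' Stable column order of the specimen feature vector: 3 wing-size metrics,
#' then for each channel (Lum, X, Y, Sat): the mean pixel value, per scale
#' the four orientation energies plus `Emean`, `V`, `D`, and the seven
#' across-scale summaries (`Esum`, `Vsum`, `Dsum`, `maxE_scale_cm`,
#' `E_at_max`, `V_at_max`, `D_at_max`). With the default 6-scale, 4-orientation
#' bank this is `3 + 4 * (1 + 6*7 + 7) = 203` columns. (Published
#' granularity analyses count such metric sets slightly differently,
#' 195-207 columns depending on the breakdown; the schema here is fixed and
#' documented rather than forced to any particular count -- see the
#' vignette.)
#'
#' @param bank a [build_gabor_bank()].
#' @return Character vector of column names.
#' @export
feature_schema <- function(bank) {
  ns <- length(bank$scales_cm); os <- bank$orientations_deg
  per_channel <- function(ch) {
    c(paste0(ch, "_mean"),
      unlist(lapply(seq_len(ns), function(s)
        paste0(ch, "_s", s, "_", c(paste0("E", os), "Emean", "V", "D")))),
      paste0(ch, "_", c("Esum", "Vsum", "Dsum", "maxE_scale_cm",
                        "E_at_max", "V_at_max", "D_at_max")))
  }
  c("area_cm2", "length_cm", "breadth_cm",
    unlist(lapply(channel_names(), per_channel)))
}

#' Extract the full feature vector for one specimen
#'
#' Combines wing-size metrics, per-channel means and the Gabor granularity
#' statistics of all four channels into the canonical schema
#' ([feature_schema()]).
#'
#' @param stack a [channel_stack()], already orientation-normalised.
#' @param bank a [build_gabor_bank()].
#' @param size a [wing_size()] for the same specimen.
#' @return Named numeric vector following [feature_schema()].
#' @export
extract_features <- function(stack, bank, size) {
  stopifnot(inherits(stack, "channel_stack"), inherits(size, "wing_size"))
  means <- channel_means(stack)
  grids <- gabor_energy_stack(stack, bank)
  out <- c(area_cm2 = size$area_cm2, length_cm = size$length_cm,
           breadth_cm = size$breadth_cm)
  for (ch in channel_names()) {
    st <- orientation_stats(grids[[ch]])
    sm <- scale_summary(st)
    vals <- c(means[[ch]])
    for (s in seq_len(nrow(st)))
      vals <- c(vals, grids[[ch]][s, ], st$Emean[s], st$V[s], st$D[s])
    vals <- c(vals, sm$Esum, sm$Vsum, sm$Dsum, sm$max_scale_cm,
              sm$E_at_max, sm$V_at_max, sm$D_at_max)
    out <- c(out, vals)
  }
  names(out) <- feature_schema(bank)
  if (anyNA(out)) stop("feature extraction produced missing values")
  out
}

#' Feature table for a set of specimens
#'
#' Full image pipeline per specimen: orientation normalisation, wing size,
#' channel conversion, Gabor granularity, one feature row each.
#'
#' @param images list of [cone_catch_image()].
#' @param bank a [build_gabor_bank()]; its `px_per_cm` must match the images.
#' @param params an [rnl_params()].
#' @param ids optional character ids used as a leading `id` column.
#' @param orient logical; rotate each wing to the horizontal first
#'   (default `TRUE`).
#' @return Data frame: `id` plus the columns of [feature_schema()].
#' @export
dataset_features <- function(images, bank, params = rnl_params(), ids = NULL,
                             orient = TRUE) {
  ids <- ids %||% sprintf("spec%03d", seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    if (orient) img <- orient_wing(img)
    size <- wing_size(img$mask, img$px_per_cm)
    extract_features(channel_stack(img, params), bank, size)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), out)
}
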