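#' Z-score the columns of a table
#'
#' Scales every numeric column to mean 0, sd 1 (denominator `n - 1`).
#' Constant columns cannot be scaled; they are dropped with a warning and
#' recorded in the `dropped` attribute.
#'
#' @param x data frame or matrix of numeric columns.
#' @return Data frame of scaled columns; attribute `dropped` lists removed
#'   constant columns.
#' @export
standardize <- function(x) {
  x <- as.data.frame(x)
  sds <- vapply(x, sd, numeric(1))
  dropped <- names(x)[sds == 0 | !is.finite(sds)]
  if (length(dropped))
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
  keep <- setdiff(names(x), dropped)
  out <- as.data.frame(lapply(x[keep], function(v) (v - mean(v)) / sd(v)))
  names(out) <- keep
  attr(out, "dropped") <- dropped
  out
}

#' Principal component analysis of the feature table
#'
#' Correlation-matrix PCA: features are z-scored ([standardize()]) and
#' decomposed by SVD. For interpretability each of the first `n_components`
#' axes is sign-fixed: if the sum of a component's loadings is negative, the
#' loadings and scores of that component are multiplied by -1 and the flip
#' is recorded. Flipping changes nothing downstream except the sign of
#' estimates that are themselves reported on the flipped axis.
#'
#' @param features numeric data frame or matrix (specimens x metrics); a
#'   character `id` column, if present, is set aside.
#' @param n_components number of components to keep (default 3).
#' @return Object of class `pca_result`: `scores` (n x k), `loadings`
#'   (p x k), `var_explained` (full spectrum, fractions), `flipped`
#'   (logical k), `sdev`, `dropped` (constant metrics removed).
#' @export
run_pca <- function(features, n_components = 3L) {
  features <- as.data.frame(features)
  if (!is.null(features$id)) features$id <- NULL
  if (nrow(features) < 2 || ncol(features) < 2)
    stop("need at least 2 specimens and 2 metrics")
  z <- suppressWarnings(standardize(features))
  maxk <- min(nrow(z) - 1L, ncol(z))
  if (n_components > maxk)
    stop("requested ", n_components, " components but rank allows only ", maxk)
  p <- prcomp(as.matrix(z), center = FALSE, scale. = FALSE)
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  loadings <- p$rotation[, seq_len(n_components), drop = FALSE]
  flipped <- colSums(loadings) < 0
  for (k in which(flipped)) {
    loadings[, k] <- -loadings[, k]
    scores[, k] <- -scores[, k]
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = ve, flipped = flipped, sdev = p$sdev,
                 dropped = attr(z, "dropped")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("pca_result: %d specimens, %d components kept (%s%% of variance)\n",
              nrow(x$scores), k,
              paste(round(100 * x$var_explained[seq_len(k)], 1), collapse = "/")))
  invisible(x)
}

#' Which retained component is luminance-dominated?
#'
#' The component (among those kept) with the largest absolute loading on the
#' mean-luminance metric `Lum_mean`.
#'
#' @param pca a [run_pca()] result whose loadings include `Lum_mean`.
#' @return Integer component index.
#' @export
luminance_pc <- function(pca) {
  if (!"Lum_mean" %in% rownames(pca$loadings))
    stop("loadings do not include a Lum_mean metric")
  which.max(abs(pca$loadings["Lum_mean", ]))
}

# model frame shared by all per-component fits
lmm_model_frame <- function(meta, reference_year = NULL) {
  need <- c("sex", "taxon", "wear", "collection_year", "latitude",
            "longitude", "collection_group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  keep <- meta$taxon != "none"      # unannotated specimens are excluded
  meta <- meta[keep, , drop = FALSE]
  reference_year <- reference_year %||% max(meta$collection_year)
  z <- function(v) (v - mean(v)) / sd(v)
  mf <- data.frame(
    sex = factor(meta$sex, levels = c("female", "male")),
    taxon = factor(meta$taxon, levels = c("badiata", "fennokarelica")),
    wear = z(meta$wear),
    age = z(reference_year - meta$collection_year),
    latitude = z(meta$latitude),
    longitude = z(meta$longitude),
    collection_group = factor(meta$collection_group))
  attr(mf, "kept") <- which(keep)
  mf
}

#' Linear mixed model of one principal component on specimen covariates
#'
#' Fits `PC_k ~ sex + taxon + wear + age + latitude + longitude +
#' (1 | collection_group)` with [lme4::lmer()] (REML). Numeric covariates are
#' z-scored; `sex` uses female and `taxon` uses *badiata* as reference, so
#' the reported contrasts are "male" and "fennokarelica". Specimens without
#' subspecific annotation (`taxon == "none"`) are excluded. Specimen age is
#' `reference_year - collection_year` with the newest collection year as
#' reference. Degrees of freedom use the residual approximation
#' `n - n_fixed` (recorded in the `df_method` attribute; a
#' Satterthwaite-type correction would need an additional package and the
#' resulting dfs are not comparable across approximations anyway). Singular
#' fits (random-effect variance estimated at zero) are reported via the
#' `singular` attribute, not treated as errors; with a single collection
#' group the model falls back to ordinary least squares (`df_method "ols"`).
#'
#' @param pca a [run_pca()] result.
#' @param meta metadata with `sex`, `taxon`, `wear`, `collection_year`,
#'   `latitude`, `longitude`, `collection_group`, row-aligned with the PCA
#'   scores.
#' @param component which component to model (default 1).
#' @param reference_year optional reference year for specimen age.
#' @return Data frame of class `lmm_table` with columns `component`,
#'   `effect`, `df`, `estimate`, `se`, `t`, `p`; attributes `df_method` and
#'   `singular`.
#' @export
fit_lmm <- function(pca, meta, component = 1L, reference_year = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  if (nrow(meta) != nrow(pca$scores))
    stop("metadata rows do not match PCA scores")
  mf <- lmm_model_frame(meta, reference_year)
  mf$pc <- pca$scores[attr(mf, "kept"), component]
  singular <- FALSE
  if (nlevels(droplevels(mf$collection_group)) > 1) {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(pc ~ sex + taxon + wear + age + latitude + longitude +
                   (1 | collection_group),
                 data = mf, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    singular <- lme4::isSingular(fit)
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    df_method <- "residual"
  } else {
    fit <- stats::lm(pc ~ sex + taxon + wear + age + latitude + longitude,
                     data = mf)
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    df_method <- "ols"
  }
  df <- nrow(mf) - length(beta)
  tval <- beta / se
  out <- data.frame(component = paste0("PC", component),
                    effect = names(beta), df = df,
                    estimate = unname(beta), se = unname(se),
                    t = unname(tval),
                    p = unname(2 * pt(-abs(tval), df)),
                    row.names = NULL)
  attr(out, "df_method") <- df_method
  attr(out, "singular") <- singular
  class(out) <- c("lmm_table", class(out))
  out
}

#' Full statistical analysis of a feature table
#'
#' Standardises, runs the PCA and fits the mixed model for each retained
#' component; convenience wrapper for the `analyze` pipeline stage.
#'
#' @param features feature data frame (optionally with an `id` column).
#' @param meta metadata table, row-aligned with `features`.
#' @param n_components components to keep and model (default 3).
#' @return List with `pca` ([run_pca()]), `lmm` (row-bound [fit_lmm()]
#'   tables) and `luminance_pc`.
#' @export
analyze_dataset <- function(features, meta, n_components = 3L) {
  pca <- run_pca(features, n_components)
  tabs <- lapply(seq_len(n_components), function(k) fit_lmm(pca, meta, k))
  lmm <- do.call(rbind, tabs)
  attr(lmm, "df_method") <- attr(tabs[[1]], "df_method")
  list(pca = pca, lmm = lmm, luminance_pc = luminance_pc(pca))
}
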