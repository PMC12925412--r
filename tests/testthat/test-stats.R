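test_that("standardize z-scores, is idempotent and drops constants", {
  out <- standardize(data.frame(a = c(1, 2, 3)))
  expect_equal(out$a, c(-1, 0, 1))
  again <- standardize(out)
  expect_equal(again$a, out$a)
  expect_warning(res <- standardize(data.frame(a = 1:4, b = rep(2, 4))),
                 "constant")
  expect_identical(attr(res, "dropped"), "b")
  expect_null(res$b)
})

test_that("PCA handles rank-1 data and is rotation-invariant in spectrum", {
  x <- data.frame(a = 1:10, b = 2 * (1:10), c = -3 * (1:10))
  p <- run_pca(x, 2)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-12)

  set.seed(4)
  m <- matrix(rnorm(40 * 6), 40, 6)
  # correlation PCA is invariant to variance-preserving orthogonal maps;
  # use a random signed permutation of the metrics
  perm <- diag(sample(c(-1, 1), 6, TRUE))[, sample(6)]
  p1 <- run_pca(as.data.frame(m), 3)
  p2 <- run_pca(as.data.frame(m %*% perm), 3)
  expect_equal(p1$var_explained, p2$var_explained, tolerance = 1e-9)

  expect_error(run_pca(as.data.frame(m), 41), "rank")
})

test_that("sign-flip rule normalises loadings and is an involution", {
  set.seed(6)
  m <- as.data.frame(matrix(rnorm(30 * 5), 30, 5))
  p <- run_pca(m, 3)
  expect_true(all(colSums(p$loadings) >= 0))
  # flipping twice is the identity: flipped components re-flip to themselves
  for (k in seq_len(3)) {
    l2 <- -p$loadings[, k]
    expect_true(sum(l2) <= 0)
  }
  # |scores| and explained variance do not depend on the flip
  q <- prcomp(as.matrix(standardize(m)), center = FALSE, scale. = FALSE)
  expect_equal(abs(unname(p$scores)), abs(unname(q$x[, 1:3])), tolerance = 1e-9)
})

test_that("PCA reconstructs the standardized data at full rank", {
  set.seed(7)
  m <- as.data.frame(matrix(rnorm(12 * 5), 12, 5))
  p <- run_pca(m, 5)
  z <- as.matrix(standardize(m))
  expect_equal(unname(p$scores %*% t(p$loadings)), unname(z), tolerance = 1e-9)
})

test_that("mixed model matches the OLS oracle when groups carry no signal", {
  set.seed(8)
  n <- 60
  meta <- data.frame(
    sex = sample(c("male", "female"), n, TRUE),
    taxon = sample(c("badiata", "fennokarelica"), n, TRUE),
    wear = sample(1:3, n, TRUE),
    collection_year = sample(1950:2020, n, TRUE),
    latitude = runif(n, 55, 65), longitude = runif(n, 20, 35),
    collection_group = sample(paste0("g", 1:12), n, TRUE))
  scores <- matrix(rnorm(n * 3), n, 3)   # iid: group variance is 0
  pca <- structure(list(scores = scores,
                        loadings = matrix(0, 2, 3,
                                          dimnames = list(c("Lum_mean", "x"), NULL)),
                        var_explained = rep(1 / 3, 3),
                        flipped = rep(FALSE, 3)),
                   class = "pca_result")
  tab <- fit_lmm(pca, meta, 1)
  mf <- wingscape:::lmm_model_frame(meta)
  mf$pc <- scores[, 1]
  ols <- stats::lm(pc ~ sex + taxon + wear + age + latitude + longitude, data = mf)
  expect_equal(tab$estimate, unname(coef(ols)), tolerance = 1e-6)
  # internal consistency: t = estimate / SE
  expect_equal(tab$t, tab$estimate / tab$se, tolerance = 1e-12)
  expect_identical(attr(tab, "df_method"), "residual")
})

test_that("unannotated specimens are excluded and labels are treatment-coded", {
  set.seed(9)
  n <- 40
  meta <- data.frame(
    sex = rep(c("male", "female"), n / 2),
    taxon = c(rep("badiata", 18), rep("fennokarelica", 18), rep("none", 4)),
    wear = sample(1:3, n, TRUE),
    collection_year = sample(1950:2020, n, TRUE),
    latitude = runif(n, 55, 65), longitude = runif(n, 20, 35),
    collection_group = sample(paste0("g", 1:8), n, TRUE))
  scores <- matrix(rnorm(n * 2), n, 2)
  pca <- structure(list(scores = scores,
                        loadings = matrix(0, 2, 2,
                                          dimnames = list(c("Lum_mean", "x"), NULL)),
                        var_explained = c(0.6, 0.4), flipped = c(FALSE, FALSE)),
                   class = "pca_result")
  tab <- fit_lmm(pca, meta, 1)
  expect_equal(tab$df[1], 36 - length(unique(tab$effect)))
  expect_true(all(c("sexmale", "taxonfennokarelica") %in% tab$effect))
})

test_that("one full replicate recovers the injected sex effect strongly", {
  rep1 <- profile_replicate(21, effect_config())
  res <- analyze_dataset(rep1$features[-1], rep1$meta)
  k <- res$luminance_pc
  row <- subset(res$lmm, component == paste0("PC", k) & effect == "sexmale")
  expect_lt(row$p, 1e-3)
  expect_equal(res$lmm$t, res$lmm$estimate / res$lmm$se, tolerance = 1e-12)
  # sign-flip bookkeeping does not change p-values
  expect_true(is.logical(res$pca$flipped))
})
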