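# label 4-connected components by iterative minimum-label propagation
label_components <- function(fg) {
  lab <- matrix(0L, nrow(fg), ncol(fg))
  lab[fg] <- seq_len(sum(fg))
  big <- sum(fg) + 1L
  repeat {
    cur <- lab
    cur[!fg] <- big
    up <- rbind(big, cur[-nrow(cur), , drop = FALSE])
    dn <- rbind(cur[-1, , drop = FALSE], big)
    lf <- cbind(big, cur[, -ncol(cur), drop = FALSE])
    rt <- cbind(cur[, -1, drop = FALSE], big)
    nb <- pmin(cur, up, dn, lf, rt)
    nb[!fg] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  lab
}

#' Segment the wing from a uniform background
#'
#' Returns the largest connected foreground component, where foreground is
#' any pixel deviating from the background level (estimated as the median of
#' the image border) by more than `threshold`. If an explicit mask is
#' supplied it is validated and passed through unchanged -- museum
#' workflows isolate wings manually, so a hand-drawn mask always wins.
#'
#' @param image numeric matrix, or a [cone_catch_image()] (its luminance is
#'   segmented).
#' @param threshold minimum absolute deviation from background (default 0.05).
#' @param mask optional explicit mask, returned as-is after a shape check.
#' @return Logical mask of the wing.
#' @export
segment_wing <- function(image, threshold = 0.05, mask = NULL) {
  m <- if (inherits(image, "cone_catch_image")) compute_luminance(image) else as.matrix(image)
  if (!is.null(mask)) {
    mask <- as.matrix(mask) > 0
    if (!all(dim(mask) == dim(m))) stop("supplied mask does not match image shape")
    return(mask)
  }
  border <- c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)])
  bg <- stats::median(border)
  fg <- abs(m - bg) > threshold
  if (!any(fg)) stop("no foreground found: image is all background")
  lab <- label_components(fg)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# bilinear sampler with constant fill outside the image
bilinear_sample <- function(m, xs, ys, fill) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(xs); y0 <- floor(ys)
  dx <- xs - x0; dy <- ys - y0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- rep(fill, length(r))
    v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  v00 <- get(y0, x0); v01 <- get(y0, x0 + 1)
  v10 <- get(y0 + 1, x0); v11 <- get(y0 + 1, x0 + 1)
  (1 - dy) * ((1 - dx) * v00 + dx * v01) + dy * ((1 - dx) * v10 + dx * v11)
}

# rotate a matrix by `theta` radians about its centre (inverse mapping)
rotate_matrix <- function(m, theta, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  xo <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  yo <- matrix(seq_len(nr), nr, nc) - cy
  xs <- cos(theta) * xo - sin(theta) * yo + cx
  ys <- sin(theta) * xo + cos(theta) * yo + cy
  matrix(bilinear_sample(m, as.vector(xs), as.vector(ys), fill), nr, nc)
}

mask_principal_angle <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) stop("degenerate mask: fewer than 3 pixels")
  xy <- cbind(x = pts[, 2], y = pts[, 1])
  cv <- stats::cov(xy)
  if (abs(cv[1, 1] - cv[2, 2]) < 1e-12 && abs(cv[1, 2]) < 1e-12)
    stop("degenerate mask: isotropic second moments")
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  atan2(v[2], v[1])
}

#' Rotate a specimen so the wing's longest dimension is horizontal
#'
#' Finds the principal axis of the mask's second moments and rotates image
#' and mask so that axis is horizontal. The sign is fixed deterministically:
#' the apex (the thin extreme, identified by the sign of the third moment
#' along the major axis) points right; at exact symmetry the orientation is
#' kept. Rotation uses bilinear interpolation for the channels and a 0.5
#' threshold for the mask, so applying the operation twice is idempotent up
#' to interpolation error.
#'
#' @param x a [cone_catch_image()] or [channel_stack()].
#' @return Object of the same class, rotated, with attribute
#'   `rotation_rad` (the applied angle).
#' @export
orient_wing <- function(x) {
  mask <- x$mask
  theta <- mask_principal_angle(mask)
  rot <- function(m, fill) rotate_matrix(m, theta, fill)
  newmask <- rot(mask + 0, 0) > 0.5
  # apex-right convention: positive skewness of x within the mask
  pts <- which(newmask, arr.ind = TRUE)[, 2]
  sk <- mean((pts - mean(pts))^3)
  flip <- sk < -1e-9
  finish <- function(m, fill) {
    out <- rot(m, fill)
    if (flip) out <- out[rev(seq_len(nrow(out))), rev(seq_len(ncol(out)))]
    out
  }
  if (flip) newmask <- newmask[rev(seq_len(nrow(newmask))), rev(seq_len(ncol(newmask)))]
  if (inherits(x, "cone_catch_image")) {
    q <- x$q
    for (ch in seq_len(dim(q)[3])) {
      fill <- mean(x$q[, , ch][!mask])
      if (!is.finite(fill)) fill <- mean(x$q[, , ch])
      q[, , ch] <- finish(x$q[, , ch], fill)
    }
    out <- cone_catch_image(q, newmask, x$px_per_cm)
  } else if (inherits(x, "channel_stack")) {
    out <- x
    for (ch in channel_names()) {
      fill <- mean(x[[ch]][!mask])
      if (!is.finite(fill)) fill <- mean(x[[ch]])
      out[[ch]] <- finish(x[[ch]], fill)
    }
    out$mask <- newmask
  } else stop("orient_wing needs a cone_catch_image or channel_stack")
  attr(out, "rotation_rad") <- if (flip) theta + pi else theta
  out
}

# minimum-area oriented bounding box over a point cloud (rotating calipers)
min_area_box <- function(xy) {
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  n <- nrow(hull)
  best <- c(Inf, 0, 0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    w <- diff(range(pu)); hgt <- diff(range(pv))
    if (w * hgt < best[1]) best <- c(w * hgt, w, hgt)
  }
  sort(best[2:3], decreasing = TRUE)
}

#' Wing size metrics
#'
#' Area from the pixel count and scale; major length and minor breadth as
#' the side lengths of the minimum-area oriented bounding box of the mask
#' (pixel extents, so a filled 200 x 100 px rectangle at 100 px/cm measures
#' exactly 2 cm x 1 cm).
#'
#' @param mask logical wing mask.
#' @param px_per_cm pixels per centimetre (> 0).
#' @return Object of class `wing_size`: list with `area_cm2`, `length_cm`,
#'   `breadth_cm`.
#' @export
wing_size <- function(mask, px_per_cm) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("empty mask")
  if (px_per_cm <= 0) stop("px_per_cm must be > 0")
  pts <- which(mask, arr.ind = TRUE)
  xy <- cbind(pts[, 2], pts[, 1])
  # pixel corners so extents count whole pixels
  corners <- rbind(xy + rep(c(-0.5, -0.5), each = nrow(xy)),
                   xy + rep(c(-0.5, 0.5), each = nrow(xy)),
                   xy + rep(c(0.5, -0.5), each = nrow(xy)),
                   xy + rep(c(0.5, 0.5), each = nrow(xy)))
  sides <- min_area_box(corners)
  structure(list(area_cm2 = sum(mask) / px_per_cm^2,
                 length_cm = sides[1] / px_per_cm,
                 breadth_cm = sides[2] / px_per_cm),
            class = "wing_size")
}

#' @export
print.wing_size <- function(x, ...) {
  cat(sprintf("wing_size: area %.4g cm^2, length %.4g cm, breadth %.4g cm\n",
              x$area_cm2, x$length_cm, x$breadth_cm))
  invisible(x)
}
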