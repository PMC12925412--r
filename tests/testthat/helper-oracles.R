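# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (direct spatial convolution, brute-force
# loops, exhaustive Steiner search).

# direct spatial convolution Gabor energy (quadratic; tiny inputs only)
gabor_energy_direct <- function(map, mask, bank) {
  ns <- length(bank$scales_cm); no <- length(bank$orientations_deg)
  nr <- nrow(map); nc <- ncol(map)
  mu <- mean(map[mask]); filled <- map; filled[!mask] <- mu
  E <- matrix(0, ns, no)
  for (s in seq_len(ns)) {
    r_er <- bank$erosion_px[s]
    offs <- expand.grid(dy = -r_er:r_er, dx = -r_er:r_er)
    offs <- offs[offs$dy^2 + offs$dx^2 <= r_er^2, ]
    idx <- which(mask, arr.ind = TRUE)
    keep <- vapply(seq_len(nrow(idx)), function(k) {
      ys <- idx[k, 1] + offs$dy; xs <- idx[k, 2] + offs$dx
      all(ys >= 1 & ys <= nr & xs >= 1 & xs <= nc) && all(mask[cbind(ys, xs)])
    }, logical(1))
    em <- matrix(FALSE, nr, nc); em[idx[keep, , drop = FALSE]] <- TRUE
    for (o in seq_len(no)) {
      kern <- bank$kernels[[s]][[o]]
      rk <- (nrow(kern) - 1) / 2
      tot <- 0; cnt <- 0
      for (k in which(em)) {
        y <- (k - 1) %% nr + 1; x <- (k - 1) %/% nr + 1
        acc <- 0 + 0i
        for (dy in -rk:rk) for (dx in -rk:rk) {
          yy <- y + dy; xx <- x + dx
          v <- if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc) filled[yy, xx] else mu
          acc <- acc + v * kern[dy + rk + 1, dx + rk + 1]
        }
        tot <- tot + Mod(acc); cnt <- cnt + 1
      }
      E[s, o] <- tot / cnt
    }
  }
  E
}

# Hamming helpers and exhaustive Steiner-minimal tree length over the
# median closure of the terminals (exact on the toy instances used here)
ham_oracle <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

ham_matrix_oracle <- function(ss) {
  n <- length(ss); d <- matrix(0L, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- ham_oracle(ss[i], ss[j])
  d
}

mst_length_oracle <- function(d) {
  n <- nrow(d); if (n < 2) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1)); mind <- d[, 1]; tot <- 0
  for (k in seq_len(n - 1)) {
    i <- which(!intree)[which.min(mind[!intree])]
    tot <- tot + mind[i]; intree[i] <- TRUE; mind <- pmin(mind, d[, i])
  }
  tot
}

median3_oracle <- function(a, b, c) {
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]], strsplit(c, "")[[1]])
  paste0(apply(m, 2, function(s) {
    tb <- table(s)
    if (max(tb) >= 2) names(tb)[which.max(tb)] else min(s)
  }), collapse = "")
}

median_closure_oracle <- function(ss) {
  repeat {
    if (length(ss) < 3) return(ss)
    new <- character(0)
    cmb <- utils::combn(length(ss), 3)
    for (k in seq_len(ncol(cmb))) {
      m <- median3_oracle(ss[cmb[1, k]], ss[cmb[2, k]], ss[cmb[3, k]])
      if (!(m %in% ss) && !(m %in% new)) new <- c(new, m)
    }
    if (!length(new)) return(ss)
    ss <- c(ss, new)
  }
}

steiner_min_oracle <- function(terms) {
  cl <- setdiff(median_closure_oracle(terms), terms)
  best <- mst_length_oracle(ham_matrix_oracle(terms))
  if (length(cl)) for (k in 1:min(4, length(cl))) {
    cmb <- utils::combn(length(cl), k)
    for (j in seq_len(ncol(cmb))) {
      len <- mst_length_oracle(ham_matrix_oracle(c(terms, cl[cmb[, j]])))
      if (len < best) best <- len
    }
  }
  best
}

# star-like toy instance: haplotypes 1-2 mutations from a common backbone,
# optionally with the backbone itself unsampled
star_instance <- function(L, nh, drop_ancestor) {
  anc <- paste0(sample(c("0", "1"), L, TRUE), collapse = "")
  strs <- anc
  for (i in seq_len(nh - 1)) {
    k <- sample(1:2, 1)
    v <- strsplit(anc, "")[[1]]
    pos <- sample(L, k)
    v[pos] <- ifelse(v[pos] == "0", "1", "0")
    strs <- c(strs, paste0(v, collapse = ""))
  }
  if (drop_ancestor) strs <- strs[-1]
  unique(strs)
}

# build a haplotype_set directly from strings (unit weight)
toy_haps <- function(strs, counts = rep(1L, length(strs))) {
  ord <- order(-counts, strs)
  structure(list(sequences = strs[ord], counts = counts[ord],
                 members = lapply(ord, function(i) paste0("r", i)),
                 kept_columns = seq_len(nchar(strs[1]))),
            class = "haplotype_set")
}
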