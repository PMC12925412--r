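#' Collapse aligned records into haplotypes
#'
#' Masks every alignment column that carries a gap or ambiguity code in
#' *any* in-scope record (the convention of haplotype-network software, so
#' haplotype counts are reproducible), then merges records identical over
#' the remaining columns. The outgroup is excluded from networks by
#' default.
#'
#' @param aln a [read_alignment()] result.
#' @param exclude_groups group labels left out of the haplotyping
#'   (default `"tellensis"`, the outgroup). Use `character(0)` for none.
#' @return Object of class `haplotype_set`: `sequences` (haplotype strings
#'   over kept columns, ordered by decreasing count then lexicographically),
#'   `counts`, `members` (list of record ids), `kept_columns`.
#' @export
collapse_haplotypes <- function(aln, exclude_groups = "tellensis") {
  stopifnot(inherits(aln, "barcode_alignment"))
  scope <- !(aln$groups %in% exclude_groups)
  if (!any(scope)) stop("no records left in scope")
  seqs <- aln$seqs[scope, , drop = FALSE]
  clean <- apply(seqs, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(clean)) stop("all columns masked: no unambiguous sites shared by the records")
  seqs <- seqs[, clean, drop = FALSE]
  strs <- apply(seqs, 1, paste0, collapse = "")
  split_ids <- split(rownames(seqs), strs)
  counts <- lengths(split_ids)
  ord <- order(-counts, names(split_ids))
  structure(list(sequences = names(split_ids)[ord],
                 counts = unname(counts[ord]),
                 members = unname(split_ids[ord]),
                 kept_columns = which(clean)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes over %d sites, %d records, %d singletons\n",
              length(x$sequences), nchar(x$sequences[1]), sum(x$counts),
              sum(x$counts == 1)))
  invisible(x)
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

hamming_matrix <- function(strs) {
  m <- do.call(rbind, strsplit(strs, ""))
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

# epsilon-relaxed minimum spanning network (union of all minimum spanning
# trees, plus edges within epsilon of the connecting weight)
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2) return(data.frame(from = integer(0), to = integer(0), w = integer(0)))
  comp <- seq_len(n)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ew <- d[pairs]
  keep <- logical(nrow(pairs))
  for (w in sort(unique(ew))) {
    at <- which(ew <= w & ew > w - 1 - epsilon & !keep)
    at <- at[comp[pairs[at, 1]] != comp[pairs[at, 2]]]
    if (!length(at)) next
    keep[at] <- TRUE
    for (k in at) {      # merge components after accepting the whole tier
      c1 <- comp[pairs[k, 1]]; c2 <- comp[pairs[k, 2]]
      comp[comp == c2] <- c1
    }
  }
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2], w = as.integer(ew[keep]))
}

mst_length <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1))
  mind <- d[, 1]
  total <- 0
  for (k in seq_len(n - 1)) {
    i <- which(!intree)[which.min(mind[!intree])]
    total <- total + mind[i]
    intree[i] <- TRUE
    mind <- pmin(mind, d[, i])
  }
  total
}

# componentwise median of three sequences; where all three states differ the
# lexicographically smallest of them is taken (cost-equivalent, deterministic)
triplet_median <- function(a, b, c) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]; vc <- strsplit(c, "")[[1]]
  paste0(ifelse(va == vb | va == vc, va, ifelse(vb == vc, vb, pmin(va, vb, vc))),
         collapse = "")
}

# character-matrix helpers for the network construction
ham_rows <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n > 1) for (i in seq_len(n - 1)) {
    s <- rowSums(m[(i + 1):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    d[i, (i + 1):n] <- s; d[(i + 1):n, i] <- s
  }
  d
}

dist_to_rows <- function(m, v) {
  as.integer(rowSums(m != matrix(v, nrow(m), ncol(m), byrow = TRUE)))
}

#' Median-joining haplotype network
#'
#' Builds the epsilon-relaxed minimum spanning network on Hamming distances
#' among the haplotypes, then repeatedly proposes median (consensus) vectors
#' of triplets that are mutually connectable in the current network -- at
#' least two of the three pairs joined by network edges -- and adds, one at a
#' time, the median that most reduces the total network length (the minimum
#' spanning tree length over the node set). Obsolete median vectors
#' (unsampled nodes of network degree < 3) are removed, and the process
#' iterates to a fixpoint. All ties are broken lexicographically by
#' sequence, so the result is independent of input order.
#'
#' @param haps a [collapse_haplotypes()] result.
#' @param epsilon non-negative integer relaxation of the spanning network
#'   (default 0).
#' @return Object of class `haplo_network`: `sequences`, `sampled` (logical;
#'   `FALSE` for median vectors), `counts` (0 for medians), `members`,
#'   `edges` (data frame `from`, `to`, `mutations`).
#' @export
median_joining <- function(haps, epsilon = 0) {
  stopifnot(inherits(haps, "haplotype_set"))
  mat <- do.call(rbind, strsplit(haps$sequences, ""))
  seqs <- haps$sequences
  sampled <- rep(TRUE, length(seqs))
  repeat {
    d <- ham_rows(mat)
    net <- msn_edges(d, epsilon)
    # prune unsampled degree-<3 nodes, worst first
    deg <- tabulate(c(net$from, net$to), nbins = length(seqs))
    drop <- which(!sampled & deg < 3)
    if (length(drop)) {
      drop <- drop[order(seqs[drop])][1]
      mat <- mat[-drop, , drop = FALSE]
      seqs <- seqs[-drop]; sampled <- sampled[-drop]
      next
    }
    if (length(seqs) >= 3) {
      adj <- matrix(FALSE, length(seqs), length(seqs))
      adj[cbind(net$from, net$to)] <- TRUE
      adj <- adj | t(adj)
      trip <- utils::combn(length(seqs), 3)
      linked <- logical(ncol(trip)); meds <- character(ncol(trip))
      for (k in seq_len(ncol(trip))) {
        va <- mat[trip[1, k], ]; vb <- mat[trip[2, k], ]; vc <- mat[trip[3, k], ]
        linked[k] <- adj[trip[1, k], trip[2, k]] + adj[trip[1, k], trip[3, k]] +
          adj[trip[2, k], trip[3, k]] >= 2
        meds[k] <- paste0(ifelse(va == vb | va == vc, va,
                                 ifelse(vb == vc, vb, pmin(va, vb, vc))),
                          collapse = "")
      }
      base_len <- mst_length(d)
      cand_rows <- function(ms) do.call(rbind, strsplit(ms, ""))
      with_cand <- function(rows) {
        d2 <- d
        for (r in seq_len(nrow(rows))) {
          dm <- c(dist_to_rows(mat, rows[r, ]),
                  if (r > 1) dist_to_rows(rows[seq_len(r - 1), , drop = FALSE],
                                          rows[r, ]))
          d2 <- rbind(cbind(d2, dm), c(dm, 0L))
        }
        d2
      }
      best_single <- function(cand) {
        best <- NULL; best_len <- base_len
        for (m in cand) {
          len <- mst_length(with_cand(cand_rows(m)))
          if (len < best_len - 1e-9) { best <- m; best_len <- len }
        }
        best
      }
      # tier 1: medians of triplets connectable in the current network
      best <- best_single(sort(setdiff(unique(meds[linked]), seqs)))
      cand_all <- sort(setdiff(unique(meds), seqs))
      # tier 2: any triplet's median (the spanning network can hide the
      # triplet that generates the useful consensus vector)
      if (is.null(best)) best <- best_single(cand_all)
      # tier 3: a median may split an edge without shortening the tree while
      # enabling a second one to shorten it; search pairs on small sets
      if (is.null(best) && length(cand_all) >= 2 && length(cand_all) <= 60) {
        best_len <- base_len
        for (i in seq_len(length(cand_all) - 1)) for (j in (i + 1):length(cand_all)) {
          len <- mst_length(with_cand(cand_rows(cand_all[c(i, j)])))
          if (len < best_len - 1e-9) { best <- cand_all[c(i, j)]; best_len <- len }
        }
        if (is.null(best) && length(cand_all) >= 3 && length(cand_all) <= 25) {
          cmb <- utils::combn(length(cand_all), 3)
          for (k in seq_len(ncol(cmb))) {
            len <- mst_length(with_cand(cand_rows(cand_all[cmb[, k]])))
            if (len < best_len - 1e-9) { best <- cand_all[cmb[, k]]; best_len <- len }
          }
        }
      }
      if (!is.null(best)) {
        mat <- rbind(mat, cand_rows(best))
        seqs <- c(seqs, best); sampled <- c(sampled, rep(FALSE, length(best)))
        next
      }
    }
    break
  }
  d <- ham_rows(mat)
  net <- msn_edges(d, epsilon)
  idx <- match(seqs, haps$sequences)
  structure(list(sequences = seqs, sampled = sampled,
                 counts = ifelse(sampled, haps$counts[idx], 0L),
                 members = lapply(seq_along(seqs), function(i)
                   if (sampled[i]) haps$members[[idx[i]]] else character(0)),
                 edges = data.frame(from = net$from, to = net$to,
                                    mutations = net$w)),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d haplotypes + %d median vectors, %d edges, total length %d\n",
              sum(x$sampled), sum(!x$sampled), nrow(x$edges), sum(x$edges$mutations)))
  invisible(x)
}

#' Convert a haplotype network to an igraph graph
#'
#' @param net a [median_joining()] result.
#' @return An \pkg{igraph} graph with vertex attributes `sequence`,
#'   `sampled`, `count` and edge attribute `mutations` (also set as
#'   `weight`).
#' @export
haplo_network_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges,
    directed = FALSE,
    vertices = data.frame(name = seq_along(net$sequences),
                          sequence = net$sequences,
                          sampled = as.integer(net$sampled),
                          count = net$counts))
  igraph::E(g)$weight <- igraph::E(g)$mutations
  g
}

#' Summary statistics of a haplotype network
#'
#' Haplotype and singleton counts, the modal (most frequent) haplotype and
#' every sampled haplotype's graph distance from it in mutations
#' (mutation-weighted shortest path).
#'
#' @param net a [median_joining()] result.
#' @return List: `n_haplotypes`, `n_singletons`, `modal` (index into
#'   `net$sequences`), `modal_count`, `distance_from_modal` (named by
#'   haplotype index, sampled haplotypes only), `max_distance`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "haplo_network"))
  g <- haplo_network_igraph(net)
  comp <- igraph::components(g)
  if (comp$no > 1) stop("network is disconnected (", comp$no, " components)")
  sampled <- which(net$sampled)
  mx <- max(net$counts[sampled])
  cands <- sampled[net$counts[sampled] == mx]
  modal <- cands[order(net$sequences[cands])][1]
  dd <- igraph::distances(g, v = as.character(modal),
                          to = as.character(sampled),
                          weights = igraph::E(g)$mutations)[1, ]
  names(dd) <- sampled
  list(n_haplotypes = length(sampled),
       n_singletons = sum(net$counts[sampled] == 1),
       modal = modal, modal_count = mx,
       distance_from_modal = dd,
       max_distance = max(dd))
}

#' Write a haplotype network as GML
#'
#' @param net a [median_joining()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_gml <- function(net, path) {
  igraph::write_graph(haplo_network_igraph(net), path, format = "gml")
  invisible(path)
}

#' Write a haplotype network as a PopArt-style NEXUS file
#'
#' Emits a TAXA block (one taxon per haplotype, named `H1`, `H2`, ...), a
#' CHARACTERS block with the haplotype sequences over the unmasked columns,
#' and a NETWORK block listing the edges with their mutation counts.
#'
#' @param net a [median_joining()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_nexus <- function(net, path) {
  n <- length(net$sequences)
  lab <- ifelse(net$sampled, paste0("H", cumsum(net$sampled)),
                paste0("mv", cumsum(!net$sampled)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN TAXA;",
               sprintf("  DIMENSIONS NTAX=%d;", n), "  TAXLABELS",
               paste0("    ", lab), "  ;", "END;", "", "BEGIN CHARACTERS;",
               sprintf("  DIMENSIONS NCHAR=%d;", nchar(net$sequences[1])),
               "  FORMAT DATATYPE=DNA MISSING=? GAP=-;", "  MATRIX"), con)
  writeLines(sprintf("    %s %s", lab, net$sequences), con)
  writeLines(c("  ;", "END;", "", "BEGIN NETWORK;",
               sprintf("  DIMENSIONS NVERTICES=%d NEDGES=%d;", n, nrow(net$edges)),
               "  EDGES"), con)
  writeLines(sprintf("    %s %s %d", lab[net$edges$from], lab[net$edges$to],
                     net$edges$mutations), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
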