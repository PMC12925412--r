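IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")

#' Read an aligned barcode FASTA with group labels
#'
#' Reads a pre-aligned mtCOI FASTA (via \pkg{ape}), uppercases the
#' sequences, validates that all records have equal length and only IUPAC
#' characters, and attaches a taxon-group label to every record.
#'
#' @param path FASTA file of aligned sequences.
#' @param group_map either a named character vector (`id -> group`), a data
#'   frame with columns `id` and `group`, or the path of a CSV with those
#'   columns. Every record id must be covered.
#' @return Object of class `barcode_alignment`: `seqs` (character matrix,
#'   records x sites), `groups` (named character), `length`.
#' @export
read_alignment <- function(path, group_map) {
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0) stop("no sequences in ", path)
  lens <- lengths(recs)
  if (length(unique(lens)) > 1) {
    bad <- names(recs)[lens != stats::median(lens)]
    stop("ragged alignment: record(s) ", paste(bad, collapse = ", "),
         " differ in length")
  }
  seqs <- toupper(do.call(rbind, as.character(recs)))
  rownames(seqs) <- names(recs)
  if (anyDuplicated(rownames(seqs)))
    stop("duplicate record ids in alignment")
  bad <- !seqs %in% IUPAC_CODES
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("illegal character '%s' in record %s",
                 seqs[i[1], i[2]], rownames(seqs)[i[1]]))
  }
  if (is.character(group_map) && length(group_map) == 1 && file.exists(group_map))
    group_map <- read.csv(group_map, stringsAsFactors = FALSE)
  if (is.data.frame(group_map))
    group_map <- setNames(as.character(group_map$group), group_map$id)
  miss <- setdiff(rownames(seqs), names(group_map))
  if (length(miss))
    stop("group_map lacks id(s): ", paste(miss, collapse = ", "))
  structure(list(seqs = seqs,
                 groups = group_map[rownames(seqs)],
                 length = ncol(seqs)),
            class = "barcode_alignment")
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("barcode_alignment: %d records x %d sites; groups: %s\n",
              nrow(x$seqs), x$length,
              paste(names(table(x$groups)), table(x$groups),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Pairwise deletion: only sites where both sequences carry an unambiguous
#' A/C/G/T are compared. With transition proportion `P` and transversion
#' proportion `Q` over the compared sites,
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, in substitutions per site.
#'
#' @param seq1,seq2 character vectors of single bases, or single strings, of
#'   equal length.
#' @return Numeric distance (substitutions/site).
#' @export
k2p_distance <- function(seq1, seq2) {
  if (length(seq1) == 1L) seq1 <- strsplit(seq1, "")[[1]]
  if (length(seq2) == 1L) seq2 <- strsplit(seq2, "")[[1]]
  if (length(seq1) != length(seq2)) stop("sequences differ in length")
  a <- toupper(seq1); b <- toupper(seq2)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0) stop("no comparable sites (pairwise deletion removed all)")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  P <- sum(diff & is_transition(a, b)) / n
  Q <- sum(diff & !is_transition(a, b)) / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined: substitution saturation (1-2P-Q or 1-2Q <= 0)")
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix
#'
#' @param aln a [read_alignment()] result.
#' @return Symmetric matrix of K2P distances (substitutions/site) with zero
#'   diagonal.
#' @export
k2p_matrix <- function(aln) {
  stopifnot(inherits(aln, "barcode_alignment"))
  n <- nrow(aln$seqs)
  d <- matrix(0, n, n, dimnames = list(rownames(aln$seqs), rownames(aln$seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- k2p_distance(aln$seqs[i, ], aln$seqs[j, ])
  d
}

#' Between-group K2P distance summary
#'
#' Mean pairwise K2P distance for every pair of groups (off-diagonal:
#' between-group means, i.e. the average over all cross-group record pairs;
#' diagonal: within-group means). Also reports the range of between-group
#' means among ingroup annotations and between each ingroup annotation and
#' the outgroup.
#'
#' @param aln a [read_alignment()] result.
#' @param outgroup group label treated as outgroup (default `"tellensis"`).
#' @return List: `between` (group x group matrix of mean distances),
#'   `ingroup_range` (`c(min, max)` of ingroup between-group means),
#'   `outgroup_range` (`c(min, max)` of ingroup-vs-outgroup means; `NA` if
#'   the outgroup is absent). Distances are substitutions/site; multiply by
#'   100 for percent.
#' @export
group_distance_summary <- function(aln, outgroup = "tellensis") {
  d <- k2p_matrix(aln)
  gs <- sort(unique(aln$groups))
  if (length(gs) < 2) stop("need at least 2 groups")
  between <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    ri <- which(aln$groups == gs[i]); rj <- which(aln$groups == gs[j])
    vals <- if (i == j) {
      if (length(ri) < 2) NA_real_ else d[ri, ri][upper.tri(d[ri, ri])]
    } else as.vector(d[ri, rj, drop = FALSE])
    between[i, j] <- mean(vals)
  }
  ing <- setdiff(gs, outgroup)
  ing_vals <- between[ing, ing, drop = FALSE][upper.tri(diag(length(ing)))]
  out_vals <- if (outgroup %in% gs) between[ing, outgroup] else NA_real_
  list(between = between,
       ingroup_range = if (length(ing_vals)) range(ing_vals) else c(NA, NA),
       outgroup_range = if (all(is.na(out_vals))) c(NA, NA) else range(out_vals))
}
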