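#' Simulate a star-shaped mtCOI barcode alignment (synthetic stand-in)
#'
#' Generates a synthetic aligned barcode dataset with the composition and
#' topology typical of a recently expanded moth population: 49 records in
#' six groups (30 `badiata_WE`, 5 `badiata_SF`, 5 `fennokarelica`,
#' 2 `kolomietsi`, 4 `asia_unassigned`, 3 `tellensis` outgroups), 18 ingroup
#' haplotypes among the 46 ingroup records of which 14 are singletons, a
#' dominant central haplotype shared across European groups, the
#' `kolomietsi` haplotype one substitution from the centre, Asian singletons
#' up to four substitutions away, and the outgroup about 2.7% divergent.
#' Four records are truncated to the short (~440 bp) fragment, so pairwise
#' deletion and column masking are exercised. This is a synthetic stand-in
#' for a real accession set, not real data.
#'
#' @param seed integer seed.
#' @param n_sites alignment length (default 658).
#' @return A `barcode_alignment` (see [read_alignment()]).
#' @export
simulate_barcodes <- function(seed = 1L, n_sites = 658L) {
  stopifnot(n_sites >= 400)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    anc <- sample(bases, n_sites, replace = TRUE)
    # substitutions live in the region shared by the short fragment
    mut_sites <- sample(260:(n_sites - 10), 60)
    ptr <- 0L
    mutate <- function(seq, k) {
      for (i in seq_len(k)) {
        ptr <<- ptr + 1L
        s <- mut_sites[ptr]
        seq[s] <- sample(setdiff(bases, seq[s]), 1)
      }
      seq
    }
    # ingroup haplotypes: counts 24/4/2 shared + kolomietsi pair + 14 singletons
    haplo <- list(central = anc,
                  sharedA = mutate(anc, 1),
                  sharedC = mutate(anc, 2),
                  kolo = mutate(anc, 1))
    singles <- lapply(c(1, 1, 1, 2, 2, 2, 1, 3, 2, 1, 4, 3, 2, 4),
                      function(k) mutate(anc, k))
    tell <- mutate(anc, 18)   # ~2.7% from the ingroup centre
    tell_var <- list(tell, mutate(tell, 1), tell)
    recs <- list(); groups <- character(0)
    add <- function(seq, group, n = 1) {
      for (i in seq_len(n)) {
        recs[[length(recs) + 1L]] <<- seq
        groups <<- c(groups, group)
      }
    }
    add(haplo$central, "badiata_WE", 18)
    add(haplo$central, "badiata_SF", 3)
    add(haplo$central, "fennokarelica", 3)
    add(haplo$sharedA, "badiata_SF", 2)
    add(haplo$sharedA, "fennokarelica", 2)
    add(haplo$sharedC, "badiata_WE", 2)
    add(haplo$kolo, "kolomietsi", 2)
    for (i in 1:9) add(singles[[i]], "badiata_WE")
    for (i in 10) add(singles[[i]], "asia_unassigned")
    add(singles[[11]], "asia_unassigned")
    add(singles[[12]], "asia_unassigned")
    add(singles[[13]], "asia_unassigned")
    add(singles[[14]], "badiata_WE")
    for (i in 1:3) add(tell_var[[i]], "tellensis")
    seqs <- do.call(rbind, recs)
    ids <- sprintf("%s_%02d", groups, stats::ave(seq_along(groups), groups,
                                                 FUN = seq_along))
    rownames(seqs) <- ids
    # four short-fragment records: leading region missing
    short <- which(groups == "badiata_WE")[1:4]
    seqs[short, 1:218] <- "-"
    structure(list(seqs = seqs, groups = setNames(groups, ids),
                   length = n_sites),
              class = "barcode_alignment")
  })
}

#' Write a barcode alignment as FASTA plus group CSV
#'
#' @param aln a `barcode_alignment`.
#' @param fasta,group_csv output paths.
#' @return Invisibly, `c(fasta, group_csv)`.
#' @export
write_alignment <- function(aln, fasta, group_csv) {
  stopifnot(inherits(aln, "barcode_alignment"))
  lines <- as.vector(rbind(paste0(">", rownames(aln$seqs)),
                           apply(aln$seqs, 1, paste0, collapse = "")))
  writeLines(lines, fasta)
  write.csv(data.frame(id = rownames(aln$seqs), group = unname(aln$groups)),
            group_csv, row.names = FALSE)
  invisible(c(fasta, group_csv))
}
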