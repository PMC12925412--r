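write_tmp_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), f)
  f
}

test_that("alignment reading validates shape, case and group coverage", {
  f <- write_tmp_fasta(c(a = "ACGTAC", b = "acgtac", c = "ACGTRN"))
  groups <- c(a = "badiata_WE", b = "fennokarelica", c = "tellensis")
  aln <- read_alignment(f, groups)
  expect_identical(nrow(aln$seqs), 3L)
  expect_identical(aln$seqs["b", ], aln$seqs["a", ])   # lowercase normalised
  expect_identical(unname(aln$groups["c"]), "tellensis")

  ragged <- write_tmp_fasta(c(a = "ACGTAC", b = "ACG"))
  expect_error(read_alignment(ragged, groups), "b")
  expect_error(read_alignment(f, groups[-2]), "b")
})

test_that("K2P matches its closed form and is zero on identical input", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  # derived: 100 sites, 2 transitions, 1 transversion
  s1 <- strrep("A", 50)
  s2 <- paste0(strrep("A", 47), "GGT")   # A->G x2 (transitions), A->T (transversion)
  base <- paste0(strrep("C", 50))
  seq1 <- paste0(s1, base); seq2 <- paste0(s2, base)
  expect_equal(k2p_distance(seq1, seq2), -0.5 * log(0.95 * sqrt(0.98)),
               tolerance = 1e-12)
  expect_equal(-0.5 * log(0.95 * sqrt(0.98)), 0.0306973, tolerance = 1e-6)
})

test_that("K2P uses pairwise deletion and reports undefined distances", {
  # gaps and ambiguities are excluded site-by-site
  expect_equal(k2p_distance("ACG-", "ACGT"), 0)
  expect_equal(k2p_distance("NCGT", "ACGT"), 0)
  expect_error(k2p_distance("----", "ACGT"), "comparable")
  # saturation: P large enough that 1 - 2P - Q <= 0
  a <- strrep("A", 10); g <- strrep("G", 10)
  expect_error(k2p_distance(a, g), "saturation")
})

test_that("K2P matrix agrees with the ape oracle and dominates p-distance", {
  aln <- simulate_barcodes(3)
  d <- k2p_matrix(aln)
  oracle <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(aln$seqs)),
                                    model = "K80", pairwise.deletion = TRUE))
  expect_equal(max(abs(d - oracle)), 0, tolerance = 1e-9)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # K >= p-distance over random pairs in the valid domain
  set.seed(10)
  for (i in 1:20) {
    n <- 200
    s1 <- sample(c("A", "C", "G", "T"), n, TRUE)
    s2 <- s1
    mut <- sample(n, 12)
    s2[mut] <- vapply(s2[mut],
                      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                      character(1))
    p <- mean(s1 != s2)
    expect_gte(k2p_distance(s1, s2), p - 1e-12)
  }
})

test_that("group summary equals the brute-force double loop", {
  aln <- simulate_barcodes(4)
  gs <- group_distance_summary(aln)
  d <- k2p_matrix(aln)
  groups <- aln$groups
  for (g1 in rownames(gs$between)) for (g2 in colnames(gs$between)) {
    if (g1 == g2) next
    vals <- c()
    for (i in which(groups == g1)) for (j in which(groups == g2))
      vals <- c(vals, d[i, j])
    expect_equal(gs$between[g1, g2], mean(vals), tolerance = 1e-12)
  }
  ing <- setdiff(rownames(gs$between), "tellensis")
  sub <- gs$between[ing, ing][upper.tri(diag(length(ing)))]
  expect_equal(gs$ingroup_range, range(sub))
})

test_that("two clone groups one substitution apart give the single-pair K2P", {
  f <- write_tmp_fasta(c(a1 = strrep("A", 50), a2 = strrep("A", 50),
                         b1 = paste0("G", strrep("A", 49))))
  aln <- read_alignment(f, c(a1 = "g1", a2 = "g1", b1 = "g2"))
  gs <- group_distance_summary(aln, outgroup = "none_present")
  expect_equal(gs$between["g1", "g1"], 0)
  expect_equal(gs$between["g1", "g2"], k2p_distance(strrep("A", 50),
                                                    paste0("G", strrep("A", 49))),
               tolerance = 1e-12)
})

test_that("the synthetic barcode world has its designed structure", {
  aln <- simulate_barcodes(1)
  expect_identical(nrow(aln$seqs), 49L)
  expect_identical(unname(table(aln$groups)["tellensis"]), 3L)
  gs <- group_distance_summary(aln)
  expect_gt(100 * gs$outgroup_range[1], 2)       # clearly divergent outgroup
  expect_lt(100 * gs$ingroup_range[2], 1)        # shallow ingroup
  haps <- collapse_haplotypes(aln)
  expect_identical(length(haps$sequences), 18L)
  expect_identical(sum(haps$counts), 46L)
  expect_identical(sum(haps$counts == 1), 14L)
})
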