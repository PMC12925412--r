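make_aln <- function(seqs, groups) {
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  structure(list(seqs = m, groups = setNames(groups, names(seqs)),
                 length = ncol(m)),
            class = "barcode_alignment")
}

test_that("haplotype collapsing masks dirty columns and conserves counts", {
  aln <- make_aln(c(r1 = "AAA", r2 = "AAA", r3 = "AAT"), rep("g", 3))
  h <- collapse_haplotypes(aln, exclude_groups = character(0))
  expect_identical(length(h$sequences), 2L)
  expect_identical(h$counts, c(2L, 1L))
  expect_identical(sum(h$counts == 1), 1L)

  aln2 <- make_aln(c(r1 = "AA-", r2 = "AAT"), rep("g", 2))
  h2 <- collapse_haplotypes(aln2, exclude_groups = character(0))
  expect_identical(h2$kept_columns, 1:2)
  expect_identical(length(h2$sequences), 1L)
  expect_identical(h2$counts, 2L)

  # record order never changes the partition
  aln3 <- make_aln(c(r3 = "AAT", r1 = "AAA", r2 = "AAA"), rep("g", 3))
  h3 <- collapse_haplotypes(aln3, exclude_groups = character(0))
  expect_identical(h3$sequences, h$sequences)
  expect_identical(h3$counts, h$counts)

  expect_error(collapse_haplotypes(make_aln(c(a = "N-", b = "A-"), rep("g", 2)),
                                   character(0)), "masked")
})

test_that("median joining solves the canonical chain, star and singleton", {
  chain <- median_joining(toy_haps(c("000", "100", "110")))
  expect_identical(length(chain$sequences), 3L)
  expect_identical(sum(!chain$sampled), 0L)
  expect_identical(sum(chain$edges$mutations), 2L)

  star <- median_joining(toy_haps(c("100", "010", "001")))
  expect_identical(sum(!star$sampled), 1L)
  expect_identical(star$sequences[!star$sampled], "000")
  expect_identical(sum(star$edges$mutations), 3L)
  # the median vector has degree 3
  g <- haplo_network_igraph(star)
  deg <- igraph::degree(g)[as.character(which(!star$sampled))]
  expect_gte(unname(deg), 3)

  single <- median_joining(toy_haps("0101"))
  expect_identical(length(single$sequences), 1L)
  expect_identical(nrow(single$edges), 0L)
})

test_that("median joining is deterministic under input permutation", {
  strs <- c("0000", "1000", "1100", "0011", "0111")
  a <- median_joining(toy_haps(strs))
  b <- median_joining(toy_haps(rev(strs)))
  expect_identical(sort(a$sequences), sort(b$sequences))
  expect_identical(sum(a$edges$mutations), sum(b$edges$mutations))
})

test_that("every median strictly shortened the network and MSN is kept", {
  set.seed(12)
  for (i in 1:10) {
    strs <- star_instance(sample(5:8, 1), sample(3:6, 1), runif(1) < 0.5)
    if (length(strs) < 2) next
    net <- median_joining(toy_haps(strs))
    base <- mst_length_oracle(ham_matrix_oracle(strs))
    final <- mst_length_oracle(ham_matrix_oracle(net$sequences))
    if (sum(!net$sampled) > 0) expect_lt(final, base) else expect_equal(final, base)
    # edge weights are the Hamming distances of their endpoints
    for (k in seq_len(nrow(net$edges)))
      expect_identical(net$edges$mutations[k],
                       ham_oracle(net$sequences[net$edges$from[k]],
                                  net$sequences[net$edges$to[k]]))
    # connected
    g <- haplo_network_igraph(net)
    expect_equal(igraph::components(g)$no, 1)
  }
})

test_that("network statistics match brute-force shortest paths", {
  # chain A(3) - B(1) - C(1): modal A, distance C -> A = 2
  chain <- median_joining(toy_haps(c("00", "10", "11"), counts = c(3L, 1L, 1L)))
  st <- network_stats(chain)
  expect_identical(st$n_haplotypes, 3L)
  expect_identical(st$modal_count, 3L)
  expect_identical(net_seq <- chain$sequences[st$modal], "00")
  expect_equal(max(st$distance_from_modal), 2)

  # star of 5 leaves, one mutation each, around a sampled centre
  strs <- c("00000", "10000", "01000", "00100", "00010")
  star <- median_joining(toy_haps(strs, counts = c(5L, 1L, 1L, 1L, 1L)))
  st2 <- network_stats(star)
  leaf <- setdiff(seq_along(star$sequences), st2$modal)
  expect_true(all(st2$distance_from_modal[as.character(leaf)] == 1))
  expect_identical(st2$n_singletons, 4L)

  # oracle equivalence on a mixed network: Dijkstra vs dense Floyd-Warshall
  net <- median_joining(toy_haps(c("0000", "1100", "0011", "1111", "1000")))
  sts <- network_stats(net)
  n <- length(net$sequences)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in seq_len(nrow(net$edges))) {
    D[net$edges$from[k], net$edges$to[k]] <- net$edges$mutations[k]
    D[net$edges$to[k], net$edges$from[k]] <- net$edges$mutations[k]
  }
  for (m in 1:n) for (i in 1:n) for (j in 1:n)
    D[i, j] <- min(D[i, j], D[i, m] + D[m, j])
  expect_equal(unname(sts$distance_from_modal),
               unname(D[sts$modal, which(net$sampled)]))
})

test_that("network exports are well-formed text files", {
  net <- median_joining(toy_haps(c("100", "010", "001")))
  gml <- tempfile(fileext = ".gml"); nex <- tempfile(fileext = ".nex")
  write_network_gml(net, gml)
  write_network_nexus(net, nex)
  g2 <- igraph::read_graph(gml, format = "gml")
  expect_equal(igraph::gorder(g2), 4)
  lines <- readLines(nex)
  expect_identical(lines[1], "#NEXUS")
  expect_true(any(grepl("BEGIN NETWORK;", lines)))
  expect_true(any(grepl("^    H1 ", lines)))
})
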