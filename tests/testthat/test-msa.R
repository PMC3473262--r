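test_that("low-complexity masking replaces long single-residue runs", {
  s <- paste0("HDS", strrep("A", 12), "KLM")
  expect_equal(mask_low_complexity(s, 10),
               paste0("HDS", strrep("X", 12), "KLM"))
  s9 <- paste0("HDS", strrep("A", 9), "KLM")
  expect_equal(mask_low_complexity(s9, 10), s9)
  expect_equal(mask_low_complexity("HDSKLM", 10), "HDSKLM")
  expect_error(mask_low_complexity("AAA", 1), "min_run")
})

test_that("pairwise alignment scores are optimal and symmetric", {
  m <- blosum62_matrix()
  expect_equal(global_affine_align("AAA", "AAA")$score, 12)
  expect_equal(global_affine_align("AA", "A", g = gap_penalties(5, 1))$score,
               -2)
  set.seed(101)
  for (i in 1:12) {
    a <- random_peptide(sample(1:4, 1))
    b <- random_peptide(sample(1:4, 1))
    g <- gap_penalties(sample(3:10, 1), sample(1:3, 1))
    got <- global_affine_align(a, b, m, g)
    expect_equal(got$score, enum_align_score(a, b, m, g),
                 info = paste(a, b))
    expect_equal(global_affine_align(b, a, m, g)$score, got$score)
    # de-gapped alignment rows reproduce the inputs
    expect_equal(gsub("-", "", got$a, fixed = TRUE), a)
    expect_equal(gsub("-", "", got$b, fixed = TRUE), b)
  }
  # X is neutral
  expect_equal(global_affine_align("AXA", "AAA")$score, 8)
})

test_that("guide trees equal neighbour joining on alignment distances", {
  set.seed(5)
  seqs <- setNames(vapply(rep(30, 4), random_peptide, ""),
                   paste0("s", 1:4))
  m <- blosum62_matrix(); g <- gap_penalties()
  D <- matrix(0, 4, 4, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:3) for (j in (i + 1):4) {
    aln <- global_affine_align(seqs[[i]], seqs[[j]], m, g)
    av <- strsplit(aln$a, "")[[1]]; bv <- strsplit(aln$b, "")[[1]]
    ok <- av != "-" & bv != "-"
    D[i, j] <- D[j, i] <- 1 - mean(av[ok] == bv[ok])
  }
  expect_equal(rf_distance(build_guide_tree(seqs, m, g),
                           neighbor_joining(D)), 0L)
  expect_error(build_guide_tree(seqs[1]), "at least 2")
  # three sequences give the unique unrooted topology
  expect_s3_class(build_guide_tree(seqs[1:3], m, g), "phylo")
})

test_that("progressive alignment degenerates to pairwise and conserves rows", {
  m <- blosum62_matrix(); g <- gap_penalties()
  set.seed(21)
  two <- setNames(c(random_peptide(25), random_peptide(30)), c("a", "b"))
  pw <- global_affine_align(two[["a"]], two[["b"]], m, g)
  pa <- progressive_align(two, m = m, g = g)
  expect_equal(degap(pa, "a"), two[["a"]])
  expect_equal(unname(apply(unclass(pa)[c("a", "b"), ], 1, paste,
                            collapse = "")), c(pw$a, pw$b))

  dup <- setNames(c(two[["a"]], two[["a"]], two[["b"]]), c("x", "y", "z"))
  pd <- progressive_align(dup, m = m, g = g)
  expect_equal(unclass(pd)["x", ], unclass(pd)["y", ])

  for (seed in 1:3) {
    set.seed(seed)
    seqs <- setNames(vapply(sample(20:40, 5, replace = TRUE),
                            random_peptide, ""), paste0("t", 1:5))
    a <- progressive_align(seqs, m = m, g = g)
    expect_gte(ncol(a), max(nchar(seqs)))
    for (id in names(seqs)) expect_equal(degap(a, id), seqs[[id]])
  }
})

test_that("consensus keeps exactly the columns agreed by every run", {
  a1 <- deg_msa(c(r1 = "AC-DE", r2 = "ACKDE", r3 = "AC-DE"))
  expect_equal(unclass(consensus_merge(list(a1, a1, a1))), unclass(a1))

  # two alignments of the same sequences with partially different homology
  b1 <- deg_msa(c(r1 = "AD-E", r2 = "ADKE"))
  b2 <- deg_msa(c(r1 = "ADE-", r2 = "ADKE"))
  got <- consensus_merge(list(b1, b2))
  # brute-force signature agreement oracle
  sig <- function(a) {
    M <- unclass(a)
    idx <- t(apply(M != "-", 1, cumsum))
    vapply(seq_len(ncol(M)), function(j) {
      r <- which(M[, j] != "-")
      paste(rownames(M)[r], idx[r, j], collapse = "|")
    }, "")
  }
  keep <- sig(b1) %in% sig(b2)
  expect_equal(unclass(got), unclass(b1)[, keep, drop = FALSE])
  expect_equal(ncol(got), 2L)   # the K-column homology differs between runs

  c1 <- deg_msa(c(r1 = "AB-", r2 = "-AB"))   # no shared residue columns
  c2 <- deg_msa(c(r1 = "-AB", r2 = "AB-"))
  expect_error(consensus_merge(list(c1, c2)), "shared")

  d2 <- deg_msa(c(r1 = "AD-E", rX = "ADKE"))
  expect_error(consensus_merge(list(b1, d2)), "row sets")
})

test_that("consensus columns are homology subsets of every input", {
  set.seed(31)
  seqs <- setNames(vapply(c(30, 32, 28), random_peptide, ""),
                   paste0("q", 1:3))
  runs <- list(progressive_align(seqs, g = gap_penalties(10, 1)),
               progressive_align(seqs, g = gap_penalties(4, 2)))
  cons <- consensus_merge(runs)
  sig <- function(a) {
    M <- unclass(a)[names(seqs), , drop = FALSE]
    idx <- t(apply(M != "-", 1, cumsum))
    vapply(seq_len(ncol(M)), function(j) {
      r <- which(M[, j] != "-")
      paste(names(seqs)[r], idx[r, j], collapse = "|")
    }, "")
  }
  for (r in runs) expect_true(all(sig(cons) %in% sig(r)))
})

test_that("gap-column stripping follows the configured threshold", {
  a <- deg_msa(c(r1 = "ACDE", r2 = "ACDE", r3 = "ACDE", r4 = "ACDE"))
  expect_equal(unclass(strip_gap_columns(a)), unclass(a),
               ignore_attr = TRUE)

  b <- deg_msa(c(r1 = "AC-E", r2 = "ACDE", r3 = "ACDE", r4 = "ACDE"))
  sb <- strip_gap_columns(b)
  expect_equal(ncol(sb), 3L)
  expect_equal(attr(sb, "kept_columns"), c(1L, 2L, 4L))

  c4 <- deg_msa(c(r1 = "A--E", r2 = "AC-E", r3 = "ACDE", r4 = "AC-E"))
  sc <- strip_gap_columns(c4, max_gap_frac = 0.5)
  gap_frac <- colMeans(unclass(c4) == "-")
  expect_equal(attr(sc, "kept_columns"), which(gap_frac <= 0.5))
})

test_that("alignments round-trip through FASTA and relaxed PHYLIP", {
  a <- deg_msa(c(s1 = "AC-DE", s2 = "ACKDE"))
  for (fmt in c("fasta", "phylip")) {
    p <- withr::local_tempfile()
    write_alignment(a, p, fmt)
    expect_equal(unclass(read_alignment(p, fmt)), unclass(a))
  }
})
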