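test_that("FASTA reading enforces the alignment contract", {
  p <- write_tmp_fasta(c("acgu", "ACGA"))
  a <- read_fasta_alignment(p)
  expect_s3_class(a, "dna_alignment")
  expect_equal(n_seq(a), 2L)
  expect_equal(n_sites(a), 4L)
  # lowercasing and U -> T
  expect_equal(unname(a$mat[1, ]), c("A", "C", "G", "T"))

  expect_error(read_fasta_alignment(write_tmp_fasta(c("ACGT", "ACG"))),
               "ragged alignment")
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(read_fasta_alignment(empty), "input error")
  expect_error(read_fasta_alignment(tempfile()), "not found")
  expect_error(dna_alignment(c("ACXT", "ACGT")), "non-IUPAC symbol 'X'")
  expect_error(dna_alignment(c("AC", "GT"), ids = c("a", "a")), "duplicated")
})

test_that("study-scale shape contract holds (98 x 16038)", {
  seqs <- rep(strrep("ACGT", 16038 / 2), 98) # 32076-char template
  seqs <- substr(seqs, 1, 16038)
  p <- write_tmp_fasta(seqs, ids = sprintf("LC%06d", seq_len(98)))
  a <- read_fasta_alignment(p)
  expect_equal(n_seq(a), 98L)
  expect_equal(n_sites(a), 16038L)
})

test_that("clean_columns implements both policies and is idempotent", {
  a <- aln("A-G", "AAG")
  cg <- clean_columns(a, "drop-gap-columns")
  expect_equal(n_sites(cg), 2L)
  expect_equal(attr(cg, "retained"), c(1L, 3L))

  b <- aln("ANG", "AAG")
  expect_equal(n_sites(clean_columns(b, "drop-gap-columns")), 3L)
  expect_equal(n_sites(clean_columns(b, "drop-gap-or-ambiguous-columns")), 2L)

  gapfree <- aln("ACGT", "ACGA")
  expect_equal(clean_columns(gapfree)$mat, gapfree$mat)

  twice <- clean_columns(clean_columns(a))
  expect_equal(twice$mat, cg$mat)
  expect_lte(n_sites(cg), n_sites(a))

  expect_error(clean_columns(aln("--", "AA")), "degenerate")
})

test_that("collapse_haplotypes preserves multiplicities and order", {
  h <- collapse_haplotypes(aln("AAA", "AAA", "AAT"))
  expect_equal(h$H, 2L)
  expect_equal(h$multiplicity, c(2L, 1L))
  expect_equal(collapse_haplotypes(aln("AA", "AA", "AA", "AA", "AA"))$H, 1L)
  expect_equal(collapse_haplotypes(aln("AA", "AT", "TA", "TT"))$H, 4L)
  # property: multiplicities always sum to n
  for (seed in 1:10) {
    a <- random_alignment(n = sample(2:12, 1), L = 5, seed = seed)
    h <- collapse_haplotypes(a)
    expect_equal(sum(h$multiplicity), n_seq(a))
    expect_lte(h$H, n_seq(a))
  }
})

test_that("pairwise_differences matches examples and the naive oracle", {
  expect_equal(pairwise_differences(aln("AAA", "AAT"))$d[1, 2], 1L)

  pd <- pairwise_differences(aln("AAN", "AAT"), "pairwise-deletion")
  expect_equal(pd$d[1, 2], 0L)
  expect_equal(pd$eff[1, 2], 2L)

  pd3 <- pairwise_differences(aln("AAAA", "AATT", "ATTT"))
  expect_equal(pd3$d[1, 2], 2L)
  expect_equal(pd3$d[1, 3], 3L)
  expect_equal(pd3$d[2, 3], 1L)

  expect_error(pairwise_differences(aln("AAA")), "insufficient sample")

  # oracle equivalence and permutation invariance on small random cases
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(2:6, 1); L <- sample(5:20, 1)
    chars <- sample(c("A", "C", "G", "T", "N", "-"), n * L, replace = TRUE,
                    prob = c(rep(0.22, 4), 0.06, 0.06))
    a <- dna_alignment(apply(matrix(chars, n, L), 1, paste0, collapse = ""))
    for (pol in c("pairwise-deletion", "complete-deletion")) {
      d <- pairwise_differences(a, pol)$d
      expect_equal(unname(d), naive_pair_diffs(a, pol))
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
    }
    perm <- sample(n)
    ap <- dna_alignment(apply(a$mat, 1, paste0, collapse = "")[perm],
                        ids = a$ids[perm])
    expect_equal(unname(pairwise_differences(ap)$d),
                 unname(pairwise_differences(a)$d[perm, perm]))
  }
})

test_that("subset_by_group restricts rows and errors usefully", {
  a <- aln("AA", "AT", "TA", "TT", "CC")
  g <- data.frame(sample_id = a$ids,
                  group = c("MUS", "MUS", "MUS", "CAS", "CAS"))
  expect_equal(n_seq(subset_by_group(a, g, "MUS")), 3L)
  expect_error(subset_by_group(a, g, "X"), "key error")
  g1 <- data.frame(sample_id = a$ids, group = "ALL")
  expect_equal(subset_by_group(a, g1, "ALL")$mat, a$mat)
})

test_that("group metadata reader validates its schema", {
  p <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = c("a", "b"), group = c("g1", "g2"),
                         locality = c("x", "y")),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- read_group_table(p)
  expect_named(g, c("sample_id", "group", "locality"))
  write.table(data.frame(sample_id = c("a", "a"), group = "g"),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_group_table(p), "duplicated")
  write.table(data.frame(id = "a"), p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_group_table(p), "mandatory")
})
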