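# Shared fixture builders; everything is generated in code at test time.

aln <- function(..., ids = NULL) {
  seqs <- c(...)
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  dna_alignment(seqs, ids = ids)
}

write_tmp_fasta <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

random_alignment <- function(n, L, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  dna_alignment(apply(m, 1L, paste0, collapse = ""))
}

# naive per-site difference counter, the independent oracle for
# pairwise_differences()
naive_pair_diffs <- function(a, policy = "pairwise-deletion") {
  n <- n_seq(a)
  good <- function(x) x %in% c("A", "C", "G", "T")
  if (policy == "complete-deletion") {
    keep <- apply(a$mat, 2, function(col) all(good(col)))
    mat <- a$mat[, keep, drop = FALSE]
  } else mat <- a$mat
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- good(mat[i, ]) & good(mat[j, ])
    d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok])
  }
  d
}

# star alignment: a central haplotype (repeated `center_mult` times) plus
# `n_leaves` singletons each carrying one private mutation
star_alignment <- function(n_leaves = 5, L = max(8, n_leaves), center_mult = 3) {
  center <- strrep("A", L)
  leaves <- vapply(seq_len(n_leaves), function(i) {
    s <- strsplit(center, "")[[1]]
    s[i] <- "T"
    paste0(s, collapse = "")
  }, character(1))
  dna_alignment(c(rep(center, center_mult), leaves))
}
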