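# Alignment container and column-level utilities.
#
# Sequences are stored as an n x L character matrix over the IUPAC DNA
# alphabet; only unambiguous bases (A/C/G/T) contribute to statistics.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")
UNAMBIGUOUS <- c("A", "C", "G", "T")

#' DNA alignment object
#'
#' Build a rectangular haploid alignment from a character vector of
#' sequences. Residues are uppercased and `U` is mapped to `T`. Every row
#' must have the same number of columns and ids must be unique.
#'
#' @param seqs character vector of equal-length sequence strings.
#' @param ids sample identifiers; defaults to `names(seqs)`.
#' @return an object of class `dna_alignment` with fields `ids` (character)
#'   and `mat` (n x L character matrix, rownames = ids).
#' @export
dna_alignment <- function(seqs, ids = names(seqs)) {
  if (length(seqs) < 1L) stop("input error: alignment needs at least one sequence")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("input error: duplicated sequence ids")
  seqs <- toupper(as.character(seqs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths differ (", paste(unique(lens), collapse = ", "), ")")
  L <- lens[[1L]]
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), ncol = L, byrow = TRUE,
                dimnames = list(ids, NULL))
  bad <- !(mat %in% IUPAC_DNA)
  if (any(bad)) {
    idx <- which(bad)[1L]
    r <- (idx - 1L) %% nrow(mat) + 1L
    cc <- (idx - 1L) %/% nrow(mat) + 1L
    stop(sprintf("input error: non-IUPAC symbol '%s' in sequence '%s' at column %d",
                 mat[r, cc], ids[r], cc))
  }
  structure(list(ids = ids, mat = mat), class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("dna_alignment: %d sequences x %d columns\n", n_seq(x), n_sites(x)))
  invisible(x)
}

#' Number of sequences / columns of an alignment
#' @param a a `dna_alignment`.
#' @return integer count.
#' @export
n_seq <- function(a) nrow(a$mat)

#' @rdname n_seq
#' @export
n_sites <- function(a) ncol(a$mat)

#' Read a FASTA alignment
#'
#' Reads a multi-FASTA file into a [dna_alignment()]. Records must all have
#' the same length (an aligned matrix); ids are taken from the FASTA headers
#' (first whitespace-delimited token).
#'
#' @param path path to a FASTA file.
#' @return a `dna_alignment`.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("input error: cannot parse FASTA: ",
                                          conditionMessage(e)))
  if (length(ss) == 0L) stop("input error: empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dna_alignment(as.character(ss), ids = ids)
}

#' Write an alignment to FASTA
#' @param a a `dna_alignment`.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(a, path, width = 70L) {
  seqs <- apply(a$mat, 1L, paste0, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", a$ids[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated file with mandatory columns `sample_id` and `group`;
#' further columns (e.g. locality) are carried through untouched.
#'
#' @param path path to a TSV file.
#' @return a data.frame with at least `sample_id` and `group`.
#' @export
read_group_table <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  g <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("input error: metadata lacks mandatory column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(g$sample_id))
    stop("input error: duplicated sample_id in metadata (each id maps to exactly one group)")
  g
}

#' Remove gap (and optionally ambiguous) columns
#'
#' Keeps only columns where no row carries `-` (policy
#' `"drop-gap-columns"`), or additionally where no row carries `N` or any
#' IUPAC ambiguity code (policy `"drop-gap-or-ambiguous-columns"`). The
#' retained original column indices (1-based) are attached as attribute
#' `"retained"`.
#'
#' @param a a `dna_alignment`.
#' @param policy column-removal policy.
#' @return a cleaned `dna_alignment` with attribute `retained`.
#' @export
clean_columns <- function(a,
                          policy = c("drop-gap-columns",
                                     "drop-gap-or-ambiguous-columns")) {
  policy <- match.arg(policy)
  drop_syms <- if (policy == "drop-gap-columns") "-" else setdiff(IUPAC_DNA, UNAMBIGUOUS)
  bad_col <- apply(matrix(a$mat %in% drop_syms, nrow = nrow(a$mat)), 2L, any)
  keep <- which(!bad_col)
  if (length(keep) == 0L)
    stop("degenerate output: all columns removed by policy '", policy, "'")
  out <- structure(list(ids = a$ids, mat = a$mat[, keep, drop = FALSE]),
                   class = "dna_alignment")
  attr(out, "retained") <- keep
  out
}

#' Write the retained-column report of [clean_columns()]
#' @param a a cleaned alignment carrying attribute `retained`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_retained_report <- function(a, path) {
  keep <- attr(a, "retained")
  if (is.null(keep)) keep <- seq_len(n_sites(a))
  utils::write.table(data.frame(retained_column = keep),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse identical sequences into haplotypes
#'
#' Exact-match collapse preserving first-occurrence order. Row order of the
#' input determines haplotype numbering; members lists the sample ids
#' carrying each haplotype.
#'
#' @param a a `dna_alignment`.
#' @return an object of class `haplotype_set`: fields `seqs` (H x L
#'   character matrix), `ids` (representative sample id per haplotype),
#'   `multiplicity`, `members` (list of id vectors), `n`, `H`.
#' @export
collapse_haplotypes <- function(a) {
  key <- apply(a$mat, 1L, paste0, collapse = "")
  first <- !duplicated(key)
  uk <- key[first]
  idx <- match(key, uk)
  members <- split(a$ids, idx)
  members <- members[order(as.integer(names(members)))]
  structure(list(
    seqs = a$mat[first, , drop = FALSE],
    ids = a$ids[first],
    multiplicity = as.integer(tabulate(idx, nbins = length(uk))),
    members = unname(members),
    n = n_seq(a),
    H = length(uk)
  ), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: H=%d haplotypes from n=%d samples\n", x$H, x$n))
  invisible(x)
}

# integer base codes: A=1 C=2 G=3 T=4, anything else NA (gap/N/ambiguity
# treated as missing -- ambiguity codes never count as partial matches)
.base_codes <- function(mat) {
  structure(match(mat, UNAMBIGUOUS), dim = dim(mat))
}

#' Pairwise nucleotide difference matrix
#'
#' Counts, for every pair of rows, sites at which both carry differing
#' unambiguous bases. Under `"pairwise-deletion"` (default; DnaSP
#' convention) sites with a gap/N/ambiguity in either member are excluded
#' for that pair only; under `"complete-deletion"` any column with a
#' missing symbol in any row is dropped for all pairs.
#'
#' @param a a `dna_alignment` with `n >= 2`.
#' @param missing_policy `"pairwise-deletion"` or `"complete-deletion"`.
#' @return an object of class `pairwise_diffs`: `d` (n x n integer
#'   difference matrix), `eff` (n x n effective-site counts), `policy`.
#' @export
pairwise_differences <- function(a,
                                 missing_policy = c("pairwise-deletion",
                                                    "complete-deletion")) {
  missing_policy <- match.arg(missing_policy)
  if (n_seq(a) < 2L) stop("insufficient sample: need n >= 2 sequences")
  code <- .base_codes(a$mat)
  if (missing_policy == "complete-deletion") {
    keep <- !apply(is.na(code), 2L, any)
    code <- code[, keep, drop = FALSE]
  }
  valid <- !is.na(code)
  eff <- tcrossprod(valid * 1)
  match_ct <- matrix(0, nrow(code), nrow(code))
  for (b in 1:4) {
    ind <- (valid & code == b & !is.na(code)) * 1
    match_ct <- match_ct + tcrossprod(ind)
  }
  d <- eff - match_ct
  diag(d) <- 0
  storage.mode(d) <- "integer"
  storage.mode(eff) <- "integer"
  dimnames(d) <- dimnames(eff) <- list(a$ids, a$ids)
  structure(list(d = d, eff = eff, policy = missing_policy),
            class = "pairwise_diffs")
}

#' @export
print.pairwise_diffs <- function(x, ...) {
  cat(sprintf("pairwise_diffs: %d sequences, policy=%s, mean diff=%.3f\n",
              nrow(x$d), x$policy, mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Subset an alignment by group label
#'
#' @param a a `dna_alignment`.
#' @param g metadata data.frame from [read_group_table()].
#' @param label group label to keep.
#' @return a `dna_alignment` restricted to samples with that label,
#'   original row order preserved.
#' @export
subset_by_group <- function(a, g, label) {
  if (!label %in% g$group)
    stop("key error: group label not found in metadata: '", label, "'")
  want <- g$sample_id[g$group == label]
  keep <- a$ids %in% want
  if (!any(keep))
    stop("degenerate output: no alignment rows carry group '", label, "'")
  structure(list(ids = a$ids[keep], mat = a$mat[keep, , drop = FALSE]),
            class = "dna_alignment")
}
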