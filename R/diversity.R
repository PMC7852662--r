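# Per-group diversity statistics: the Table-1-style summary row.

#' Diversity summary for one alignment
#'
#' Computes the classical per-group summary: sample size `n`, haplotype
#' count `H`, haplotype diversity `Hd` (sample-size-corrected,
#' `(n/(n-1)) * (1 - sum(p_i^2))`), segregating sites `S` (columns with at
#' least two distinct unambiguous bases; columns varying only in gaps or
#' ambiguity codes do not count), nucleotide diversity `Pi` as a percent
#' (100 x mean per-pair differences / effective sites), and `K`, the mean
#' number of pairwise nucleotide differences.
#'
#' @param a a `dna_alignment` with `n >= 2`.
#' @param missing_policy passed to [pairwise_differences()].
#' @return object of class `diversity_summary` (a one-row data.frame with
#'   columns `n, H, Hd, S, Pi_percent, K`).
#' @export
summarize_diversity <- function(a,
                                missing_policy = c("pairwise-deletion",
                                                   "complete-deletion")) {
  missing_policy <- match.arg(missing_policy)
  n <- n_seq(a)
  if (n < 2L) stop("insufficient sample: need n >= 2 sequences")
  pd <- pairwise_differences(a, missing_policy)
  ut <- upper.tri(pd$d)
  K <- mean(pd$d[ut])
  eff <- pd$eff[ut]
  if (any(eff == 0))
    stop("degenerate output: some pairs share no effective sites")
  Pi <- 100 * mean(pd$d[ut] / eff)
  S <- count_segregating_sites(a)
  hs <- collapse_haplotypes(a)
  p <- hs$multiplicity / n
  Hd <- (n / (n - 1)) * (1 - sum(p^2))
  out <- data.frame(n = n, H = hs$H, Hd = Hd, S = S, Pi_percent = Pi, K = K)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' Count segregating sites
#'
#' Columns carrying two or more distinct unambiguous bases.
#' @param a a `dna_alignment`.
#' @return integer count.
#' @export
count_segregating_sites <- function(a) {
  code <- .base_codes(a$mat)
  seg <- apply(code, 2L, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) >= 2L
  })
  sum(seg)
}

#' Diversity table over groups
#'
#' One [summarize_diversity()] row per group label; groups with fewer than
#' two samples are skipped with a message.
#'
#' @param a a cleaned `dna_alignment`.
#' @param g metadata data.frame (`sample_id`, `group`).
#' @param missing_policy passed through.
#' @return data.frame with columns `group, n, H, Hd, S, Pi_percent, K`.
#' @export
diversity_table <- function(a, g, missing_policy = "pairwise-deletion") {
  labs <- unique(g$group[g$sample_id %in% a$ids])
  rows <- list()
  for (lab in labs) {
    sub <- subset_by_group(a, g, lab)
    if (n_seq(sub) < 2L) {
      message("skipping group '", lab, "': insufficient-sample (n=", n_seq(sub), ")")
      next
    }
    r <- summarize_diversity(sub, missing_policy)
    rows[[lab]] <- cbind(data.frame(group = lab), as.data.frame(r))
  }
  if (!length(rows)) stop("degenerate output: no group has n >= 2")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a diversity table as TSV
#' @param tab data.frame from [diversity_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diversity_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
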