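# Neutrality tests: Tajima's D and Fu's Fs, with coalescent-null p-values.
#
# Both statistics are computed from summary quantities (n, S, K, H) so the
# null distribution can be simulated at the genealogy level without
# materialising sequences.

# Tajima (1989) constants and statistic from (n, S, K).
.tajima_d_stat <- function(n, S, K) {
  if (n < 4L) stop("insufficient sample: Tajima's D needs n >= 4")
  if (S < 1L) stop("undefined statistic: Tajima's D requires S >= 1")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a2 + a1^2)
  (K - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Normalised difference between the pairwise (`K`) and segregating-site
#' (`S/a1`) estimators of theta. Negative values indicate an excess of rare
#' variants, the signature of recent population expansion.
#'
#' @param a a `dna_alignment` with `n >= 4` and at least one segregating
#'   site.
#' @param missing_policy passed to [pairwise_differences()].
#' @return numeric statistic.
#' @export
tajimas_d <- function(a, missing_policy = "pairwise-deletion") {
  n <- n_seq(a)
  S <- count_segregating_sites(a)
  pd <- pairwise_differences(a, missing_policy)
  K <- mean(pd$d[upper.tri(pd$d)])
  .tajima_d_stat(n, S, K)
}

#' Ewens allele-count probabilities
#'
#' Probability of observing `h = 1..n` distinct alleles in a sample of `n`
#' under the Ewens sampling distribution with parameter `theta`:
#' `Pr(H = h) = |S(n,h)| theta^h / (theta)_(n)` with unsigned Stirling
#' numbers of the first kind and the rising factorial. Computed by the
#' numerically stable sequential (Chinese-restaurant) recurrence
#' `P(n+1, h) = P(n, h) n/(theta+n) + P(n, h-1) theta/(theta+n)`, which
#' avoids overflow for large `n`.
#'
#' @param n sample size (`>= 1`).
#' @param theta positive scaled mutation rate.
#' @return numeric vector of length `n` summing to 1; element `h` is
#'   `Pr(H = h)`.
#' @export
ewens_hap_probs <- function(n, theta) {
  stopifnot(n >= 1L, theta > 0)
  p <- 1 # distribution over h after 1 sample: P(H=1)=1
  if (n > 1L) {
    for (m in seq_len(n - 1L)) { # add sample m+1
      stay <- m / (theta + m)
      new <- theta / (theta + m)
      p <- c(p * stay, 0) + c(0, p * new)
    }
  }
  p
}

# Fs from (n, H_obs, K); theta-hat = K per Fu (1997).
.fu_fs_stat <- function(n, H_obs, K) {
  if (n < 2L) stop("insufficient sample: Fu's Fs needs n >= 2")
  if (!(K > 0)) stop("undefined statistic: Fu's Fs requires K > 0 (monomorphic sample)")
  stopifnot(H_obs >= 1L, H_obs <= n)
  probs <- ewens_hap_probs(n, K)
  Sp <- sum(probs[H_obs:n])
  Sp <- min(max(Sp, .Machine$double.xmin), 1 - .Machine$double.eps)
  log(Sp / (1 - Sp))
}

#' Fu's Fs
#'
#' Log-odds of observing at least as many distinct haplotypes as seen,
#' under the Ewens sampling distribution with `theta` estimated by the mean
#' pairwise difference `K` (Fu 1997). Strongly negative values indicate an
#' excess of haplotypes relative to `K`, the signature of expansion.
#'
#' @inheritParams tajimas_d
#' @return numeric statistic.
#' @export
fu_fs <- function(a, missing_policy = "pairwise-deletion") {
  n <- n_seq(a)
  pd <- pairwise_differences(a, missing_policy)
  K <- mean(pd$d[upper.tri(pd$d)])
  H_obs <- collapse_haplotypes(a)$H
  .fu_fs_stat(n, H_obs, K)
}

#' Neutrality tests with coalescent-null significance
#'
#' Computes Tajima's D and Fu's Fs for an alignment and attaches
#' simulation p-values: `reps` constant-size coalescent samples are drawn
#' (via the package's own simulator) with matched `n` and `theta` set to
#' the observed `K` (Arlequin-style conditioning on the theta estimate, not
#' on S). The default p-value is lower-tailed, `p = Pr(stat* <= stat_obs)`,
#' the direction in which expansion pushes both statistics; `tail =
#' "two-sided"` doubles the smaller tail. Replicates on which a statistic
#' is undefined (e.g. S* = 0) are dropped from that statistic's
#' denominator.
#'
#' @param a a `dna_alignment`.
#' @param reps null replicates (`>= 100`).
#' @param seed integer seed; results are reproducible given the seed.
#' @param tail `"lower"` (default) or `"two-sided"`.
#' @param fu_rule if `TRUE`, significance of Fs at the 0.05 level is
#'   declared when `p_Fs < 0.02` (Fu's recommendation); default off.
#' @param missing_policy passed through to the statistics.
#' @return object of class `neutrality_result`: `D, Fs, p_D, p_Fs,
#'   sig_D, sig_Fs, reps, seed, tail, fu_rule`.
#' @export
neutrality_test <- function(a, reps = 1000L, seed = NULL,
                            tail = c("lower", "two-sided"),
                            fu_rule = FALSE,
                            missing_policy = "pairwise-deletion") {
  tail <- match.arg(tail)
  if (reps < 100L) stop("reps must be >= 100 for significance testing")
  n <- n_seq(a)
  S <- count_segregating_sites(a)
  pd <- pairwise_differences(a, missing_policy)
  K <- mean(pd$d[upper.tri(pd$d)])
  H_obs <- collapse_haplotypes(a)$H
  D <- .tajima_d_stat(n, S, K)
  Fs <- .fu_fs_stat(n, H_obs, K)
  if (!is.null(seed)) set.seed(seed)
  Dstar <- Fstar <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    sm <- simulate_summary(sim_config(n = n, theta = K))
    if (sm$S >= 1L) Dstar[r] <- .tajima_d_stat(n, sm$S, sm$K)
    if (sm$K > 0) Fstar[r] <- .fu_fs_stat(n, sm$H, sm$K)
  }
  p_tail <- function(stars, obs) {
    stars <- stars[!is.na(stars)]
    if (!length(stars)) return(NA_real_)
    lo <- mean(stars <= obs)
    if (tail == "lower") lo else min(1, 2 * min(lo, mean(stars >= obs)))
  }
  p_D <- p_tail(Dstar, D)
  p_Fs <- p_tail(Fstar, Fs)
  fs_cut <- if (fu_rule) 0.02 else 0.05
  structure(list(D = D, Fs = Fs, p_D = p_D, p_Fs = p_Fs,
                 sig_D = !is.na(p_D) && p_D < 0.05,
                 sig_Fs = !is.na(p_Fs) && p_Fs < fs_cut,
                 reps = reps, seed = seed, tail = tail, fu_rule = fu_rule),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  mark <- function(p) if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  cat(sprintf("Tajima's D = %.3f (p = %.4g)%s\n", x$D, x$p_D, mark(x$p_D)))
  cat(sprintf("Fu's Fs    = %.3f (p = %.4g)%s\n", x$Fs, x$p_Fs, mark(x$p_Fs)))
  cat(sprintf("null: constant-size coalescent, theta = K, %d reps, %s tail%s\n",
              x$reps, x$tail, if (x$fu_rule) ", Fu 0.02 rule" else ""))
  invisible(x)
}
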