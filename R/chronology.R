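# Conversion of mutational / genetic quantities to calendar time under a
# tiered, time-dependent substitution-rate ledger.
#
# The core identity is T = tau / (2 mu k): tau in mutational units, mu in
# substitutions/site/year, k sites. The generation-time form
# t = tau/(2 u k) with u = mu g is carried as documentation only; g cancels
# in T = t g.

#' Time-dependent substitution-rate ledger
#'
#' The default tiers encode the rate scheme used for mouse mtDNA dating:
#' ancient (>100,000 y) Cytb 3.0e-8 and mitogenome 2.4e-8 (the mitogenome
#' rate being 80% of the Cytb rate), intermediate (50,000-60,000 y)
#' 4.7e-8, recent (<20,000 y) Cytb 1.1e-7 with the mitogenome-scaled
#' 0.9e-7 flagged as an alternative, and the literature's high alternatives
#' 2.0e-7 and 4.0e-7. Units: substitutions/site/year; windows in years
#' before present. Alternatives are never auto-selected by
#' [rate_for_age()].
#'
#' @param tiers optional replacement data.frame with columns
#'   `locus, tier, rate, age_min, age_max, alternative`.
#' @return object of class `rate_policy` (a validated data.frame).
#' @export
rate_policy <- function(tiers = NULL) {
  if (is.null(tiers)) {
    tiers <- data.frame(
      locus = c("cytb", "mitogenome", "cytb", "mitogenome",
                "cytb", "mitogenome", "mitogenome", "mitogenome", "mitogenome"),
      tier = c("ancient", "ancient", "intermediate", "intermediate",
               "recent", "recent", "recent-scaled", "high-alt-2", "high-alt-4"),
      rate = c(3.0e-8, 2.4e-8, 4.7e-8, 4.7e-8,
               1.1e-7, 1.1e-7, 0.9e-7, 2.0e-7, 4.0e-7),
      age_min = c(1e5, 1e5, 5e4, 5e4, 0, 0, 0, 0, 0),
      age_max = c(Inf, Inf, 6e4, 6e4, 2e4, 2e4, 2e4, 2e4, 2e4),
      alternative = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE
    )
  }
  need <- c("locus", "tier", "rate", "age_min", "age_max", "alternative")
  stopifnot(all(need %in% names(tiers)))
  if (any(tiers$rate <= 0)) stop("domain error: all rates must be > 0")
  # non-alternative windows must not overlap within a locus
  for (loc in unique(tiers$locus)) {
    tt <- tiers[tiers$locus == loc & !tiers$alternative, , drop = FALSE]
    if (nrow(tt) > 1L) {
      tt <- tt[order(tt$age_min), ]
      if (any(tt$age_max[-nrow(tt)] > tt$age_min[-1L]))
        stop("invalid rate policy: overlapping non-alternative windows for locus ", loc)
    }
  }
  structure(tiers, class = c("rate_policy", "data.frame"))
}

#' Read / write a rate ledger as TSV config
#' @param path TSV path with the [rate_policy()] columns.
#' @return a `rate_policy`.
#' @export
read_rate_policy <- function(path) {
  rate_policy(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_rate_policy
#' @param policy a `rate_policy`.
#' @export
write_rate_policy <- function(policy, path) {
  utils::write.table(as.data.frame(policy), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expansion time in years
#'
#' `T = tau / (2 mu k)`, rounded to the nearest year for reporting (set
#' `round = FALSE` for the exact value).
#'
#' @param tau expansion age in mutational units (`>= 0`).
#' @param mu substitution rate per site per year (`> 0`).
#' @param k number of sites (`> 0`; defaults to the mitogenome analysis
#'   length 16038).
#' @param round round to nearest year (default `TRUE`).
#' @return time in years before present.
#' @export
expansion_time <- function(tau, mu, k = 16038, round = TRUE) {
  if (any(tau < 0)) stop("domain error: tau must be >= 0")
  if (any(mu <= 0) || any(k <= 0)) stop("domain error: mu and k must be > 0")
  T <- tau / (2 * mu * k)
  if (round) base::round(T) else T
}

#' Expansion-time table over a set of rates
#'
#' Converts a fitted `tau` (and its CI, when present) to years at each
#' rate; by default the four reporting rates 0.9, 1.1, 2.0 and 4.0 x 1e-7
#' substitutions/site/year.
#'
#' @param fit an `expansion_fit` (or a list with `tau` and optional
#'   `tau_CI`).
#' @param rates numeric vector of rates.
#' @param k sites used (echoed in the output since T depends on it).
#' @return data.frame of class `expansion_time_table` with columns
#'   `rate, T_years, T_ci_low, T_ci_high, k, tau`.
#' @export
expansion_time_table <- function(fit,
                                 rates = c(0.9e-7, 1.1e-7, 2.0e-7, 4.0e-7),
                                 k = 16038) {
  tau <- fit$tau
  ci <- if (!is.null(fit$tau_CI)) fit$tau_CI else c(NA_real_, NA_real_)
  out <- data.frame(
    rate = rates,
    T_years = expansion_time(tau, rates, k),
    T_ci_low = if (is.na(ci[1])) NA_real_ else expansion_time(ci[1], rates, k),
    T_ci_high = if (is.na(ci[2])) NA_real_ else expansion_time(ci[2], rates, k),
    k = k, tau = tau
  )
  class(out) <- c("expansion_time_table", "data.frame")
  out
}

#' Divergence time from per-site distance
#'
#' `T = d / (2 mu)` for a per-site genetic distance `d` between two clades
#' under a strict clock.
#'
#' @param d per-site distance (`>= 0`).
#' @param mu substitution rate per site per year (`> 0`).
#' @return time in years (unrounded).
#' @export
divergence_time <- function(d, mu) {
  if (any(d < 0)) stop("domain error: d must be >= 0")
  if (any(mu <= 0)) stop("domain error: mu must be > 0")
  d / (2 * mu)
}

#' Scale a rate between loci
#'
#' `mu = base_rate * dist_ratio`, the locus-scaling rule by which the
#' mitogenome rate is derived as ~80% of the Cytb rate (mean pairwise
#' distance of the target locus over the calibrated locus on the same
#' samples).
#'
#' @param base_rate calibrated rate (`> 0`).
#' @param dist_ratio distance ratio in `(0, 2]`.
#' @return scaled rate.
#' @export
calibrate_locus_rate <- function(base_rate, dist_ratio) {
  if (base_rate <= 0) stop("domain error: base_rate must be > 0")
  if (dist_ratio <= 0 || dist_ratio > 2)
    stop("domain error: dist_ratio must lie in (0, 2]")
  base_rate * dist_ratio
}

#' Estimate the between-locus distance ratio
#'
#' Mean per-site pairwise distance of locus A over locus B on the shared
#' samples; the input for [calibrate_locus_rate()].
#'
#' @param aln_a,aln_b `dna_alignment`s of the two loci (ids matched by
#'   intersection).
#' @param missing_policy passed to [pairwise_differences()].
#' @return numeric ratio.
#' @export
estimate_dist_ratio <- function(aln_a, aln_b,
                                missing_policy = "pairwise-deletion") {
  shared <- intersect(aln_a$ids, aln_b$ids)
  if (length(shared) < 2L)
    stop("insufficient sample: need >= 2 shared samples across loci")
  sub <- function(a) structure(list(ids = shared,
                                    mat = a$mat[shared, , drop = FALSE]),
                               class = "dna_alignment")
  persite <- function(a) {
    pd <- pairwise_differences(sub(a), missing_policy)
    ut <- upper.tri(pd$d)
    mean(pd$d[ut] / pd$eff[ut])
  }
  persite(aln_a) / persite(aln_b)
}

#' Select the rate tier covering an age
#'
#' Returns the non-alternative rate whose applicability window contains
#' `age_years` for the given locus; ties at shared window edges resolve
#' toward the younger tier. Ages falling in a gap between windows (e.g.
#' 20,000-50,000 y) raise an error listing the declared windows rather
#' than interpolating.
#'
#' @param age_years age in years (`>= 0`).
#' @param policy a [rate_policy()].
#' @param locus locus name (default `"mitogenome"`).
#' @return the rate (substitutions/site/year).
#' @export
rate_for_age <- function(age_years, policy = rate_policy(),
                         locus = "mitogenome") {
  if (age_years < 0) stop("domain error: age must be >= 0")
  tt <- policy[policy$locus == locus & !policy$alternative, , drop = FALSE]
  if (!nrow(tt)) stop("coverage error: no tiers declared for locus ", locus)
  hit <- tt[tt$age_min <= age_years & age_years <= tt$age_max, , drop = FALSE]
  if (!nrow(hit)) {
    wins <- paste(sprintf("[%g, %g] (%s)", tt$age_min, tt$age_max, tt$tier),
                  collapse = ", ")
    stop("coverage error: no rate tier covers age ", age_years,
         " y for locus ", locus, "; declared windows: ", wins)
  }
  hit <- hit[order(hit$age_min), , drop = FALSE] # tie -> younger tier
  hit$rate[1L]
}
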