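# Mismatch distributions and the sudden-expansion model: observed
# histograms, the closed-form transient expectation, least-squares fitting,
# the parametric-bootstrap SSD test and the raggedness index.

#' Observed mismatch distribution
#'
#' Histogram of pairwise difference counts over classes `0..d_max`, where
#' `d_max` is the largest observed difference.
#'
#' @param pd a `pairwise_diffs` object (or an n x n difference matrix).
#' @return object of class `mismatch_distribution`: `counts` (named vector
#'   over classes), `freqs`, `n_pairs`, `d_max`.
#' @export
observed_mismatch <- function(pd) {
  D <- if (inherits(pd, "pairwise_diffs")) pd$d else pd
  if (nrow(D) < 2L) stop("insufficient sample: need n >= 2")
  v <- D[upper.tri(D)]
  d_max <- max(v)
  counts <- tabulate(v + 1L, nbins = d_max + 1L)
  names(counts) <- 0:d_max
  structure(list(counts = counts, freqs = counts / sum(counts),
                 n_pairs = sum(counts), d_max = d_max),
            class = "mismatch_distribution")
}

#' @export
print.mismatch_distribution <- function(x, ...) {
  cat(sprintf("mismatch_distribution: %d pairs, classes 0..%d, mean %.3f\n",
              x$n_pairs, x$d_max, sum(as.numeric(names(x$counts)) * x$freqs)))
  invisible(x)
}

# Equilibrium distribution F^_j(theta) = theta^j / (theta+1)^(j+1),
# computed in log space so theta up to 1e5 and j up to hundreds are safe.
.equilibrium_mismatch <- function(theta, j) {
  exp(j * log(theta) - (j + 1) * log1p(theta))
}

#' Expected mismatch distribution under sudden expansion
#'
#' Closed-form transient distribution of pairwise differences `j` time
#' `tau` (mutational units) after an instantaneous change from `theta0` to
#' `theta1`:
#' `F_j = Fhat_j(theta1) + exp(-tau (theta1+1)/theta1) *
#'   sum_{i=0}^{j} tau^(j-i)/(j-i)! (Fhat_i(theta0) - Fhat_i(theta1))`
#' with `Fhat_j(theta) = theta^j/(theta+1)^(j+1)`. The Poisson weights are
#' evaluated via `dpois` and the residual factor `exp(-tau/theta1)`, so no
#' intermediate term overflows. At `tau = 0` this reduces to the
#' equilibrium at `theta0`; for large `tau` it approaches the equilibrium
#' at `theta1`.
#'
#' @param tau expansion age in mutational units (`>= 0`).
#' @param theta0,theta1 scaled sizes before/after expansion (`> 0`).
#' @param d_max largest difference class to evaluate.
#' @return numeric vector of `F_j`, `j = 0..d_max`, with the unassigned
#'   tail mass `1 - sum(F_j)` in attribute `"tail_mass"`.
#' @export
expected_mismatch <- function(tau, theta0, theta1, d_max) {
  if (tau < 0 || theta0 <= 0 || theta1 <= 0 || d_max < 0)
    stop("domain error: need tau >= 0, theta0 > 0, theta1 > 0, d_max >= 0")
  j <- 0:d_max
  F0 <- .equilibrium_mismatch(theta0, j)
  F1 <- .equilibrium_mismatch(theta1, j)
  delta <- F0 - F1
  # exp(-tau (theta1+1)/theta1) tau^m/m! = exp(-tau/theta1) dpois(m, tau)
  pv <- stats::dpois(j, tau)
  conv <- if (d_max == 0L) delta * pv else {
    # polynomial product: conv[j] = sum_i pv[j-i] delta[i]
    stats::convolve(delta, rev(pv), type = "open")[seq_along(j)]
  }
  Fj <- F1 + exp(-tau / theta1) * conv
  Fj <- pmax(Fj, 0)
  attr(Fj, "tail_mass") <- max(0, 1 - sum(Fj))
  Fj
}

# Expected frequencies over classes 0..d_max with tail mass folded into
# the last class (the comparison convention for SSD).
.expected_mismatch_folded <- function(tau, theta0, theta1, d_max) {
  f <- expected_mismatch(tau, theta0, theta1, d_max)
  f[d_max + 1L] <- f[d_max + 1L] + attr(f, "tail_mass")
  attributes(f) <- NULL
  f
}

#' Raggedness index
#'
#' Harpending's raggedness of a mismatch distribution:
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` over the relative frequencies
#' `x_0..x_d` with the terminal zero `x_{d+1} = 0` (closed convention).
#' Smooth unimodal (expansion-like) distributions give small `r`.
#'
#' @param m a `mismatch_distribution` or a numeric frequency vector.
#' @return numeric raggedness.
#' @export
raggedness <- function(m) {
  x <- if (inherits(m, "mismatch_distribution")) m$freqs else m
  sum(diff(c(x, 0))^2)
}

# Fast SSD objective factory: precomputes the Poisson-weight Toeplitz
# index once per observed vector so each optimizer step is a single small
# matrix-vector product. Agrees with expected_mismatch()/folding to
# machine precision (asserted in tests).
.make_ssd_fn <- function(obs_freq) {
  d <- length(obs_freq) - 1L
  j <- 0:d
  dd <- d + 1L
  idx <- outer(j, j, "-")
  sel <- idx + 2L
  sel[idx < 0L] <- 1L # padded zero
  function(tau, theta0, theta1) {
    F0 <- exp(j * log(theta0) - (j + 1) * log1p(theta0))
    F1 <- exp(j * log(theta1) - (j + 1) * log1p(theta1))
    pv0 <- c(0, stats::dpois(j, tau))
    Fj <- F1 + exp(-tau / theta1) *
      drop(matrix(pv0[sel], dd, dd) %*% (F0 - F1))
    Fj[Fj < 0] <- 0
    Fj[dd] <- Fj[dd] + max(0, 1 - sum(Fj))
    sum((obs_freq - Fj)^2)
  }
}

# SSD between observed frequencies (classes 0..d_max) and the folded model
# expectation.
.ssd <- function(obs_freq, tau, theta0, theta1) {
  .make_ssd_fn(obs_freq)(tau, theta0, theta1)
}

#' Fit the sudden-expansion model by least squares
#'
#' Minimises the sum of squared deviations (SSD) between the observed
#' mismatch frequencies over classes `0..d_max` (model tail mass folded
#' into the last class) and the closed-form expectation, over
#' `(tau, theta0, theta1)`. Optimisation is bounded derivative-free
#' (Nelder-Mead on log-transformed parameters, `theta1` parameterised as
#' `theta0 + exp(.)` so the ordering `theta0 <= theta1` holds by
#' construction, capped at 1e5) from 8 deterministic multi-starts spread
#' over log-spaced `tau` and `theta0` around the moment initialisation
#' `tau0 = mean(m)`.
#'
#' @param m a `mismatch_distribution`.
#' @param theta1_max upper bound for `theta1` (default 1e5, effectively
#'   infinite).
#' @return object of class `expansion_fit`: `tau, theta0, theta1, SSD,
#'   r` (observed raggedness), with `p_SSD, p_r, tau_CI, reps, seed` set
#'   to `NA` until completed by [bootstrap_expansion_test()].
#' @export
fit_sudden_expansion <- function(m, theta1_max = 1e5) {
  stopifnot(inherits(m, "mismatch_distribution"))
  if (m$n_pairs < 3L) stop("insufficient sample: need >= 3 pairs")
  obs <- m$freqs
  r_obs <- raggedness(m)
  if (sum(obs > 0) < 2L) {
    # monomorphic (all mass in class 0): degenerate limit tau ~ 0, theta0 ~ 0
    eps <- 1e-8
    fit <- list(tau = 0, theta0 = eps, theta1 = eps,
                SSD = .ssd(obs, 0, eps, eps))
    return(.expansion_fit(fit, r_obs))
  }
  mbar <- sum((0:m$d_max) * obs)
  ssd_fn <- .make_ssd_fn(obs)
  obj <- function(p) {
    tau <- exp(p[1]) - 1e-6
    th0 <- min(exp(p[2]), theta1_max)
    th1 <- min(th0 + exp(p[3]), theta1_max)
    if (tau < 0) tau <- 0
    ssd_fn(tau, th0, th1)
  }
  taus <- pmax(mbar, 0.1) * c(0.25, 0.5, 1, 2)
  th0s <- c(0.1, max(mbar / 4, 0.2))
  starts <- expand.grid(tau = taus, th0 = th0s)
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    p0 <- c(log(starts$tau[s] + 1e-6), log(starts$th0[s]), log(1e4))
    o <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 1200, reltol = 1e-10))
    if (o$convergence == 0) any_conv <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- best$par
  tau <- max(exp(p[1]) - 1e-6, 0)
  theta0 <- min(exp(p[2]), theta1_max)
  theta1 <- min(theta0 + exp(p[3]), theta1_max)
  fit <- list(tau = tau, theta0 = theta0, theta1 = theta1, SSD = best$value)
  if (!any_conv) {
    cond <- structure(class = c("mitodemog_fit_error", "error", "condition"),
                      list(message = "fit error: optimizer failed to converge from all restarts",
                           call = sys.call(), best = .expansion_fit(fit, r_obs)))
    stop(cond)
  }
  .expansion_fit(fit, r_obs)
}

.expansion_fit <- function(fit, r_obs) {
  structure(list(tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
                 SSD = fit$SSD, r = r_obs,
                 p_SSD = NA_real_, p_r = NA_real_,
                 tau_CI = c(NA_real_, NA_real_),
                 reps = NA_integer_, seed = NA_integer_,
                 ci_level = NA_real_, n_failed = NA_integer_),
            class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf("sudden-expansion fit: tau = %.3f, theta0 = %.4g, theta1 = %.4g\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.5f (p = %s), raggedness r = %.5f (p = %s)\n",
              x$SSD, format(x$p_SSD, digits = 3), x$r,
              format(x$p_r, digits = 3)))
  if (!is.na(x$tau_CI[1]))
    cat(sprintf("  tau %.0f%% CI: (%.3f, %.3f); bootstrap reps = %d\n",
                100 * x$ci_level, x$tau_CI[1], x$tau_CI[2], x$reps))
  if (!is.na(x$p_SSD))
    cat(if (x$p_SSD >= 0.05) "  expansion model not rejected\n"
        else "  expansion model rejected (p_SSD < 0.05)\n")
  invisible(x)
}

#' Parametric bootstrap for the sudden-expansion fit
#'
#' Completes an [fit_sudden_expansion()] result: `reps` coalescent
#' replicates are simulated under the fitted `(tau, theta0, theta1)` with
#' matched sample size, each replicate is re-fitted, and the replicate SSD
#' and raggedness are recorded. `p_SSD = Pr(SSD* >= SSD_obs)` and
#' `p_r = Pr(r* >= r_obs)`; a non-significant `p_SSD` means the expansion
#' model is not rejected. The `tau` confidence interval is the percentile
#' interval of the replicate estimates at `ci_level` (widened, if needed,
#' to contain the point estimate). Replicates whose re-fit fails are
#' dropped and counted; more than 20% failures aborts.
#'
#' @param a the observed `dna_alignment` (only its sample size enters the
#'   simulation), or an integer sample size.
#' @param fit an `expansion_fit` with point estimates.
#' @param reps bootstrap replicates (`>= 100`; the production default is
#'   1000).
#' @param seed integer seed.
#' @param ci_level confidence level for the `tau` interval.
#' @return the completed `expansion_fit`.
#' @export
bootstrap_expansion_test <- function(a, fit, reps = 1000L, seed = NULL,
                                     ci_level = 0.95) {
  stopifnot(inherits(fit, "expansion_fit"))
  if (reps < 100L) stop("reps must be >= 100")
  n <- if (inherits(a, "dna_alignment")) n_seq(a) else as.integer(a)
  if (!is.null(seed)) set.seed(seed)
  th0 <- max(fit$theta0, 1e-6)
  th1 <- max(fit$theta1, th0)
  cfg <- sim_config(n = n, theta0 = th0, theta1 = th1, tau = fit$tau)
  ssd_star <- r_star <- tau_star <- rep(NA_real_, reps)
  failed <- 0L
  for (b in seq_len(reps)) {
    sm <- simulate_summary(cfg)
    mm <- observed_mismatch(sm$D)
    f <- tryCatch(fit_sudden_expansion(mm), error = function(e) NULL)
    if (is.null(f)) { failed <- failed + 1L; next }
    ssd_star[b] <- f$SSD
    r_star[b] <- raggedness(mm)
    tau_star[b] <- f$tau
  }
  if (failed > 0.2 * reps)
    stop("bootstrap error: ", failed, "/", reps, " replicate fits failed")
  ok <- !is.na(ssd_star)
  fit$p_SSD <- mean(ssd_star[ok] >= fit$SSD)
  fit$p_r <- mean(r_star[ok] >= fit$r)
  alpha <- 1 - ci_level
  ci <- stats::quantile(tau_star[ok], c(alpha / 2, 1 - alpha / 2),
                        names = FALSE)
  fit$tau_CI <- c(min(ci[1], fit$tau), max(ci[2], fit$tau))
  fit$reps <- as.integer(reps)
  fit$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  fit$ci_level <- ci_level
  fit$n_failed <- failed
  fit
}
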