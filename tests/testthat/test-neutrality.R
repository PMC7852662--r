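# Independent oracles --------------------------------------------------

# Unsigned Stirling numbers of the first kind via polynomial expansion of
# the rising factorial x(x+1)...(x+n-1) (coefficient route, independent of
# the sequential recurrence used by ewens_hap_probs).
stirling1 <- function(n) {
  co <- c(0, 1) # coefficients of x
  if (n > 1) {
    for (m in 1:(n - 1)) {
      shifted <- c(0, co)           # x * poly
      co <- c(co * m, 0) + shifted  # (x + m) * poly
    }
  }
  co[-1] # |S(n, 1..n)|
}

ewens_probs_oracle <- function(n, theta) {
  s <- stirling1(n)
  p <- s * theta^(1:n) / prod(theta + 0:(n - 1))
  p
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    q <- p + (p >= k)
    cbind(rep(k, nrow(q)), q)
  }))
}

cycle_count <- function(perm) {
  seen <- rep(FALSE, length(perm)); ncyc <- 0L
  for (i in seq_along(perm)) {
    if (seen[i]) next
    ncyc <- ncyc + 1L
    j <- i
    while (!seen[j]) { seen[j] <- TRUE; j <- perm[j] }
  }
  ncyc
}

# Tests -----------------------------------------------------------------

test_that("Tajima's D matches the frozen hand evaluation and errors", {
  a <- aln("AAAA", "AAAT", "AATT", "ATTT")
  # frozen from direct evaluation of the a1..e2 constants at n=4, S=3, K=10/6
  expect_equal(tajimas_d(a), 0.1676558, tolerance = 1e-6)
  expect_error(tajimas_d(aln("AA", "AA", "AA", "AA")), "undefined statistic")
  expect_error(tajimas_d(aln("AA", "AT", "TA")), "insufficient sample")
})

test_that("Fu's Fs reproduces the exhaustive Ewens evaluation at n = 3", {
  expect_equal(ewens_hap_probs(3, 2 / 3), c(0.45, 0.45, 0.10), tolerance = 1e-12)
  expect_equal(fu_fs(aln("AA", "AA", "AT")), log(0.55 / 0.45), tolerance = 1e-9)
  expect_error(fu_fs(aln("AA", "AA")), "undefined statistic")
})

test_that("Ewens probabilities are normalised and match both oracles", {
  for (n in c(2, 5, 10, 25, 50)) for (theta in c(0.1, 1, 10)) {
    p <- ewens_hap_probs(n, theta)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # polynomial-coefficient Stirling oracle, n <= 8
  for (n in 2:8) for (theta in c(0.3, 1, 4)) {
    expect_equal(ewens_hap_probs(n, theta), ewens_probs_oracle(n, theta),
                 tolerance = 1e-10)
  }
  # exhaustive permutation-cycle counts, n <= 6
  for (n in 2:6) {
    counts <- tabulate(apply(all_perms(n), 1, cycle_count), nbins = n)
    expect_equal(stirling1(n), counts)
  }
  # large n must not overflow
  expect_equal(sum(ewens_hap_probs(300, 5)), 1, tolerance = 1e-9)
})

test_that("D and Fs are invariant under row and site permutation", {
  a <- random_alignment(8, 15, seed = 11)
  set.seed(3)
  rows <- sample(8); cols <- sample(15)
  ap <- dna_alignment(apply(a$mat[rows, cols], 1, paste0, collapse = ""))
  expect_equal(tajimas_d(ap), tajimas_d(a))
  expect_equal(fu_fs(ap), fu_fs(a))
})

test_that("expansion genealogies drive D negative; Fs power >= D power", {
  set.seed(2024)
  cfg <- sim_config(n = 30, theta0 = 1, theta1 = 500, tau = 10)
  null_cfg <- function(K) sim_config(n = 30, theta = K)
  Ds <- Fss <- pD <- pFs <- numeric(100)
  nullD <- matrix(NA_real_, 100, 100)
  for (i in 1:100) {
    sm <- simulate_summary(cfg)
    Ds[i] <- mitodemog:::.tajima_d_stat(30, sm$S, sm$K)
    Fss[i] <- mitodemog:::.fu_fs_stat(30, sm$H, sm$K)
    # shared null per dataset (theta = observed K), 100 reps for speed
    nD <- nF <- numeric(100)
    for (r in 1:100) {
      nm <- simulate_summary(null_cfg(sm$K))
      nD[r] <- if (nm$S >= 1) mitodemog:::.tajima_d_stat(30, nm$S, nm$K) else NA
      nF[r] <- if (nm$K > 0) mitodemog:::.fu_fs_stat(30, nm$H, nm$K) else NA
    }
    pD[i] <- mean(nD[!is.na(nD)] <= Ds[i])
    pFs[i] <- mean(nF[!is.na(nF)] <= Fss[i])
  }
  expect_lt(mean(Ds), 0)
  expect_lt(mean(Fss), 0)
  # literature expectation: Fs at least as powerful as D for expansion
  expect_gte(mean(pFs < 0.05), mean(pD < 0.05))
})

test_that("neutrality_test is reproducible and tail-correct", {
  set.seed(5)
  sim <- simulate_alignment(sim_config(n = 12, theta0 = 0.5, theta1 = 1e4,
                                       tau = 8, L = 3000))
  r1 <- neutrality_test(sim$alignment, reps = 100, seed = 99)
  r2 <- neutrality_test(sim$alignment, reps = 100, seed = 99)
  expect_identical(r1$p_D, r2$p_D)
  expect_identical(r1$p_Fs, r2$p_Fs)
  expect_true(r1$p_D >= 0 && r1$p_D <= 1)
  expect_true(r1$p_Fs >= 0 && r1$p_Fs <= 1)
  # strong expansion signal: p values should sit in the lower tail
  expect_lt(r1$p_D, 0.2)
  expect_error(neutrality_test(sim$alignment, reps = 10), "reps")
})
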