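test_that("observed mismatch histograms conserve the pair total", {
  m <- observed_mismatch(pairwise_differences(aln("AA", "AT", "TT")))
  expect_equal(unname(m$counts), c(0L, 2L, 1L))
  expect_equal(m$n_pairs, 3L)

  mono <- observed_mismatch(pairwise_differences(aln("GG", "GG", "GG")))
  expect_equal(unname(mono$counts), 3L) # all mass at class 0
  expect_equal(mono$d_max, 0L)

  for (seed in 1:5) {
    a <- random_alignment(n = sample(3:10, 1), L = 12, seed = 200 + seed)
    m <- observed_mismatch(pairwise_differences(a))
    n <- n_seq(a)
    expect_equal(sum(m$counts), n * (n - 1) / 2)
    expect_equal(sum(m$freqs), 1)
  }
})

test_that("expected_mismatch has the right limits and normalisation", {
  # theta = 1 equilibrium is geometric 2^-(j+1)
  eq1 <- expected_mismatch(1e4, 5, 1, 8) # large tau -> equilibrium at theta1
  expect_equal(as.numeric(expected_mismatch(0, 1, 77, 5))[1:3],
               c(0.5, 0.25, 0.125), tolerance = 1e-12)
  # tau = 0 reduces to equilibrium at theta0, any theta1
  f0 <- expected_mismatch(0, 2.5, 999, 10)
  expect_equal(as.numeric(f0),
               2.5^(0:10) / 3.5^(1:11), tolerance = 1e-10)
  # large tau approaches equilibrium at theta1 (sup norm < 1e-6)
  f_inf <- expected_mismatch(200, 5, 1, 10)
  expect_lt(max(abs(f_inf - 0.5^(1:11))), 1e-6)
  # normalisation within 1e-9 across a parameter grid
  for (tau in c(0, 0.5, 5, 25)) for (th0 in c(0.1, 1, 10)) for (th1 in c(1, 100, 1e5)) {
    f <- expected_mismatch(tau, th0, th1, 80)
    expect_lt(abs(sum(f) + attr(f, "tail_mass") - 1), 1e-9)
    expect_true(all(f >= 0))
  }
  expect_error(expected_mismatch(-1, 1, 1, 5), "domain error")
  expect_error(expected_mismatch(1, 0, 1, 5), "domain error")
})

test_that("raggedness follows the closed (terminal-zero) convention", {
  expect_equal(raggedness(c(0.5, 0.5)), 0.25)
  expect_equal(raggedness(1.0), 1.0) # all mass in one class
  # smoothness: equal frequencies over more classes -> smaller r
  rs <- vapply(2:10, function(k) raggedness(rep(1 / k, k)), numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("SSD is zero iff the distributions coincide", {
  f <- mitodemog:::.expected_mismatch_folded(4, 0.5, 50, 20)
  expect_equal(mitodemog:::.ssd(f, 4, 0.5, 50), 0, tolerance = 1e-18)
  expect_gt(mitodemog:::.ssd(f, 8, 0.5, 50), 0)
  # fast objective closure agrees with the public model
  set.seed(31)
  for (i in 1:10) {
    tau <- runif(1, 0, 30); th0 <- runif(1, 0.05, 10)
    th1 <- th0 + runif(1, 0, 1e4); d <- sample(3:50, 1)
    obs <- runif(d + 1); obs <- obs / sum(obs)
    expect_equal(mitodemog:::.ssd(obs, tau, th0, th1),
                 sum((obs - mitodemog:::.expected_mismatch_folded(tau, th0, th1, d))^2),
                 tolerance = 1e-13)
  }
})

test_that("fit recovers parameters from the model's own output", {
  f <- expected_mismatch(10, 1, 1000, 60)
  obs <- as.numeric(f)
  obs[61] <- obs[61] + attr(f, "tail_mass")
  m <- structure(list(counts = obs * 1e6, freqs = obs, n_pairs = 1e6,
                      d_max = 60L), class = "mismatch_distribution")
  fit <- fit_sudden_expansion(m)
  expect_lt(abs(fit$tau - 10), 0.2)
  expect_lt(abs(fit$tau - 10) / 10, 0.02) # noiseless self-consistency
  expect_lte(fit$theta0, fit$theta1)
  expect_lt(fit$SSD, 1e-10)
})

test_that("monomorphic input yields the degenerate limit", {
  m <- observed_mismatch(pairwise_differences(aln("CC", "CC", "CC")))
  fit <- fit_sudden_expansion(m)
  expect_equal(fit$tau, 0)
  expect_lt(fit$theta0, 1e-6)
})

test_that("bootstrap completes the fit deterministically", {
  set.seed(17)
  sm <- simulate_summary(sim_config(n = 20, theta0 = 1, theta1 = 1e4, tau = 8))
  mm <- observed_mismatch(sm$D)
  fit <- fit_sudden_expansion(mm)
  b1 <- bootstrap_expansion_test(20L, fit, reps = 100, seed = 7)
  b2 <- bootstrap_expansion_test(20L, fit, reps = 100, seed = 7)
  expect_identical(b1$p_SSD, b2$p_SSD)
  expect_identical(b1$p_r, b2$p_r)
  expect_identical(b1$tau_CI, b2$tau_CI)
  # CI contains the point estimate; p-values in [0,1]
  expect_lte(b1$tau_CI[1], b1$tau)
  expect_gte(b1$tau_CI[2], b1$tau)
  expect_true(b1$p_SSD >= 0 && b1$p_SSD <= 1)
  # data generated by an expansion: the expansion model is not rejected
  expect_gte(b1$p_SSD, 0.05)
  expect_output(print(b1), "not rejected")
  expect_error(bootstrap_expansion_test(20L, fit, reps = 50), "reps")
})
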