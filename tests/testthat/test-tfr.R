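# Morlet transform, STP and ITPC estimators.

test_that("cycle rule hits its anchor, asymptote and inflection value", {
  fn <- cycle_function()
  expect_equal(cycles_at(fn, 1), 3)
  expect_equal(cycles_at(fn, 1e4), 29, tolerance = 1e-6)

  # value at the inflection point follows the anchored-logistic closed form
  s0 <- plogis(0.05 * (1 - 70))
  expected_70 <- 3 + 26 * (0.5 - s0) / (1 - s0)
  expect_equal(cycles_at(fn, 70), expected_70)

  expect_true(!is.unsorted(cycles_at(fn, 1:200), strictly = TRUE))
  expect_error(cycles_at(fn, 0.5), "anchor")
})

test_that("unit sinusoid at a grid frequency maps to |coefficient| ~ 1", {
  m <- sinusoid_trials(0, f = 40, dur = 1)
  tfr <- morlet_transform(epochs_from_matrix(cbind(m, m)), freqs = c(30, 40, 50))
  h <- tfr$edge_samples[2]
  interior <- (h + 1):(length(tfr$t) - h)
  amp <- Mod(tfr$coeffs[1, 2, interior])
  expect_true(all(abs(amp - 1) < 0.02))
  # off-frequency rows respond less
  expect_lt(mean(Mod(tfr$coeffs[1, 1, interior])), 0.5)
})

test_that("transform is linear and zero on zero signals", {
  set.seed(5)
  m <- matrix(rnorm(512 * 3), 512, 3)
  ep1 <- epochs_from_matrix(m)
  ep2 <- epochs_from_matrix(3.5 * m)
  t1 <- morlet_transform(ep1, freqs = c(20, 40))
  t2 <- morlet_transform(ep2, freqs = c(20, 40))
  expect_equal(Mod(t2$coeffs), 3.5 * Mod(t1$coeffs), tolerance = 1e-10)

  t0 <- morlet_transform(epochs_from_matrix(matrix(0, 512, 2)), freqs = 40)
  expect_true(all(Mod(t0$coeffs) < 1e-12))
})

test_that("transform refuses epochs shorter than the wavelet support", {
  ep <- epochs_from_matrix(matrix(rnorm(256 * 2), 256, 2))
  expect_error(morlet_transform(ep, freqs = 5:10), "support")
  expect_silent(morlet_transform(ep, freqs = 40))
})

test_that("STP of identical unit sinusoid trials is ~ 1 at the grid frequency", {
  m <- sinusoid_trials(c(0, 0, 0), f = 40)
  stp <- compute_stp(morlet_transform(epochs_from_matrix(m), freqs = 40))
  expect_equal(interior_row_mean(stp, 40, "power"), 1, tolerance = 0.01)
  expect_true(all(stp$power >= 0))
})

test_that("STP is invariant to trial order", {
  set.seed(8)
  m <- matrix(rnorm(512 * 6), 512, 6)
  s1 <- compute_stp(morlet_transform(epochs_from_matrix(m), freqs = c(20, 40)))
  s2 <- compute_stp(morlet_transform(epochs_from_matrix(m[, 6:1]), freqs = c(20, 40)))
  expect_equal(s1$power, s2$power)
})

test_that("ITPC is 1 for identical trials and 0 for evenly spaced phases", {
  m <- sinusoid_trials(rep(0.3, 40), f = 40)
  it <- compute_itpc(morlet_transform(epochs_from_matrix(m), freqs = 40))
  expect_equal(interior_row_mean(it, 40), 1, tolerance = 1e-9)

  m8 <- sinusoid_trials(2 * pi * (0:7) / 8, f = 40)
  it8 <- compute_itpc(morlet_transform(epochs_from_matrix(m8), freqs = 40))
  expect_equal(interior_row_mean(it8, 40), 0, tolerance = 1e-9)

  expect_true(all(it$itpc >= 0 & it$itpc <= 1))
})

test_that("ITPC is a phase-only statistic: per-trial amplitude scaling has no effect", {
  set.seed(9)
  phases <- runif(20, 0, 2 * pi)
  m <- sinusoid_trials(phases, f = 40)
  scales <- rep(c(0.2, 5), 10)
  it1 <- compute_itpc(morlet_transform(epochs_from_matrix(m), freqs = 40))
  it2 <- compute_itpc(morlet_transform(
    epochs_from_matrix(sweep(m, 2, scales, "*")), freqs = 40))
  expect_equal(it1$itpc, it2$itpc, tolerance = 1e-12)
})

test_that("null ITPC decays like sqrt(pi/4)/sqrt(N) with trial count", {
  set.seed(10)
  for (n in c(25, 100, 400)) {
    reps <- replicate(20, {
      m <- sinusoid_trials(runif(n, 0, 2 * pi), f = 40, dur = 0.5)
      it <- compute_itpc(morlet_transform(epochs_from_matrix(m), freqs = 40))
      interior_row_mean(it, 40)
    })
    expected <- sqrt(pi / 4) / sqrt(n)
    expect_equal(mean(reps), expected, tolerance = 0.25)
  }
})

test_that("ITPC needs at least two trials", {
  m <- sinusoid_trials(0, f = 40)
  expect_error(compute_itpc(morlet_transform(epochs_from_matrix(m), freqs = 40)),
               "two trials")
})

test_that("mean 40 Hz ITPC summary averages the interior and validates windows", {
  m <- sinusoid_trials(rep(0, 10), f = 40, dur = 0.25)
  it <- compute_itpc(morlet_transform(epochs_from_matrix(m), freqs = 40))
  maps <- list(`3` = it, `9` = it)
  tab <- mean_itpc_40hz(maps)
  expect_equal(tab$gap_width_ms, c(3, 9))
  expect_equal(tab$mean_itpc, c(1, 1), tolerance = 1e-9)
  expect_error(mean_itpc_40hz(maps, window = c(0.1, 0.1)), "zero-length")
})
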