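test_that("composite histograms conserve counts and match per-trace histograms", {
  edges <- log_bin_edges()
  h0 <- build_histogram(list(), edges)
  expect_equal(sum(h0$counts), 0)
  expect_equal(h0$n_traces, 0)
  expect_error(build_histogram(list(), c(-2, -3, -1)), "strictly increasing")

  # single noiseless plateau trace: identical to its per-trace histogram
  sp <- species_model("flat", conductance_g0 = 1e-3, sigma_between = 0,
                      plateau_length_mean = 0.3, plateau_length_sd = 0)
  set.seed(40)
  tr <- simulate_trace(mixture_spec(list(sp), 1e-6, p_junction = 1),
                       quiet_gen(plateau_slope = 0))
  h1 <- build_histogram(list(tr), edges)
  expect_equal(h1$counts, per_trace_histogram(tr, screening_config()))

  # 20-trace toy ensemble vs brute-force enumeration
  ens <- simulate_ensemble(20, default_mix(p_junction = 0.5),
                           generator_config(), seed = 41)
  h20 <- build_histogram(ens, edges)
  brute <- integer(length(edges) - 1L)
  for (tr in ens) {
    brute <- brute + oracle_bin_counts(log10(tr$conductance), edges)
  }
  expect_equal(h20$counts, brute)

  # count conservation on several ensembles
  for (seed in c(50, 51)) {
    ens <- simulate_ensemble(30, default_mix(), generator_config(),
                             seed = seed)
    h <- build_histogram(ens, edges)
    in_window <- sum(vapply(ens, function(tr) {
      y <- log10(tr$conductance)
      sum(y >= edges[1] & y < edges[length(edges)])
    }, numeric(1)))
    expect_equal(sum(h$counts), in_window)
  }
})

test_that("Gaussian fits recover exactly sampled peaks to solver precision", {
  # single exact Gaussian (no baseline in the data)
  h1 <- gaussian_histogram(mu = -3.0, sigma = 0.3, amplitude = 500)
  p1 <- fit_gaussian_peaks(h1, k = 1, baseline = FALSE)
  expect_equal(p1$mu_log, -3.0, tolerance = 1e-6)
  expect_equal(p1$sigma_log, 0.3, tolerance = 1e-6)
  expect_equal(p1$amplitude, 500, tolerance = 1e-4)
  expect_true(attr(p1, "converged"))

  # the constant-offset variant recovers the same peak on offset data
  h1b <- gaussian_histogram(mu = -3.0, sigma = 0.3, amplitude = 500,
                            baseline = 120)
  p1b <- fit_gaussian_peaks(h1b, k = 1, baseline = TRUE)
  expect_equal(p1b$mu_log, -3.0, tolerance = 1e-6)
  expect_equal(attr(p1b, "baseline"), 120, tolerance = 1e-3)

  # noiseless sum of two Gaussians: both centres recovered
  h2 <- gaussian_histogram(mu = c(-3.79, -2.45), sigma = c(0.2, 0.25),
                           amplitude = c(300, 150))
  p2 <- fit_gaussian_peaks(h2, k = 2, baseline = FALSE)
  expect_equal(p2$mu_log, c(-3.79, -2.45), tolerance = 1e-4)
  expect_equal(p2$amplitude, c(300, 150), tolerance = 1e-2)

  # peaks come back sorted by position
  expect_true(all(diff(p2$mu_log) > 0))
})

test_that("fitting is idempotent: refitting from the solution reproduces it", {
  h <- gaussian_histogram(mu = c(-3.8, -2.5), sigma = c(0.18, 0.2),
                          amplitude = c(400, 250), baseline = 80)
  p <- fit_gaussian_peaks(h, k = 2)
  # feed the fitted parameters back as a histogram built from the model
  h2 <- gaussian_histogram(mu = p$mu_log, sigma = p$sigma_log,
                           amplitude = p$amplitude,
                           baseline = attr(p, "baseline"))
  p2 <- fit_gaussian_peaks(h2, k = 2)
  expect_equal(p2$mu_log, p$mu_log, tolerance = 1e-6)
  expect_equal(p2$sigma_log, p$sigma_log, tolerance = 1e-6)
})

test_that("initialization refuses more peaks than separable maxima", {
  h1 <- gaussian_histogram(mu = -3.0, sigma = 0.2, amplitude = 500)
  expect_error(fit_gaussian_peaks(h1, k = 3), "reduce k")
})

test_that("well-separated peaks are resolved, never merged", {
  # default widths, separation >= 1 decade, screening and noise on
  for (seed in c(60, 61)) {
    mix <- mixture_spec(c("ds_CG3x3", "CG3x3_quad"), c(1e-6, 1e-6))
    ens <- simulate_ensemble(1200, mix, generator_config(), seed = seed)
    hist <- build_histogram(screen_ensemble(ens)$selected)
    peaks <- fit_gaussian_peaks(hist, k = 2)
    expect_equal(nrow(peaks), 2)
    expect_gt(abs(diff(peaks$mu_log)), 0.8)
    expect_true(all(peak_present(peaks)))
  }
})

test_that("generator means are recovered within 0.05 decades across the window", {
  # parameter-recovery sweep over 1e-5..1e-2 G0 with noise and screening on
  mus <- c(1e-5, 1e-4, 1e-3, 1e-2)
  for (i in seq_along(mus)) {
    sp <- species_model("sweep", conductance_g0 = mus[i])
    mix <- mixture_spec(list(sp), 1e-6, p_junction = 0.125)
    ens <- simulate_ensemble(2000, mix, generator_config(), seed = 70 + i)
    hist <- build_histogram(screen_ensemble(ens)$selected)
    peaks <- fit_gaussian_peaks(hist, k = 1)
    expect_lt(abs(peaks$mu_log - log10(mus[i])), 0.05)
  }
})

test_that("repeat summaries report mean and sample standard deviation per matched peak", {
  mk <- function(mu) {
    out <- data.frame(mu_log = mu, sigma_log = 0.2, amplitude = 100,
                      conductance_g0 = 10^mu)
    class(out) <- c("smbj_peaks", "data.frame")
    out
  }
  # three identical repeats -> zero spread
  s0 <- summarize_repeats(list(mk(-3.5), mk(-3.5), mk(-3.5)))
  expect_equal(s0$sd_g0, 0)

  # hand-computed: repeats at 1, 2, 3 x 1e-4 G0
  reps <- list(mk(log10(1e-4)), mk(log10(2e-4)), mk(log10(3e-4)))
  s1 <- summarize_repeats(reps)
  expect_equal(s1$mean_g0, 2e-4, tolerance = 1e-12)
  expect_equal(s1$sd_g0, 1e-4, tolerance = 1e-12)
  expect_equal(s1$n_repeats, 3)

  # two-peak repeats are matched by nearest position even when order varies
  two <- function(mu1, mu2) mk(c(mu1, mu2))
  s2 <- summarize_repeats(list(two(-3.8, -2.4), two(-3.75, -2.45)))
  expect_equal(s2$mu_log_mean, c(-3.775, -2.425))

  expect_error(summarize_repeats(list(mk(-3), two(-3.8, -2.4))),
               "cannot be matched")
})

test_that("the conductance quantum conversion follows from physical constants", {
  expect_equal(round(conductance_quantum_uS(), 2), 77.48)
  expect_equal(g0_to_microsiemens(0), 0)
  expect_equal(g0_to_microsiemens(3.55e-3), 3.55e-3 * 77.48091729,
               tolerance = 1e-7)
  expect_equal(g0_to_microsiemens(3.55e-3), 0.2751, tolerance = 1e-3)
  expect_error(g0_to_microsiemens(-1), "non-negative")
})
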