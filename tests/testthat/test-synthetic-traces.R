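test_that("capture weights normalise, compress concentration, and exclude parallel quads", {
  # single species
  m1 <- mixture_spec("ds_GGCGAGCGCC", 3e-7)
  expect_equal(unname(capture_weights(m1)), 1)

  # two identical species at equal concentration
  sp <- smbj_species("ds_GGCGAGCGCC")
  sp2 <- sp; sp2$name <- "copy"
  m2 <- mixture_spec(list(sp, sp2), c(2e-7, 2e-7))
  expect_equal(unname(capture_weights(m2)), c(0.5, 0.5))

  # closed-form oracle: w1 = r^alpha / (1 + r^alpha) for equal affinities
  r <- 4.44e-9
  m3 <- mixture_spec(c("G3T3G3_quad", "ds_GGCGAGCGCC"), c(r * 0.45e-6, 0.45e-6))
  w_expect <- r^0.08 / (1 + r^0.08)
  expect_equal(unname(capture_weights(m3))[1], w_expect, tolerance = 1e-12)
  expect_equal(w_expect, 0.177, tolerance = 0.02)  # ~0.18: minor species stays visible

  # parallel topology cannot bridge: weight 0
  par_quad <- species_model("pq", conductance_g0 = 3e-3,
                            topology = "parallel_quad")
  m4 <- mixture_spec(list(par_quad, sp), c(1e-6, 1e-6))
  w <- capture_weights(m4)
  expect_equal(unname(w[1]), 0)
  expect_equal(sum(w), 1)
  m5 <- mixture_spec(list(par_quad), 1e-6)
  expect_error(capture_weights(m5), "no junction-forming species")
  expect_error(capture_weights(mixture_spec(sp, 0)), "no junction-forming")
})

test_that("the KCl environment flips antiparallel quads and shifts duplex conductance", {
  mix_pbs <- default_mix()
  expect_identical(apply_environment(mix_pbs), mix_pbs)

  quad_only <- mixture_spec("CG3x3_quad", 1e-6,
                            environment = environment_condition("PBS_KCl"))
  shifted <- apply_environment(quad_only)
  expect_equal(shifted$components[[1]]$species$topology, "parallel_quad")
  expect_error(capture_weights(shifted), "no junction-forming species")

  mix_kcl <- default_mix(environment = "PBS_KCl")
  shifted <- apply_environment(mix_kcl)
  duplex <- shifted$components[[1]]$species
  expect_equal(10^duplex$mu, 3.13e-4, tolerance = 1e-9)  # KCl-condition value
  expect_equal(shifted$components[[2]]$species$topology, "parallel_quad")
  # idempotent
  expect_identical(apply_environment(shifted), shifted)

  expect_error(environment_condition("PBS", kcl_mM = 50), "kcl_mM = 0")
})

test_that("noiseless tunneling traces are exact lines with slope -beta", {
  cfg <- quiet_gen()
  mix <- default_mix(p_junction = 0)
  set.seed(99)
  tr <- simulate_trace(mix, cfg)
  y <- log10(tr$conductance)
  n <- length(y)
  # all but the final floor-clamped sample lie exactly on the line
  expect_equal(y[-n], log10(cfg$ceiling) - cfg$beta * tr$distance[-n],
               tolerance = 1e-12)
  expect_equal(y[n], log10(cfg$floor), tolerance = 1e-12)
  expect_true(is.na(tr$label))
  # spacing is retraction_rate / sampling_rate
  expect_equal(unique(round(diff(tr$distance), 12)),
               cfg$retraction_rate / cfg$sampling_rate)
})

test_that("forced noiseless junctions hold the plateau for round(L*fs/v) samples at mu", {
  sp <- species_model("flat", conductance_g0 = 1e-3, sigma_between = 0,
                      plateau_length_mean = 0.31, plateau_length_sd = 0)
  mix <- mixture_spec(list(sp), 1e-6, p_junction = 1)
  cfg <- quiet_gen(plateau_slope = 0)
  set.seed(7)
  tr <- simulate_trace(mix, cfg)
  y <- log10(tr$conductance)
  n_expect <- round(0.31 * cfg$sampling_rate / cfg$retraction_rate)
  at_mu <- which(abs(y - sp$mu) < 1e-12)
  expect_equal(length(at_mu), n_expect)
  expect_equal(at_mu, seq(min(at_mu), length.out = n_expect))  # consecutive
  expect_equal(tr$label, "flat")
})

test_that("the default floor corresponds to the 10 pA preamplifier limit at 0.1 V", {
  cfg <- generator_config()
  # 10 pA / 0.1 V = 1e-10 S = 1.29e-6 G0
  expect_equal(cfg$floor, 1.29e-6, tolerance = 0.003)
  set.seed(12)
  tr <- simulate_trace(default_mix(), cfg)
  expect_equal(tr$conductance[length(tr$conductance)], cfg$floor,
               tolerance = 1e-12)
})

test_that("ensembles are seed-deterministic and respect the conductance window", {
  mix <- default_mix()
  cfg <- generator_config()
  e1 <- simulate_ensemble(60, mix, cfg, seed = 42)
  e2 <- simulate_ensemble(60, mix, cfg, seed = 42)
  expect_identical(unclass(e1)[], unclass(e2)[])
  e3 <- simulate_ensemble(60, mix, cfg, seed = 43)
  expect_false(identical(unclass(e1)[], unclass(e3)[]))

  for (tr in e1) {
    expect_true(all(tr$conductance >= cfg$floor - 1e-15))
    expect_true(all(tr$conductance <= cfg$ceiling + 1e-15))
    expect_equal(length(tr$distance), length(tr$conductance))
    expect_gt(length(tr$distance), 0)
  }
})

test_that("the junction fraction follows Binomial(n, p_junction)", {
  mix0 <- default_mix(p_junction = 0)
  e0 <- simulate_ensemble(200, mix0, generator_config(), seed = 1)
  expect_equal(sum(!is.na(trace_labels(e0))), 0)

  n <- 2000
  p <- 0.125
  ens <- simulate_ensemble(n, default_mix(), generator_config(), seed = 2)
  k <- sum(!is.na(trace_labels(ens)))
  expect_lt(abs(k - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("species draw frequencies match the capture weights", {
  mix <- mixture_spec(c("ds_GGCGAGCGCC", "G3T3G3_quad"), c(0.45e-6, 2e-12),
                      p_junction = 1)
  w <- capture_weights(mix)
  ens <- simulate_ensemble(1500, mix, generator_config(), seed = 8)
  tab <- table(factor(trace_labels(ens), levels = names(w)))
  expect_gt(stats::chisq.test(tab, p = w)$p.value, 1e-4)
})

test_that("a species mean outside the conductance window is rejected", {
  sp <- species_model("toolow", conductance_g0 = 1e-8)
  mix <- mixture_spec(list(sp), 1e-6, p_junction = 1)
  set.seed(4)
  expect_error(simulate_trace(mix, generator_config()),
               "window cannot contain")
})

test_that("type constructors enforce their invariants", {
  expect_error(species_model("x", conductance_g0 = 1e-3, sigma_between = -1),
               "sigma_between")
  expect_error(species_model("x", conductance_g0 = 1e-3,
                             plateau_length_mean = 0), "plateau_length_mean")
  expect_error(species_model("x", conductance_g0 = 1e-3,
                             capture_affinity = -0.1), "capture_affinity")
  expect_error(species_model("x"), "exactly one")
  expect_error(mixture_spec("ds_GGCGAGCGCC", -1e-6), "concentrations")
  expect_error(mixture_spec("ds_GGCGAGCGCC", 1e-6, p_junction = 1.2),
               "p_junction")
  expect_error(mixture_spec(list(), numeric(0)), "at least one")
  expect_error(generator_config(beta = -1), "beta")
  expect_error(generator_config(ceiling = 1e-7), "ceiling > floor")
  expect_error(generator_config(noise_sd = -0.1), "noise_sd")
  expect_error(smbj_species("nope"), "unknown species preset")
  expect_error(smbj_trace(c(0, 1), 1, 0.1, 4e4, 80), "equal, nonzero length")
  expect_error(smbj_trace(c(0, 1, 1), c(1, 1, 1), 0.1, 4e4, 80),
               "strictly increase")
})
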