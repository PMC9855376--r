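# Shared fixtures and independent brute-force oracles.

default_mix <- function(p_junction = 0.125, environment = "PBS") {
  mixture_spec(c("ds_CG3x3", "CG3x3_quad"), c(1e-6, 1e-6),
               environment = environment_condition(environment),
               p_junction = p_junction)
}

quiet_gen <- function(...) {
  # noiseless generator for exact-construction oracles
  generator_config(noise_sd = 0, ...)
}

# Force a junction on every retraction without touching screening defaults.
forced_mix <- function(species = "ds_GGCGAGCGCC", conc = 1e-6, ...) {
  mixture_spec(species, conc, p_junction = 1, ...)
}

# Independent OLS oracle via stats::lm (the package uses closed-form sums).
oracle_semilog_fit <- function(trace, window = c(-5.5, -1)) {
  y <- log10(trace$conductance)
  keep <- y >= window[1] & y < window[2]
  fit <- stats::lm(y[keep] ~ trace$distance[keep])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       residual = sqrt(mean(residuals(fit)^2)))
}

# Brute-force half-open bin assignment, one sample at a time.
oracle_bin_counts <- function(values, edges) {
  counts <- integer(length(edges) - 1L)
  for (v in values) {
    for (b in seq_len(length(edges) - 1L)) {
      if (v >= edges[b] && v < edges[b + 1L]) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}

# Straightforward reimplementation of the whole two-criterion screen.
oracle_screen <- function(traces, config) {
  edges <- log_bin_edges(config$window, config$bins_per_decade)
  vapply(traces, function(tr) {
    y <- log10(tr$conductance)
    keep <- y >= config$window[1] & y < config$window[2]
    fit <- stats::lm(y[keep] ~ tr$distance[keep])
    rmse <- sqrt(mean(residuals(fit)^2))
    counts <- oracle_bin_counts(y, edges)
    rmse >= config$residual_threshold &&
      max(counts) >= config$amplitude_threshold
  }, logical(1))
}

# Exactly sampled Gaussian histogram (optionally two components + offset).
gaussian_histogram <- function(mu, sigma, amplitude, baseline = 0,
                               edges = log_bin_edges()) {
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- rep(baseline, length(centers))
  for (j in seq_along(mu)) {
    counts <- counts + amplitude[j] *
      exp(-0.5 * ((centers - mu[j]) / sigma[j])^2)
  }
  structure(list(edges = edges, centers = centers, counts = counts,
                 n_traces = 0L),
            class = "smbj_histogram")
}
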