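#' Generator configuration for synthetic retraction traces
#'
#' Parameters of the synthetic break-junction experiment.  Conductance is
#' dimensionless (G/G0) throughout; the window `[floor, ceiling]` emulates
#' the preamplifier: traces start at the saturation ceiling and end at the
#' current noise floor.  By default the floor is computed from a 10 pA
#' preamplifier limit at the configured bias, giving about 1.29e-6 G0 at
#' 0.1 V.
#'
#' @param beta Tunneling decay rate, decades of conductance per nm (> 0).
#' @param ceiling Upper conductance bound in G0 units (saturation).
#' @param floor Lower conductance bound in G0 units (noise floor); default
#'   derived from a 10 pA current limit at `bias`.
#' @param noise_sd Per-sample noise in decades (log-normal multiplicative).
#' @param plateau_slope Tilt of conductance plateaus, decades/nm.  The tilt
#'   is centred on the drawn plateau level so the level remains the mean
#'   log-conductance of the plateau.
#' @param bias Applied bias, volts.
#' @param sampling_rate Samples per second.
#' @param retraction_rate Electrode retraction speed, nm/s.
#' @param seed Default integer seed for [simulate_ensemble()].
#' @return An object of class `smbj_generator`.
#' @export
generator_config <- function(beta = 6, ceiling = 0.1, floor = NULL,
                             noise_sd = 0.05, plateau_slope = -0.3,
                             bias = 0.1, sampling_rate = 4e4,
                             retraction_rate = 80, seed = 1L) {
  if (bias <= 0) stop("bias must be > 0", call. = FALSE)
  if (is.null(floor)) floor <- noise_floor_g0(bias)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (!(ceiling > floor && floor > 0)) {
    stop("need ceiling > floor > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (sampling_rate <= 0 || retraction_rate <= 0) {
    stop("sampling_rate and retraction_rate must be > 0", call. = FALSE)
  }
  structure(
    list(beta = beta, ceiling = ceiling, floor = floor, noise_sd = noise_sd,
         plateau_slope = plateau_slope, bias = bias,
         sampling_rate = sampling_rate, retraction_rate = retraction_rate,
         seed = as.integer(seed)),
    class = "smbj_generator"
  )
}

#' A single conductance-distance retraction trace
#'
#' @param distance Distances in nm, starting at 0, strictly increasing by
#'   `retraction_rate / sampling_rate` per sample.
#' @param conductance Conductance samples in G0 units, same length.
#' @param bias Bias in volts.
#' @param sampling_rate Samples/s.
#' @param retraction_rate nm/s.
#' @param label Optional ground-truth species name (`NA` for tunneling-only
#'   traces and for real data).
#' @return An object of class `smbj_trace`.
#' @export
smbj_trace <- function(distance, conductance, bias, sampling_rate,
                       retraction_rate, label = NA_character_) {
  n <- length(distance)
  if (n == 0L || length(conductance) != n) {
    stop("distance and conductance must have equal, nonzero length",
         call. = FALSE)
  }
  if (distance[1] != 0 || (n > 1L && any(diff(distance) <= 0))) {
    stop("distance must start at 0 and strictly increase", call. = FALSE)
  }
  structure(
    list(distance = distance, conductance = conductance, bias = bias,
         sampling_rate = sampling_rate, retraction_rate = retraction_rate,
         label = label),
    class = "smbj_trace"
  )
}

#' @export
print.smbj_trace <- function(x, ...) {
  cat(sprintf("<smbj_trace> %d samples over %.3g nm%s\n",
              length(x$distance), max(x$distance),
              if (is.na(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

# Drawn plateau length in samples; truncated-normal (> 0) by rejection.
.draw_plateau_samples <- function(sp, step_nm) {
  repeat {
    L <- stats::rnorm(1, sp$plateau_length_mean, sp$plateau_length_sd)
    if (L > 0) break
  }
  round(L * 1 / step_nm)
}

#' Simulate one retraction trace
#'
#' Draws one conductance-distance trace from the current RNG stream.  With
#' probability `1 - p_junction` the trace is a pure tunneling decay,
#' `log10 G(d) = log10(ceiling) - beta * d` plus noise.  Otherwise a species
#' is drawn according to [capture_weights()], a plateau level from
#' `Normal(mu, sigma_between)` and a plateau length from the species' length
#' distribution (truncated positive); the trace decays to the plateau level,
#' holds it for `round(length * sampling_rate / retraction_rate)` samples
#' (with the configured tilt, centred on the level), then decays to the
#' floor.  The trace ends at the first sample at or below the floor and all
#' samples are clamped to `[floor, ceiling]`.
#'
#' The environment of the mixture is applied first, so a KCl mixture whose
#' only species is an antiparallel quadruplex yields tunneling-only traces.
#'
#' @param mixture An [mixture_spec()].
#' @param config A [generator_config()].
#' @return An [smbj_trace()], with `label` set to the captured species name
#'   or `NA` for tunneling events.
#' @seealso [simulate_ensemble()] for seeded ensembles.
#' @export
simulate_trace <- function(mixture, config) {
  stopifnot(inherits(mixture, "smbj_mixture"),
            inherits(config, "smbj_generator"))
  mixture <- apply_environment(mixture)
  step <- config$retraction_rate / config$sampling_rate
  lc <- log10(config$ceiling)
  lf <- log10(config$floor)

  weights <- tryCatch(capture_weights(mixture), error = function(e) NULL)
  p_junction <- if (is.null(weights)) 0 else mixture$p_junction
  junction <- stats::runif(1) < p_junction

  if (junction) {
    idx <- if (length(weights) == 1L) 1L else {
      sample.int(length(weights), 1L, prob = weights)
    }
    sp <- mixture$components[[idx]]$species
    if (sp$mu <= lf || sp$mu >= lc) {
      stop("generator window cannot contain species mu = ", signif(sp$mu, 4),
           call. = FALSE)
    }
    level <- stats::rnorm(1, sp$mu, sp$sigma_between)
    n_p <- .draw_plateau_samples(sp, step)
    # decay samples strictly above the plateau level
    n1 <- max(0, ceiling((lc - level) / (config$beta * step) - 1e-12))
    y_decay1 <- if (n1 > 0) lc - config$beta * step * (0:(n1 - 1)) else numeric(0)
    y_plat <- if (n_p > 0) {
      level + config$plateau_slope * step * ((seq_len(n_p) - 1) - (n_p - 1) / 2)
    } else numeric(0)
    n2 <- ceiling((level - lf) / (config$beta * step))
    y <- c(y_decay1, y_plat, level - config$beta * step * seq_len(max(n2, 1L)))
    label <- sp$name
  } else {
    n <- ceiling((lc - lf) / (config$beta * step))
    y <- lc - config$beta * step * (0:n)
    label <- NA_character_
  }

  if (config$noise_sd > 0) {
    y <- y + stats::rnorm(length(y), 0, config$noise_sd)
  }
  hit <- which(y <= lf)
  y <- if (length(hit)) y[seq_len(hit[1])] else c(y, lf)
  y <- pmin(pmax(y, lf), lc)

  smbj_trace(distance = step * (seq_along(y) - 1),
             conductance = 10^y,
             bias = config$bias,
             sampling_rate = config$sampling_rate,
             retraction_rate = config$retraction_rate,
             label = label)
}

#' Simulate a seeded ensemble of retraction traces
#'
#' Draws `n` independent traces from one seeded random stream
#' (Mersenne-Twister, inversion normals), so the same seed reproduces the
#' ensemble bitwise, within a session and across processes.  The caller's
#' RNG state is preserved.
#'
#' @param n Number of traces (>= 1).
#' @param mixture An [mixture_spec()].
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of [smbj_trace()] objects with class `smbj_ensemble` and
#'   attributes `seed`, `mixture`, `config`.
#' @examples
#' mix <- mixture_spec("ds_GGCGAGCGCC", 1e-6)
#' ens <- simulate_ensemble(50, mix, generator_config(), seed = 7)
#' length(ens)
#' @export
simulate_ensemble <- function(n, mixture, config = generator_config(),
                              seed = config$seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  mixture <- apply_environment(mixture)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    traces[[i]] <- simulate_trace(mixture, config)
  }
  structure(traces, class = "smbj_ensemble", seed = as.integer(seed),
            mixture = mixture, config = config)
}

#' @export
print.smbj_ensemble <- function(x, ...) {
  labs <- vapply(x, function(tr) tr$label, character(1))
  cat(sprintf("<smbj_ensemble> %d traces (%d junction-labelled), seed %d\n",
              length(x), sum(!is.na(labs)), attr(x, "seed")))
  invisible(x)
}

#' Ground-truth labels of an ensemble
#'
#' @param ensemble A list of traces (e.g. from [simulate_ensemble()]).
#' @return Character vector of species labels, `NA` for tunneling traces.
#' @export
trace_labels <- function(ensemble) {
  vapply(ensemble, function(tr) tr$label, character(1))
}
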