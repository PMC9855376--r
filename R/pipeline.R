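#' Derive a child seed from a master seed
#'
#' Deterministic multiplicative-congruential derivation
#' `(seed * 48271 + index) mod (2^31 - 1)` (the classic MINSTD multiplier),
#' used to give every repeat and titration point its own reproducible
#' stream while keeping all seeds valid 32-bit integers.
#'
#' @param seed Master seed (integer-valued).
#' @param index Child index (integer-valued).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  s <- ((as.double(seed) %% 2147483647) * 48271 + as.double(index)) %% 2147483647
  as.integer(max(s, 1))
}

.CONFIG_KEYS <- list(
  generator = c("beta", "ceiling", "floor", "noise_sd", "plateau_slope",
                "bias", "sampling_rate", "retraction_rate", "seed"),
  mixture = c("species", "concentrations", "environment", "kcl_mM",
              "p_junction", "alpha"),
  screening = c("residual_threshold", "window", "bins_per_decade",
                "amplitude_threshold"),
  histogram = c("window", "bins_per_decade"),
  fit = c("k", "weighting", "baseline"),
  titration = c("n_per_direction", "c_min", "c_max", "c_fixed", "n_traces",
                "repeats")
)
.CONFIG_TOP <- c(names(.CONFIG_KEYS), "seed", "n_traces", "repeats")

#' Validated run configuration
#'
#' Builds the full pipeline configuration from a nested list (or a file in
#' the [read_config()] format): sections `generator`, `mixture`,
#' `screening`, `histogram`, `fit`, `titration`, plus top-level `seed`,
#' `n_traces` and `repeats`.  Every section is validated through its module
#' constructor, and unknown sections or keys are rejected.
#'
#' @param x Nested list or path to a config file.  The `mixture` section
#'   must give `species` (preset names, see [smbj_species()]) and
#'   `concentrations` (molar).
#' @return An object of class `smbj_config` holding constructed
#'   `generator`, `mixture`, `screening` objects, histogram `edges`, and
#'   `fit`, `titration`, `seed`, `n_traces`, `repeats` settings.
#' @examples
#' cfg <- smbj_config(list(
#'   mixture = list(species = c("ds_CG3x3", "CG3x3_quad"),
#'                  concentrations = c(1e-6, 1e-6)),
#'   seed = 42, n_traces = 500))
#' @export
smbj_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) x <- read_config(x)
  if (inherits(x, "smbj_config")) return(x)
  if (!is.list(x)) stop("config must be a list or a file path", call. = FALSE)
  unknown <- setdiff(names(x), .CONFIG_TOP)
  if (length(unknown)) {
    stop("unknown config section/key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(.CONFIG_KEYS)) {
    bad <- setdiff(names(x[[sec]]), .CONFIG_KEYS[[sec]])
    if (length(bad)) {
      stop("unknown key in [", sec, "]: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  gen <- do.call(generator_config, as.list(x$generator))
  mx <- x$mixture %||% list(species = c("ds_CG3x3", "CG3x3_quad"),
                            concentrations = c(1e-6, 1e-6))
  env <- environment_condition(mx$environment %||% "PBS",
                               kcl_mM = mx$kcl_mM)
  mixture <- mixture_spec(
    species = mx$species %||% c("ds_CG3x3", "CG3x3_quad"),
    concentrations = mx$concentrations %||% rep(1e-6, length(mx$species)),
    environment = env,
    p_junction = mx$p_junction %||% 0.125,
    alpha = mx$alpha %||% 0.08)
  scr <- do.call(screening_config, as.list(x$screening))
  hg <- x$histogram %||% list()
  edges <- log_bin_edges(hg$window %||% scr$window,
                         hg$bins_per_decade %||% scr$bins_per_decade)
  fit <- x$fit %||% list()
  if (!is.null(fit$k) && fit$k < 1) stop("fit k must be >= 1", call. = FALSE)
  structure(
    list(generator = gen, mixture = mixture, screening = scr, edges = edges,
         fit = list(k = fit$k %||% length(mixture$components),
                    weighting = fit$weighting %||% "none",
                    baseline = isTRUE(as.logical(fit$baseline %||% TRUE))),
         titration = as.list(x$titration),
         seed = as.integer(x$seed %||% gen$seed),
         n_traces = as.integer(x$n_traces %||% 5000),
         repeats = as.integer(x$repeats %||% 1)),
    class = "smbj_config"
  )
}

.empty_peaks <- function() {
  out <- data.frame(mu_log = numeric(0), sigma_log = numeric(0),
                    amplitude = numeric(0), conductance_g0 = numeric(0))
  class(out) <- c("smbj_peaks", "data.frame")
  out
}

# Fit k peaks, backing off to fewer peaks when initialization cannot find
# k separable maxima; returns an empty peak set for an empty histogram.
.fit_with_backoff <- function(hist, k, weighting, baseline) {
  if (sum(hist$counts) == 0) return(.empty_peaks())
  for (kk in seq(k, 1)) {
    peaks <- tryCatch(
      fit_gaussian_peaks(hist, kk, weighting = weighting,
                         baseline = baseline),
      error = function(e) NULL)
    if (!is.null(peaks)) return(peaks)
  }
  .empty_peaks()
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) an ensemble, screen it, accumulate the composite
#' conductance histogram, fit Gaussian peaks, test peak presence, assign
#' conformations, and summarise over independent repeats.  Each repeat uses
#' a seed derived from the master seed via [derive_seed()], so "N
#' independent measurements" are reproducible.
#'
#' @param config An [smbj_config()], nested list, or config file path.
#' @param traces Optional list of traces to analyse instead of simulating
#'   (screening onwards only; repeats then reuse the same traces).
#' @param table A [reference_table()] for conformation assignment.
#' @param verbose If `TRUE`, log per-stage timings and the selection
#'   fraction to stderr.
#' @return An object of class `smbj_report`: a list with `n_traces`,
#'   `repeats`, `selection_fraction` (per repeat), `peaks` (first-repeat
#'   peak table with microsiemens, presence flag and conformation labels),
#'   `summary` (repeat statistics from [summarize_repeats()] over detected
#'   peaks, when matchable), and `message` (`"no peaks detected"` when
#'   nothing passes the presence test).
#' @export
run_pipeline <- function(config = smbj_config(), traces = NULL,
                         table = reference_table(), verbose = FALSE) {
  config <- smbj_config(config)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  sel_frac <- numeric(config$repeats)
  peak_sets <- vector("list", config$repeats)
  first <- NULL
  for (r in seq_len(config$repeats)) {
    t0 <- proc.time()[["elapsed"]]
    ens <- if (is.null(traces)) {
      simulate_ensemble(config$n_traces, config$mixture, config$generator,
                        seed = derive_seed(config$seed, r))
    } else traces
    t1 <- proc.time()[["elapsed"]]
    scr <- screen_ensemble(ens, config$screening)
    sel_frac[r] <- scr$selection_fraction
    t2 <- proc.time()[["elapsed"]]
    hist <- build_histogram(scr$selected, config$edges)
    peaks <- .fit_with_backoff(hist, config$fit$k, config$fit$weighting,
                               config$fit$baseline)
    present <- if (nrow(peaks)) peak_present(peaks) else logical(0)
    detected <- peaks[present, , drop = FALSE]
    class(detected) <- class(peaks)
    attr(detected, "median_nonzero") <- attr(peaks, "median_nonzero")
    peak_sets[[r]] <- detected
    t3 <- proc.time()[["elapsed"]]
    say("repeat %d: simulate %.1fs | screen %.1fs (selection %.1f%%) | fit %.1fs",
        r, t1 - t0, t2 - t1, 100 * scr$selection_fraction, t3 - t2)
    if (r == 1L) {
      labels <- assign_conformations(detected, table)
      first <- list(hist = hist, peaks = peaks, present = present,
                    labels = labels)
    }
  }
  kdet <- vapply(peak_sets, nrow, integer(1))
  summary <- if (all(kdet == kdet[1]) && kdet[1] > 0) {
    tryCatch(summarize_repeats(peak_sets), error = function(e) NULL)
  } else NULL
  ptab <- first$peaks
  ptab$microsiemens <- g0_to_microsiemens(ptab$conductance_g0)
  ptab$present <- first$present
  ptab$conformation <- rep("unassigned", nrow(ptab))
  if (any(first$present)) ptab$conformation[first$present] <- first$labels
  structure(
    list(n_traces = if (is.null(traces)) config$n_traces else length(traces),
         repeats = config$repeats,
         selection_fraction = sel_frac,
         histogram = first$hist,
         peaks = ptab,
         summary = summary,
         message = if (!any(first$present)) "no peaks detected" else ""),
    class = "smbj_report"
  )
}

#' @export
print.smbj_report <- function(x, ...) {
  cat(sprintf("<smbj_report> %d traces x %d repeat(s)\n", x$n_traces,
              x$repeats))
  cat(sprintf("  selection fraction: %s\n",
              paste(sprintf("%.1f%%", 100 * x$selection_fraction),
                    collapse = ", ")))
  if (nzchar(x$message)) {
    cat("  ", x$message, "\n", sep = "")
  } else {
    p <- x$peaks[x$peaks$present, , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      cat(sprintf("  peak %d: %.3g G0 (%.4g uS), sigma %.2f dec, amp %.0f -> %s\n",
                  i, p$conductance_g0[i], p$microsiemens[i], p$sigma_log[i],
                  p$amplitude[i], p$conformation[i]))
    }
    if (!is.null(x$summary)) {
      for (i in seq_len(nrow(x$summary))) {
        cat(sprintf("  repeat stats peak %d: %.3g +/- %.2g G0 (n=%d)\n",
                    i, x$summary$mean_g0[i], x$summary$sd_g0[i],
                    x$summary$n_repeats[i]))
      }
    }
  }
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report An [run_pipeline()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    n_traces = report$n_traces,
    repeats = report$repeats,
    selection_fraction = report$selection_fraction,
    peaks = report$peaks,
    summary = report$summary,
    message = report$message
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}
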