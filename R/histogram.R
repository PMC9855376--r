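#' Composite semi-logarithmic conductance histogram
#'
#' Adds the in-window samples of all selected traces into one histogram over
#' log10(G/G0) with half-open bins.  The total count equals the number of
#' in-window samples across the traces (count conservation).
#'
#' @param traces List of [smbj_trace()] objects (normally the selected
#'   subset from [screen_ensemble()]); may be empty.
#' @param edges Monotone increasing bin edges in log10(G/G0); defaults to
#'   the standard window `[-5.5, -1)` at 40 bins/decade.
#' @return An object of class `smbj_histogram`: a list with `edges`,
#'   `centers`, `counts` and `n_traces`.
#' @export
build_histogram <- function(traces, edges = log_bin_edges()) {
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    stop("edges must be strictly increasing", call. = FALSE)
  }
  counts <- integer(length(edges) - 1L)
  for (tr in traces) {
    counts <- counts + .bin_counts(log10(tr$conductance), edges)
  }
  structure(
    list(edges = edges,
         centers = (edges[-1] + edges[-length(edges)]) / 2,
         counts = counts,
         n_traces = length(traces)),
    class = "smbj_histogram"
  )
}

#' @export
print.smbj_histogram <- function(x, ...) {
  cat(sprintf(
    "<smbj_histogram> %d bins over [%.2f, %.2f] log10(G/G0), %d traces, %d counts\n",
    length(x$counts), min(x$edges), max(x$edges), x$n_traces, sum(x$counts)))
  invisible(x)
}

#' @export
plot.smbj_histogram <- function(x, peaks = NULL, ...) {
  graphics::plot(x$centers, x$counts, type = "s",
                 xlab = expression(log[10](G / G[0])), ylab = "Counts", ...)
  if (!is.null(peaks)) {
    xx <- seq(min(x$edges), max(x$edges), length.out = 400)
    yy <- rep(attr(peaks, "baseline") %||% 0, length(xx))
    for (i in seq_len(nrow(peaks))) {
      yy <- yy + peaks$amplitude[i] *
        exp(-0.5 * ((xx - peaks$mu_log[i]) / peaks$sigma_log[i])^2)
    }
    graphics::lines(xx, yy, col = "red", lwd = 2)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Initialization for the peak fit: local maxima of a lightly smoothed
# histogram, greedily thinned to a minimum separation, tallest first.
.peak_init <- function(x, y, k, min_separation) {
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  n <- length(ys)
  cand <- which(ys >= c(-Inf, ys[-n]) & ys > c(ys[-1], -Inf) & y > 0)
  if (length(cand) == 0L) cand <- which.max(y)
  cand <- cand[order(ys[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(x[i] - x[keep]) >= min_separation)) keep <- c(keep, i)
    if (length(keep) == k) break
  }
  if (length(keep) < k) {
    stop("initialization failed; reduce k", call. = FALSE)
  }
  list(mu = x[keep], A = pmax(y[keep], 1))
}

#' Fit a sum of Gaussians to a conductance histogram
#'
#' Nonlinear least squares of `k` Gaussian peaks (in log10-conductance
#' space) to the bin counts, as is standard for break-junction histograms.
#' Initial centres are the `k` most prominent local maxima separated by at
#' least `min_separation` decades.  Optionally the counts can be weighted by
#' the Poisson expectation, and a constant baseline can be included.
#'
#' @param hist An [build_histogram()] result.
#' @param k Number of peaks (>= 1).
#' @param weighting `"none"` (unweighted least squares, default) or
#'   `"poisson"` (residuals scaled by the square root of the model counts).
#' @param baseline If `TRUE` (default), add a constant offset to the model.
#'   The composite histogram of selected traces carries a nearly uniform
#'   background from the tunneling-decay segments of every trace (about
#'   `sampling_rate / (retraction_rate * beta * bins_per_decade)` counts per
#'   bin per trace); without the offset a multi-peak fit absorbs that
#'   background into the Gaussians and misplaces their centres.  Set
#'   `baseline = FALSE` for background-free histograms.
#' @param min_separation Minimum separation of initial centres, decades.
#' @param control Passed to [minpack.lm::nls.lm()].
#' @return A data frame of class `smbj_peaks`, one row per peak sorted by
#'   `mu_log`, with columns `mu_log`, `sigma_log`, `amplitude`,
#'   `conductance_g0`, and attributes `converged`, `info`, `baseline`,
#'   `median_nonzero` (median nonzero bin count of the histogram).
#' @examples
#' mix <- mixture_spec("ds_GGCGAGCGCC", 1e-6)
#' ens <- simulate_ensemble(400, mix, generator_config(), seed = 11)
#' hist <- build_histogram(screen_ensemble(ens)$selected)
#' fit_gaussian_peaks(hist, k = 1)
#' @export
fit_gaussian_peaks <- function(hist, k, weighting = c("none", "poisson"),
                               baseline = TRUE, min_separation = 0.5,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500, ftol = 1e-13, ptol = 1e-13)) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(hist, "smbj_histogram"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("k must be >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  x <- hist$centers
  y <- as.numeric(hist$counts)
  if (sum(y > 0) < 3L * k) {
    stop("histogram has fewer than 3k nonempty bins", call. = FALSE)
  }
  init <- .peak_init(x, y, k, min_separation)

  model <- function(par) {
    A <- par[seq_len(k)]
    mu <- par[k + seq_len(k)]
    sg <- par[2L * k + seq_len(k)]
    b <- if (baseline) par[3L * k + 1L] else 0
    yhat <- rep(b, length(x))
    for (j in seq_len(k)) {
      yhat <- yhat + A[j] * exp(-0.5 * ((x - mu[j]) / sg[j])^2)
    }
    yhat
  }
  residfun <- function(par) {
    r <- y - model(par)
    if (weighting == "poisson") r <- r / sqrt(pmax(model(par), 1))
    r
  }
  par0 <- c(init$A, init$mu, rep(0.15, k), if (baseline) max(min(y), 0))
  span <- max(x) - min(x)
  lower <- c(rep(0, k), rep(min(x), k), rep(1e-3, k), if (baseline) 0)
  upper <- c(rep(Inf, k), rep(max(x), k), rep(span, k), if (baseline) Inf)
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = residfun, control = control)
  p <- fit$par
  ord <- order(p[k + seq_len(k)])
  out <- data.frame(
    mu_log = p[k + seq_len(k)][ord],
    sigma_log = abs(p[2L * k + seq_len(k)][ord]),
    amplitude = p[seq_len(k)][ord],
    conductance_g0 = 10^(p[k + seq_len(k)][ord])
  )
  class(out) <- c("smbj_peaks", "data.frame")
  attr(out, "converged") <- fit$info %in% 1:4
  attr(out, "info") <- fit$info
  attr(out, "baseline") <- if (baseline) p[3L * k + 1L] else NULL
  nz <- y[y > 0]
  attr(out, "median_nonzero") <- if (length(nz)) stats::median(nz) else 0
  out
}

#' Peak-presence test
#'
#' Decides which fitted peaks correspond to a real conductance population
#' rather than the smooth tunneling background or counting noise.  The
#' composite histogram of selected traces carries a roughly uniform
#' background from the decay segments of every trace; a peak is declared
#' present when its height above that background exceeds `n_sigma` times
#' the Poisson fluctuation of the background level (estimated by the median
#' nonzero bin count), and its width is that of a plateau population rather
#' than a background artefact.  When the fit included a constant baseline
#' the amplitude is already the height above background; otherwise the
#' background level is subtracted first.
#'
#' @param peaks An [fit_gaussian_peaks()] result.
#' @param n_sigma Significance multiple on the background counting noise.
#' @param sigma_max Maximum credible peak width, decades.
#' @return Logical vector, one entry per peak.
#' @export
peak_present <- function(peaks, n_sigma = 5, sigma_max = 0.6) {
  m <- attr(peaks, "median_nonzero") %||% 0
  excess <- if (is.null(attr(peaks, "baseline"))) {
    peaks$amplitude - m
  } else {
    peaks$amplitude
  }
  excess >= n_sigma * sqrt(max(m, 1)) & peaks$sigma_log <= sigma_max
}

#' Summarise peak positions over independent repeats
#'
#' Matches peaks across repeats by nearest log-conductance to the first
#' repeat's peaks (one-to-one) and reports the mean and sample standard
#' deviation of the conductance of each matched peak, the convention used
#' to quote a conductance value with its error from several independent
#' measurements.
#'
#' @param peak_list List of [fit_gaussian_peaks()] results, one per repeat,
#'   all with the same number of peaks.
#' @return A data frame with one row per peak: `peak`, `mu_log_mean`,
#'   `mean_g0`, `sd_g0`, `n_repeats`.  `sd_g0` is `NA` for a single repeat.
#' @export
summarize_repeats <- function(peak_list) {
  if (length(peak_list) < 1L) stop("need at least one repeat", call. = FALSE)
  k <- nrow(peak_list[[1]])
  if (any(vapply(peak_list, nrow, integer(1)) != k)) {
    stop("peaks cannot be matched one-to-one across repeats", call. = FALSE)
  }
  ref <- peak_list[[1]]$mu_log
  g <- matrix(NA_real_, nrow = k, ncol = length(peak_list))
  mu <- matrix(NA_real_, nrow = k, ncol = length(peak_list))
  for (r in seq_along(peak_list)) {
    pk <- peak_list[[r]]
    # greedy one-to-one matching by smallest |mu - ref|
    d <- abs(outer(ref, pk$mu_log, "-"))
    take_ref <- rep(NA_integer_, k)
    for (step in seq_len(k)) {
      i <- which(d == min(d), arr.ind = TRUE)[1, ]
      take_ref[i[1]] <- i[2]
      d[i[1], ] <- Inf
      d[, i[2]] <- Inf
    }
    if (anyNA(take_ref) || anyDuplicated(take_ref)) {
      stop("peaks cannot be matched one-to-one across repeats", call. = FALSE)
    }
    g[, r] <- pk$conductance_g0[take_ref]
    mu[, r] <- pk$mu_log[take_ref]
  }
  data.frame(
    peak = seq_len(k),
    mu_log_mean = rowMeans(mu),
    mean_g0 = rowMeans(g),
    sd_g0 = apply(g, 1, function(v) if (length(v) > 1) stats::sd(v) else NA_real_),
    n_repeats = length(peak_list)
  )
}
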