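#' Screening configuration
#'
#' Parameters of the two-criterion automated trace screen: traces well fit
#' by a straight line on the semi-log plot (tunneling decays) are rejected
#' by the residual criterion, and surviving traces must additionally show a
#' spike in their individual log-conductance histogram (the signature of a
#' plateau).
#'
#' @param residual_threshold Minimum root-mean-square residual (decades) of
#'   the semi-log line fit for a trace to be kept.
#' @param window `c(low, high)` in log10(G/G0); both criteria are evaluated
#'   on samples with `low <= log10(G) < high`.
#' @param bins_per_decade Bin density of the per-trace histogram; the same
#'   convention is used for the composite histogram.
#' @param amplitude_threshold Minimum count in the tallest per-trace bin.
#' @return An object of class `smbj_screening`.
#' @export
screening_config <- function(residual_threshold = 0.15,
                             window = c(-5.5, -1),
                             bins_per_decade = 40,
                             amplitude_threshold = 15) {
  if (residual_threshold <= 0) {
    stop("residual_threshold must be > 0", call. = FALSE)
  }
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("window must be c(low, high) with high > low", call. = FALSE)
  }
  if (bins_per_decade < 1) stop("bins_per_decade must be >= 1", call. = FALSE)
  if (amplitude_threshold < 1) {
    stop("amplitude_threshold must be >= 1", call. = FALSE)
  }
  structure(
    list(residual_threshold = residual_threshold, window = window,
         bins_per_decade = bins_per_decade,
         amplitude_threshold = amplitude_threshold),
    class = "smbj_screening"
  )
}

#' Log-conductance bin edges
#'
#' Half-open bins `[edge_i, edge_{i+1})` of width `1 / bins_per_decade`
#' starting at `window[1]`; the last edge is the largest that does not
#' exceed `window[2]`.
#'
#' @param window `c(low, high)` in log10(G/G0).
#' @param bins_per_decade Bins per decade.
#' @return Numeric vector of bin edges.
#' @export
log_bin_edges <- function(window = c(-5.5, -1), bins_per_decade = 40) {
  nb <- floor(diff(window) * bins_per_decade + 1e-9)
  if (nb < 1) stop("window too narrow for bin width", call. = FALSE)
  window[1] + (0:nb) / bins_per_decade
}

# Counts of values in half-open bins [e_i, e_{i+1}); values outside ignored.
.bin_counts <- function(y, edges) {
  nb <- length(edges) - 1L
  idx <- findInterval(y, edges)
  tabulate(idx[idx >= 1L & idx <= nb & y < edges[nb + 1L]], nbins = nb)
}

#' Fit a straight line to a trace on the semi-log plot
#'
#' Ordinary least squares of log10(conductance) against distance over the
#' in-window samples.  A pure tunneling decay is an exact line in these
#' coordinates, so its residual is zero; a plateau breaks the line.
#'
#' @param trace An [smbj_trace()].
#' @param window `c(low, high)` in log10(G/G0).
#' @return A list with `slope` (decades/nm), `intercept` (decades) and
#'   `residual` (RMS of the fit residuals, decades).
#' @export
fit_semilog_line <- function(trace, window = c(-5.5, -1)) {
  y <- log10(trace$conductance)
  keep <- y >= window[1] & y < window[2]
  if (sum(keep) < 3L) stop("trace too short to screen", call. = FALSE)
  x <- trace$distance[keep]
  yy <- y[keep]
  mx <- mean(x)
  my <- mean(yy)
  sxx <- sum((x - mx)^2)
  slope <- if (sxx == 0) 0 else sum((x - mx) * (yy - my)) / sxx
  intercept <- my - slope * mx
  res <- yy - (intercept + slope * x)
  list(slope = slope, intercept = intercept,
       residual = sqrt(mean(res^2)))
}

#' Per-trace log-conductance histogram
#'
#' Counts of in-window samples in half-open bins of width
#' `1 / bins_per_decade`.  Traces with a plateau show a sharp spike; pure
#' decays spread their samples evenly.
#'
#' @param trace An [smbj_trace()].
#' @param config A [screening_config()].
#' @return Integer vector of counts, one per bin of
#'   `log_bin_edges(config$window, config$bins_per_decade)`.
#' @export
per_trace_histogram <- function(trace, config = screening_config()) {
  edges <- log_bin_edges(config$window, config$bins_per_decade)
  .bin_counts(log10(trace$conductance), edges)
}

#' Screen one trace
#'
#' Applies the two criteria in order: the semi-log line-fit residual must
#' reach `residual_threshold` (rejecting tunneling decays) and the tallest
#' bin of the individual histogram must reach `amplitude_threshold`
#' (requiring a plateau spike inside the window).
#'
#' @param trace An [smbj_trace()].
#' @param config A [screening_config()].
#' @return A list with `residual`, `max_bin_count`, `max_bin_center` and
#'   `selected` (class `smbj_screening_result`).
#' @export
screen_trace <- function(trace, config = screening_config()) {
  fit <- fit_semilog_line(trace, config$window)
  counts <- per_trace_histogram(trace, config)
  edges <- log_bin_edges(config$window, config$bins_per_decade)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  imax <- which.max(counts)
  structure(
    list(residual = fit$residual,
         max_bin_count = counts[imax],
         max_bin_center = centers[imax],
         selected = fit$residual >= config$residual_threshold &&
           counts[imax] >= config$amplitude_threshold),
    class = "smbj_screening_result"
  )
}

#' Screen an ensemble of traces
#'
#' @param traces A list of [smbj_trace()] objects (e.g. an ensemble).
#' @param config A [screening_config()].
#' @return A list with `selected` (order-preserving subset of the traces),
#'   `selection_fraction`, and `results`, a data frame with one row per
#'   trace (`id`, `residual`, `max_bin_count`, `max_bin_center`, `selected`,
#'   `label`).
#' @examples
#' mix <- mixture_spec("ds_GGCGAGCGCC", 1e-6)
#' ens <- simulate_ensemble(200, mix, generator_config(), seed = 3)
#' scr <- screen_ensemble(ens)
#' scr$selection_fraction
#' @export
screen_ensemble <- function(traces, config = screening_config()) {
  if (length(traces) < 1L) stop("need at least one trace", call. = FALSE)
  res <- lapply(traces, screen_trace, config = config)
  sel <- vapply(res, function(r) r$selected, logical(1))
  results <- data.frame(
    id = seq_along(traces),
    residual = vapply(res, function(r) r$residual, numeric(1)),
    max_bin_count = vapply(res, function(r) r$max_bin_count, numeric(1)),
    max_bin_center = vapply(res, function(r) r$max_bin_center, numeric(1)),
    selected = sel,
    label = vapply(traces, function(tr) tr$label, character(1)),
    stringsAsFactors = FALSE
  )
  list(selected = traces[sel],
       selection_fraction = mean(sel),
       results = results)
}
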