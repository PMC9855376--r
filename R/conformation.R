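#' Assign fitted peaks to DNA conformations
#'
#' Labels each fitted peak with the reference conformation whose
#' log-conductance is nearest, provided the distance is within the entry's
#' tolerance.  Assignment is one-to-one, preferring globally smallest
#' distances; ties break toward the lower-conductance reference.  Peaks that
#' match no remaining reference within tolerance are labelled
#' `"unassigned"`.
#'
#' @param peaks An [fit_gaussian_peaks()] result (possibly empty).
#' @param table A [reference_table()].
#' @return Character vector of labels, one per peak.
#' @examples
#' hist_peaks <- data.frame(mu_log = log10(c(2.31e-4, 3.5e-3)),
#'                          sigma_log = 0.2, amplitude = 100,
#'                          conductance_g0 = c(2.31e-4, 3.5e-3))
#' assign_conformations(hist_peaks, reference_table())
#' @export
assign_conformations <- function(peaks, table = reference_table()) {
  if (nrow(table) < 1L) stop("reference table is empty", call. = FALSE)
  n <- nrow(peaks)
  labels <- rep("unassigned", n)
  if (n == 0L) return(character(0))
  ref_mu <- log10(table$conductance_g0)
  d <- abs(outer(peaks$mu_log, ref_mu, "-"))
  d[d > matrix(table$tol_decades, n, nrow(table), byrow = TRUE)] <- Inf
  for (step in seq_len(min(n, nrow(table)))) {
    if (all(!is.finite(d))) break
    dmin <- min(d)
    hits <- which(d == dmin, arr.ind = TRUE)
    # ties broken toward the lower-conductance reference
    hit <- hits[order(ref_mu[hits[, 2]]), , drop = FALSE][1, ]
    labels[hit[1]] <- table$conformation[hit[2]]
    d[hit[1], ] <- Inf
    d[, hit[2]] <- Inf
  }
  labels
}

#' Peak-height ratio of quadruplex to duplex
#'
#' Ratio of the fitted Gaussian amplitudes of the G-quadruplex and duplex
#' peaks, the titration readout.
#'
#' @param peaks An [fit_gaussian_peaks()] result.
#' @param labels Labels from [assign_conformations()].
#' @return `amplitude[G-quadruplex] / amplitude[duplex]`.
#' @export
peak_height_ratio <- function(peaks, labels) {
  iq <- which(labels == "G-quadruplex")
  id <- which(labels == "duplex")
  if (length(iq) != 1L || length(id) != 1L) {
    stop("ratio undefined: need exactly one G-quadruplex and one duplex peak",
         call. = FALSE)
  }
  peaks$amplitude[iq] / peaks$amplitude[id]
}

#' Concentration grid for a two-species titration
#'
#' Sweeps each species from `c_min` to `c_max` (log-spaced) while holding
#' the other at `c_fixed`, both directions, mirroring a titration in which
#' the quadruplex is swept against a fixed duplex concentration and vice
#' versa.  Duplicate grid points are dropped.
#'
#' @param n_per_direction Points per sweep direction.
#' @param c_min,c_max Sweep endpoints, molar.
#' @param c_fixed Fixed counter-species concentration, molar.
#' @return Data frame with columns `c_quad`, `c_duplex` sorted by the
#'   concentration ratio `c_quad / c_duplex`.
#' @examples
#' titration_grid(n_per_direction = 3)
#' @export
titration_grid <- function(n_per_direction = 9, c_min = 2e-15,
                           c_max = 0.45e-6, c_fixed = 0.45e-6) {
  stopifnot(c_min > 0, c_max > c_min, c_fixed > 0, n_per_direction >= 1)
  sweep <- 10^seq(log10(c_min), log10(c_max), length.out = n_per_direction)
  sweep[1] <- c_min
  sweep[n_per_direction] <- c_max
  g <- rbind(
    data.frame(c_quad = sweep, c_duplex = c_fixed),
    data.frame(c_quad = c_fixed, c_duplex = sweep)
  )
  g <- unique(g)
  g[order(g$c_quad / g$c_duplex), , drop = FALSE]
}

#' Run a two-species titration through the full pipeline
#'
#' For every `(c_quad, c_duplex)` grid point: simulate an ensemble, screen
#' it, build the composite histogram, fit two Gaussian peaks, assign
#' conformations, test peak presence, and record the quadruplex/duplex
#' peak-height ratio, averaged over independent seeded repeats.  Stage
#' failures at a point are flagged in the `note` column without aborting
#' the grid.
#'
#' @param grid Data frame with columns `c_quad`, `c_duplex` (molar, > 0), at
#'   least 2 rows; see [titration_grid()].
#' @param quad,duplex `smbj_species` objects (or preset names) for the two
#'   components.
#' @param config A [generator_config()].
#' @param screening A [screening_config()].
#' @param edges Histogram bin edges.
#' @param table A [reference_table()] for peak assignment.
#' @param n_traces Traces per ensemble.
#' @param repeats Independent measurements per grid point (averaged).
#' @param seed Master seed; per-point, per-repeat seeds are derived from it.
#' @param p_junction,alpha Passed to [mixture_spec()].
#' @param environment An [environment_condition()].
#' @return Data frame, one row per grid point: `c_quad`, `c_duplex`,
#'   `ratio` (concentration ratio), `peak_height_ratio` (mean over repeats;
#'   `NA` unless both peaks detected in every repeat), `both_detected`,
#'   `n_selected` (mean selected traces per repeat), `seed`, `note`.
#' @export
run_titration <- function(grid,
                          quad = smbj_species("G3T3G3_quad"),
                          duplex = smbj_species("ds_GGCGAGCGCC"),
                          config = generator_config(),
                          screening = screening_config(),
                          edges = log_bin_edges(),
                          table = reference_table(),
                          n_traces = 1500, repeats = 2, seed = 1,
                          p_junction = 0.125, alpha = 0.08,
                          environment = environment_condition("PBS")) {
  if (is.character(quad)) quad <- smbj_species(quad)
  if (is.character(duplex)) duplex <- smbj_species(duplex)
  stopifnot(is.data.frame(grid), all(c("c_quad", "c_duplex") %in% names(grid)))
  if (nrow(grid) < 2L) stop("need at least 2 grid points", call. = FALSE)
  if (any(grid$c_quad <= 0) || any(grid$c_duplex <= 0)) {
    stop("all concentrations must be > 0", call. = FALSE)
  }
  out <- grid[, c("c_quad", "c_duplex")]
  out$ratio <- grid$c_quad / grid$c_duplex
  out$peak_height_ratio <- NA_real_
  out$both_detected <- FALSE
  out$n_selected <- NA_real_
  out$seed <- NA_integer_
  out$note <- ""
  for (i in seq_len(nrow(grid))) {
    mix <- mixture_spec(list(quad, duplex),
                        c(grid$c_quad[i], grid$c_duplex[i]),
                        environment = environment,
                        p_junction = p_junction, alpha = alpha)
    ratios <- numeric(0)
    detected <- logical(0)
    nsel <- numeric(0)
    notes <- character(0)
    point_seed <- derive_seed(seed, i)
    for (r in seq_len(repeats)) {
      rep_seed <- derive_seed(point_seed, r)
      res <- tryCatch({
        ens <- simulate_ensemble(n_traces, mix, config, seed = rep_seed)
        scr <- screen_ensemble(ens, screening)
        hist <- build_histogram(scr$selected, edges)
        peaks <- fit_gaussian_peaks(hist, k = 2)
        labels <- assign_conformations(peaks, table)
        present <- peak_present(peaks)
        ok <- "G-quadruplex" %in% labels[present] &&
          "duplex" %in% labels[present]
        list(ratio = if (ok) peak_height_ratio(peaks, labels) else NA_real_,
             detected = ok, n_selected = length(scr$selected), note = "")
      }, error = function(e) {
        list(ratio = NA_real_, detected = FALSE, n_selected = NA_real_,
             note = conditionMessage(e))
      })
      ratios <- c(ratios, res$ratio)
      detected <- c(detected, res$detected)
      nsel <- c(nsel, res$n_selected)
      if (nzchar(res$note)) notes <- c(notes, res$note)
    }
    out$both_detected[i] <- all(detected)
    out$peak_height_ratio[i] <- if (all(detected)) mean(ratios) else NA_real_
    out$n_selected[i] <- mean(nsel)
    out$seed[i] <- point_seed
    out$note[i] <- paste(unique(notes), collapse = "; ")
  }
  rownames(out) <- NULL
  out
}
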