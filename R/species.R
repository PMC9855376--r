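#' Junction model for one DNA species
#'
#' Describes how one DNA conformation behaves in the break junction: the
#' log-conductance at which its plateaus sit, the trace-to-trace spread of
#' that level, the plateau geometry, a dimensionless capture affinity used by
#' the mixture capture model, and the strand topology.  Parallel
#' G-quadruplexes carry both thiol linkers on the same end and therefore do
#' not bridge the electrodes: their capture weight is always zero.
#'
#' @param name Species name (free text, unique within a mixture).
#' @param conductance_g0 Most-probable junction conductance in units of G0.
#'   Exactly one of `conductance_g0` and `mu` must be given.
#' @param mu Mean plateau position in log10(G/G0); alternative to
#'   `conductance_g0`.
#' @param sigma_between Trace-to-trace standard deviation of the plateau
#'   log-conductance, in decades.
#' @param plateau_length_mean,plateau_length_sd Plateau length distribution in
#'   nm (normal, truncated to positive lengths).
#' @param capture_affinity Dimensionless affinity entering the capture-weight
#'   model; must be non-negative.
#' @param topology One of `"duplex"`, `"antiparallel_quad"`,
#'   `"parallel_quad"`.
#' @param conductance_g0_kcl Optional conductance (G0 units) the species
#'   adopts in potassium-containing buffer; used by [apply_environment()] for
#'   duplexes, whose B-form geometry shifts slightly with the cation.
#' @return An object of class `smbj_species`.
#' @seealso [smbj_species()] for the built-in reference species.
#' @export
species_model <- function(name,
                          conductance_g0 = NULL,
                          mu = NULL,
                          sigma_between = 0.15,
                          plateau_length_mean = 0.3,
                          plateau_length_sd = 0.1,
                          capture_affinity = 1,
                          topology = c("duplex", "antiparallel_quad",
                                       "parallel_quad"),
                          conductance_g0_kcl = NULL) {
  topology <- match.arg(topology)
  if (is.null(mu) == is.null(conductance_g0)) {
    stop("give exactly one of `conductance_g0` and `mu`", call. = FALSE)
  }
  if (is.null(mu)) {
    if (conductance_g0 <= 0) stop("conductance_g0 must be > 0", call. = FALSE)
    mu <- log10(conductance_g0)
  }
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (sigma_between < 0) stop("sigma_between must be >= 0", call. = FALSE)
  if (plateau_length_mean <= 0) {
    stop("plateau_length_mean must be > 0", call. = FALSE)
  }
  if (plateau_length_sd < 0) {
    stop("plateau_length_sd must be >= 0", call. = FALSE)
  }
  if (capture_affinity < 0) {
    stop("capture_affinity must be >= 0", call. = FALSE)
  }
  mu_kcl <- if (is.null(conductance_g0_kcl)) NA_real_ else {
    if (conductance_g0_kcl <= 0) {
      stop("conductance_g0_kcl must be > 0", call. = FALSE)
    }
    log10(conductance_g0_kcl)
  }
  structure(
    list(name = name, mu = mu, sigma_between = sigma_between,
         plateau_length_mean = plateau_length_mean,
         plateau_length_sd = plateau_length_sd,
         capture_affinity = capture_affinity, topology = topology,
         mu_kcl = mu_kcl),
    class = "smbj_species"
  )
}

# Reference conductances (G0 units) for the sequences used as
# single-conformation controls and mixtures; peak positions from repeated
# break-junction measurements.  KCl values are the single remaining duplex
# peak after potassium suppresses the antiparallel quadruplex.
.SPECIES_PRESETS <- list(
  ds_GGCGAGCGCC = list(g = 3.03e-4, topology = "duplex",     g_kcl = NULL),
  ds_CG3x3      = list(g = 1.63e-4, topology = "duplex",     g_kcl = 3.13e-4),
  ds_C3G3x2     = list(g = 2.31e-4, topology = "duplex",     g_kcl = 3.36e-4),
  G3T3G3_quad   = list(g = 3.77e-3, topology = "antiparallel_quad", g_kcl = NULL),
  CG3x3_quad    = list(g = 3.50e-3, topology = "antiparallel_quad", g_kcl = NULL),
  C3G3x2_quad   = list(g = 3.55e-3, topology = "antiparallel_quad", g_kcl = NULL)
)

#' Built-in reference species
#'
#' Returns a [species_model()] preset for one of the DNA strands
#' characterised by single-conformation control measurements:
#'
#' * `ds_GGCGAGCGCC` - 10-bp GC-rich B-form duplex, 3.03e-4 G0.
#' * `ds_CG3x3` - duplex form of (CG3)3, 1.63e-4 G0 (3.13e-4 in KCl).
#' * `ds_C3G3x2` - duplex form of (C3G3)2, 2.31e-4 G0 (3.36e-4 in KCl).
#' * `G3T3G3_quad` - antiparallel G-quadruplex of G3-T3-G3, 3.77e-3 G0.
#' * `CG3x3_quad` - antiparallel G-quadruplex of (CG3)3, 3.50e-3 G0.
#' * `C3G3x2_quad` - antiparallel G-quadruplex of (C3G3)2, 3.55e-3 G0.
#'
#' @param name Preset name (see above).
#' @param ... Overrides passed on to [species_model()] (for example
#'   `capture_affinity`).
#' @return An `smbj_species` object.
#' @examples
#' smbj_species("ds_GGCGAGCGCC")
#' @export
smbj_species <- function(name, ...) {
  if (!name %in% names(.SPECIES_PRESETS)) {
    stop("unknown species preset '", name, "'; available: ",
         paste(names(.SPECIES_PRESETS), collapse = ", "), call. = FALSE)
  }
  p <- .SPECIES_PRESETS[[name]]
  species_model(name = name, conductance_g0 = p$g, topology = p$topology,
                conductance_g0_kcl = p$g_kcl, ...)
}

#' Reference table of conformation conductances
#'
#' Maps conformation classes to their reference conductance, with an
#' assignment tolerance in decades.  Defaults come from the
#' single-conformation controls: the B-form duplex ds(GGCGAGCGCC) and the
#' (G3-T3-G3) antiparallel G-quadruplex.  The default tolerance of 0.35
#' decades covers the sequence-to-sequence spread of duplex conductances
#' (1.6e-4 to 3.4e-4 G0) without overlapping the quadruplex band.
#'
#' @param conformation Character vector of conformation names (unique).
#' @param conductance_g0 Reference conductances in G0 units.
#' @param tol_decades Assignment tolerance per entry, decades (> 0).
#' @return A data frame with columns `conformation`, `conductance_g0`,
#'   `tol_decades`.
#' @export
reference_table <- function(conformation = c("duplex", "G-quadruplex"),
                            conductance_g0 = c(3.03e-4, 3.77e-3),
                            tol_decades = 0.35) {
  if (length(conformation) < 1L) stop("table must be nonempty", call. = FALSE)
  if (anyDuplicated(conformation)) {
    stop("conformation names must be unique", call. = FALSE)
  }
  if (length(conductance_g0) != length(conformation)) {
    stop("lengths of `conformation` and `conductance_g0` differ", call. = FALSE)
  }
  tol_decades <- rep_len(tol_decades, length(conformation))
  if (any(tol_decades <= 0)) stop("tolerances must be > 0", call. = FALSE)
  if (any(conductance_g0 <= 0)) {
    stop("reference conductances must be > 0", call. = FALSE)
  }
  data.frame(conformation = conformation,
             conductance_g0 = conductance_g0,
             tol_decades = tol_decades,
             stringsAsFactors = FALSE)
}

#' @export
print.smbj_species <- function(x, ...) {
  cat(sprintf("<smbj_species> %s (%s)\n", x$name, x$topology))
  cat(sprintf("  G = %.3g G0 (mu = %.3f log10 G/G0, sigma_between = %.3g)\n",
              10^x$mu, x$mu, x$sigma_between))
  if (!is.na(x$mu_kcl)) {
    cat(sprintf("  G in KCl = %.3g G0\n", 10^x$mu_kcl))
  }
  cat(sprintf("  plateau %.3g +/- %.3g nm, affinity %.3g\n",
              x$plateau_length_mean, x$plateau_length_sd, x$capture_affinity))
  invisible(x)
}
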