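#' Buffer environment for a measurement
#'
#' Either plain 100 mM sodium phosphate buffer (`"PBS"`) or the same buffer
#' with potassium chloride added (`"PBS_KCl"`).  Potassium destabilises the
#' antiparallel G-quadruplex topology in favour of the parallel one, which
#' cannot bridge the electrodes.
#'
#' @param name `"PBS"` or `"PBS_KCl"`.
#' @param kcl_mM KCl concentration in millimolar.  Defaults to 0 for PBS and
#'   100 for PBS_KCl; PBS requires 0.
#' @return An object of class `smbj_environment`.
#' @export
environment_condition <- function(name = c("PBS", "PBS_KCl"), kcl_mM = NULL) {
  name <- match.arg(name)
  if (is.null(kcl_mM)) kcl_mM <- if (name == "PBS") 0 else 100
  if (!is.numeric(kcl_mM) || length(kcl_mM) != 1L || kcl_mM < 0) {
    stop("kcl_mM must be a single non-negative number", call. = FALSE)
  }
  if (name == "PBS" && kcl_mM != 0) {
    stop("PBS implies kcl_mM = 0", call. = FALSE)
  }
  structure(list(name = name, kcl_mM = kcl_mM), class = "smbj_environment")
}

#' Concentration-weighted mixture of junction-forming species
#'
#' @param species A single `smbj_species`, a character vector of preset names
#'   (see [smbj_species()]), or a list of `smbj_species` objects.
#' @param concentrations Molar concentrations, one per species, all >= 0.
#' @param environment An [environment_condition()].
#' @param p_junction Probability that a retraction event forms any molecular
#'   junction (in `[0, 1]`).
#' @param alpha Compression exponent of the capture-weight model; see
#'   [capture_weights()].
#' @return An object of class `smbj_mixture` with a `components` list of
#'   `(species, concentration)` pairs.
#' @export
mixture_spec <- function(species, concentrations,
                         environment = environment_condition("PBS"),
                         p_junction = 0.125, alpha = 0.08) {
  if (inherits(species, "smbj_species")) species <- list(species)
  if (is.character(species)) species <- lapply(species, smbj_species)
  if (!is.list(species) || length(species) < 1L ||
      !all(vapply(species, inherits, logical(1), "smbj_species"))) {
    stop("`species` must name or hold at least one smbj_species", call. = FALSE)
  }
  if (!is.numeric(concentrations) ||
      length(concentrations) != length(species)) {
    stop("`concentrations` must match `species` in length", call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (!inherits(environment, "smbj_environment")) {
    stop("`environment` must be an environment_condition()", call. = FALSE)
  }
  if (!is.numeric(p_junction) || length(p_junction) != 1L ||
      p_junction < 0 || p_junction > 1) {
    stop("p_junction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be > 0", call. = FALSE)
  }
  components <- mapply(function(sp, conc) list(species = sp,
                                               concentration = conc),
                       species, concentrations, SIMPLIFY = FALSE)
  structure(list(components = components, environment = environment,
                 p_junction = p_junction, alpha = alpha),
            class = "smbj_mixture")
}

#' Per-species capture probabilities
#'
#' Probability that a junction-forming retraction event captures each species
#' of the mixture.  The weight of component *i* is
#' \eqn{w_i \propto (a_i c_i)^\alpha} with affinity \eqn{a_i}, concentration
#' \eqn{c_i} and a small compression exponent \eqn{\alpha} (default 0.08),
#' normalised to sum to one.  The strongly sublinear concentration dependence
#' is a modelling assumption that keeps a minor species visible across many
#' orders of magnitude of concentration ratio, as observed in titrations; it
#' is not a fitted physical law.  Species with `parallel_quad` topology get
#' weight zero (both thiols on one end, no bridge).
#'
#' @param mixture An [mixture_spec()].
#' @param alpha Compression exponent; defaults to the mixture's own.
#' @return Named numeric vector of probabilities summing to 1.
#' @examples
#' m <- mixture_spec(c("ds_GGCGAGCGCC", "G3T3G3_quad"), c(0.45e-6, 2e-15))
#' capture_weights(m)
#' @export
capture_weights <- function(mixture, alpha = mixture$alpha) {
  stopifnot(inherits(mixture, "smbj_mixture"))
  w <- vapply(mixture$components, function(cmp) {
    sp <- cmp$species
    if (sp$topology == "parallel_quad") return(0)
    ac <- sp$capture_affinity * cmp$concentration
    if (ac <= 0) 0 else ac^alpha
  }, numeric(1))
  if (all(w == 0)) {
    stop("no junction-forming species in mixture", call. = FALSE)
  }
  names(w) <- vapply(mixture$components, function(cmp) cmp$species$name,
                     character(1))
  w / sum(w)
}

#' Apply the buffer environment to a mixture
#'
#' Under `PBS_KCl`, every antiparallel G-quadruplex species is converted to
#' the parallel topology (capture weight zero: potassium flips the topology
#' and the parallel form cannot bridge the electrodes), and duplex species
#' that declare a KCl conductance have their plateau position replaced by it.
#' Under `PBS` the mixture is returned unchanged.  The operation is
#' idempotent.
#'
#' @param mixture An [mixture_spec()].
#' @return The mixture with environment effects applied.
#' @export
apply_environment <- function(mixture) {
  stopifnot(inherits(mixture, "smbj_mixture"))
  if (mixture$environment$name == "PBS") return(mixture)
  mixture$components <- lapply(mixture$components, function(cmp) {
    sp <- cmp$species
    if (sp$topology == "antiparallel_quad") {
      sp$topology <- "parallel_quad"
    } else if (sp$topology == "duplex" && !is.na(sp$mu_kcl)) {
      sp$mu <- sp$mu_kcl
    }
    cmp$species <- sp
    cmp
  })
  mixture
}

#' @export
print.smbj_mixture <- function(x, ...) {
  cat(sprintf("<smbj_mixture> %d species, %s, p_junction = %.3g, alpha = %.3g\n",
              length(x$components), x$environment$name, x$p_junction, x$alpha))
  for (cmp in x$components) {
    cat(sprintf("  %-14s %-17s %.3g M  (G = %.3g G0)\n",
                cmp$species$name, cmp$species$topology, cmp$concentration,
                10^cmp$species$mu))
  }
  invisible(x)
}
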