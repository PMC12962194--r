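#' Construct a spin system
#'
#' A spin system is the set of chemically inequivalent (or equivalent) protons
#' of one metabolite fragment: a chemical shift per proton (ppm) and a
#' symmetric scalar-coupling matrix (Hz). Metabolites whose protons split into
#' uncoupled fragments (e.g. the creatine CH3 and CH2 groups) may be shipped as
#' several small systems sharing a `metabolite` label; their simulated signals
#' add linearly with the given `scale` weights, which keeps the Hilbert-space
#' dimension low.
#'
#' @param name Identifier of this system (unique within a configuration file).
#' @param shifts Numeric vector of chemical shifts, ppm, one per proton.
#' @param couplings Either a symmetric n x n matrix of J couplings in Hz with
#'   zero diagonal, or a list of `c(i, j, J_hz)` triplets (1-based indices).
#' @param reference_concentration Reference concentration in mM used when
#'   scaling simulated responses to in vivo levels.
#' @param metabolite Metabolite this system belongs to; defaults to `name`.
#' @param scale Multiplicative weight of this system within its metabolite
#'   (e.g. anomeric fraction, or proton multiplicity of a collapsed group).
#'
#' @return Object of class `spin_system`.
#' @export
#' @examples
#' gly <- spin_system("Gly", shifts = c(3.548, 3.548), couplings = list(),
#'                    reference_concentration = 0.7)
#' gly$n_protons
spin_system <- function(name, shifts, couplings = list(),
                        reference_concentration = NA_real_,
                        metabolite = name, scale = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  shifts <- as.numeric(shifts)
  n <- length(shifts)
  if (n < 1L) stop("spin system '", name, "': needs at least one proton")
  if (any(!is.finite(shifts)) || any(shifts < 0 | shifts > 10)) {
    stop("spin system '", name, "': shifts must be finite and within [0, 10] ppm")
  }
  J <- couplings_matrix(couplings, n, name)
  if (!isTRUE(all.equal(J, t(J), tolerance = 1e-12)) || any(diag(J) != 0)) {
    stop("spin system '", name, "': coupling matrix must be symmetric with zero diagonal")
  }
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  structure(
    list(name = name, metabolite = metabolite, shifts = shifts, couplings = J,
         n_protons = n, reference_concentration = as.numeric(reference_concentration),
         scale = scale),
    class = "spin_system"
  )
}

couplings_matrix <- function(couplings, n, name) {
  if (is.matrix(couplings)) {
    if (!all(dim(couplings) == c(n, n))) {
      stop("spin system '", name, "': coupling matrix dimension does not match ",
           "the number of shifts (", n, ")")
    }
    return(unname(couplings * 1.0))
  }
  J <- matrix(0.0, n, n)
  for (trip in couplings) {
    trip <- as.numeric(unlist(trip))
    if (length(trip) != 3L) {
      stop("spin system '", name, "': each coupling must be [i, j, J_hz]")
    }
    i <- trip[1]; j <- trip[2]
    if (i != round(i) || j != round(j) || i < 1 || j < 1 || i > n || j > n || i == j) {
      stop("spin system '", name, "': invalid coupling indices (", i, ", ", j, ")")
    }
    if (J[i, j] != 0) {
      stop("spin system '", name, "': duplicate coupling entry (", i, ", ", j, ")")
    }
    J[i, j] <- J[j, i] <- trip[3]
  }
  J
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %s (%s): %d proton(s), %d coupling(s), ref %.3g mM, scale %.3g\n",
              x$name, x$metabolite, x$n_protons,
              sum(x$couplings[upper.tri(x$couplings)] != 0),
              x$reference_concentration, x$scale))
  invisible(x)
}

#' Load spin systems from a configuration file
#'
#' Reads a YAML file containing one entry per spin system with fields
#' `name`, `shifts`, `couplings` (list of `[i, j, J_hz]` triplets),
#' `reference_concentration_mM`, and optionally `metabolite` and `scale`
#' (see [spin_system()]). Unknown fields are rejected so that typos in the
#' editable configuration surface immediately.
#'
#' @param config_path Path to the YAML file. Defaults to the configuration
#'   shipped with the package, which covers Gly, mI, Glc (both anomers at a
#'   36:64 alpha:beta ratio), Thr, GABA, Cr and NAA.
#'
#' @return Named list of `spin_system` objects (names are the system names).
#' @export
#' @examples
#' sys <- load_spin_systems()
#' names(sys)
load_spin_systems <- function(config_path = default_spin_system_file()) {
  if (!file.exists(config_path)) stop("spin-system file not found: ", config_path)
  entries <- yaml::read_yaml(config_path)
  if (length(entries) == 0L) stop("spin-system file is empty: ", config_path)
  allowed <- c("name", "metabolite", "scale", "shifts", "couplings",
               "reference_concentration_mM")
  out <- list()
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    label <- if (!is.null(e$name)) e$name else paste0("entry ", k)
    bad <- setdiff(names(e), allowed)
    if (length(bad)) {
      stop("spin-system entry '", label, "': unknown field(s): ",
           paste(bad, collapse = ", "))
    }
    if (is.null(e$name) || is.null(e$shifts)) {
      stop("spin-system entry '", label, "': fields 'name' and 'shifts' are required")
    }
    if (!is.null(out[[e$name]])) stop("duplicate spin-system name '", e$name, "'")
    sys <- spin_system(
      name = e$name,
      shifts = e$shifts,
      couplings = if (is.null(e$couplings)) list() else e$couplings,
      reference_concentration = if (is.null(e$reference_concentration_mM))
        NA_real_ else e$reference_concentration_mM,
      metabolite = if (is.null(e$metabolite)) e$name else e$metabolite,
      scale = if (is.null(e$scale)) 1 else e$scale
    )
    if (any(abs(sys$couplings) >= 20)) {
      stop("spin-system entry '", label, "': |J| >= 20 Hz is outside the range ",
           "expected for the shipped proton systems")
    }
    out[[e$name]] <- sys
  }
  out
}

#' @rdname load_spin_systems
#' @export
default_spin_system_file <- function() {
  system.file("extdata", "spin_systems.yaml", package = "glymega", mustWork = TRUE)
}

#' Group spin systems by metabolite
#'
#' @param systems Named list of `spin_system` objects, as returned by
#'   [load_spin_systems()].
#' @return Named list: one element per metabolite, each a list of the
#'   `spin_system` fragments that compose it.
#' @export
metabolite_groups <- function(systems) {
  mets <- vapply(systems, function(s) s$metabolite, character(1))
  split(unname(systems), mets)[unique(mets)]
}

#' Reference concentration of a metabolite
#'
#' @param systems Named list of `spin_system` objects.
#' @param metabolite Metabolite name.
#' @return Reference concentration in mM (taken from the first fragment that
#'   declares one).
#' @export
reference_concentration <- function(systems, metabolite) {
  grp <- metabolite_groups(systems)[[metabolite]]
  if (is.null(grp)) stop("unknown metabolite: ", metabolite)
  conc <- vapply(grp, function(s) s$reference_concentration, numeric(1))
  conc <- conc[is.finite(conc)]
  if (!length(conc)) return(NA_real_)
  conc[[1]]
}
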