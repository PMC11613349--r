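#' Element-level Lennard-Jones parameter table
#'
#' Loads per-element 12-6 Lennard-Jones parameters (well depth epsilon in
#' kJ/mol, `rmin_half` in Angstrom).  Atom types are deliberately not used:
#' every atom of an element shares one parameter set.  Pair parameters are
#' combined with the Lorentz-Berthelot rules (arithmetic mean of radii,
#' geometric mean of well depths).
#'
#' @param path YAML parameter file; defaults to the table shipped with the
#'   package.
#' @return an object of class `lj_params`: a data frame with one row per
#'   element.
#' @export
lj_params <- function(path = system.file("extdata", "lj_params.yaml",
                                         package = "ramafield")) {
  cfg <- yaml::read_yaml(path)
  el <- names(cfg$elements)
  out <- tibble::tibble(
    element = el,
    epsilon = unname(vapply(cfg$elements, function(e) as.numeric(e$epsilon),
                            numeric(1L))),
    rmin_half = unname(vapply(cfg$elements, function(e) as.numeric(e$rmin_half),
                              numeric(1L)))
  )
  if (any(out$epsilon <= 0) || any(out$rmin_half <= 0)) {
    stop("LJ epsilon and rmin_half must be positive", call. = FALSE)
  }
  class(out) <- c("lj_params", class(out))
  out
}

# Combined pair parameters for element vectors; errors name missing elements.
lj_combine <- function(params, ei, ej) {
  ii <- match(ei, params$element)
  jj <- match(ej, params$element)
  if (anyNA(ii) || anyNA(jj)) {
    bad <- c(ei[is.na(ii)], ej[is.na(jj)])[1L]
    stop("element '", bad, "' missing from LJ parameter table", call. = FALSE)
  }
  list(epsilon = sqrt(params$epsilon[ii] * params$epsilon[jj]),
       rmin = params$rmin_half[ii] + params$rmin_half[jj])
}

# 12-6 energy from squared distance, CHARMM convention E(rmin) = -eps.
lj_energy_d2 <- function(d2, epsilon, rmin) {
  s6 <- (rmin^2 / d2)^3
  epsilon * (s6^2 - 2 * s6)
}

#' Pairwise 12-6 Lennard-Jones energy
#'
#' \eqn{E(r) = \epsilon [(r_{min}/r)^{12} - 2 (r_{min}/r)^6]} with
#' Lorentz-Berthelot-combined pair parameters, so \eqn{E(r_{min}) =
#' -\epsilon}.
#'
#' @param r distance in Angstrom (vectorized).
#' @param elem_i,elem_j element symbols.
#' @param params an [lj_params()] table.
#' @return energy in kJ/mol.
#' @examples
#' lj_pair_energy(1.5, "N", "N")  # approx 4.2e4 kJ/mol
#' @export
lj_pair_energy <- function(r, elem_i, elem_j, params = lj_params()) {
  if (any(r <= 0)) stop("distance must be positive", call. = FALSE)
  p <- lj_combine(params, elem_i, elem_j)
  lj_energy_d2(r^2, p$epsilon, p$rmin)
}

#' Total Lennard-Jones energy of one conformation
#'
#' Sum of pairwise 12-6 energies over every mask pair (all pairs at least
#' four covalent bonds apart, by default).
#'
#' @inheritParams count_overlaps
#' @param params an [lj_params()] table.
#' @return energy in kJ/mol.
#' @export
lj_structure_energy <- function(structure, params = lj_params(),
                                mask = pair_mask(structure)) {
  if (nrow(mask) == 0L) return(0)
  p <- lj_combine(params, mask$elem_i, mask$elem_j)
  d2 <- rowSums((structure$xyz[mask$i, , drop = FALSE] -
                 structure$xyz[mask$j, , drop = FALSE])^2)
  sum(lj_energy_d2(d2, p$epsilon, p$rmin))
}

#' Admissibility of a side-chain configuration
#'
#' A configuration enters the Lennard-Jones averaging only if every
#' backbone--side-chain pair at least four covalent bonds apart is farther
#' apart than \eqn{\lambda R_s}.  `lambda = 0` admits every configuration;
#' a pair at exactly \eqn{\lambda R_s} is inadmissible (strict inequality).
#'
#' @inheritParams count_overlaps
#' @param lambda dimensionless exclusion factor, >= 0.
#' @param mask a backbone--side-chain [pair_mask()]; built from the
#'   structure by default.
#' @return logical scalar.
#' @export
is_admissible <- function(structure, radii = contact_radii(), lambda = 1,
                          mask = pair_mask(structure, "backbone_sidechain")) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (nrow(mask) == 0L) return(TRUE)
  rs <- radii_lookup(radii, mask$elem_i, mask$elem_j)
  d2 <- rowSums((structure$xyz[mask$i, , drop = FALSE] -
                 structure$xyz[mask$j, , drop = FALSE])^2)
  all(d2 > (lambda * rs)^2)
}
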