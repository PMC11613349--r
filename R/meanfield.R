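# Gas constant in kJ/(mol K); RT at the default 298 K is 2.478 kJ/mol,
# i.e. beta = 1/RT ~ 1/2.479 (kJ/mol)^-1.
GAS_R <- 8.314462618e-3

#' Side-chain-averaged Lennard-Jones landscape
#'
#' For every (phi, psi) bin, averages the total intramolecular 12-6
#' Lennard-Jones energy over the admissible side-chain configurations.  A
#' configuration is admissible when every backbone--side-chain pair at
#' least four covalent bonds apart is farther than \eqn{\lambda R_s}
#' ([is_admissible()]); averaging over all eligible pairs is unrestricted.
#' Bins with no admissible configuration receive `penalty` (500,000 kJ/mol
#' by default), preserving the high-energy regions of Ramachandran space.
#' For residues without chi torsions the bin value is the single-structure
#' energy (or the penalty if the lone configuration is inadmissible).
#'
#' @inheritParams steric_scan
#' @param params an [lj_params()] table.
#' @param lambda exclusion factor(s) in \[0, 1\]; a vector computes all
#'   values in one pass over the scan.
#' @param penalty energy assigned to bins with no admissible configuration,
#'   kJ/mol.
#' @return a [rama_grid()] of kind `"energy_kJ_mol"` for scalar `lambda`;
#'   a named list of grids (names `"lambda=..."`) for a vector.
#' @export
lj_meanfield_scan <- function(structure, params = lj_params(),
                              radii = contact_radii(), lambda = 1,
                              backbone_step = 2, chi_step = 2,
                              penalty = 5e5) {
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  res <- chi_scan_engine(structure, radii = radii, params = params,
                         lambdas = lambda, backbone_step = backbone_step,
                         chi_step = chi_step, compute = "lj",
                         penalty = penalty)
  grids <- lapply(seq_along(lambda), function(q) {
    rama_grid(res$lj[[q]], phi_step = backbone_step,
              psi_step = backbone_step, kind = "energy_kJ_mol",
              meta = list(residue = structure$residue,
                          backbone_angle = structure$backbone_angle,
                          chi_step = chi_step, lambda = lambda[q],
                          penalty = penalty))
  })
  if (length(lambda) == 1L) grids[[1L]] else
    stats::setNames(grids, paste0("lambda=", format(lambda)))
}

#' Convert a Ramachandran probability distribution to free energies
#'
#' Boltzmann inversion \eqn{E(\phi,\psi) = -RT \ln(p/p_o)} with the
#' reference probability \eqn{p_o} equal to the smallest bin value, so the
#' least populated bin has zero free energy and the most populated basin is
#' negative.  The input must be strictly positive everywhere; floor the
#' density first if it contains zeros (the shipped Gaussian models are
#' strictly positive by construction).
#'
#' @param P a probability [rama_grid()].
#' @param temperature absolute temperature in K.
#' @return an energy [rama_grid()] (kJ/mol) with `p_o` and `temperature`
#'   recorded in its metadata.
#' @export
density_to_energy <- function(P, temperature = 298) {
  if (grid_kind(P) != "probability") stop("P must be a probability grid",
                                          call. = FALSE)
  if (any(P <= 0)) {
    stop("probability grid contains non-positive bins; floor the density ",
         "before Boltzmann inversion", call. = FALSE)
  }
  po <- min(P)
  E <- -GAS_R * temperature * log(unclass(P) / po)
  rama_grid(matrix(E, nrow(P), ncol(P)),
            attr(P, "phi_step"), attr(P, "psi_step"), "energy_kJ_mol",
            meta = c(grid_meta(P),
                     list(p_o = po, temperature = temperature)))
}

#' Convert a free-energy landscape to a Ramachandran distribution
#'
#' Boltzmann weighting \eqn{p \propto \exp(-E/RT)}, normalized to sum to 1.
#' The minimum energy is subtracted before exponentiation so arbitrarily
#' large penalty energies underflow to zero probability instead of
#' overflowing.
#'
#' @param E an energy [rama_grid()] (kJ/mol).
#' @param temperature absolute temperature in K.
#' @return a probability [rama_grid()].
#' @export
energy_to_density <- function(E, temperature = 298) {
  if (grid_kind(E) != "energy_kJ_mol") stop("E must be an energy grid",
                                            call. = FALSE)
  if (!all(is.finite(E))) stop("energies must be finite", call. = FALSE)
  w <- exp(-(unclass(E) - min(E)) / (GAS_R * temperature))
  rama_grid(w / sum(w), attr(E, "phi_step"), attr(E, "psi_step"),
            "probability",
            meta = c(grid_meta(E), list(temperature = temperature)))
}

#' Sum two energy landscapes
#'
#' Elementwise sum of the side-chain-averaged Lennard-Jones field and the
#' backbone--water field (or any two energy grids on the same grid spec).
#'
#' @param E_lj,E_water energy [rama_grid()] objects with identical steps.
#' @return an energy [rama_grid()].
#' @export
combine_fields <- function(E_lj, E_water) {
  if (grid_kind(E_lj) != "energy_kJ_mol" ||
      grid_kind(E_water) != "energy_kJ_mol") {
    stop("both inputs must be energy grids", call. = FALSE)
  }
  if (attr(E_lj, "phi_step") != attr(E_water, "phi_step") ||
      attr(E_lj, "psi_step") != attr(E_water, "psi_step")) {
    stop("grid specs differ; cannot combine", call. = FALSE)
  }
  rama_grid(unclass(E_lj) + unclass(E_water),
            attr(E_lj, "phi_step"), attr(E_lj, "psi_step"), "energy_kJ_mol",
            meta = c(grid_meta(E_lj),
                     water = list(grid_meta(E_water))))
}

#' Backbone--water free-energy surface
#'
#' Evaluates the empirical Gaussian-model Ramachandran distribution on the
#' requested grid and Boltzmann-inverts it ([density_to_energy()]).  The
#' surface is derived from the alanine model and reused unchanged for every
#' residue, representing mean peptide-backbone hydration.
#'
#' @param model a [gaussian_model()].
#' @param phi_step,psi_step grid steps in degrees.
#' @param temperature absolute temperature in K.
#' @return an energy [rama_grid()].
#' @export
water_field <- function(model = gaussian_model(), phi_step = 2,
                        psi_step = phi_step, temperature = 298) {
  density_to_energy(gaussian_density(model, phi_step, psi_step),
                    temperature = temperature)
}
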