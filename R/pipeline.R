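#' Run the full mean-field pipeline
#'
#' For each residue: builds the mimetic, computes the average-overlap
#' landscape, the side-chain-averaged Lennard-Jones field for every lambda,
#' adds the backbone--water surface, Boltzmann-inverts the combined field
#' to a Ramachandran distribution, and summarizes each distribution as
#' mesostate populations and Karplus J-couplings.  Fully deterministic:
#' outputs are a function of the configuration and input files only.
#'
#' @param residues character vector of residue codes.
#' @param lambdas exclusion factors for the Lennard-Jones averaging.
#' @param backbone_step,chi_step scan steps in degrees.
#' @param backbone_angle N-CA-C' angle in degrees.
#' @param temperature absolute temperature in K.
#' @param penalty energy for bins with no admissible configuration, kJ/mol.
#' @param geometry,radii,lj,gaussian,mesostates,karplus configuration
#'   objects (see [default_geometry()], [contact_radii()], [lj_params()],
#'   [gaussian_model()], [mesostate_set()], [karplus_set()]).
#' @param keep_grids keep all intermediate grids in the result (memory
#'   permitting); the probability grids are always kept.
#' @return an object of class `rama_pipeline` with elements `populations`
#'   and `couplings` (tibbles over residue x lambda), `grids` (per residue:
#'   `steric`, `water`, and per lambda `lj` and `prob`), and `config`.
#' @export
run_pipeline <- function(residues = c("ALA", "VAL", "LEU", "ILE"),
                         lambdas = c(0, seq(0.7, 1, by = 0.05)),
                         backbone_step = 10, chi_step = 15,
                         backbone_angle = 110, temperature = 298,
                         penalty = 5e5,
                         geometry = default_geometry(),
                         radii = contact_radii(),
                         lj = lj_params(),
                         gaussian = gaussian_model(),
                         mesostates = mesostate_set(),
                         karplus = karplus_set(),
                         keep_grids = TRUE) {
  E_water <- water_field(gaussian, phi_step = backbone_step,
                         psi_step = backbone_step,
                         temperature = temperature)
  grids <- list()
  pops <- list(); coups <- list()
  for (res in residues) {
    st <- build_mimetic(res, backbone_angle, geometry)
    steric <- steric_scan(st, radii, backbone_step, chi_step)
    ljg <- lj_meanfield_scan(st, lj, radii, lambda = lambdas,
                             backbone_step = backbone_step,
                             chi_step = chi_step, penalty = penalty)
    if (length(lambdas) == 1L) ljg <- list(ljg)
    probs <- list()
    for (q in seq_along(lambdas)) {
      comb <- combine_fields(ljg[[q]], E_water)
      P <- energy_to_density(comb, temperature)
      probs[[q]] <- P
      pops[[length(pops) + 1L]] <- dplyr::mutate(
        mesostate_populations(P, mesostates),
        residue = res, lambda = lambdas[q], .before = 1L)
      coups[[length(coups) + 1L]] <- dplyr::mutate(
        jcouplings(P, karplus),
        residue = res, lambda = lambdas[q], .before = 1L)
    }
    names(probs) <- paste0("lambda=", format(lambdas))
    grids[[res]] <- if (keep_grids) {
      list(steric = steric, water = E_water,
           lj = stats::setNames(ljg, names(probs)), prob = probs)
    } else list(prob = probs)
  }
  structure(
    list(populations = dplyr::bind_rows(pops),
         couplings = dplyr::bind_rows(coups),
         grids = grids,
         config = list(residues = residues, lambdas = lambdas,
                       backbone_step = backbone_step, chi_step = chi_step,
                       backbone_angle = backbone_angle,
                       temperature = temperature, penalty = penalty,
                       mesostate_source = attr(mesostates, "source"))),
    class = "rama_pipeline"
  )
}

#' @export
print.rama_pipeline <- function(x, ...) {
  cfg <- x$config
  cat("<rama_pipeline> ", paste(cfg$residues, collapse = ", "),
      " | lambda = ", paste(format(cfg$lambdas), collapse = ", "), "\n",
      "  grid ", cfg$backbone_step, " deg backbone, ", cfg$chi_step,
      " deg chi, N-CA-C' = ", cfg$backbone_angle, " deg\n", sep = "")
  print(glance.rama_pipeline(x))
  invisible(x)
}

#' @method tidy rama_pipeline
#' @export
tidy.rama_pipeline <- function(x, ...) {
  dplyr::full_join(
    x$populations,
    tidyr::pivot_wider(x$couplings, names_from = "coupling",
                       values_from = "J_Hz"),
    by = c("residue", "lambda")
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row-per-condition summary of a pipeline run
#'
#' @param x a [run_pipeline()] result.
#' @param ... unused.
#' @return a tibble with one row per residue and lambda: the pPII, total
#'   beta (ab + bt + pb) and helical populations, and the J-couplings.
#' @method glance rama_pipeline
#' @export
glance.rama_pipeline <- function(x, ...) {
  popw <- tidyr::pivot_wider(x$populations, names_from = "mesostate",
                             values_from = "population")
  popw$beta_total <- popw$ab + popw$bt + popw$pb
  out <- dplyr::select(popw, "residue", "lambda", "pPII", "beta_total",
                       ab = "ab", bt = "bt", pb = "pb", alphaR = "aR")
  dplyr::full_join(out,
                   tidyr::pivot_wider(x$couplings, names_from = "coupling",
                                      values_from = "J_Hz"),
                   by = c("residue", "lambda"))
}

#' Mesostate populations versus lambda, as a plot
#'
#' @param x a [run_pipeline()] result.
#' @param mesostates subset of mesostate names to show.
#' @return a ggplot object, faceted by residue.
#' @export
plot_populations <- function(x, mesostates = NULL) {
  df <- x$populations
  if (!is.null(mesostates)) {
    df <- dplyr::filter(df, .data$mesostate %in% mesostates)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$population,
                                   colour = .data$mesostate)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~residue) +
    ggplot2::labs(x = expression(lambda), y = "population")
}
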