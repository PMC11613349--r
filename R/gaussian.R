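#' Gaussian-mixture Ramachandran model
#'
#' Loads a weighted mixture of 2D Gaussian components over (phi, psi) --
#' the empirical representation of the backbone--water Ramachandran
#' density.  Each component has a peak center, widths and an optional
#' phi-psi correlation coefficient.  Weights are normalized to sum to 1.
#' The shipped default is a synthetic stand-in for the published alanine
#' model (see the file's header); supply the real parameter file to
#' reproduce it exactly.
#'
#' @param path YAML model file.
#' @return an object of class `gaussian_rama_model`: a tibble with one row
#'   per component.
#' @export
gaussian_model <- function(path = system.file("extdata",
                                              "gaussian_ala_synthetic.yaml",
                                              package = "ramafield")) {
  cfg <- yaml::read_yaml(path)
  comp <- cfg$components
  if (length(comp) == 0L) stop("model needs at least one component",
                               call. = FALSE)
  out <- tibble::tibble(
    name = vapply(comp, function(x) x$name %||% "", character(1L)),
    weight = vapply(comp, function(x) as.numeric(x$weight), numeric(1L)),
    phi0 = vapply(comp, function(x) as.numeric(x$phi0), numeric(1L)),
    psi0 = vapply(comp, function(x) as.numeric(x$psi0), numeric(1L)),
    sigma_phi = vapply(comp, function(x) as.numeric(x$sigma_phi),
                       numeric(1L)),
    sigma_psi = vapply(comp, function(x) as.numeric(x$sigma_psi),
                       numeric(1L)),
    rho = vapply(comp, function(x) as.numeric(x$rho %||% 0), numeric(1L))
  )
  if (any(out$weight <= 0)) stop("component weights must be positive",
                                 call. = FALSE)
  if (any(out$sigma_phi <= 0) || any(out$sigma_psi <= 0)) {
    stop("component widths must be positive", call. = FALSE)
  }
  if (any(abs(out$rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  out$weight <- out$weight / sum(out$weight)
  class(out) <- c("gaussian_rama_model", class(out))
  out
}

#' Evaluate a Gaussian-mixture Ramachandran density on a grid
#'
#' The mixture density is evaluated at bin centers with periodic wrapping
#' on \[-180, 180) (each component is summed over its +-360-degree image
#' replicas in both angles) and normalized to sum to 1 over the grid.
#'
#' @param model a [gaussian_model()].
#' @param phi_step,psi_step grid steps in degrees.
#' @return a probability [rama_grid()].
#' @export
gaussian_density <- function(model, phi_step = 2, psi_step = phi_step) {
  phi <- bin_centers(phi_step)
  psi <- bin_centers(psi_step)
  vals <- matrix(0, length(phi), length(psi))
  images <- c(-360, 0, 360)
  for (k in seq_len(nrow(model))) {
    m <- model[k, ]
    cmp <- matrix(0, length(phi), length(psi))
    for (ox in images) {
      u <- (phi - m$phi0 + ox) / m$sigma_phi
      for (oy in images) {
        v <- (psi - m$psi0 + oy) / m$sigma_psi
        q <- outer(u^2, v^2, `+`)
        if (m$rho != 0) q <- q - 2 * m$rho * outer(u, v)
        cmp <- cmp + exp(-q / (2 * (1 - m$rho^2)))
      }
    }
    vals <- vals + m$weight * cmp / (2 * pi * m$sigma_phi * m$sigma_psi *
                                       sqrt(1 - m$rho^2))
  }
  rama_grid(vals / sum(vals), phi_step, psi_step, "probability",
            meta = list(model_components = nrow(model)))
}
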