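#' Mesostate rectangle definitions
#'
#' Loads named non-overlapping rectangles of Ramachandran space (pPII, the
#' antiparallel-beta basin `ab`, the beta transition region `bt`, the
#' parallel-beta basin `pb`, and the right-handed helix `aR`).  Membership
#' is by bin center with half-open edges \[min, max), giving an unambiguous
#' partition at shared boundaries.
#'
#' @param path YAML file with a `mesostates` map of
#'   `[phi_min, phi_max, psi_min, psi_max]` vectors (degrees).
#' @return an object of class `mesostate_set`: a tibble of rectangles,
#'   with the source path in attribute `source`.
#' @export
mesostate_set <- function(path = system.file("extdata", "mesostates.yaml",
                                             package = "ramafield")) {
  cfg <- yaml::read_yaml(path)
  out <- tibble::tibble(
    mesostate = names(cfg$mesostates),
    phi_min = unname(vapply(cfg$mesostates, function(r) r[[1L]], numeric(1L))),
    phi_max = unname(vapply(cfg$mesostates, function(r) r[[2L]], numeric(1L))),
    psi_min = unname(vapply(cfg$mesostates, function(r) r[[3L]], numeric(1L))),
    psi_max = unname(vapply(cfg$mesostates, function(r) r[[4L]], numeric(1L)))
  )
  if (any(out$phi_min >= out$phi_max) || any(out$psi_min >= out$psi_max)) {
    stop("degenerate mesostate rectangle", call. = FALSE)
  }
  if (any(out$phi_min < -180 | out$phi_max > 180 |
          out$psi_min < -180 | out$psi_max > 180)) {
    stop("mesostate rectangles must lie within [-180, 180)^2", call. = FALSE)
  }
  for (a in seq_len(nrow(out))) {
    for (b in seq_len(nrow(out))) {
      if (a < b &&
          out$phi_min[a] < out$phi_max[b] && out$phi_min[b] < out$phi_max[a] &&
          out$psi_min[a] < out$psi_max[b] && out$psi_min[b] < out$psi_max[a]) {
        stop("mesostate rectangles overlap: ", out$mesostate[a], " and ",
             out$mesostate[b], call. = FALSE)
      }
    }
  }
  attr(out, "source") <- path
  class(out) <- c("mesostate_set", class(out))
  out
}

#' Mesostate populations of a Ramachandran distribution
#'
#' Integrates bin probabilities over each mesostate rectangle (bin-center
#' membership, half-open edges).  Mass outside every rectangle is reported
#' as `"other"`, so the populations sum to 1.
#'
#' @param P a probability [rama_grid()].
#' @param mesostates a [mesostate_set()].
#' @return a tibble with columns `mesostate` and `population`.
#' @export
mesostate_populations <- function(P, mesostates = mesostate_set()) {
  if (grid_kind(P) != "probability") stop("P must be a probability grid",
                                          call. = FALSE)
  phi <- bin_centers(attr(P, "phi_step"))
  psi <- bin_centers(attr(P, "psi_step"))
  pops <- vapply(seq_len(nrow(mesostates)), function(k) {
    m <- mesostates[k, ]
    sel_phi <- phi >= m$phi_min & phi < m$phi_max
    sel_psi <- psi >= m$psi_min & psi < m$psi_max
    sum(unclass(P)[sel_phi, sel_psi])
  }, numeric(1L))
  tibble::tibble(
    mesostate = c(mesostates$mesostate, "other"),
    population = c(pops, 1 - sum(pops))
  )
}

#' Marginal distribution over one backbone angle
#'
#' Sums the 2D Ramachandran distribution over the other axis.
#'
#' @param P a probability [rama_grid()].
#' @param angle `"phi"` or `"psi"`.
#' @return a tibble with columns `theta` (bin centers, degrees) and `prob`,
#'   summing to 1.
#' @export
marginalize <- function(P, angle = c("phi", "psi")) {
  angle <- match.arg(angle)
  if (grid_kind(P) != "probability") stop("P must be a probability grid",
                                          call. = FALSE)
  if (angle == "phi") {
    tibble::tibble(theta = bin_centers(attr(P, "phi_step")),
                   prob = unname(rowSums(unclass(P))))
  } else {
    tibble::tibble(theta = bin_centers(attr(P, "psi_step")),
                   prob = unname(colSums(unclass(P))))
  }
}

#' Karplus coefficient sets
#'
#' @param path YAML file defining `J(theta) = A cos^2(theta + offset) +
#'   B cos(theta + offset) + C` for each coupling, plus the backbone angle
#'   it depends on.
#' @return a tibble with one row per coupling.
#' @export
karplus_set <- function(path = system.file("extdata", "karplus.yaml",
                                           package = "ramafield")) {
  cfg <- yaml::read_yaml(path)
  tibble::tibble(
    coupling = names(cfg$couplings),
    A = unname(vapply(cfg$couplings, function(x) as.numeric(x$A), numeric(1L))),
    B = unname(vapply(cfg$couplings, function(x) as.numeric(x$B), numeric(1L))),
    C = unname(vapply(cfg$couplings, function(x) as.numeric(x$C), numeric(1L))),
    offset = unname(vapply(cfg$couplings, function(x) as.numeric(x$offset),
                           numeric(1L))),
    angle = unname(vapply(cfg$couplings, function(x) x$angle, character(1L)))
  )
}

#' Ensemble-averaged Karplus coupling from a 1D angle distribution
#'
#' \eqn{\langle J \rangle = \sum_\theta P(\theta) [A \cos^2(\theta +
#' \Delta) + B \cos(\theta + \Delta) + C]}.
#'
#' @param P1d a tibble from [marginalize()] (columns `theta`, `prob`).
#' @param A,B,C Karplus coefficients in Hz.
#' @param offset phase offset in degrees.
#' @return the expected coupling in Hz.
#' @export
karplus_coupling <- function(P1d, A, B, C, offset = 0) {
  p <- P1d$prob / sum(P1d$prob)
  ct <- cos(deg2rad(P1d$theta + offset))
  sum(p * (A * ct^2 + B * ct + C))
}

#' All configured J-couplings of a Ramachandran distribution
#'
#' Marginalizes the distribution over the relevant backbone angle for each
#' configured coupling and applies [karplus_coupling()].
#'
#' @param P a probability [rama_grid()].
#' @param karplus a [karplus_set()].
#' @return a tibble with columns `coupling` and `J_Hz`.
#' @export
jcouplings <- function(P, karplus = karplus_set()) {
  J <- vapply(seq_len(nrow(karplus)), function(k) {
    kp <- karplus[k, ]
    karplus_coupling(marginalize(P, kp$angle), kp$A, kp$B, kp$C, kp$offset)
  }, numeric(1L))
  tibble::tibble(coupling = karplus$coupling, J_Hz = J)
}

#' Deviation report against reference couplings
#'
#' Absolute deviations |J_computed - J_reference|, flagged against the
#' reference uncertainty band.
#'
#' @param computed tibble with columns `coupling`, `J_Hz` and optionally
#'   grouping columns (`residue`, `lambda`) carried through.
#' @param reference tibble with columns `coupling`, `value`, `uncertainty`
#'   (and matching grouping columns, if present in `computed`).
#' @return `computed` with extra columns `reference`, `abs_dev`,
#'   `within_uncertainty`.
#' @export
deviation_report <- function(computed, reference) {
  keys <- intersect(c("residue", "coupling"), names(computed))
  keys <- keys[keys %in% names(reference)]
  if (!"coupling" %in% keys) stop("both tables need a `coupling` column",
                                  call. = FALSE)
  out <- dplyr::left_join(computed, reference, by = keys)
  if (anyNA(out$value)) {
    bad <- out[is.na(out$value), , drop = FALSE]
    stop("missing reference for coupling ", bad$coupling[1L], call. = FALSE)
  }
  dplyr::mutate(out,
                reference = .data$value,
                abs_dev = abs(.data$J_Hz - .data$value),
                within_uncertainty = .data$abs_dev <= .data$uncertainty,
                value = NULL, uncertainty = NULL)
}

#' Reference experimental couplings shipped with the package
#'
#' @param path YAML file of per-residue reference values and uncertainties;
#'   the shipped defaults are literature-typical and documented in the file
#'   header.
#' @return a tibble with columns `residue`, `coupling`, `value`,
#'   `uncertainty`.
#' @export
reference_couplings <- function(path = system.file(
                                  "extdata", "reference_couplings.yaml",
                                  package = "ramafield")) {
  cfg <- yaml::read_yaml(path)
  purrr::map_dfr(names(cfg$references), function(res) {
    purrr::map_dfr(names(cfg$references[[res]]), function(cp) {
      tibble::tibble(residue = res, coupling = cp,
                     value = as.numeric(cfg$references[[res]][[cp]]$value),
                     uncertainty =
                       as.numeric(cfg$references[[res]][[cp]]$uncertainty))
    })
  })
}
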