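#' Contact-radii table
#'
#' Loads a symmetric element-pair table of minimum approach distances
#' \eqn{R_s} (Angstrom).  Two eligible atoms closer than \eqn{R_s} count as
#' an atomic overlap.  The shipped defaults are the canonical hard-sphere
#' contact limits of Ramachandran-type analyses.
#'
#' @param path YAML file with a `pairs` map keyed `"C-N"` etc.; defaults to
#'   the table shipped with the package.
#' @return an object of class `contact_radii`: a symmetric named matrix of
#'   distances in Angstrom.
#' @export
contact_radii <- function(path = system.file("extdata", "contact_radii.yaml",
                                             package = "ramafield")) {
  cfg <- yaml::read_yaml(path)
  keys <- strsplit(names(cfg$pairs), "-", fixed = TRUE)
  elems <- sort(unique(unlist(keys)))
  m <- matrix(NA_real_, length(elems), length(elems),
              dimnames = list(elems, elems))
  for (k in seq_along(keys)) {
    i <- keys[[k]][1L]; j <- keys[[k]][2L]
    v <- as.numeric(cfg$pairs[[k]])
    if (!is.finite(v) || v <= 0) stop("contact radius must be positive: ",
                                      names(cfg$pairs)[k], call. = FALSE)
    m[i, j] <- v; m[j, i] <- v
  }
  structure(m, class = c("contact_radii", "matrix"))
}

# Look up R_s for element vectors ei, ej; error names any missing pair.
radii_lookup <- function(radii, ei, ej) {
  known <- rownames(radii)
  bad <- which(!(ei %in% known) | !(ej %in% known))
  if (length(bad)) {
    stop("no contact radius for element pair ", ei[bad[1L]], "-",
         ej[bad[1L]], call. = FALSE)
  }
  out <- unname(radii[cbind(ei, ej)])
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("no contact radius for element pair ", ei[bad], "-", ej[bad],
         call. = FALSE)
  }
  out
}

#' Eligible atom-pair mask
#'
#' All unordered atom pairs separated by at least `min_separation` covalent
#' bonds.  With `scope = "backbone_sidechain"` only pairs with one atom of
#' role backbone or cap (the peptide-group atoms, which count as backbone
#' for masking) and one side-chain atom are retained -- the pair set used by
#' the lambda admissibility rule.
#'
#' @param structure a [build_mimetic()] object (or fixture).
#' @param scope `"all"` or `"backbone_sidechain"`.
#' @param min_separation minimum bond-path length (default 4).
#' @return a tibble with columns `i`, `j`, `sep`, `elem_i`, `elem_j`.
#' @export
pair_mask <- function(structure, scope = c("all", "backbone_sidechain"),
                      min_separation = 4L) {
  scope <- match.arg(scope)
  n <- nrow(structure$atoms)
  idx <- which(upper.tri(structure$sep) & structure$sep >= min_separation,
               arr.ind = TRUE)
  i <- unname(idx[, 1L]); j <- unname(idx[, 2L])
  if (scope == "backbone_sidechain") {
    role <- structure$atoms$role
    bb <- role %in% c("backbone", "cap")
    sc <- role == "sidechain"
    keep <- (bb[i] & sc[j]) | (sc[i] & bb[j])
    i <- i[keep]; j <- j[keep]
  }
  tibble::tibble(
    i = i, j = j,
    sep = as.integer(structure$sep[cbind(i, j)]),
    elem_i = structure$atoms$element[i],
    elem_j = structure$atoms$element[j]
  )
}

#' Count hard-sphere atomic overlaps in one conformation
#'
#' Number of mask pairs whose interatomic distance is strictly less than the
#' contact radius \eqn{R_s} for the element pair.
#'
#' @inheritParams pair_mask
#' @param radii a [contact_radii()] table.
#' @param mask a [pair_mask()] tibble; defaults to all eligible pairs.
#' @return integer overlap count.
#' @export
count_overlaps <- function(structure, radii = contact_radii(),
                           mask = pair_mask(structure)) {
  if (nrow(mask) == 0L) return(0L)
  rs <- radii_lookup(radii, mask$elem_i, mask$elem_j)
  d2 <- rowSums((structure$xyz[mask$i, , drop = FALSE] -
                 structure$xyz[mask$j, , drop = FALSE])^2)
  sum(d2 < rs^2)
}

#' Average-overlap landscape over Ramachandran space
#'
#' For every (phi, psi) bin, sets the backbone torsions to the bin center,
#' enumerates the full nested product of side-chain torsion configurations
#' at `chi_step` (a full 360-degree sweep of each chi starting from the
#' built structure's current value), sums the overlap counts over all
#' configurations and divides by the number of configurations sampled,
#' \eqn{(360/\Delta\chi)^{N_\chi}}.  For alanine (no chi torsions) the bin
#' value is the single-conformation count.
#'
#' @inheritParams count_overlaps
#' @param backbone_step,chi_step grid steps in degrees; must divide 360.
#' @return a [rama_grid()] of kind `"overlap_count"`.
#' @export
steric_scan <- function(structure, radii = contact_radii(),
                        backbone_step = 2, chi_step = 2) {
  res <- chi_scan_engine(structure, radii = radii,
                         backbone_step = backbone_step, chi_step = chi_step,
                         compute = "overlap")
  rama_grid(res$overlap, phi_step = backbone_step, psi_step = backbone_step,
            kind = "overlap_count",
            meta = list(residue = structure$residue,
                        backbone_angle = structure$backbone_angle,
                        chi_step = chi_step))
}
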