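#' Load the idealized geometry configuration
#'
#' Reads the declarative internal-coordinate (Z-matrix) description of the
#' residue mimetics.  The shipped file uses standard peptide geometry
#' (Engh-Huber-type bond lengths and angles) with L-chirality; supplying a
#' modified copy lets the builder reproduce any externally distributed
#' structure set bit-for-bit.
#'
#' @param path path to a geometry YAML file; defaults to the file shipped
#'   with the package.
#' @return a named list as parsed from the YAML file.
#' @export
default_geometry <- function(path = system.file("extdata", "geometry.yaml",
                                                package = "ramafield")) {
  yaml::read_yaml(path)
}

# Parse a dihedral/angle field that may be numeric, "phi", "psi",
# "phi+122.5", "psi-30", or "backbone".
parse_symbolic <- function(x, phi, psi, backbone_angle) {
  if (is.numeric(x)) return(x)
  x <- gsub(" ", "", as.character(x))
  if (x == "backbone") return(backbone_angle)
  m <- regmatches(x, regexec("^(phi|psi)([+-][0-9.]+)?$", x))[[1]]
  if (length(m) == 0L) stop("cannot parse symbolic value: ", x, call. = FALSE)
  base <- if (m[2L] == "phi") phi else psi
  off <- if (nzchar(m[3L])) as.numeric(m[3L]) else 0
  base + off
}

#' Build an amino-acid residue mimetic structure
#'
#' Constructs a single-residue mimetic -- the residue itself plus the
#' carbonyl group (C', O) of the preceding residue and the amide group
#' (N, H) of the following residue -- from idealized internal coordinates.
#' Peptide bonds are planar trans (omega = 180), the alpha carbon is
#' L-chiral, and the N-CA-C' backbone angle is set exactly to
#' `backbone_angle`.  Side-chain torsions follow the standard heavy-atom
#' definitions (chi1 = N-CA-CB-CG..., methyl rotations excluded), so the
#' number of chi torsions is ALA 0, VAL 1, LEU 2, ILE 2.
#'
#' @param residue one of `"ALA"`, `"VAL"`, `"LEU"`, `"ILE"`.
#' @param backbone_angle the N-CA-C' angle in degrees (default 110, with
#'   105 and 115 as the vibrational-variant values).
#' @param geometry geometry configuration, see [default_geometry()].
#' @return an object of class `mimetic` with components `residue`, `atoms`
#'   (a tibble with id, name, element, role, resno), `xyz` (n x 3 matrix,
#'   Angstrom), `bonds` (2-column index matrix), `torsions` (named list of
#'   axis-atom indices + rotating set), `backbone_angle`, and `sep`
#'   (bond-separation matrix).
#' @examples
#' v <- build_mimetic("VAL")
#' get_torsion(v, "phi")
#' @export
build_mimetic <- function(residue, backbone_angle = 110,
                          geometry = default_geometry()) {
  residue <- toupper(as.character(residue)[1L])
  if (!residue %in% names(geometry$residues)) {
    stop("unsupported residue code '", residue,
         "'; supported: ", paste(names(geometry$residues), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(backbone_angle) || backbone_angle < 90 || backbone_angle > 130) {
    stop("backbone_angle must lie in [90, 130] degrees", call. = FALSE)
  }
  spec <- geometry$residues[[residue]]
  phi0 <- geometry$phi_init %||% -120
  psi0 <- geometry$psi_init %||% 120

  n <- length(spec$atoms)
  ids <- vapply(spec$atoms, function(a) a$id, character(1L))
  xyz <- matrix(NA_real_, n, 3L)
  bonds <- NULL
  for (k in seq_len(n)) {
    a <- spec$atoms[[k]]
    refs <- match(unlist(a$refs), ids)
    if (k == 1L) {
      xyz[k, ] <- c(0, 0, 0)
    } else if (length(refs) == 1L) {
      xyz[k, ] <- xyz[refs[1L], ] + c(a$bond, 0, 0)
    } else if (length(refs) == 2L) {
      # third atom: in the xy-plane at the requested angle from ref2
      th <- deg2rad(parse_symbolic(a$angle, phi0, psi0, backbone_angle))
      u <- vunit(xyz[refs[2L], ] - xyz[refs[1L], ])
      perp <- vunit(vcross(c(0, 0, 1), u))
      xyz[k, ] <- xyz[refs[1L], ] + a$bond * (cos(th) * u + sin(th) * perp)
    } else {
      xyz[k, ] <- place_atom(xyz[refs[1L], ], xyz[refs[2L], ], xyz[refs[3L], ],
                             a$bond,
                             parse_symbolic(a$angle, phi0, psi0, backbone_angle),
                             parse_symbolic(a$dihedral, phi0, psi0, backbone_angle))
    }
    if (length(refs) >= 1L) bonds <- rbind(bonds, c(refs[1L], k))
  }

  atoms <- tibble::tibble(
    id = ids,
    name = vapply(spec$atoms, function(a) a$name, character(1L)),
    element = vapply(spec$atoms, function(a) a$element, character(1L)),
    role = vapply(spec$atoms, function(a) a$role, character(1L)),
    resno = vapply(spec$atoms, function(a) as.integer(a$res), integer(1L))
  )

  torsion_defs <- c(
    list(phi = c("C0", "N", "CA", "C"), psi = c("N", "CA", "C", "N2")),
    stats::setNames(
      lapply(spec$chis, function(ch) unlist(ch$atoms)),
      vapply(spec$chis, function(ch) ch$name, character(1L))
    )
  )

  st <- new_mimetic(residue, atoms, xyz, bonds, torsion_defs, backbone_angle)
  # exact backbone dihedrals at the configured initial values
  st <- set_torsion(st, "phi", phi0)
  st <- set_torsion(st, "psi", psi0)
  st
}

# Assemble a mimetic object from parts; derives rotating sets and the
# bond-separation matrix from the bond graph.
new_mimetic <- function(residue, atoms, xyz, bonds, torsion_defs,
                        backbone_angle) {
  n <- nrow(atoms)
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (igraph::components(g)$no != 1L) {
    stop("bond graph is not connected", call. = FALSE)
  }
  sep <- igraph::distances(g)

  torsions <- lapply(torsion_defs, function(idq) {
    idx <- match(idq, atoms$id)
    if (anyNA(idx)) stop("torsion references unknown atom id", call. = FALSE)
    g2 <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, idx[2:3])
    )
    comp <- igraph::components(g2)$membership
    rotating <- which(comp == comp[idx[4L]])
    list(atoms = idx, rotating = rotating)
  })

  structure(
    list(residue = residue, atoms = atoms, xyz = xyz, bonds = bonds,
         graph = g, sep = sep, torsions = torsions,
         backbone_angle = backbone_angle),
    class = "mimetic"
  )
}

#' @export
print.mimetic <- function(x, ...) {
  cat("<mimetic> ", x$residue, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds, N-CA-C' = ",
      format(x$backbone_angle), " deg\n", sep = "")
  chis <- setdiff(names(x$torsions), c("phi", "psi"))
  tor <- vapply(names(x$torsions), function(nm) get_torsion(x, nm), numeric(1L))
  cat("  torsions: ",
      paste(sprintf("%s = %.1f", names(tor), tor), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Measure a torsion angle
#'
#' @param structure a [build_mimetic()] object.
#' @param torsion torsion name (`"phi"`, `"psi"`, `"chi1"`, `"chi2"`).
#' @return the dihedral angle in degrees, in \[-180, 180).
#' @export
get_torsion <- function(structure, torsion) {
  td <- structure$torsions[[torsion]]
  if (is.null(td)) stop("unknown torsion '", torsion, "'", call. = FALSE)
  X <- structure$xyz
  i <- td$atoms
  dihedral4(X[i[1L], ], X[i[2L], ], X[i[3L], ], X[i[4L], ])
}

#' Set a torsion angle exactly
#'
#' Rotates precisely the atoms downstream of the torsion axis (the connected
#' component containing the fourth axis atom after cutting the central bond)
#' about the axis, leaving every other atom, every bond length and every bond
#' angle untouched.
#'
#' @inheritParams get_torsion
#' @param angle target angle in degrees (absolute, unless `relative`).
#' @param relative if `TRUE`, rotate by `angle` instead of to `angle`.
#' @return the modified `mimetic` object.
#' @export
set_torsion <- function(structure, torsion, angle, relative = FALSE) {
  td <- structure$torsions[[torsion]]
  if (is.null(td)) stop("unknown torsion '", torsion, "'", call. = FALSE)
  delta <- if (relative) angle else wrap180(angle - get_torsion(structure, torsion))
  i <- td$atoms
  axis_p <- structure$xyz[i[2L], ]
  axis_k <- vunit(structure$xyz[i[3L], ] - structure$xyz[i[2L], ])
  structure$xyz <- rotate_about_axis(structure$xyz, td$rotating,
                                     axis_p, axis_k, delta)
  structure
}

#' Number of covalent bonds separating two atoms
#'
#' Shortest path length in the covalent-bond graph; the eligibility rule for
#' steric and Lennard-Jones pairs is a separation of at least 4 bonds.
#'
#' @inheritParams get_torsion
#' @param i,j atom indices.
#' @return integer bond count.
#' @export
bond_separation <- function(structure, i, j) {
  n <- nrow(structure$atoms)
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) {
    stop("atom index out of range", call. = FALSE)
  }
  s <- structure$sep[i, j]
  if (!is.finite(s)) stop("atoms are not connected in the bond graph",
                          call. = FALSE)
  as.integer(s)
}

#' Signed chirality volume at the alpha carbon
#'
#' Signed volume of the tetrahedron spanned by N, C', C-beta and H-alpha;
#' positive for L-amino acids.  Its sign is invariant under any sequence of
#' torsion operations.
#'
#' @inheritParams get_torsion
#' @return signed volume in cubic Angstrom.
#' @export
chirality_volume <- function(structure) {
  idx <- match(c("N", "C", "CB", "HA"), structure$atoms$id)
  if (anyNA(idx)) stop("structure lacks N/C/CB/HA atoms", call. = FALSE)
  X <- structure$xyz
  det(rbind(X[idx[3L], ] - X[idx[1L], ],
            X[idx[2L], ] - X[idx[1L], ],
            X[idx[4L], ] - X[idx[1L], ])) / 6
}

#' Number of side-chain torsions of a mimetic
#' @inheritParams get_torsion
#' @return integer (0 for ALA, 1 for VAL, 2 for LEU and ILE).
#' @export
n_chi <- function(structure) {
  length(setdiff(names(structure$torsions), c("phi", "psi")))
}

#' Atom table of a mimetic as a tibble
#'
#' @param x a `mimetic` object.
#' @param ... unused.
#' @return a tibble with one row per atom: id, name, element, role, resno
#'   and Cartesian coordinates.
#' @method as_tibble mimetic
#' @export
as_tibble.mimetic <- function(x, ...) {
  dplyr::bind_cols(x$atoms,
                   tibble::tibble(x = x$xyz[, 1L], y = x$xyz[, 2L],
                                  z = x$xyz[, 3L]))
}
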