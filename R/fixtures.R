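#' Toy structures with known bond graphs for oracle tests
#'
#' Small synthetic structures whose overlap counts, Lennard-Jones energies
#' and admissibility can be checked by hand or against naive
#' implementations:
#'
#' * `two_atom_pair`: a 5-atom chain whose two terminal atoms (the only
#'   pair four bonds apart) sit exactly `distance` apart; the first
#'   terminal is backbone, the second side chain.
#' * `linear_chain`: five collinear atoms at 1.5 Angstrom spacing --
#'   exactly one pair with bond separation >= 4.
#' * `random_branched`: a random tree of `n_atoms` atoms with random
#'   elements, roles and coordinates; reproducible from `seed`.
#'
#' @param kind fixture type.
#' @param seed integer seed for `random_branched`.
#' @param distance terminal distance for `two_atom_pair`, Angstrom.
#' @param elements length-2 element vector for the `two_atom_pair`
#'   terminals.
#' @param n_atoms number of atoms for `random_branched`.
#' @return a `mimetic` object (with no torsion definitions).
#' @export
make_fixture <- function(kind = c("two_atom_pair", "linear_chain",
                                  "random_branched"),
                         seed = 1L, distance = 2.0,
                         elements = c("C", "C"), n_atoms = 10L) {
  kind <- match.arg(kind)
  if (kind == "two_atom_pair") {
    xyz <- rbind(c(0, 0, 0), c(0.7, 1, 0), c(0, 2, 0), c(0.7, 3, 0),
                 c(distance, 0, 0))
    atoms <- tibble::tibble(
      id = paste0("A", 1:5),
      name = paste0("A", 1:5),
      element = c(elements[1L], "C", "C", "C", elements[2L]),
      role = c("backbone", "cap", "cap", "cap", "sidechain"),
      resno = 1L
    )
    bonds <- cbind(1:4, 2:5)
  } else if (kind == "linear_chain") {
    xyz <- cbind(1.5 * (0:4), 0, 0)
    atoms <- tibble::tibble(
      id = paste0("A", 1:5), name = paste0("A", 1:5),
      element = rep("C", 5L),
      role = c("backbone", "backbone", "backbone", "sidechain", "sidechain"),
      resno = 1L
    )
    bonds <- cbind(1:4, 2:5)
  } else {
    set.seed(seed)
    n <- n_atoms
    parent <- c(NA_integer_, vapply(2:n, function(k)
      sample.int(k - 1L, 1L), integer(1L)))
    xyz <- matrix(stats::runif(3L * n, -2.5, 2.5), n, 3L)
    atoms <- tibble::tibble(
      id = paste0("A", seq_len(n)), name = paste0("A", seq_len(n)),
      element = sample(c("C", "N", "O", "H"), n, replace = TRUE),
      role = sample(c("backbone", "sidechain", "cap"), n, replace = TRUE),
      resno = 1L
    )
    bonds <- cbind(parent[-1L], 2:n)
  }
  new_mimetic("TOY", atoms, xyz, bonds, torsion_defs = list(),
              backbone_angle = NA_real_)
}
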