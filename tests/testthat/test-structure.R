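test_that("built mimetics have the right topology and chi counts", {
  expected_chi <- c(ALA = 0L, VAL = 1L, LEU = 2L, ILE = 2L)
  for (res in names(expected_chi)) {
    st <- cached_mimetic(res)
    expect_identical(n_chi(st), expected_chi[[res]])
    expect_setequal(c("phi", "psi"), intersect(names(st$torsions),
                                               c("phi", "psi")))
    # connected bond graph, all four elements known
    expect_true(all(is.finite(st$sep)))
    expect_true(all(st$atoms$element %in% c("C", "N", "O", "H")))
    # caps are exactly the preceding C', O and following N, H
    expect_identical(st$atoms$id[st$atoms$role == "cap"],
                     c("C0", "O0", "N2", "H2"))
  }
})

test_that("the backbone N-CA-C angle is set exactly", {
  for (ang in c(105, 110, 115)) {
    st <- build_mimetic("VAL", ang)
    idx <- match(c("N", "CA", "C"), st$atoms$id)
    measured <- acos(sum(
      (st$xyz[idx[1], ] - st$xyz[idx[2], ]) *
        (st$xyz[idx[3], ] - st$xyz[idx[2], ])
    ) / (sqrt(sum((st$xyz[idx[1], ] - st$xyz[idx[2], ])^2)) *
           sqrt(sum((st$xyz[idx[3], ] - st$xyz[idx[2], ])^2)))) * 180 / pi
    expect_equal(measured, ang, tolerance = 1e-9)
  }
  expect_error(build_mimetic("TRP"), "unsupported residue")
  expect_error(build_mimetic("ALA", 45), "backbone_angle")
})

test_that("peptide bonds are planar trans and never modified", {
  st <- cached_mimetic("LEU")
  # trans peptide plane: the amide H is anti to the carbonyl O and the
  # following amide N is anti to that O about the C'-CA axis
  planar <- function(s, ids, expected) {
    i <- match(ids, s$atoms$id)
    d <- ramafield:::dihedral4(s$xyz[i[1], ], s$xyz[i[2], ],
                               s$xyz[i[3], ], s$xyz[i[4], ])
    abs(ramafield:::wrap180(d - expected))
  }
  expect_lt(planar(st, c("O", "C", "N2", "H2"), 180), 1e-6)
  expect_lt(planar(st, c("O0", "C0", "N", "H"), 180), 1e-6)
  st2 <- set_torsion(set_torsion(st, "phi", -63), "chi1", 55)
  expect_lt(planar(st2, c("O", "C", "N2", "H2"), 180), 1e-6)
  expect_lt(planar(st2, c("O0", "C0", "N", "H"), 180), 1e-6)
})

test_that("set_torsion is exact, local, composable and periodic", {
  st <- cached_mimetic("ILE")
  for (tor in c("phi", "psi", "chi1", "chi2")) {
    target <- 37.25
    st2 <- set_torsion(st, tor, target)
    expect_equal(get_torsion(st2, tor), target, tolerance = 1e-9)
    # locality: atoms outside the rotating set do not move
    outside <- setdiff(seq_len(nrow(st$atoms)),
                       st$torsions[[tor]]$rotating)
    expect_equal(max(abs(st2$xyz[outside, ] - st$xyz[outside, ])), 0)
  }
  # +360 is the identity
  st3 <- set_torsion(st, "chi1", 360, relative = TRUE)
  expect_equal(max(abs(st3$xyz - st$xyz)), 0, tolerance = 1e-9)
  # relative rotations compose additively
  a <- set_torsion(set_torsion(st, "chi2", 40, relative = TRUE),
                   "chi2", 25, relative = TRUE)
  b <- set_torsion(st, "chi2", 65, relative = TRUE)
  expect_equal(a$xyz, b$xyz, tolerance = 1e-9)
  expect_error(set_torsion(st, "chi9", 10), "unknown torsion")
  expect_error(get_torsion(st, "zeta"), "unknown torsion")
})

test_that("torsion operations preserve internal geometry and chirality", {
  st <- cached_mimetic("VAL")
  bond_lengths <- function(s) {
    apply(s$bonds, 1L, function(b) {
      sqrt(sum((s$xyz[b[1], ] - s$xyz[b[2], ])^2))
    })
  }
  v0 <- chirality_volume(st)
  expect_gt(v0, 0)  # L-amino acid
  set.seed(42)
  s <- st
  for (k in 1:25) {
    tor <- sample(names(s$torsions), 1L)
    s <- set_torsion(s, tor, runif(1, -180, 180))
  }
  expect_equal(bond_lengths(s), bond_lengths(st), tolerance = 1e-9)
  expect_equal(chirality_volume(s), v0, tolerance = 1e-9)
  expect_gt(chirality_volume(s), 0)
})

test_that("rotating sets are the connected component past the cut bond", {
  st <- cached_mimetic("LEU")
  # chi2 rotating set is strictly inside chi1's
  r1 <- st$torsions$chi1$rotating
  r2 <- st$torsions$chi2$rotating
  expect_true(all(r2 %in% r1))
  expect_gt(length(r1), length(r2))
  # every rotating atom is on the far side of the axis bond
  d <- st$torsions$chi1$atoms[4L]
  expect_true(d %in% r1)
  expect_false(st$torsions$chi1$atoms[1L] %in% r1)
})

test_that("bond separation matches a breadth-first-search oracle", {
  st <- cached_mimetic("ILE")
  n <- nrow(st$atoms)
  set.seed(7)
  for (k in 1:40) {
    ij <- sample.int(n, 2L)
    expect_identical(bond_separation(st, ij[1], ij[2]),
                     bfs_separation(st$bonds, n, ij[1], ij[2]))
  }
  # random branched fixtures too
  for (seed in 1:3) {
    fx <- make_fixture("random_branched", seed = seed)
    m <- nrow(fx$atoms)
    for (k in 1:15) {
      ij <- sample.int(m, 2L)
      expect_identical(bond_separation(fx, ij[1], ij[2]),
                       bfs_separation(fx$bonds, m, ij[1], ij[2]))
    }
  }
  expect_error(bond_separation(st, 0, 5), "out of range")
})

test_that("PDB round trip preserves coordinates and the bond graph", {
  st <- cached_mimetic("VAL")
  st <- set_torsion(set_torsion(st, "phi", -65), "psi", 145)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mimetic(st, path)
  lines <- readLines(path)
  # first ATOM record is the preceding C' with serial 1
  atom1 <- lines[grep("^ATOM", lines)[1L]]
  expect_identical(as.integer(substr(atom1, 7, 11)), 1L)
  expect_identical(trimws(substr(atom1, 13, 16)), "C")
  expect_true(any(grepl("^CONECT", lines)))

  rt <- read_mimetic(path)
  expect_identical(rt$residue, "VAL")
  expect_equal(rt$xyz, st$xyz, tolerance = 1e-3)
  norm_bonds <- function(b) {
    b <- t(apply(b, 1L, sort))
    b[order(b[, 1], b[, 2]), ]
  }
  expect_equal(norm_bonds(rt$bonds), norm_bonds(st$bonds),
               ignore_attr = TRUE)
  expect_equal(get_torsion(rt, "phi"), -65, tolerance = 1e-2)
  expect_identical(rt$atoms$role, st$atoms$role)

  # CONECT records are mandatory
  stripped <- withr::local_tempfile(fileext = ".pdb")
  writeLines(grep("^CONECT", lines, value = TRUE, invert = TRUE), stripped)
  expect_error(read_mimetic(stripped), "CONECT")
})
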