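test_that("the 12-6 potential has its minimum and asymptotics right", {
  params <- lj_params()
  for (pair in list(c("C", "C"), c("N", "O"), c("H", "C"))) {
    i <- match(pair[1], params$element); j <- match(pair[2], params$element)
    rmin <- params$rmin_half[i] + params$rmin_half[j]
    eps <- sqrt(params$epsilon[i] * params$epsilon[j])
    expect_equal(lj_pair_energy(rmin, pair[1], pair[2], params), -eps,
                 tolerance = 1e-12)
    expect_lt(abs(lj_pair_energy(10 * rmin, pair[1], pair[2], params)),
              1e-5 * eps)
  }
  expect_error(lj_pair_energy(-1, "C", "C", params), "positive")
  expect_error(lj_pair_energy(1.5, "C", "X", params), "missing")
})

test_that("structure energies match a naive pair loop", {
  params <- lj_params()
  # no eligible pairs -> zero energy
  pairless <- make_fixture("two_atom_pair")
  pairless$sep[] <- 2
  expect_identical(lj_structure_energy(pairless, params,
                                       pair_mask(pairless)), 0)
  # a single eligible pair at the combined r_min gives -epsilon
  rmin_cc <- 2 * params$rmin_half[params$element == "C"]
  eps_cc <- params$epsilon[params$element == "C"]
  two <- make_fixture("two_atom_pair", distance = rmin_cc)
  expect_equal(lj_structure_energy(two, params), -eps_cc, tolerance = 1e-12)
  # random structures against the brute-force loop
  for (seed in 1:5) {
    fx <- make_fixture("random_branched", seed = seed, n_atoms = 11L)
    expect_equal(lj_structure_energy(fx, params), naive_lj_energy(fx, params),
                 tolerance = 1e-10)
  }
  st <- set_torsion(cached_mimetic("VAL"), "psi", 150)
  expect_equal(lj_structure_energy(st, params), naive_lj_energy(st, params),
               tolerance = 1e-10)
})

test_that("admissibility is a strict lambda * R_s exclusion", {
  radii <- contact_radii()
  rs <- radii["C", "C"]
  lambda <- 0.8
  at_threshold <- make_fixture("two_atom_pair", distance = lambda * rs)
  expect_false(is_admissible(at_threshold, radii, lambda))
  beyond <- make_fixture("two_atom_pair", distance = lambda * rs + 1e-9)
  expect_true(is_admissible(beyond, radii, lambda))
  # lambda = 0 excludes nothing
  clashing <- make_fixture("two_atom_pair", distance = 0.1)
  expect_true(is_admissible(clashing, radii, 0))
  expect_error(is_admissible(clashing, radii, -0.5), "lambda")
  for (seed in 1:5) {
    fx <- make_fixture("random_branched", seed = seed, n_atoms = 12L)
    for (l in c(0, 0.7, 1)) {
      expect_identical(is_admissible(fx, radii, l,
                                     pair_mask(fx, "backbone_sidechain")),
                       naive_admissible(fx, radii, l))
    }
  }
})

test_that("the mean-field LJ scan matches a filtering rebuild oracle", {
  radii <- contact_radii()
  params <- lj_params()
  for (res in c("ALA", "VAL")) {
    st <- cached_mimetic(res)
    lams <- c(0, 0.9, 1)
    g <- lj_meanfield_scan(st, params, radii, lambda = lams,
                           backbone_step = 60, chi_step = 90)
    nv <- naive_scans(st, radii, params, lambdas = lams,
                      backbone_step = 60, chi_step = 90)
    for (q in seq_along(lams)) {
      expect_equal(unclass(g[[q]]), nv$lj[[q]], tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("bins with no admissible configuration get the penalty energy", {
  radii <- contact_radii()
  params <- lj_params()
  st <- cached_mimetic("VAL")
  # an absurdly large lambda excludes every configuration everywhere
  g <- lj_meanfield_scan(st, params, radii, lambda = 5,
                         backbone_step = 90, chi_step = 90)
  expect_true(all(unclass(g) == 5e5))
  g2 <- lj_meanfield_scan(st, params, radii, lambda = 5,
                          backbone_step = 90, chi_step = 90,
                          penalty = 123)
  expect_true(all(unclass(g2) == 123))
})

test_that("Boltzmann inversion fixes the zero at the least populated bin", {
  uni <- rama_grid(matrix(1 / 144, 12, 12), 30, kind = "probability")
  E <- density_to_energy(uni, 298)
  expect_true(all(unclass(E) == 0))

  v <- matrix(1, 12, 12); v[3, 4] <- exp(1); v[5, 6] <- exp(2)
  P <- rama_grid(v / sum(v), 30, kind = "probability")
  E <- density_to_energy(P, 298)
  RT <- 8.314462618e-3 * 298
  expect_equal(max(E), 0)
  expect_equal(E[3, 4], -RT, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(which.min(E), which.max(unclass(P)))
  # round trip back to the distribution
  P2 <- energy_to_density(E, 298)
  expect_equal(unclass(P2), unclass(P), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero bins are rejected with advice to floor first
  v0 <- v; v0[1, 1] <- 0
  Pz <- rama_grid(v0 / sum(v0), 30, kind = "probability")
  expect_error(density_to_energy(Pz), "floor")
})

test_that("Boltzmann weighting reproduces energy differences", {
  e <- matrix(0, 12, 12)
  RT <- 8.314462618e-3 * 298
  e[1, 1] <- RT  # exactly one RT above the rest
  E <- rama_grid(e, 30, kind = "energy_kJ_mol")
  P <- energy_to_density(E, 298)
  expect_equal(P[2, 2] / P[1, 1], exp(1), tolerance = 1e-12,
               ignore_attr = TRUE)
  # uniform energies give a uniform distribution
  Pu <- energy_to_density(rama_grid(matrix(3, 12, 12), 30,
                                    kind = "energy_kJ_mol"))
  expect_true(all(abs(Pu - 1 / 144) < 1e-15))
  # penalty bins underflow to zero probability
  ep <- matrix(0, 12, 12); ep[4, 4] <- 5e5
  Pp <- energy_to_density(rama_grid(ep, 30, kind = "energy_kJ_mol"))
  expect_identical(as.numeric(Pp[4, 4]), 0)
})

test_that("field combination is an elementwise sum with shape checks", {
  set.seed(3)
  a <- rama_grid(matrix(rnorm(144), 12), 30, kind = "energy_kJ_mol")
  b <- rama_grid(matrix(rnorm(144), 12), 30, kind = "energy_kJ_mol")
  zero <- rama_grid(matrix(0, 12, 12), 30, kind = "energy_kJ_mol")
  expect_equal(unclass(combine_fields(a, zero)), unclass(a),
               ignore_attr = TRUE)
  expect_equal(unclass(combine_fields(a, b)), unclass(combine_fields(b, a)),
               ignore_attr = TRUE)
  c36 <- rama_grid(matrix(0, 36, 36), 10, kind = "energy_kJ_mol")
  expect_error(combine_fields(a, c36), "grid specs differ")
  # probabilities are invariant to constant offsets in either field
  shifted <- rama_grid(unclass(a) + 57.3, 30, kind = "energy_kJ_mol")
  P1 <- energy_to_density(combine_fields(a, b))
  P2 <- energy_to_density(combine_fields(shifted, b))
  expect_equal(unclass(P1), unclass(P2), tolerance = 1e-12)
})

test_that("the Gaussian mixture density wraps periodically", {
  # single isotropic component peaks at its center bin
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("components:",
               "  - {weight: 1, phi0: -60, psi0: 150, sigma_phi: 15, sigma_psi: 15}"),
             tmp)
  m <- gaussian_model(tmp)
  P <- gaussian_density(m, 4)
  ij <- which(unclass(P) == max(P), arr.ind = TRUE)[1L, ]
  centers <- bin_centers(4)
  expect_lte(abs(centers[ij[1]] + 60), 2)  # argmax bin contains the center
  expect_lte(abs(centers[ij[2]] - 150), 2)

  # two equal, well-separated components split the mass evenly
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("components:",
               "  - {weight: 0.5, phi0: -90, psi0: 120, sigma_phi: 10, sigma_psi: 10}",
               "  - {weight: 0.5, phi0: 60, psi0: -60, sigma_phi: 10, sigma_psi: 10}"),
             tmp2)
  P2 <- gaussian_density(gaussian_model(tmp2), 4)
  phi <- bin_centers(4)
  left <- sum(unclass(P2)[phi < 0, bin_centers(4) > 0])
  expect_equal(left, 0.5, tolerance = 0.01)

  # a component at the seam is continuous across +-180
  tmp3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("components:",
               "  - {weight: 1, phi0: -179, psi0: 0, sigma_phi: 12, sigma_psi: 12}"),
             tmp3)
  P3 <- gaussian_density(gaussian_model(tmp3), 2)
  # bins at -177 and +179 are both 2 degrees from the -179 center,
  # one of them across the seam
  expect_equal(as.numeric(P3[2, 90]), as.numeric(P3[180, 90]),
               tolerance = 1e-10)
  # the same model expressed with an equivalent center (+181 = -179 mod 360)
  tmp4 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("components:",
               "  - {weight: 1, phi0: 181, psi0: 0, sigma_phi: 12, sigma_psi: 12}"),
             tmp4)
  P4 <- gaussian_density(gaussian_model(tmp4), 2)
  expect_equal(unclass(P3), unclass(P4), tolerance = 1e-10)
})

test_that("alanine's distribution is insensitive to lambda", {
  st <- cached_mimetic("ALA")
  radii <- contact_radii()
  params <- lj_params()
  g <- lj_meanfield_scan(st, params, radii, lambda = c(0.7, 1.0),
                         backbone_step = 15, chi_step = 15)
  W <- water_field(gaussian_model(), 15)
  pops <- lapply(g, function(E) {
    mesostate_populations(energy_to_density(combine_fields(E, W)))
  })
  expect_lt(max(abs(pops[[1]]$population - pops[[2]]$population)), 0.01)
})
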