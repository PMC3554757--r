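one_atom_system <- function(born = 2.0, charge = 1, screen = 0.72) {
  mm_system(data.frame(serial = 1L, name = "C1", element = "C",
                       resname = "TOY", resid = 1L, chain = "A",
                       charge = charge, rmin_half = 1.9, epsilon = 0.1,
                       born_radius = born, screen = screen))
}

test_that("effective Born radii: isolated limit and distant-neighbor limit", {
  sys <- one_atom_system(born = 2.0)
  expect_equal(as.numeric(effective_born_radii(sys, matrix(0, 1, 3))),
               1.91, tolerance = 1e-12)
  two <- mm_system(rbind(sys$atoms, within(sys$atoms, serial <- 2L)))
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  a2 <- as.numeric(effective_born_radii(two, far))
  expect_lt(max(abs(a2 - 1.91)), 1e-6)
})

test_that("pairwise descreening matches a Monte-Carlo volume integral", {
  set.seed(6)
  # three-atom cluster; compare the summed pair integrals entering 1/alpha
  rho <- c(1.61, 1.41, 1.71)       # offset-corrected intrinsic radii
  screen <- c(0.8, 0.85, 0.72)
  coords <- rbind(c(0, 0, 0), c(3.1, 0.4, 0), c(1.2, 2.8, 0.6))
  sys <- mm_system(data.frame(
    serial = 1:3, name = "C1", element = "C", resname = "TOY",
    resid = 1:3, chain = "A", charge = 0, rmin_half = 1.9, epsilon = 0.1,
    born_radius = rho + 0.09, screen = screen))
  alpha <- as.numeric(effective_born_radii(sys, coords))
  for (i in 1:3) {
    mc_sum <- 0
    for (j in setdiff(1:3, i)) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      mc_sum <- mc_sum + oracle_hct_integral(r, rho[i], screen[j] * rho[j])
    }
    alpha_mc <- 1 / (1 / rho[i] - mc_sum)
    expect_equal(alpha[i], alpha_mc, tolerance = 0.01)
  }
})

test_that("GB polar energy: Born closed form, asymptotic additivity, oracle", {
  m0 <- solvent_model(kappa = 0)
  born_exact <- -(332.0636 / 2) * (1 - 1 / 80) / 2.0
  g1 <- gb_polar_energy(matrix(0, 1, 3), 1,
                        structure(2.0, class = "born_radii"), m0)
  expect_equal(g1$g_pol, born_exact, tolerance = 1e-9)

  # far enough apart that the screened-Coulomb pair tail (~k/r) is below
  # the tolerance; the energy is then the sum of the two self terms
  far <- rbind(c(0, 0, 0), c(1e7, 0, 0))
  g2 <- gb_polar_energy(far, c(1, 1), structure(c(2, 2),
                                                class = "born_radii"), m0)
  expect_equal(g2$g_pol, 2 * born_exact, tolerance = 1e-6)

  set.seed(7)
  for (rep in 1:5) {
    rs <- random_system(6)
    alpha <- as.numeric(effective_born_radii(rs$system, rs$coords))
    q <- rs$system$atoms$charge
    for (kappa in c(0, 0.1)) {
      mk <- solvent_model(kappa = kappa)
      got <- gb_polar_energy(rs$coords, q, alpha, mk, per_atom = TRUE)
      expect_equal(got$g_pol,
                   oracle_gb(rs$coords, q, alpha, kappa = kappa),
                   tolerance = 1e-10)
      expect_equal(sum(got$per_atom_pol), got$g_pol, tolerance = 1e-8)
    }
  }
})

test_that("GB salt screening strengthens polar solvation monotonically", {
  # self term: larger kappa screens the solvent term -> more negative G_pol
  kappas <- c(0, 0.05, 0.1, 0.2, 0.5)
  g <- vapply(kappas, function(k)
    gb_polar_energy(matrix(0, 1, 3), 1, structure(2.0, class = "born_radii"),
                    solvent_model(kappa = k))$g_pol, 0)
  expect_true(all(diff(abs(g)) > 0))
  # single-signed charges: G_pol <= 0
  set.seed(8)
  rs <- random_system(6)
  q <- abs(rs$system$atoms$charge)
  alpha <- effective_born_radii(rs$system, rs$coords)
  expect_lt(gb_polar_energy(rs$coords, q, alpha, solvent_model())$g_pol, 0)
})

test_that("kappa from ionic strength matches the Debye-Hueckel closed form", {
  # independent direct evaluation in CGS-style practical units:
  # kappa[1/A] = 50.29123... * sqrt(I / (eps * T))
  direct <- function(I, eps, T) {
    e <- 4.80320425e-10      # esu
    kB <- 1.380649e-16       # erg/K
    NA_ <- 6.02214076e23
    sqrt(8 * pi * e^2 * NA_ * I / (1000 * eps * kB * T)) * 1e-8
  }
  expect_equal(debye_kappa(0.1, 80, 300), direct(0.1, 80, 300),
               tolerance = 1e-4 / debye_kappa(0.1, 80, 300))
})

test_that("SASA: analytic sphere, buried atom, and two-sphere overlap", {
  sys <- one_atom_system()
  sys$atoms$rmin_half <- 1.6
  s <- sasa(sys, matrix(0, 1, 3), probe_radius = 1.4)
  expect_equal(s$total, 4 * pi * 3^2, tolerance = 1e-9)

  # atom caged by a shell of neighbors -> zero area
  shell_dirs <- mmgbsa:::fibonacci_sphere(40)
  atoms <- data.frame(serial = 1:41, name = "C1", element = "C",
                      resname = "TOY", resid = 1L, chain = "A",
                      charge = 0, rmin_half = c(1.6, rep(2.2, 40)),
                      epsilon = 0.1, born_radius = 1.7, screen = 0.72)
  shell <- mm_system(atoms)
  coords <- rbind(c(0, 0, 0), shell_dirs * 2.0)
  s2 <- sasa(shell, coords)
  expect_equal(s2$per_atom_area[1], 0)
  expect_equal(sum(s2$per_atom_area), s2$total)

  # two overlapping spheres vs the closed-form spherical-cap area
  r1 <- 1.6 + 1.4; r2 <- 1.9 + 1.4; d <- 2.4
  two <- mm_system(data.frame(
    serial = 1:2, name = "C1", element = "C", resname = "TOY",
    resid = 1:2, chain = "A", charge = 0, rmin_half = c(1.6, 1.9),
    epsilon = 0.1, born_radius = 1.7, screen = 0.72))
  got <- sasa(two, rbind(c(0, 0, 0), c(d, 0, 0)))
  cap_h <- function(R, Ro, d) R - (d^2 + R^2 - Ro^2) / (2 * d)
  exact <- c(4 * pi * r1^2 - 2 * pi * r1 * cap_h(r1, r2, d),
             4 * pi * r2^2 - 2 * pi * r2 * cap_h(r2, r1, d))
  expect_equal(got$per_atom_area, exact, tolerance = 0.02)

  # deterministic and rigid-transform stable to point-set tolerance
  set.seed(9)
  rs <- random_system(10)
  a1 <- sasa(rs$system, rs$coords)
  a2 <- sasa(rs$system, rs$coords)
  expect_identical(a1$total, a2$total)
  a3 <- sasa(rs$system, rigid_transform(rs$coords))
  expect_equal(a3$total, a1$total, tolerance = 0.01)
})

test_that("nonpolar energy is gamma * SASA + beta", {
  m <- solvent_model()
  expect_equal(nonpolar_energy(113.097, m), 0.8143, tolerance = 1e-4)
  mb <- solvent_model(beta_offset = 0.92)
  expect_equal(nonpolar_energy(0, mb), 0.92)
})

test_that("binding buries surface area: nonpolar binding term <= 0", {
  toy <- make_toy_complex(toy_complex_spec(n_frames = 1, jitter_sigma = 0,
                                           seed = 3))
  m <- solvent_model()
  be <- binding_energy(toy$system, toy$ensemble, "chain R", "chain L", m)
  expect_lte(be$frames$g_np[1], 0)
})
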