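test_that("per-atom electrostatic decomposition conserves the total", {
  set.seed(12)
  m <- solvent_model()
  for (rep in 1:3) {
    rs <- random_system(6)
    per <- decompose_electrostatic(rs$system, rs$coords, model = m)
    alpha <- effective_born_radii(rs$system, rs$coords)
    q <- rs$system$atoms$charge
    gb <- gb_polar_energy(rs$coords, q, alpha, m)$g_pol
    coul <- 0
    for (i in 1:5) for (j in (i + 1):6)
      coul <- coul + 332.0636 * q[i] * q[j] /
        sqrt(sum((rs$coords[i, ] - rs$coords[j, ])^2))
    expect_equal(sum(per), gb + coul, tolerance = 1e-10)
    expect_equal(attr(per, "total"), gb + coul, tolerance = 1e-10)
  }
})

test_that("symmetric two-atom system splits its energy into equal halves", {
  sys <- mm_system(data.frame(
    serial = 1:2, name = "C1", element = "C", resname = "TOY",
    resid = 1:2, chain = "A", charge = 0.5, rmin_half = 1.9,
    epsilon = 0.1, born_radius = 1.8, screen = 0.8))
  coords <- rbind(c(0, 0, 0), c(3, 0, 0))
  per <- decompose_electrostatic(sys, coords)
  expect_equal(per[1], per[2], tolerance = 1e-12)
  expect_equal(sum(per), attr(per, "total"), tolerance = 1e-12)
})

test_that("GB residue decomposition reproduces every binding component", {
  m <- solvent_model()
  for (seed in c(3, 17)) {
    toy <- make_toy_complex(toy_complex_spec(n_frames = 2, seed = seed))
    be <- binding_energy(toy$system, toy$ensemble, "chain R", "chain L", m)
    dec <- decompose_binding(toy$system, toy$ensemble, "chain R", "chain L",
                             m)
    for (comp in c("e_ele", "e_vdw", "g_pol", "g_np", "total"))
      expect_equal(sum(dec[[comp]]), mmgbsa:::breakdown_mean(be, comp),
                   tolerance = 1e-6)
  }
})

test_that("charged contact residues dominate the decomposed energies", {
  toy <- make_toy_complex(toy_complex_spec(n_frames = 1, jitter_sigma = 0,
                                           seed = 8, n_interface = 1,
                                           interaction_strength = 3))
  m <- solvent_model()
  dec <- decompose_binding(toy$system, toy$ensemble, "chain R", "chain L", m)
  # electrostatics localizes on the residues that carry charge ...
  charged_res <- unique(toy$system$atoms$residue_index[
    toy$system$atoms$charge != 0])
  ele_share <- abs(dec$e_ele)
  expect_gte(sum(ele_share[charged_res]) / sum(ele_share), 0.95)
  # ... and the most favorable residue is one of the contact pair itself
  contact_res <- unique(toy$system$atoms$residue_index[
    c(toy$truth$receptor_interface, toy$truth$ligand_interface)])
  expect_true(which.min(dec$total) %in% contact_res)
})

test_that("swapping receptor/ligand labels transposes sides only", {
  toy <- make_toy_complex(toy_complex_spec(n_frames = 1, seed = 9))
  m <- solvent_model()
  d1 <- decompose_binding(toy$system, toy$ensemble, "chain R", "chain L", m)
  d2 <- decompose_binding(toy$system, toy$ensemble, "chain L", "chain R", m)
  key <- function(d) paste(d$chain, d$resid)
  ord <- match(key(d1), key(d2))
  expect_equal(d1$total, d2$total[ord], tolerance = 1e-10)
  expect_equal(d1$side,
               c(receptor = "ligand", ligand = "receptor")[d2$side[ord]],
               ignore_attr = TRUE)
})

test_that("far-separated ligand leaves all residue contributions near zero", {
  toy <- make_toy_complex(toy_complex_spec(geometry = "separated",
                                           n_frames = 1, jitter_sigma = 0,
                                           seed = 10))
  dec <- decompose_binding(toy$system, toy$ensemble, "chain R", "chain L",
                           solvent_model(kappa = 0))
  expect_lt(max(abs(dec$total)), 1e-2)
})

test_that("PB residue decomposition closes approximately on a small toy", {
  toy <- make_toy_complex(toy_complex_spec(n_receptor_atoms = 6,
                                           n_ligand_atoms = 4,
                                           n_frames = 1, jitter_sigma = 0,
                                           seed = 11,
                                           interaction_strength = 2))
  m <- solvent_model(kappa = 0)
  be <- binding_energy(toy$system, toy$ensemble, "chain R", "chain L", m,
                       polar_method = "PB", pb_spacing = 0.6, pb_padding = 5)
  dec <- decompose_binding(toy$system, toy$ensemble, "chain R", "chain L",
                           m, polar_method = "PB", pb_spacing = 0.6,
                           pb_padding = 5)
  total_pol <- mmgbsa:::breakdown_mean(be, "g_pol")
  expect_lt(abs(sum(dec$g_pol) - total_pol),
            0.15 * max(abs(total_pol), 1))
  # the two solvation models agree residue-by-residue on the polar term of
  # this unambiguous toy: same sign and close magnitude
  decgb <- decompose_binding(toy$system, toy$ensemble, "chain R", "chain L",
                             m)
  strong <- abs(decgb$g_pol) > 0.5
  expect_true(any(strong))
  expect_true(all(sign(dec$g_pol[strong]) == sign(decgb$g_pol[strong])))
  expect_lt(max(abs(dec$g_pol[strong] / decgb$g_pol[strong] - 1)), 0.15)
})

test_that("hotspot report filters by magnitude and sorts ascending", {
  tab <- data.frame(chain = "R", resid = 1:3, resname = "TOY",
                    side = "receptor",
                    e_ele = 0, e_vdw = 0, g_pol = 0, g_np = 0,
                    total = c(-6.4, -0.3, 2.6))
  class(tab) <- c("residue_contributions", "data.frame")
  hs <- hotspot_report(tab, threshold = 1.0)
  expect_equal(hs$total, c(-6.4, 2.6))
  empty <- hotspot_report(tab[0, ], 1.0)
  expect_equal(nrow(empty), 0)
  low <- hotspot_report(tab[2, ], 1.0)
  expect_equal(nrow(low), 0)
  expect_match(attr(low, "note"), "no residue")
})
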