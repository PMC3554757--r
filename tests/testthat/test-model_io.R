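test_that("multi-model PDB parsing preserves records and frame structure", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, n_models = 2)
  parsed <- read_pdb(path)
  expect_equal(n_atoms(parsed$system), 5)
  expect_equal(n_frames(parsed$ensemble), 2)
  expect_equal(parsed$system$atoms$name, c("N", "CA", "C", "O", "CB"))
  expect_equal(parsed$system$atoms$element[4], "O")
  expect_equal(parsed$ensemble$coords[[2]][1, 1] -
                 parsed$ensemble$coords[[1]][1, 1], 0.01)

  # no MODEL records -> one frame
  single <- withr::local_tempfile(fileext = ".pdb")
  atom_lines <- grep("^ATOM", readLines(path), value = TRUE)[1:5]
  writeLines(c(atom_lines, "END"), single)
  expect_equal(n_frames(read_pdb(single)$ensemble), 1)
})

test_that("structural and parse errors are reported with context", {
  bad_model <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(bad_model, n_models = 2, drop_atom_in_model = 2)
  expect_error(read_pdb(bad_model), "MODEL 2")

  bad_coord <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(write_toy_pdb(withr::local_tempfile(), n_models = 1))
  substr(lines[3], 31, 38) <- "   xx.xx"
  writeLines(lines, bad_coord)
  expect_error(read_pdb(bad_coord), "line 3")
})

test_that("PDB write/read round trip preserves coordinates to PDB precision", {
  set.seed(42)
  rs <- random_system(8)
  frames <- list(rs$coords, rs$coords + 0.37, rigid_transform(rs$coords))
  ens <- frame_ensemble(frames)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(rs$system, ens, path)
  back <- read_pdb(path)
  expect_equal(n_frames(back$ensemble), 3)
  expect_equal(back$system$atoms$resname, rs$system$atoms$resname)
  for (f in 1:3)
    expect_lt(max(abs(back$ensemble$coords[[f]] - ens$coords[[f]])), 1e-3)
})

test_that("coordinate parsing agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, n_models = 1)
  mine <- read_pdb(path)
  ref <- bio3d::read.pdb(path)
  expect_equal(mine$ensemble$coords[[1]],
               matrix(ref$xyz, ncol = 3, byrow = TRUE), tolerance = 1e-8)
  expect_equal(mine$system$atoms$name, ref$atom$elety)
})

test_that("parameter application is total, flag-setting and idempotent", {
  atoms <- data.frame(serial = 1:3, name = c("N", "O", "NZ"),
                      element = c("N", "O", "N"),
                      resname = c("GLY", "GLY", "LYS"),
                      resid = c(1L, 1L, 2L), chain = "A",
                      stringsAsFactors = FALSE)
  sys <- apply_parameters(mm_system(atoms))
  expect_true(is_parameterized(sys))
  expect_true(sys$atoms$is_donor_heavy[1])    # backbone N
  expect_true(sys$atoms$is_acceptor[2])       # backbone O
  expect_true(sys$atoms$is_base_nitrogen[3])  # LYS NZ
  expect_false(sys$atoms$is_acid_oxygen[3])
  expect_identical(apply_parameters(sys)$atoms, sys$atoms)

  # keyed entry wins; element default covers unkeyed atoms; missing loud
  tab <- param_table(
    data.frame(resname = "LIG", atom = "C1", charge = 0.5, rmin_half = 1.9,
               epsilon = 0.1, born_radius = 1.7, screen = 0.72),
    data.frame(element = "O", charge = 0, rmin_half = 1.66, epsilon = 0.21,
               born_radius = 1.5, screen = 0.85))
  one <- data.frame(serial = 1L, name = "C1", element = "C",
                    resname = "LIG", resid = 1L, chain = "A")
  expect_equal(apply_parameters(mm_system(one), tab)$atoms$charge, 0.5)
  oat <- data.frame(serial = 1L, name = "OQ2", element = "O",
                    resname = "UNK", resid = 1L, chain = "A")
  expect_equal(apply_parameters(mm_system(oat), tab)$atoms$born_radius, 1.5)
  unk <- data.frame(serial = 1L, name = "XX", element = "X",
                    resname = "UNK", resid = 1L, chain = "A")
  expect_error(apply_parameters(mm_system(unk), tab, use_defaults = FALSE),
               "UNK/XX")
  expect_error(apply_parameters(mm_system(unk), tab), "UNK/XX")
})

test_that("parameter table TSV and JSON round trips preserve values", {
  tab <- default_parameter_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_parameter_table(tab, path)
  back <- read_parameter_table(path)
  expect_equal(back$entries$charge, tab$entries$charge)
  expect_equal(back$defaults$born_radius, tab$defaults$born_radius)
})

test_that("selection grammar matches brute-force set algebra", {
  set.seed(11)
  rs <- random_system(20)
  sys <- rs$system
  a <- select_atoms(sys, "chain A")
  expect_setequal(a, which(sys$atoms$chain == "A"))
  expect_setequal(select_atoms(sys, "chain A and resid 2-4"),
                  intersect(a, which(sys$atoms$resid >= 2 &
                                       sys$atoms$resid <= 4)))
  expect_setequal(select_atoms(sys, "name C1 or name O1"),
                  union(which(sys$atoms$name == "C1"),
                        which(sys$atoms$name == "O1")))
  expect_setequal(select_atoms(sys, "not (chain A or name O1)"),
                  setdiff(seq_len(20), union(a,
                                             which(sys$atoms$name == "O1"))))
  expect_setequal(select_atoms(sys, "all"), seq_len(20))
  # randomized compound expressions against per-atom evaluation
  for (i in 1:20) {
    r1 <- sample(5, 1); r2 <- sample(5, 1)
    expr <- sprintf("(chain A and resid %d-%d) or (name O1 and not chain A)",
                    min(r1, r2), max(r1, r2))
    manual <- which((sys$atoms$chain == "A" & sys$atoms$resid >= min(r1, r2) &
                       sys$atoms$resid <= max(r1, r2)) |
                      (sys$atoms$name == "O1" & sys$atoms$chain != "A"))
    expect_setequal(suppressWarnings(select_atoms(sys, expr)), manual)
  }
  expect_warning(select_atoms(sys, "not (chain A or chain B)"),
                 "matched no atoms")
  expect_error(select_atoms(sys, "chain A and and"), "syntax error")
  expect_error(select_atoms(sys, "resid ?"), "syntax error")
})

test_that("report writers emit fixed-precision TSV and lossless JSON", {
  frames <- data.frame(time = c(0, 1), e_ele = c(-176.4, -176.6),
                       e_vdw = c(-10, -12), g_pol = c(100, 101),
                       g_np = c(-2, -2))
  frames$total <- rowSums(frames[-1])
  bd <- mmgbsa:::new_energy_breakdown(frames, "GB", "run1")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(bd, tsv, "tsv")
  lines <- readLines(tsv)
  expect_true(any(grepl("kcal/mol", lines[1])))
  expect_true(any(grepl("^e_ele\t-176\\.50\t", lines)))

  js <- withr::local_tempfile(fileext = ".json")
  write_report(bd, js, "json")
  back <- read_report(js)
  expect_equal(back$table$mean, bd$aggregate$mean)
  expect_equal(back$frames$total, bd$frames$total)

  # empty interaction table -> header-only file
  fix <- make_hbond_fixture(n_frames = 4, occupancy_target = 0)
  empty <- detect_hbonds(fix$system, fix$ensemble, "chain A", "chain B",
                         mode = "heavy")
  expect_equal(nrow(empty), 0)
  etsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(empty, etsv, "tsv")
  body <- grep("^#", readLines(etsv), invert = TRUE, value = TRUE)
  expect_length(body, 1)  # header row only
})
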