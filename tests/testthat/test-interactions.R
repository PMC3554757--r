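hb_system <- function() {
  # donor N (chain A) with hydrogen, acceptor O (chain B)
  apply_parameters(mm_system(data.frame(
    serial = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
    resname = "GLY", resid = c(1L, 1L, 2L), chain = c("A", "A", "B"),
    stringsAsFactors = FALSE)))
}

test_that("hydrogen-bond geometry criteria follow distance and linearity", {
  sys <- hb_system()
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.0, 0, 0))
  hb <- detect_hbonds(sys, frame_ensemble(collinear), "chain A", "chain B",
                      min_occupancy = 0)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$occupancy, 1)
  expect_equal(hb$geometry_mode, "explicit")

  too_far <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 3.5, 0))
  expect_equal(nrow(detect_hbonds(sys, frame_ensemble(too_far),
                                  "chain A", "chain B",
                                  min_occupancy = 0)), 0)

  # in distance but 90 degrees off line -> rejected in explicit mode,
  # accepted in heavy-atom mode
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 3.0, 0))
  expect_equal(nrow(detect_hbonds(sys, frame_ensemble(bent),
                                  "chain A", "chain B",
                                  min_occupancy = 0)), 0)
  heavy <- detect_hbonds(sys, frame_ensemble(bent), "chain A", "chain B",
                         min_occupancy = 0, mode = "heavy")
  expect_equal(nrow(heavy), 1)
  expect_equal(heavy$geometry_mode, "heavy")

  no_h <- subset_system(sys, c(1, 3))
  expect_error(detect_hbonds(no_h, frame_ensemble(collinear[c(1, 3), ]),
                             "chain A", "chain B", mode = "explicit"),
               "no hydrogens")
})

test_that("occupancy filtering applies the lifetime threshold", {
  fix <- make_hbond_fixture(n_frames = 60, occupancy_target = 0.05)
  hb_all <- detect_hbonds(fix$system, fix$ensemble, "chain A", "chain B",
                          min_occupancy = 0)
  expect_equal(hb_all$occupancy, 0.05)
  filtered <- detect_hbonds(fix$system, fix$ensemble, "chain A", "chain B")
  expect_equal(nrow(filtered), 0)
  fix2 <- make_hbond_fixture(n_frames = 60, occupancy_target = 0.5)
  hb2 <- detect_hbonds(fix2$system, fix2$ensemble, "chain A", "chain B")
  expect_equal(hb2$occupancy, 0.5)
  expect_equal(sort(as.integer(strsplit(hb2$present_frames, ",")[[1]])),
               fix2$truth$bonded_frames)
})

test_that("salt-bridge detection applies the oxygen-nitrogen cutoff", {
  sys <- apply_parameters(mm_system(data.frame(
    serial = 1:2, name = c("OE1", "NZ"), element = c("O", "N"),
    resname = c("GLU", "LYS"), resid = c(1L, 2L), chain = c("A", "B"),
    stringsAsFactors = FALSE)))
  near <- matrix(c(0, 0, 0, 3.3, 0, 0), 2, 3, byrow = TRUE)
  far <- matrix(c(0, 0, 0, 3.5, 0, 0), 2, 3, byrow = TRUE)
  sb <- detect_salt_bridges(sys, frame_ensemble(near), "chain A", "chain B")
  expect_equal(nrow(sb), 1)
  expect_equal(sb$acid_resname, "GLU")
  expect_equal(sb$base_name, "NZ")
  expect_equal(nrow(detect_salt_bridges(sys, frame_ensemble(far),
                                        "chain A", "chain B")), 0)
})

test_that("detection matches brute-force geometric oracles on random ensembles", {
  set.seed(13)
  res_pool <- data.frame(
    resname = c("GLU", "LYS", "SER", "ALA"),
    name = c("OE1", "NZ", "OG", "CB"),
    element = c("O", "N", "O", "C"), stringsAsFactors = FALSE)
  for (rep in 1:8) {
    n <- 12
    pick <- sample(4, n, replace = TRUE)
    atoms <- data.frame(serial = seq_len(n), name = res_pool$name[pick],
                        element = res_pool$element[pick],
                        resname = res_pool$resname[pick],
                        resid = seq_len(n),
                        chain = rep(c("A", "B"), each = n / 2),
                        stringsAsFactors = FALSE)
    sys <- apply_parameters(mm_system(atoms))
    nf <- sample(20, 1)
    frames <- lapply(seq_len(nf), function(f)
      matrix(runif(3 * n, 0, 9), n, 3))
    ens <- frame_ensemble(frames)
    sel_a <- which(atoms$chain == "A")
    sel_b <- which(atoms$chain == "B")

    # oracle: per-frame all-pairs distance checks
    oracle_counts <- function(flag_from, flag_to, cutoff) {
      out <- list()
      for (i in sel_a) for (j in sel_b) {
        for (fromto in list(c(i, j), c(j, i))) {
          d <- fromto[1]; a <- fromto[2]
          if (!flag_from(d) || !flag_to(a)) next
          cnt <- sum(vapply(frames, function(xy)
            sqrt(sum((xy[d, ] - xy[a, ])^2)) <= cutoff, TRUE))
          if (cnt > 0)
            out[[paste(d, a)]] <- cnt / nf
        }
      }
      out
    }
    at <- sys$atoms
    hb <- detect_hbonds(sys, ens, sel_a, sel_b, min_occupancy = 0,
                        mode = "heavy")
    want <- oracle_counts(function(i) at$is_donor_heavy[i],
                          function(i) at$is_acceptor[i], 3.2)
    got_keys <- character(nrow(hb))
    if (nrow(hb)) {
      don <- match(paste(hb$donor_chain, hb$donor_resid, hb$donor_name),
                   paste(at$chain, at$resid, at$name))
      acc <- match(paste(hb$acceptor_chain, hb$acceptor_resid,
                         hb$acceptor_name),
                   paste(at$chain, at$resid, at$name))
      got_keys <- paste(don, acc)
      expect_equal(setNames(as.list(hb$occupancy), got_keys)[order(got_keys)],
                   want[order(names(want))])
    } else {
      expect_length(want, 0)
    }

    sb <- detect_salt_bridges(sys, ens, sel_a, sel_b)
    want_sb <- oracle_counts(function(i) at$is_acid_oxygen[i],
                             function(i) at$is_base_nitrogen[i], 3.4)
    expect_equal(as.numeric(sort(unname(unlist(want_sb)))),
                 sort(sb$occupancy))
  }
})

test_that("occupancy is invariant under frame reordering", {
  fix <- make_hbond_fixture(n_frames = 30, occupancy_target = 0.4, seed = 3)
  perm <- rev(seq_len(30))
  shuffled <- frame_ensemble(fix$ensemble$coords[perm],
                             times = fix$ensemble$times)
  o1 <- detect_hbonds(fix$system, fix$ensemble, "chain A", "chain B")
  o2 <- detect_hbonds(fix$system, shuffled, "chain A", "chain B")
  expect_equal(o1$occupancy, o2$occupancy)
})

test_that("Kabsch RMSD: identity, rigid motion, symmetry and oracle", {
  set.seed(14)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(a, a), 0)
  moved <- rigid_transform(a)
  expect_lt(kabsch_rmsd(a, moved), 1e-8)
  jittered <- moved + matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(kabsch_rmsd(a, jittered),
               oracle_quaternion_rmsd(a, jittered), tolerance = 1e-8)
  expect_equal(kabsch_rmsd(a, jittered), kabsch_rmsd(jittered, a),
               tolerance = 1e-10)
  expect_gte(kabsch_rmsd(a, jittered), 0)
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_rmsd(line, line + 1), "degenerate")
  expect_error(kabsch_rmsd(a[1:2, ], a[1:2, ]), "at least 3")
})
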