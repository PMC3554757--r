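#' Specification for a synthetic two-chain complex
#'
#' Describes a desk-scale stand-in for a parameterized receptor-ligand
#' complex: rigid pseudo-atom clusters with residue bookkeeping, opposite
#' partial charges of magnitude `interaction_strength * base_charge` on the
#' interface atoms, and a thermally jittered frame ensemble (i.i.d. Gaussian
#' displacement of sigma `jitter_sigma` per atom per frame standing in for
#' thermal fluctuation).  Generation is a pure function of the spec: the
#' same seed gives bit-identical output.
#'
#' @param n_receptor_atoms,n_ligand_atoms atom counts (>= 1).
#' @param interaction_strength dimensionless scale of the interface charges.
#' @param geometry `"docked"` (clusters in contact) or `"separated"`
#'   (>= 100 Angstrom apart).
#' @param jitter_sigma thermal jitter, Angstrom (>= 0).
#' @param n_frames frames in the ensemble.
#' @param seed RNG seed.
#' @param base_charge interface charge magnitude at strength 1, e.
#' @param n_interface number of charged atom pairs at the interface.
#' @return list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_receptor_atoms = 30, n_ligand_atoms = 10,
                             interaction_strength = 1,
                             geometry = c("docked", "separated"),
                             jitter_sigma = 0.1, n_frames = 20, seed = 1,
                             base_charge = 0.3, n_interface = 4) {
  geometry <- match.arg(geometry)
  stopifnot(n_receptor_atoms >= 1, n_ligand_atoms >= 1,
            jitter_sigma >= 0, n_frames >= 1,
            interaction_strength > 0, base_charge > 0,
            n_interface >= 1)
  structure(list(n_receptor_atoms = as.integer(n_receptor_atoms),
                 n_ligand_atoms = as.integer(n_ligand_atoms),
                 interaction_strength = interaction_strength,
                 geometry = geometry, jitter_sigma = jitter_sigma,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 base_charge = base_charge,
                 n_interface = as.integer(min(n_interface, n_ligand_atoms,
                                              n_receptor_atoms))),
            class = "toy_complex_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Deterministic cluster of points with minimum separation, grown by
# rejection sampling inside a sphere sized to the atom count.
sample_cluster <- function(n, min_sep = 2.2) {
  radius <- max(3, 1.8 * n^(1 / 3) * min_sep / 2)
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 20000L) stop("sample_cluster: could not place atoms")
    p <- runif(3, -radius, radius)
    if (sum(p^2) > radius^2) next
    if (placed > 0L) {
      d2 <- colSums((t(pts[seq_len(placed), , drop = FALSE]) - p)^2)
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- p
  }
  pts
}

#' Generate a synthetic parameterized complex with a frame ensemble
#'
#' Builds the receptor and ligand clusters described by a
#' [toy_complex_spec()], parameterizes every pseudo-atom from the shipped
#' `TOY` entries of the built-in parameter table, places the ligand at
#' contact distance (`docked`) or 150 Angstrom away (`separated`), assigns
#' opposite charges `+/- s * base_charge` to the `n_interface` closest
#' cross-interface atom pairs, and jitters the base coordinates into
#' `n_frames` frames.  Regenerates deterministically (bounded retries) if a
#' placement ever brings two atoms closer than 1.5 Angstrom.
#'
#' @param spec a [toy_complex_spec()].
#' @return list with `system` (parameterized [mm_system()], molecules
#'   `receptor`/`ligand`), `ensemble` ([frame_ensemble()]) and `truth`
#'   (interface atom indices and charge scale).
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  for (attempt in 0:4) {
    out <- with_seed(spec$seed + 100000L * attempt,
                     build_toy_complex(spec))
    if (!is.null(out)) return(out)
  }
  stop("make_toy_complex: atom placement failed after bounded retries")
}

build_toy_complex <- function(spec) {
  nr <- spec$n_receptor_atoms
  nl <- spec$n_ligand_atoms
  rec <- sample_cluster(nr)
  lig <- sample_cluster(nl)
  # place ligand along +x at a contact gap (or far away when separated)
  gap <- if (spec$geometry == "docked") 3.8 else 500
  shift <- max(rec[, 1]) + gap - min(lig[, 1])
  lig[, 1] <- lig[, 1] + shift

  names_cycle <- c("C1", "O1")
  atom_name <- names_cycle[(seq_len(nr + nl) - 1L) %% 2L + 1L]
  atoms <- data.frame(
    serial = seq_len(nr + nl),
    name = atom_name,
    element = substr(atom_name, 1, 1),
    resname = "TOY",
    resid = (seq_len(nr + nl) - 1L) %/% 2L + 1L,
    chain = rep(c("R", "L"), c(nr, nl)),
    stringsAsFactors = FALSE)
  # restart residue numbering on the ligand chain
  atoms$resid[atoms$chain == "L"] <-
    (seq_len(nl) - 1L) %/% 2L + 1L
  # interface pairs: the receptor atoms on the +x face meet dedicated
  # ligand partner atoms placed directly across the contact gap, so each
  # pair forms an explicit salt-bridge-like contact at the gap distance
  n_int <- min(spec$n_interface, nr, nl)
  used_r <- order(rec[, 1], decreasing = TRUE)[seq_len(n_int)]
  used_l <- order(lig[, 1])[seq_len(n_int)]
  if (spec$geometry == "docked")
    lig[used_l, ] <- rec[used_r, , drop = FALSE] +
      matrix(c(gap, 0, 0), n_int, 3, byrow = TRUE)
  base <- rbind(rec, lig)
  if (min(dist(base)) < 1.5) return(NULL)  # caller retries, shifted seed
  # each chain is kept net-neutral: interface atoms carry the attraction
  # (receptor -q, ligand +q) and the atoms farthest from the interface carry
  # the compensating charge.  Charged atoms get distinct names (QM negative,
  # QP positive) so a parameter table from toy_parameter_table() reproduces
  # the charges after a PDB round trip.
  n_int <- length(used_r)
  comp_r <- head(setdiff(order(rec[, 1]), used_r), n_int)
  comp_l <- head(setdiff(order(-lig[, 1]), used_l), n_int)
  atoms$name[used_r] <- "QM"
  atoms$name[comp_r] <- "QP"
  atoms$name[nr + used_l] <- "QP"
  atoms$name[nr + comp_l] <- "QM"
  charged <- c(used_r, comp_r, nr + used_l, nr + comp_l)
  atoms$element[charged] <- "C"
  system <- apply_parameters(mm_system(atoms))
  system$molecules <- list(receptor = seq_len(nr),
                           ligand = nr + seq_len(nl))
  q <- spec$interaction_strength * spec$base_charge
  system$atoms$charge[atoms$name == "QM"] <- -q
  system$atoms$charge[atoms$name == "QP"] <- q

  coords <- lapply(seq_len(spec$n_frames), function(f)
    base + matrix(rnorm(length(base), sd = spec$jitter_sigma),
                  nrow(base), 3))
  ens <- frame_ensemble(coords, times = (seq_len(spec$n_frames) - 1) * 10,
                        run_id = sprintf("seed%d", spec$seed))
  list(system = system, ensemble = ens,
       truth = list(strength = spec$interaction_strength,
                    receptor_interface = sort(used_r),
                    ligand_interface = sort(nr + used_l)))
}

#' Parameter table matching a synthetic complex's interface charges
#'
#' The built-in table extended with `TOY`/`QP` and `TOY`/`QM` entries whose
#' charges are `+/- interaction_strength * base_charge`, so that a complex
#' from [make_toy_complex()] written to PDB and re-parameterized with this
#' table recovers its ground-truth charges.
#'
#' @param interaction_strength charge scale of the complex.
#' @param base_charge interface charge magnitude at strength 1, e.
#' @return A [param_table()].
#' @export
toy_parameter_table <- function(interaction_strength = 1,
                                base_charge = 0.3) {
  tab <- default_parameter_table()
  q <- interaction_strength * base_charge
  tab$entries$charge[tab$entries$resname == "TOY" &
                       tab$entries$atom == "QP"] <- q
  tab$entries$charge[tab$entries$resname == "TOY" &
                       tab$entries$atom == "QM"] <- -q
  tab
}

#' Generate a graded-affinity ligand series with known ground truth
#'
#' Produces complexes that share one geometry and parameterization and
#' differ only in the interface charge scale, the synthetic analogue of a
#' receptor panel of ligands with graded binding strength: descending
#' strength is the ground-truth binding-energy order (stronger charge
#' complementarity gives a more negative binding energy, a property the
#' tests verify rather than assume).
#'
#' @param base a [toy_complex_spec()]; its `interaction_strength` is
#'   replaced by each series value.
#' @param strengths distinct positive charge scales; names become ligand
#'   labels (default `L1`, `L2`, ...).
#' @return named list of `list(system, ensemble, truth)` entries.
#' @export
make_ligand_series <- function(base = toy_complex_spec(),
                               strengths = c(5, 4, 3, 2, 1)) {
  if (any(strengths <= 0)) stop("make_ligand_series: strengths must be > 0")
  if (anyDuplicated(strengths))
    stop("make_ligand_series: strengths must be distinct")
  labels <- names(strengths)
  if (is.null(labels))
    labels <- paste0("L", seq_along(strengths))
  out <- lapply(strengths, function(s) {
    sp <- base
    sp$interaction_strength <- s
    make_toy_complex(sp)
  })
  names(out) <- labels
  out
}

#' Constructed hydrogen-bond occupancy fixture
#'
#' A three-atom donor/hydrogen/acceptor system whose geometry satisfies the
#' default bond criteria in exactly `round(occupancy_target * n_frames)`
#' frames (donor-acceptor 3.0 Angstrom, collinear) and fails them in the
#' rest (4.5 Angstrom).  Which frames are bonded is a seeded random subset.
#'
#' @param n_frames frames in the ensemble.
#' @param occupancy_target fraction of frames in criteria, in `[0, 1]`.
#' @param seed RNG seed.
#' @return list with `system` and `ensemble`; `truth$occupancy` holds the
#'   realized fraction.
#' @export
make_hbond_fixture <- function(n_frames = 60, occupancy_target = 0.5,
                               seed = 1) {
  stopifnot(occupancy_target >= 0, occupancy_target <= 1, n_frames >= 1)
  atoms <- data.frame(
    serial = 1:3,
    name = c("N", "H", "O"),
    element = c("N", "H", "O"),
    resname = c("GLY", "GLY", "GLY"),
    resid = c(1L, 1L, 2L),
    chain = c("A", "A", "B"),
    stringsAsFactors = FALSE)
  system <- apply_parameters(mm_system(atoms))
  k <- round(occupancy_target * n_frames)
  bonded <- with_seed(seed, sort(sample.int(n_frames, k)))
  in_geom <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.0, 0, 0))
  out_geom <- rbind(c(0, 0, 0), c(1, 0, 0), c(4.5, 0, 0))
  coords <- lapply(seq_len(n_frames), function(f)
    if (f %in% bonded) in_geom else out_geom)
  list(system = system,
       ensemble = frame_ensemble(coords,
                                 times = (seq_len(n_frames) - 1) * 10),
       truth = list(occupancy = k / n_frames, bonded_frames = bonded))
}
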