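#' Detect hydrogen bonds across an interface over an ensemble
#'
#' Per frame, a hydrogen bond exists between a donor heavy atom of one
#' selection and an acceptor of the other when the donor-heavy-to-acceptor
#' distance is at most `dist_cutoff` and (explicit-hydrogen mode) the
#' D-H...A deviation from linearity is at most `angle_cutoff` degrees.  In
#' heavy-atom mode (no hydrogens in the system, or `mode = "heavy"`) the
#' distance criterion alone applies and the output flags the mode.  A unique
#' bond is a (donor atom, acceptor atom) pair; records with occupancy (the
#' fraction of frames in which the bond is present) at or above
#' `min_occupancy` are returned.
#'
#' Hydrogens are associated with their donor heavy atom by proximity
#' (< 1.25 Angstrom in the first frame, same residue).
#'
#' @param system an [mm_system()] with donor/acceptor flags (see
#'   [apply_parameters()]).
#' @param ensemble a [frame_ensemble()].
#' @param sel_a,sel_b the two sides of the interface (selection strings or
#'   index vectors); only cross-selection bonds are reported.
#' @param dist_cutoff donor-heavy to acceptor distance cutoff, Angstrom.
#' @param angle_cutoff maximum D-H...A deviation from linearity, degrees.
#' @param min_occupancy occupancy (lifetime) filter, fraction of frames.
#' @param mode `"auto"` (explicit-H when hydrogens exist), `"explicit"`,
#'   or `"heavy"`.
#' @return data.frame of class `interaction_table`: one row per unique bond
#'   with partner identities, `occupancy`, `n_frames`, `present_frames`
#'   (comma-separated frame indices) and `geometry_mode`.
#' @export
detect_hbonds <- function(system, ensemble, sel_a, sel_b,
                          dist_cutoff = 3.2, angle_cutoff = 30,
                          min_occupancy = 0.10,
                          mode = c("auto", "explicit", "heavy")) {
  mode <- match.arg(mode)
  if (!"is_donor_heavy" %in% names(system$atoms))
    stop("detect_hbonds: donor/acceptor flags not assigned; run apply_parameters()")
  a_idx <- resolve_selection(system, sel_a)
  b_idx <- resolve_selection(system, sel_b)
  hydrogens <- which(system$atoms$element == "H")
  if (mode == "auto") mode <- if (length(hydrogens)) "explicit" else "heavy"
  if (mode == "explicit" && !length(hydrogens))
    stop("detect_hbonds: explicit-H mode requested but system has no hydrogens")

  h_of <- NULL
  if (mode == "explicit") {
    xyz1 <- ensemble$coords[[1]]
    donors_all <- which(system$atoms$is_donor_heavy)
    h_of <- lapply(seq_len(n_atoms(system)), function(i) integer())
    for (d in donors_all) {
      dd <- sqrt(colSums((t(xyz1[hydrogens, , drop = FALSE]) -
                            xyz1[d, ])^2))
      same_res <- system$atoms$residue_index[hydrogens] ==
        system$atoms$residue_index[d]
      h_of[[d]] <- hydrogens[dd < 1.25 & same_res]
    }
  }

  pairs <- rbind(
    hbond_candidates(system, a_idx, b_idx),
    hbond_candidates(system, b_idx, a_idx)
  )
  nf <- n_frames(ensemble)
  if (!nrow(pairs)) return(empty_interaction_table("hbond", mode))
  present <- matrix(FALSE, nrow(pairs), nf)
  for (f in seq_len(nf)) {
    xyz <- ensemble$coords[[f]]
    dv <- xyz[pairs$donor, , drop = FALSE] - xyz[pairs$acceptor, , drop = FALSE]
    dist_ok <- sqrt(rowSums(dv^2)) <= dist_cutoff
    if (mode == "heavy") {
      present[, f] <- dist_ok
    } else {
      for (p in which(dist_ok)) {
        hs <- h_of[[pairs$donor[p]]]
        if (!length(hs)) next
        dev <- vapply(hs, function(h)
          hbond_deviation(xyz[pairs$donor[p], ], xyz[h, ],
                          xyz[pairs$acceptor[p], ]), 0)
        present[p, f] <- any(dev <= angle_cutoff)
      }
    }
  }
  build_interaction_table(system, pairs$donor, pairs$acceptor,
                          present, "hbond", min_occupancy, mode,
                          roles = c("donor", "acceptor"))
}

hbond_candidates <- function(system, from, to) {
  d <- from[system$atoms$is_donor_heavy[from]]
  a <- to[system$atoms$is_acceptor[to]]
  if (!length(d) || !length(a))
    return(data.frame(donor = integer(), acceptor = integer()))
  expand.grid(donor = d, acceptor = a, KEEP.OUT.ATTRS = FALSE)
}

# deviation from linearity of D-H...A in degrees (0 = perfectly linear)
hbond_deviation <- function(d, h, a) {
  v1 <- d - h
  v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect salt bridges across an interface over an ensemble
#'
#' Per frame, a salt bridge exists between an acidic residue of one side and
#' a basic residue of the other when any acid side-chain oxygen is within
#' `cutoff` of any base side-chain nitrogen.  Records are per residue pair
#' with occupancy over the ensemble.
#'
#' @inheritParams detect_hbonds
#' @param cutoff oxygen-nitrogen distance cutoff, Angstrom.
#' @param min_occupancy occupancy filter (default 0: report all).
#' @return data.frame of class `interaction_table`, one row per residue
#'   pair; the reported atoms are the pair's closest oxygen/nitrogen in the
#'   first frame in which the bridge is present.
#' @export
detect_salt_bridges <- function(system, ensemble, sel_a, sel_b,
                                cutoff = 3.4, min_occupancy = 0) {
  if (!"is_acid_oxygen" %in% names(system$atoms))
    stop("detect_salt_bridges: acid/base flags not assigned; run apply_parameters()")
  a_idx <- resolve_selection(system, sel_a)
  b_idx <- resolve_selection(system, sel_b)
  pairs <- rbind(
    saltbridge_candidates(system, a_idx, b_idx),
    saltbridge_candidates(system, b_idx, a_idx)
  )
  nf <- n_frames(ensemble)
  if (!nrow(pairs)) return(empty_interaction_table("saltbridge", "heavy"))
  # group atom pairs by residue pair
  rkey <- paste(system$atoms$residue_index[pairs$acid],
                system$atoms$residue_index[pairs$base])
  groups <- split(seq_len(nrow(pairs)), rkey)
  present <- matrix(FALSE, length(groups), nf)
  rep_atoms <- matrix(NA_integer_, length(groups), 2)
  for (f in seq_len(nf)) {
    xyz <- ensemble$coords[[f]]
    dv <- xyz[pairs$acid, , drop = FALSE] - xyz[pairs$base, , drop = FALSE]
    dd <- sqrt(rowSums(dv^2))
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      hit <- dd[rows] <= cutoff
      present[g, f] <- any(hit)
      if (any(hit) && is.na(rep_atoms[g, 1])) {
        best <- rows[which.min(dd[rows])]
        rep_atoms[g, ] <- c(pairs$acid[best], pairs$base[best])
      }
    }
  }
  # residue pairs never in contact keep their closest first-frame atoms
  for (g in which(is.na(rep_atoms[, 1]))) {
    rows <- groups[[g]]
    xyz <- ensemble$coords[[1]]
    dd <- sqrt(rowSums((xyz[pairs$acid[rows], , drop = FALSE] -
                          xyz[pairs$base[rows], , drop = FALSE])^2))
    best <- rows[which.min(dd)]
    rep_atoms[g, ] <- c(pairs$acid[best], pairs$base[best])
  }
  build_interaction_table(system, rep_atoms[, 1], rep_atoms[, 2],
                          present, "saltbridge", min_occupancy, "heavy",
                          roles = c("acid", "base"))
}

saltbridge_candidates <- function(system, from, to) {
  o <- from[system$atoms$is_acid_oxygen[from]]
  n <- to[system$atoms$is_base_nitrogen[to]]
  if (!length(o) || !length(n))
    return(data.frame(acid = integer(), base = integer()))
  expand.grid(acid = o, base = n, KEEP.OUT.ATTRS = FALSE)
}

build_interaction_table <- function(system, part1, part2, present, kind,
                                    min_occupancy, mode, roles) {
  occ <- rowMeans(present)
  keep <- which(occ >= min_occupancy & occ > 0)
  at <- system$atoms
  col <- function(idx, role) {
    out <- data.frame(chain = at$chain[idx], resid = at$resid[idx],
                      resname = at$resname[idx], name = at$name[idx],
                      stringsAsFactors = FALSE)
    names(out) <- paste(role, names(out), sep = "_")
    out
  }
  out <- cbind(
    data.frame(kind = rep(kind, length(keep)), stringsAsFactors = FALSE),
    col(part1[keep], roles[1]), col(part2[keep], roles[2]),
    data.frame(
      occupancy = occ[keep],
      n_frames = rep(ncol(present), length(keep)),
      present_frames = vapply(keep, function(i)
        paste(which(present[i, ]), collapse = ","), ""),
      geometry_mode = rep(mode, length(keep)),
      stringsAsFactors = FALSE))
  out <- out[order(-out$occupancy,
                   out[[paste0(roles[1], "_resid")]],
                   out[[paste0(roles[2], "_resid")]]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

empty_interaction_table <- function(kind, mode) {
  roles <- if (kind == "hbond") c("donor", "acceptor") else c("acid", "base")
  cols <- c("kind",
            paste(roles[1], c("chain", "resid", "resname", "name"),
                  sep = "_"),
            paste(roles[2], c("chain", "resid", "resname", "name"),
                  sep = "_"),
            "occupancy", "n_frames", "present_frames", "geometry_mode")
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                       stringsAsFactors = FALSE)
  out$occupancy <- numeric(0)
  out$n_frames <- integer(0)
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Root-mean-square deviation after optimal rigid superposition, via the
#' standard SVD construction with a proper-rotation (det = +1) correction.
#'
#' @param coords_a,coords_b n-by-3 coordinate matrices, Angstrom.
#' @param pairing optional two-column index matrix (rows of `coords_a`
#'   matched to rows of `coords_b`); by default rows pair positionally.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b, pairing = NULL) {
  a <- unname(as.matrix(coords_a))
  b <- unname(as.matrix(coords_b))
  if (!is.null(pairing)) {
    pairing <- as.matrix(pairing)
    a <- a[pairing[, 1], , drop = FALSE]
    b <- b[pairing[, 2], , drop = FALSE]
  }
  if (nrow(a) != nrow(b)) stop("kabsch_rmsd: unequal pair counts")
  if (nrow(a) < 3) stop("kabsch_rmsd: need at least 3 paired atoms")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(bc, ac))
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("kabsch_rmsd: degenerate (collinear) coordinates")
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  diffs <- ac %*% t(rot) - bc
  sqrt(sum(diffs^2) / nrow(a))
}
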