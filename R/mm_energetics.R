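#' Intermolecular Coulomb energy between two atom groups
#'
#' Exact pairwise (no cutoff) electrostatic interaction energy
#' \eqn{E = k_e \sum_{i \in A, j \in B} q_i q_j / r_{ij}} with the
#' conversion constant \eqn{k_e} taken from the solvent model
#' (332.0636 kcal*A/(mol*e^2)).  Symmetric in group order.
#'
#' @param coords n-by-3 coordinate matrix, Angstrom.
#' @param charges per-atom partial charges, e.
#' @param group_a,group_b disjoint integer atom-index vectors.
#' @param model a [solvent_model()] (supplies `coulomb_constant`).
#' @param per_atom also return the per-atom half-split attribution vector.
#' @return list with `e_ele` (kcal/mol) and, if requested, `per_atom_ele`
#'   (length n; each pair's energy split half-and-half between partners).
#' @export
coulomb_energy <- function(coords, charges, group_a, group_b,
                           model = solvent_model(), per_atom = FALSE) {
  pw <- pair_setup(coords, charges, group_a, group_b)
  e_mat <- model$coulomb_constant *
    outer(charges[group_a], charges[group_b]) / pw$r
  res <- list(e_ele = sum(e_mat))
  if (per_atom) {
    v <- numeric(nrow(coords))
    v[group_a] <- v[group_a] + rowSums(e_mat) / 2
    v[group_b] <- v[group_b] + colSums(e_mat) / 2
    res$per_atom_ele <- v
  }
  res
}

#' Intermolecular Lennard-Jones energy between two atom groups
#'
#' 12-6 potential \eqn{E = \sum \epsilon_{ij}[(r_{min,ij}/r)^{12} -
#' 2(r_{min,ij}/r)^6]} with Lorentz-Berthelot combining on
#' \eqn{(r_{min}/2, \epsilon)}: \eqn{r_{min,ij}} is the sum of the two
#' `rmin_half` values and \eqn{\epsilon_{ij}} their geometric mean.
#' No cutoff.
#'
#' @param coords n-by-3 coordinate matrix, Angstrom.
#' @param lj_params data.frame/list with per-atom `rmin_half` (A) and
#'   `epsilon` (kcal/mol).
#' @inheritParams coulomb_energy
#' @return list with `e_vdw` and optionally `per_atom_vdw`.
#' @export
lj_energy <- function(coords, lj_params, group_a, group_b,
                      per_atom = FALSE) {
  pw <- pair_setup(coords, lj_params$rmin_half, group_a, group_b)
  rmin <- outer(lj_params$rmin_half[group_a], lj_params$rmin_half[group_b], "+")
  epsm <- sqrt(outer(lj_params$epsilon[group_a], lj_params$epsilon[group_b]))
  s6 <- (rmin / pw$r)^6
  e_mat <- epsm * (s6^2 - 2 * s6)
  res <- list(e_vdw = sum(e_mat))
  if (per_atom) {
    v <- numeric(nrow(coords))
    v[group_a] <- v[group_a] + rowSums(e_mat) / 2
    v[group_b] <- v[group_b] + colSums(e_mat) / 2
    res$per_atom_vdw <- v
  }
  res
}

pair_setup <- function(coords, values, group_a, group_b) {
  coords <- unname(as.matrix(coords))
  group_a <- as.integer(group_a)
  group_b <- as.integer(group_b)
  if (length(intersect(group_a, group_b)))
    stop("atom groups overlap; interaction groups must be disjoint")
  if (!length(group_a) || !length(group_b))
    stop("both atom groups must be non-empty")
  a <- coords[group_a, , drop = FALSE]
  b <- coords[group_b, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (any(r < 1e-6)) {
    w <- which(r < 1e-6, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "singular pair: atoms %d and %d are closer than 1e-6 A",
      group_a[w[1]], group_b[w[2]]))
  }
  list(r = r)
}

#' Intermolecular interaction energy (Coulomb + Lennard-Jones)
#'
#' The gas-phase molecular-mechanics part of the single-trajectory binding
#' energy: because complex, receptor and ligand are evaluated on identical
#' frames, all intramolecular (bonded and intra-group nonbonded) terms cancel
#' in the complex-minus-parts difference, leaving exactly the intermolecular
#' cross terms computed here.
#'
#' @param system a parameterized [mm_system()].
#' @param coords one coordinate frame (n-by-3, Angstrom).
#' @param receptor,ligand selection strings or index vectors (disjoint).
#' @param model a [solvent_model()].
#' @return Object of class `pair_energy` with `e_ele`, `e_vdw` (kcal/mol)
#'   and per-atom half-split vectors `per_atom_ele`, `per_atom_vdw`.
#' @export
interaction_energy <- function(system, coords, receptor, ligand,
                               model = solvent_model()) {
  if (!is_parameterized(system))
    stop("interaction_energy: system is not parameterized")
  coords <- check_frame(system, coords)
  ga <- resolve_selection(system, receptor)
  gb <- resolve_selection(system, ligand)
  ce <- coulomb_energy(coords, system$atoms$charge, ga, gb,
                       model = model, per_atom = TRUE)
  le <- lj_energy(coords, system$atoms, ga, gb, per_atom = TRUE)
  structure(list(e_ele = ce$e_ele, e_vdw = le$e_vdw,
                 per_atom_ele = ce$per_atom_ele,
                 per_atom_vdw = le$per_atom_vdw),
            class = "pair_energy")
}

#' @export
print.pair_energy <- function(x, ...) {
  cat(sprintf("pair_energy: E_ele = %.4f, E_vdw = %.4f kcal/mol\n",
              x$e_ele, x$e_vdw))
  invisible(x)
}
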