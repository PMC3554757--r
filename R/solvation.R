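#' Effective Born radii by pairwise descreening
#'
#' Hawkins-Cramer-Truhlar (HCT) pairwise-descreening effective radii:
#' \deqn{1/\alpha_i = 1/\tilde\rho_i - \sum_{j \ne i} H(r_{ij},
#' \tilde\rho_i, s_j \tilde\rho_j)} where \eqn{\tilde\rho = \rho - 0.09} A
#' is the offset-corrected intrinsic radius, \eqn{s_j} the descreening scale
#' factor, and \eqn{H} the closed-form Coulomb-field integral of atom j's
#' scaled sphere over the region outside \eqn{\tilde\rho_i}.  An isolated
#' atom's effective radius equals its offset-corrected intrinsic radius.
#'
#' @param system a parameterized [mm_system()].
#' @param coords one coordinate frame (n-by-3, Angstrom).
#' @param offset intrinsic-radius offset, Angstrom.
#' @return Numeric vector of effective Born radii (class `born_radii`),
#'   Angstrom.
#' @export
effective_born_radii <- function(system, coords, offset = GB_RADIUS_OFFSET) {
  if (!is_parameterized(system))
    stop("effective_born_radii: system is not parameterized")
  coords <- check_frame(system, coords)
  rho <- system$atoms$born_radius - offset
  if (any(rho <= 0))
    stop("effective_born_radii: intrinsic radius <= offset for some atom")
  scaled <- system$atoms$screen * rho
  n <- nrow(coords)
  if (n == 1L) {
    alpha <- rho
  } else {
    d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
      2 * tcrossprod(coords)
    d2[d2 < 0] <- 0
    r <- sqrt(d2)
    diag(r) <- Inf                       # self pairs contribute nothing
    S <- matrix(scaled, n, n, byrow = TRUE)   # scaled radius of atom j
    RHO <- matrix(rho, n, n)                  # descreened atom i
    U <- r + S
    L <- pmax(RHO, abs(r - S))
    H <- 0.5 * (1 / L - 1 / U +
                  0.25 * (r - S^2 / r) * (1 / U^2 - 1 / L^2) +
                  0.5 * log(L / U) / r)
    engulfed <- RHO < (S - r)            # atom i fully inside scaled sphere j
    H[engulfed] <- H[engulfed] + 2 * (1 / RHO[engulfed] - 1 / L[engulfed])
    H[RHO >= U] <- 0                     # scaled sphere j inside rho_i
    H[!is.finite(H)] <- 0                # r = Inf diagonal
    inv_alpha <- 1 / rho - rowSums(H)
    # deeply buried atoms can drive 1/alpha through zero; clamp (alpha <= 50 A)
    inv_alpha <- pmax(inv_alpha, 1 / 50)
    alpha <- 1 / inv_alpha
  }
  structure(alpha, class = "born_radii", offset = offset)
}

#' Generalized Born polar solvation energy
#'
#' \deqn{\Delta G_{pol} = -\frac{k_e}{2} \sum_{i,j} \left(\frac{1}
#' {\epsilon_{in}} - \frac{e^{-\kappa f_{GB}}}{\epsilon_w}\right)
#' \frac{q_i q_j}{f_{GB}}, \quad
#' f_{GB} = \sqrt{r_{ij}^2 + \alpha_i \alpha_j
#' e^{-r_{ij}^2 / 4 \alpha_i \alpha_j}}}
#' The double sum includes the self terms (\eqn{f_{GB} = \alpha_i} at
#' \eqn{r = 0}); Debye-Hueckel salt screening enters through the
#' \eqn{e^{-\kappa f_{GB}}} factor.
#'
#' @param coords n-by-3 coordinate matrix, Angstrom.
#' @param charges per-atom partial charges, e.
#' @param radii effective Born radii from [effective_born_radii()].
#' @param model a [solvent_model()].
#' @param per_atom also return the per-atom attribution (self term plus half
#'   of every pair term; sums exactly to the total).
#' @return list with `g_pol` (kcal/mol) and optionally `per_atom_pol`.
#' @export
gb_polar_energy <- function(coords, charges, radii, model = solvent_model(),
                            per_atom = FALSE) {
  coords <- unname(as.matrix(coords))
  n <- nrow(coords)
  alpha <- as.numeric(radii)
  if (length(alpha) != n || length(charges) != n)
    stop("gb_polar_energy: radii/charges do not match the coordinate frame")
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
    2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  aa <- outer(alpha, alpha)
  fgb <- sqrt(d2 + aa * exp(-d2 / (4 * aa)))  # diagonal reduces to alpha_i
  pref <- -(model$coulomb_constant / 2) *
    (1 / model$eps_solute - exp(-model$kappa * fgb) / model$eps_solvent)
  e_mat <- pref * outer(charges, charges) / fgb
  res <- list(g_pol = sum(e_mat))
  if (per_atom) res$per_atom_pol <- rowSums(e_mat)
  res
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point SASA with a fixed, deterministic Fibonacci-lattice point set
#' (default 960 points per atom).  Atom radii default to the Lennard-Jones
#' `rmin_half` column; each atom's accessible sphere has radius
#' `radius + probe`.
#'
#' @param system a parameterized [mm_system()] (for default radii).
#' @param coords one coordinate frame (n-by-3, Angstrom).
#' @param probe_radius solvent probe radius, Angstrom.
#' @param n_points sphere points per atom.
#' @param radii optional explicit per-atom radii, Angstrom.
#' @return list (class `sasa_result`) with `per_atom_area` and `total`,
#'   Angstrom^2.
#' @export
sasa <- function(system, coords, probe_radius = 1.4, n_points = 960,
                 radii = NULL) {
  coords <- check_frame(system, coords)
  if (is.null(radii)) {
    if (!"rmin_half" %in% names(system$atoms) ||
        anyNA(system$atoms$rmin_half))
      stop("sasa: no radii available; parameterize the system or pass radii")
    radii <- system$atoms$rmin_half
  }
  n <- nrow(coords)
  if (length(radii) != n) stop("sasa: radii length mismatch")
  expanded <- radii + probe_radius
  pts <- fibonacci_sphere(n_points)
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
    2 * tcrossprod(coords)
  area <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (expanded[i] + expanded)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * expanded[i]^2
      next
    }
    p <- sweep(pts * expanded[i], 2, coords[i, ], "+")
    rel2 <- outer(rowSums(p^2), rowSums(coords[nb, , drop = FALSE]^2), "+") -
      2 * tcrossprod(p, coords[nb, , drop = FALSE])
    exposed <- rowSums(rel2 < rep(expanded[nb]^2, each = n_points)) == 0
    area[i] <- 4 * pi * expanded[i]^2 * sum(exposed) / n_points
  }
  structure(list(per_atom_area = area, total = sum(area)),
            class = "sasa_result")
}

# Deterministic unit-sphere point set (Fibonacci / golden-angle lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  theta <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Nonpolar solvation energy from surface area
#'
#' \eqn{\Delta G_{np} = \gamma \cdot SASA + \beta} with the surface tension
#' \eqn{\gamma} (default 0.0072 kcal/(mol*A^2)) and offset \eqn{\beta}
#' taken from the solvent model.
#'
#' @param sasa_total total solvent-accessible surface area, Angstrom^2, or a
#'   `sasa_result`.
#' @param model a [solvent_model()].
#' @return kcal/mol.
#' @export
nonpolar_energy <- function(sasa_total, model = solvent_model()) {
  if (inherits(sasa_total, "sasa_result")) sasa_total <- sasa_total$total
  model$gamma * sasa_total + model$beta_offset
}
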