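#' Build a finite-difference PB grid specification
#'
#' Defines the uniform cubic grid used by [pb_polar_energy()]: the grid
#' encloses every atom sphere plus `padding` on all sides.  Atom spheres use
#' the intrinsic Born radii as dielectric radii.
#'
#' @param system a parameterized [mm_system()].
#' @param coords one coordinate frame (n-by-3, Angstrom).
#' @param spacing grid spacing h, Angstrom.
#' @param padding margin beyond the solute extent, Angstrom.
#' @return list (class `pb_grid`) with `origin`, `spacing`, `dims`.
#' @export
pb_grid <- function(system, coords, spacing = 0.5, padding = 6) {
  if (spacing <= 0) stop("pb_grid: spacing must be > 0")
  coords <- check_frame(system, coords)
  radii <- system$atoms$born_radius
  lo <- apply(coords - radii, 2, min) - padding
  hi <- apply(coords + radii, 2, max) + padding
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  if (any(dims < 8L))
    stop("pb_grid: grid too small; increase padding or reduce spacing")
  structure(list(origin = lo, spacing = spacing, dims = dims),
            class = "pb_grid")
}

#' Polar solvation energy by finite-difference linearized Poisson-Boltzmann
#'
#' Solves the linearized PB equation on a uniform grid by successive
#' over-relaxation.  The dielectric is assigned on grid faces by the
#' atom-sphere interior (solute dielectric) versus exterior (solvent
#' dielectric); the Debye-Hueckel \eqn{\kappa^2} term acts on nodes outside
#' the solute (no Stern layer).  Charges are spread trilinearly; boundary
#' potentials use the analytic Debye-Hueckel superposition.  The polar
#' solvation energy is the charging-energy difference between the solvated
#' solve and a uniform solute-dielectric reference solve on the same grid,
#' which cancels the grid self-energy.
#'
#' Intended for small systems (at most ~2000 atoms); the single-trajectory
#' analysis calls it once per frame and species.
#'
#' @param system a parameterized [mm_system()].
#' @param coords one coordinate frame (n-by-3, Angstrom).
#' @param model a [solvent_model()].
#' @param grid optional [pb_grid()]; built from `spacing`/`padding` if absent.
#' @param spacing,padding grid construction parameters, Angstrom.
#' @param tol SOR convergence tolerance on the max potential update,
#'   kcal/(mol e).
#' @param max_iter maximum SOR sweeps.
#' @param omega over-relaxation factor in (1, 2).
#' @return Polar solvation energy, kcal/mol, with attributes `iterations`.
#' @export
pb_polar_energy <- function(system, coords, model = solvent_model(),
                            grid = NULL, spacing = 0.5, padding = 6,
                            tol = 1e-5, max_iter = 20000, omega = 1.9) {
  if (!is_parameterized(system))
    stop("pb_polar_energy: system is not parameterized")
  coords <- check_frame(system, coords)
  if (n_atoms(system) > 2000)
    stop("pb_polar_energy: finite-difference solver limited to 2000 atoms, got ",
         n_atoms(system))
  if (is.null(grid)) grid <- pb_grid(system, coords, spacing, padding)
  h <- grid$spacing
  dims <- grid$dims
  ax <- grid$origin[1] + (seq_len(dims[1]) - 1) * h
  ay <- grid$origin[2] + (seq_len(dims[2]) - 1) * h
  az <- grid$origin[3] + (seq_len(dims[3]) - 1) * h
  charges <- system$atoms$charge
  radii <- system$atoms$born_radius
  ke <- model$coulomb_constant

  if (all(charges == 0)) return(structure(0, iterations = 0L))

  inside_mask <- function(gx, gy, gz) {
    # TRUE where the point is inside any atom sphere
    m <- array(FALSE, dim = c(length(gx), length(gy), length(gz)))
    for (a in seq_len(nrow(coords))) {
      r <- radii[a]
      ix <- which(abs(gx - coords[a, 1]) <= r)
      iy <- which(abs(gy - coords[a, 2]) <= r)
      iz <- which(abs(gz - coords[a, 3]) <= r)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (gx[ix] - coords[a, 1])^2
      dy2 <- (gy[iy] - coords[a, 2])^2
      dz2 <- (gz[iz] - coords[a, 3])^2
      sub <- outer(outer(dx2, dy2, "+"), dz2, "+") < r^2
      m[ix, iy, iz] <- m[ix, iy, iz] | sub
    }
    m
  }

  eps_face <- function(axis) {
    if (axis == 1) ins <- inside_mask(ax[-1] - h / 2, ay, az)
    if (axis == 2) ins <- inside_mask(ax, ay[-1] - h / 2, az)
    if (axis == 3) ins <- inside_mask(ax, ay, az[-1] - h / 2)
    ifelse(ins, model$eps_solute, model$eps_solvent)
  }

  # face arrays padded back to node shape (face idx = node idx toward +axis)
  pad_face <- function(e, axis) {
    full <- array(0, dim = dims)
    if (axis == 1) full[-dims[1], , ] <- e
    if (axis == 2) full[, -dims[2], ] <- e
    if (axis == 3) full[, , -dims[3]] <- e
    full
  }
  epsx <- pad_face(eps_face(1), 1)
  epsy <- pad_face(eps_face(2), 2)
  epsz <- pad_face(eps_face(3), 3)

  node_inside <- inside_mask(ax, ay, az)
  lambda <- array(0, dim = dims)
  if (model$kappa > 0)
    lambda[!node_inside] <- model$eps_solvent * model$kappa^2 * h^2

  # trilinear charge spreading; src = 4*pi*ke*q/h per node
  qgrid <- array(0, dim = dims)
  for (a in seq_len(nrow(coords))) {
    if (charges[a] == 0) next
    fx <- (coords[a, 1] - grid$origin[1]) / h
    fy <- (coords[a, 2] - grid$origin[2]) / h
    fz <- (coords[a, 3] - grid$origin[3]) / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    if (i0 < 0 || j0 < 0 || k0 < 0 ||
        i0 + 2 > dims[1] || j0 + 2 > dims[2] || k0 + 2 > dims[3])
      stop("pb_polar_energy: charge outside grid; increase padding")
    wx <- c(1 - (fx - i0), fx - i0)
    wy <- c(1 - (fy - j0), fy - j0)
    wz <- c(1 - (fz - k0), fz - k0)
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
      qgrid[i0 + di + 1, j0 + dj + 1, k0 + dk + 1] <-
        qgrid[i0 + di + 1, j0 + dj + 1, k0 + dk + 1] +
        charges[a] * wx[di + 1] * wy[dj + 1] * wz[dk + 1]
  }
  src <- 4 * pi * ke * qgrid / h

  # analytic boundary potentials on the outer node layer
  boundary_phi <- function(eps_bc, kappa_bc) {
    phi <- array(0, dim = dims)
    bidx <- which(slice.index(phi, 1) %in% c(1L, dims[1]) |
                    slice.index(phi, 2) %in% c(1L, dims[2]) |
                    slice.index(phi, 3) %in% c(1L, dims[3]))
    sub <- arrayInd(bidx, dims)
    pts <- cbind(ax[sub[, 1]], ay[sub[, 2]], az[sub[, 3]])
    val <- numeric(length(bidx))
    for (a in seq_len(nrow(coords))) {
      if (charges[a] == 0) next
      d <- sqrt(rowSums(sweep(pts, 2, coords[a, ])^2))
      val <- val + ke * charges[a] * exp(-kappa_bc * d) / (eps_bc * d)
    }
    phi[bidx] <- val
    phi
  }

  solve_grid <- function(epsx, epsy, epsz, lambda, phi0) {
    out <- pb_sor(as.numeric(phi0), as.numeric(epsx), as.numeric(epsy),
                  as.numeric(epsz), as.numeric(lambda), as.numeric(src),
                  dims, omega, tol, as.integer(max_iter))
    if (!out$converged)
      stop(sprintf(
        "pb_polar_energy: SOR did not converge in %d sweeps (residual %.3e)",
        max_iter, out$residual))
    structure(array(out$phi, dim = dims), iterations = out$iterations)
  }

  phi_solv <- solve_grid(epsx, epsy, epsz, lambda,
                         boundary_phi(model$eps_solvent, model$kappa))
  e_solv <- 0.5 * sum(qgrid * phi_solv)

  eps_ref <- array(model$eps_solute, dim = dims)
  phi_ref <- solve_grid(eps_ref, eps_ref, eps_ref, array(0, dim = dims),
                        boundary_phi(model$eps_solute, 0))
  e_ref <- 0.5 * sum(qgrid * phi_ref)

  structure(e_solv - e_ref,
            iterations = c(solvated = attr(phi_solv, "iterations"),
                           reference = attr(phi_ref, "iterations")))
}
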