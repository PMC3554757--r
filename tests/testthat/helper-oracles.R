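# Independent brute-force oracles and fixture builders used across the suite.

# nested-loop Coulomb cross-group sum
oracle_coulomb <- function(coords, charges, ga, gb, k = 332.0636) {
  e <- 0
  for (i in ga) for (j in gb)
    e <- e + k * charges[i] * charges[j] /
      sqrt(sum((coords[i, ] - coords[j, ])^2))
  e
}

# nested-loop Lennard-Jones cross-group sum (Lorentz-Berthelot)
oracle_lj <- function(coords, rmin_half, epsilon, ga, gb) {
  e <- 0
  for (i in ga) for (j in gb) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    rm <- rmin_half[i] + rmin_half[j]
    ep <- sqrt(epsilon[i] * epsilon[j])
    e <- e + ep * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  e
}

# nested-loop GB double sum including self terms
oracle_gb <- function(coords, charges, alpha, eps_in = 1, eps_w = 80,
                      kappa = 0, k = 332.0636) {
  n <- nrow(coords)
  e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((coords[i, ] - coords[j, ])^2)
    aa <- alpha[i] * alpha[j]
    f <- sqrt(r2 + aa * exp(-r2 / (4 * aa)))
    e <- e - (k / 2) * (1 / eps_in - exp(-kappa * f) / eps_w) *
      charges[i] * charges[j] / f
  }
  e
}

# full-loop complex-minus-parts MM difference (validates the intermolecular
# cancellation of the single-trajectory scheme)
oracle_mm_cycle <- function(coords, charges, rmin_half, epsilon, ga, gb) {
  all_pairs <- function(idx) {
    e_ele <- 0; e_vdw <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      e_ele <- e_ele + 332.0636 * charges[i] * charges[j] / r
      rm <- rmin_half[i] + rmin_half[j]
      ep <- sqrt(epsilon[i] * epsilon[j])
      e_vdw <- e_vdw + ep * ((rm / r)^12 - 2 * (rm / r)^6)
    }
    c(e_ele, e_vdw)
  }
  all_pairs(c(ga, gb)) - all_pairs(ga) - all_pairs(gb)
}

# Monte-Carlo evaluation of the pairwise descreening integral of a scaled
# sphere (radius s_r, center distance r) over the region outside rho_i:
# (1/4pi) * integral of |x|^-4 over the sphere, excluding |x| < rho_i.
oracle_hct_integral <- function(r, rho_i, s_r, n_mc = 4e5) {
  u <- matrix(runif(3 * n_mc, -1, 1), ncol = 3)
  u <- u[rowSums(u^2) <= 1, , drop = FALSE]
  pts <- u * s_r
  pts[, 1] <- pts[, 1] + r
  d2 <- rowSums(pts^2)
  vals <- ifelse(d2 >= rho_i^2, 1 / d2^2, 0)
  vol <- 4 / 3 * pi * s_r^3
  vol * mean(vals) / (4 * pi)
}

# quaternion (Horn) optimal-superposition RMSD, independent of the SVD path
oracle_quaternion_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  m <- crossprod(a, b)
  k <- matrix(0, 4, 4)
  k[1, 1] <- m[1, 1] + m[2, 2] + m[3, 3]
  k[1, 2] <- k[2, 1] <- m[2, 3] - m[3, 2]
  k[1, 3] <- k[3, 1] <- m[3, 1] - m[1, 3]
  k[1, 4] <- k[4, 1] <- m[1, 2] - m[2, 1]
  k[2, 2] <- m[1, 1] - m[2, 2] - m[3, 3]
  k[2, 3] <- k[3, 2] <- m[1, 2] + m[2, 1]
  k[2, 4] <- k[4, 2] <- m[1, 3] + m[3, 1]
  k[3, 3] <- -m[1, 1] + m[2, 2] - m[3, 3]
  k[3, 4] <- k[4, 3] <- m[2, 3] + m[3, 2]
  k[4, 4] <- -m[1, 1] - m[2, 2] + m[3, 3]
  lam <- max(eigen(k, symmetric = TRUE)$values)
  sqrt(max(0, (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)))
}

# random parameterized system with safely separated atoms
random_system <- function(n, box = 8, min_sep = 1.2, charged = TRUE) {
  coords <- matrix(NA_real_, n, 3)
  placed <- 0
  while (placed < n) {
    p <- runif(3, 0, box)
    if (placed > 0 &&
        min(colSums((t(coords[seq_len(placed), , drop = FALSE]) - p)^2)) <
          min_sep^2) next
    placed <- placed + 1
    coords[placed, ] <- p
  }
  atoms <- data.frame(
    serial = seq_len(n),
    name = sample(c("C1", "O1"), n, replace = TRUE),
    element = "C", resname = "TOY",
    resid = (seq_len(n) - 1) %/% 2 + 1,
    chain = rep(c("A", "B"), times = c(ceiling(n / 2), floor(n / 2))),
    charge = if (charged) round(runif(n, -0.8, 0.8), 3) else numeric(n),
    rmin_half = round(runif(n, 1.2, 2.0), 3),
    epsilon = round(runif(n, 0.05, 0.3), 4),
    born_radius = round(runif(n, 1.3, 2.2), 3),
    screen = round(runif(n, 0.7, 0.95), 3),
    stringsAsFactors = FALSE)
  atoms$element <- substr(atoms$name, 1, 1)
  list(system = mm_system(atoms), coords = coords)
}

# random rigid transform of a coordinate set
rigid_transform <- function(coords, angles = runif(3, 0, 2 * pi),
                            shift = runif(3, -20, 20)) {
  rx <- function(t) rbind(c(1, 0, 0), c(0, cos(t), -sin(t)),
                          c(0, sin(t), cos(t)))
  ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                          c(-sin(t), 0, cos(t)))
  rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                          c(0, 0, 1))
  rot <- rx(angles[1]) %*% ry(angles[2]) %*% rz(angles[3])
  sweep(coords %*% t(rot), 2, shift, "+")
}

# two-ligand pipeline fixture: multi-model PDBs plus per-ligand parameter
# tables that carry the scaled interface charges
write_pipeline_fixture <- function(dir, n_ligands = 2, n_frames = 4) {
  strengths <- setNames(c(4, 1), c("strong", "weak"))[seq_len(n_ligands)]
  series <- make_ligand_series(
    toy_complex_spec(seed = 31, n_frames = n_frames), strengths)
  paths <- tables <- character()
  for (label in names(series)) {
    p <- file.path(dir, paste0(label, ".pdb"))
    write_pdb(series[[label]]$system, series[[label]]$ensemble, p)
    paths[label] <- p
    tp <- file.path(dir, paste0(label, "_params.tsv"))
    write_parameter_table(toy_parameter_table(strengths[[label]]), tp)
    tables[label] <- tp
  }
  list(series = series, paths = paths, tables = tables)
}

# tiny PDB text fixture written on the fly
write_toy_pdb <- function(path, n_models = 2, drop_atom_in_model = NULL) {
  base <- data.frame(
    serial = 1:5,
    name = c("N", "CA", "C", "O", "CB"),
    resname = c("ALA", "ALA", "ALA", "ALA", "ALA"),
    chain = "A", resid = 1,
    x = c(0, 1.4, 2.1, 3.2, 1.9), y = c(0, 0.3, 1.5, 1.6, -1.1),
    z = c(0, 0, 0.2, 0.4, 0.6))
  con <- file(path, "w")
  for (m in seq_len(n_models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    rows <- seq_len(nrow(base))
    if (!is.null(drop_atom_in_model) && m == drop_atom_in_model)
      rows <- rows[-3]
    writeLines(sprintf(
      "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      base$serial[rows], base$name[rows], base$resname[rows],
      base$chain[rows], base$resid[rows],
      base$x[rows] + 0.01 * m, base$y[rows], base$z[rows],
      substr(base$name[rows], 1, 1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  path
}
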