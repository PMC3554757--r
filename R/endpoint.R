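#' Extract an analysis window from a frame ensemble
#'
#' Keeps the frames whose times fall in the closed interval
#' `[start, end]`, sampled at `stride` ps measured from `start` (each stride
#' target keeps the nearest in-window frame; ties go to the earlier frame).
#'
#' @param ensemble a [frame_ensemble()].
#' @param start,end window bounds, ps (closed interval).
#' @param stride sampling interval, ps.
#' @return A [frame_ensemble()] restricted to the window, with attribute
#'   `n_selected`.
#' @export
frame_window <- function(ensemble, start, end, stride) {
  stopifnot(end >= start, stride > 0)
  times <- ensemble$times
  eligible <- which(times >= start & times <= end)
  if (!length(eligible))
    stop(sprintf(
      "frame_window: no frames in [%g, %g] ps (ensemble spans %g..%g)",
      start, end, times[1], times[length(times)]))
  targets <- seq(start, end, by = stride)
  pick <- vapply(targets, function(tt) {
    d <- abs(times[eligible] - tt)
    eligible[which.min(d)]
  }, integer(1))
  pick <- sort(unique(pick))
  out <- frame_ensemble(ensemble$coords[pick], times[pick],
                        run_id = ensemble$run_id)
  attr(out, "n_selected") <- length(pick)
  out
}

new_energy_breakdown <- function(frames, method, run_id, window = NULL,
                                 std_error = NULL, n_runs = 1L) {
  agg_mean <- colMeans(frames[, c("e_ele", "e_vdw", "g_pol", "g_np",
                                  "total"), drop = FALSE])
  se_frames <- apply(frames[, c("e_ele", "e_vdw", "g_pol", "g_np",
                                "total"), drop = FALSE], 2,
                     function(v) if (length(v) > 1)
                       sd(v) / sqrt(length(v)) else NA_real_)
  structure(list(frames = frames,
                 aggregate = data.frame(
                   component = names(agg_mean),
                   mean = as.numeric(agg_mean),
                   std_error = if (is.null(std_error))
                     rep(NA_real_, 5) else as.numeric(std_error),
                   se_frames = as.numeric(se_frames),
                   stringsAsFactors = FALSE),
                 method = method, window = window, run_id = run_id,
                 n_runs = n_runs, entropy = "omitted"),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy_breakdown (MM-%sSA, %d frame(s), %d run(s))\n",
              x$method, nrow(x$frames), x$n_runs))
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-6s %10.2f  (SE %s, frame SE %s) kcal/mol\n",
                a$component[i], a$mean[i],
                ifelse(is.na(a$std_error[i]), "n/a",
                       sprintf("%.2f", a$std_error[i])),
                ifelse(is.na(a$se_frames[i]), "n/a",
                       sprintf("%.2f", a$se_frames[i]))))
  cat("  entropy: omitted (relative binding energies only)\n")
  invisible(x)
}

breakdown_mean <- function(x, component = "total") {
  a <- x$aggregate
  a$mean[match(component, a$component)]
}

#' Single-trajectory end-point binding energy over a frame ensemble
#'
#' For every frame, computes the binding-energy components of the
#' thermodynamic cycle \eqn{\Delta G = G_{complex} - G_{receptor} -
#' G_{ligand}} in the single-trajectory scheme (receptor and ligand use the
#' complex frame coordinates, so intramolecular mechanics cancels):
#' intermolecular Coulomb and Lennard-Jones terms, the polar solvation
#' difference by GB (each species with its own effective Born radii on the
#' same frame) or finite-difference PB, and the nonpolar surface-area
#' difference.  Entropy is not computed; results are relative binding
#' energies.
#'
#' @param system a parameterized [mm_system()].
#' @param ensemble a [frame_ensemble()] over the system atoms.
#' @param receptor,ligand disjoint selections (strings or index vectors)
#'   that jointly cover the analysis atoms.
#' @param model a [solvent_model()].
#' @param polar_method `"GB"` (default) or `"PB"`.
#' @param sasa_points sphere points per atom for the nonpolar term.
#' @param pb_spacing,pb_padding PB grid parameters (PB method only).
#' @return An `energy_breakdown`: per-frame components plus aggregate means;
#'   the per-frame standard error is reported as a diagnostic
#'   (`se_frames`), replicate-level `std_error` is filled by
#'   [aggregate_runs()].
#' @export
binding_energy <- function(system, ensemble, receptor, ligand,
                           model = solvent_model(),
                           polar_method = c("GB", "PB"),
                           sasa_points = 960,
                           pb_spacing = 0.5, pb_padding = 6) {
  polar_method <- match.arg(polar_method)
  rsel <- resolve_selection(system, receptor)
  lsel <- resolve_selection(system, ligand)
  if (length(intersect(rsel, lsel)))
    stop("binding_energy: receptor and ligand selections overlap")
  if (!is_parameterized(system))
    stop("binding_energy: system is not parameterized")
  if (polar_method == "PB" && n_atoms(system) > 2000)
    stop("binding_energy: PB limited to 2000 atoms, got ", n_atoms(system))
  keep <- sort(c(rsel, lsel))
  sub <- set_molecules(system, rsel, lsel)
  rec <- sub$molecules$receptor
  lig <- sub$molecules$ligand
  sys_r <- subset_system(sub, rec)
  sys_l <- subset_system(sub, lig)

  nf <- n_frames(ensemble)
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- check_frame(system, ensemble$coords[[f]])[keep, , drop = FALSE]
    mm <- interaction_energy(sub, xyz, rec, lig, model = model)
    if (polar_method == "GB") {
      g_c <- gb_polar_energy(xyz, sub$atoms$charge,
                             effective_born_radii(sub, xyz), model)$g_pol
      g_r <- gb_polar_energy(xyz[rec, , drop = FALSE], sys_r$atoms$charge,
                             effective_born_radii(sys_r,
                                                  xyz[rec, , drop = FALSE]),
                             model)$g_pol
      g_l <- gb_polar_energy(xyz[lig, , drop = FALSE], sys_l$atoms$charge,
                             effective_born_radii(sys_l,
                                                  xyz[lig, , drop = FALSE]),
                             model)$g_pol
    } else {
      g_c <- as.numeric(pb_polar_energy(sub, xyz, model,
                                        spacing = pb_spacing,
                                        padding = pb_padding))
      g_r <- as.numeric(pb_polar_energy(sys_r, xyz[rec, , drop = FALSE],
                                        model, spacing = pb_spacing,
                                        padding = pb_padding))
      g_l <- as.numeric(pb_polar_energy(sys_l, xyz[lig, , drop = FALSE],
                                        model, spacing = pb_spacing,
                                        padding = pb_padding))
    }
    g_pol <- g_c - g_r - g_l
    s_c <- sasa(sub, xyz, model$probe_radius, sasa_points)$total
    s_r <- sasa(sys_r, xyz[rec, , drop = FALSE], model$probe_radius,
                sasa_points)$total
    s_l <- sasa(sys_l, xyz[lig, , drop = FALSE], model$probe_radius,
                sasa_points)$total
    g_np <- nonpolar_energy(s_c, model) - nonpolar_energy(s_r, model) -
      nonpolar_energy(s_l, model)
    rows[[f]] <- data.frame(time = ensemble$times[f],
                            e_ele = mm$e_ele, e_vdw = mm$e_vdw,
                            g_pol = g_pol, g_np = g_np,
                            total = mm$e_ele + mm$e_vdw + g_pol + g_np)
  }
  frames <- do.call(rbind, rows)
  new_energy_breakdown(frames, polar_method, ensemble$run_id,
                       window = range(ensemble$times))
}

#' Aggregate replicate binding-energy runs
#'
#' Component means are means of the per-run means; the standard error is the
#' standard error over the per-run means (n = number of runs), matching the
#' replicate-level uncertainty convention.  With a single run the standard
#' error is reported as not available (`NA`).
#'
#' @param breakdowns list of `energy_breakdown` objects (one per replicate).
#' @return An `energy_breakdown` whose `frames` table is the concatenation of
#'   the runs and whose aggregate carries replicate-level standard errors.
#' @export
aggregate_runs <- function(breakdowns) {
  if (inherits(breakdowns, "energy_breakdown")) breakdowns <- list(breakdowns)
  if (!length(breakdowns)) stop("aggregate_runs: need at least one run")
  methods <- unique(vapply(breakdowns, `[[`, "", "method"))
  if (length(methods) != 1L)
    stop("aggregate_runs: runs mix polar methods: ",
         paste(methods, collapse = ", "))
  windows <- unique(vapply(breakdowns, function(b)
    paste(signif(b$window, 10), collapse = ","), ""))
  if (length(windows) != 1L)
    stop("aggregate_runs: runs use different frame windows")
  comp <- c("e_ele", "e_vdw", "g_pol", "g_np", "total")
  run_means <- t(vapply(breakdowns, function(b)
    vapply(comp, function(cc) breakdown_mean(b, cc), 0), numeric(5)))
  means <- colMeans(run_means)
  nrun <- length(breakdowns)
  se <- if (nrun > 1) apply(run_means, 2, sd) / sqrt(nrun)
        else rep(NA_real_, 5)
  frames <- do.call(rbind, lapply(breakdowns, function(b) {
    f <- b$frames
    f$run_id <- b$run_id
    f
  }))
  out <- new_energy_breakdown(frames[comp], methods, run_id = "aggregate",
                              window = breakdowns[[1]]$window,
                              std_error = se, n_runs = nrun)
  # aggregate mean must be the mean of per-run means, not of pooled frames
  out$aggregate$mean <- as.numeric(means)
  out$frames <- frames
  out
}

#' Rank ligands by mean binding energy
#'
#' Orders ligands by ascending mean total binding energy (most negative =
#' rank 1, strongest binder).  Pairs whose energy gap is smaller than the
#' combined standard error \eqn{\sqrt{SE_a^2 + SE_b^2}} are flagged as
#' statistically unresolved; replicate-level standard errors are used when
#' available, otherwise the per-frame diagnostic standard error.
#'
#' @param results named list of `energy_breakdown` objects (>= 2 ligands,
#'   same polar method).
#' @return data.frame of class `ligand_ranking` with columns `ligand`,
#'   `dg_mean`, `dg_se`, `rank`, `tied`; attribute `unresolved` lists the
#'   flagged pairs.
#' @export
rank_ligands <- function(results) {
  if (length(results) < 2L)
    stop("rank_ligands: need at least two ligands")
  if (is.null(names(results)) || any(names(results) == ""))
    stop("rank_ligands: results must be a named list")
  methods <- unique(vapply(results, `[[`, "", "method"))
  if (length(methods) != 1L)
    stop("rank_ligands: mixed polar methods: ",
         paste(methods, collapse = ", "))
  dg <- vapply(results, breakdown_mean, 0)
  se <- vapply(results, function(b) {
    a <- b$aggregate
    s <- a$std_error[a$component == "total"]
    if (is.na(s)) a$se_frames[a$component == "total"] else s
  }, 0)
  ord <- order(dg, names(results))   # ties broken by label
  out <- data.frame(ligand = names(results)[ord],
                    dg_mean = as.numeric(dg[ord]),
                    dg_se = as.numeric(se[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  out$tied <- duplicated(out$dg_mean) | duplicated(out$dg_mean,
                                                   fromLast = TRUE)
  unresolved <- list()
  for (i in seq_len(nrow(out) - 1)) for (j in (i + 1):nrow(out)) {
    gap <- abs(out$dg_mean[j] - out$dg_mean[i])
    comb <- sqrt(sum(out$dg_se[c(i, j)]^2, na.rm = TRUE))
    if (is.finite(comb) && gap < comb)
      unresolved[[length(unresolved) + 1L]] <-
        data.frame(ligand_a = out$ligand[i], ligand_b = out$ligand[j],
                   gap = gap, combined_se = comb, stringsAsFactors = FALSE)
  }
  attr(out, "unresolved") <- if (length(unresolved))
    do.call(rbind, unresolved) else
      data.frame(ligand_a = character(), ligand_b = character(),
                 gap = numeric(), combined_se = numeric())
  attr(out, "method") <- methods
  class(out) <- c("ligand_ranking", "data.frame")
  out
}

#' @export
print.ligand_ranking <- function(x, ...) {
  cat(sprintf("ligand_ranking (MM-%sSA), ascending binding energy:\n",
              attr(x, "method")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  un <- attr(x, "unresolved")
  if (nrow(un))
    cat(sprintf("  %d pair(s) statistically unresolved (gap < combined SE)\n",
                nrow(un)))
  invisible(x)
}
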