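CONFIG_KEYS <- c("structures", "parameters", "receptor", "ligand",
                 "method", "window", "solvent", "output_dir", "seed",
                 "hbond", "saltbridge", "sasa_points", "pb")

#' Validate a pipeline configuration file
#'
#' Reads a YAML or JSON configuration and checks it completely, reporting
#' every problem at once rather than stopping at the first.  A valid file
#' yields a `run_config` with documented defaults filled in (method GB,
#' solvent-model defaults including 0.1 M ionic strength and gamma 0.0072
#' kcal/(mol*A^2), hydrogen-bond cutoffs 3.2 Angstrom / 30 degrees with
#' a 0.10 occupancy filter, salt-bridge cutoff 3.4 Angstrom, seed 1).
#'
#' Recognized keys: `structures` (list of `label` + `pdb`, or `pdb` plus
#' optional `replicates`), `parameters` (table path; built-in table when
#' absent), `receptor`/`ligand` (selection strings), `method` (GB|PB),
#' `window` (`start`/`end`/`stride`, ps), `solvent` (overrides for
#' [solvent_model()]), `hbond`/`saltbridge` (cutoff overrides),
#' `sasa_points`, `pb` (`spacing`/`padding`), `output_dir`, `seed`.
#'
#' @param path configuration file path.
#' @return A `run_config` list, or an object of class `config_errors`
#'   (character vector of messages) when validation fails.
#' @export
validate_config <- function(path) {
  if (!file.exists(path))
    return(structure("config file not found", class = "config_errors"))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  errors <- character()
  bad_keys <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(bad_keys))
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(bad_keys, collapse = ", ")))
  for (req in c("structures", "receptor", "ligand"))
    if (is.null(cfg[[req]]))
      errors <- c(errors, paste0("missing required key: ", req))
  if (!is.null(cfg$structures)) {
    if (!is.list(cfg$structures) || !length(cfg$structures))
      errors <- c(errors, "structures must be a non-empty list")
    else for (i in seq_along(cfg$structures)) {
      s <- cfg$structures[[i]]
      if (is.null(s$pdb))
        errors <- c(errors, sprintf("structures[%d]: missing 'pdb'", i))
      else if (!file.exists(s$pdb))
        errors <- c(errors, sprintf("structures[%d]: no such file: %s",
                                    i, s$pdb))
      reps <- s$replicates
      if (!is.null(reps))
        for (r in unlist(reps))
          if (!file.exists(r))
            errors <- c(errors, sprintf(
              "structures[%d]: replicate file not found: %s", i, r))
      if (!is.null(s$parameters) && !file.exists(s$parameters))
        errors <- c(errors, sprintf(
          "structures[%d]: parameter table not found: %s", i, s$parameters))
    }
  }
  if (!is.null(cfg$parameters) && !file.exists(cfg$parameters))
    errors <- c(errors, paste0("parameter table not found: ",
                               cfg$parameters))
  method <- toupper(cfg$method %||% "GB")
  if (!method %in% c("GB", "PB"))
    errors <- c(errors, "method must be GB or PB")
  if (!is.null(cfg$window)) {
    w <- cfg$window
    if (is.null(w$start) || is.null(w$end) || is.null(w$stride))
      errors <- c(errors, "window needs start, end and stride (ps)")
    else {
      if (w$end < w$start)
        errors <- c(errors, "window: end must be >= start")
      if (w$stride <= 0)
        errors <- c(errors, "window: stride must be > 0")
    }
  }
  solvent <- cfg$solvent %||% list()
  bad_solv <- setdiff(names(solvent), names(formals(solvent_model)))
  if (length(bad_solv))
    errors <- c(errors, paste0("unknown solvent key(s): ",
                               paste(bad_solv, collapse = ", ")))
  if (length(errors))
    return(structure(errors, class = "config_errors"))
  structure(list(
    structures = lapply(seq_along(cfg$structures), function(i) {
      s <- cfg$structures[[i]]
      list(label = s$label %||% sprintf("complex%d", i),
           pdb = s$pdb, replicates = unlist(s$replicates),
           parameters = s$parameters)
    }),
    parameters = cfg$parameters,
    receptor = cfg$receptor, ligand = cfg$ligand,
    method = method,
    window = cfg$window,
    solvent = solvent,
    hbond = modifyList(list(dist_cutoff = 3.2, angle_cutoff = 30,
                            min_occupancy = 0.10), cfg$hbond %||% list()),
    saltbridge = modifyList(list(cutoff = 3.4),
                            cfg$saltbridge %||% list()),
    sasa_points = cfg$sasa_points %||% 960,
    pb = modifyList(list(spacing = 0.5, padding = 6), cfg$pb %||% list()),
    output_dir = cfg$output_dir %||% "results",
    seed = cfg$seed %||% 1L
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.config_errors <- function(x, ...) {
  cat("configuration errors:\n")
  for (e in x) cat("  - ", e, "\n", sep = "")
  invisible(x)
}

#' Run the full end-point analysis pipeline
#'
#' For every configured complex: read the structure(s), parameterize,
#' apply the frame window, compute the binding energy per replicate,
#' aggregate replicates, decompose per residue, and detect hydrogen bonds
#' and salt bridges; with more than one complex, rank the ligands.  All
#' tables are written under the output directory (TSV + JSON) together with
#' a provenance record (package version, configuration, frame counts).
#' Deterministic: identical configuration and inputs give byte-identical
#' outputs.
#'
#' @param config a `run_config` from [validate_config()], or a path to a
#'   configuration file.
#' @return Invisible list with the computed objects (`breakdowns`,
#'   `decompositions`, `hbonds`, `salt_bridges`, `ranking`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  if (inherits(config, "config_errors"))
    stop("run_pipeline: invalid configuration:\n  - ",
         paste(config, collapse = "\n  - "))
  stopifnot(inherits(config, "run_config"))
  table <- if (is.null(config$parameters)) default_parameter_table()
           else read_parameter_table(config$parameters)
  model <- do.call(solvent_model, config$solvent)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  results <- list()
  provenance <- list(package = "mmgbsa",
                     version = as.character(packageVersion("mmgbsa")),
                     config = unclass(config), complexes = list())
  for (entry in config$structures) {
    label <- entry$label
    # a structure-level table (e.g. per-ligand interface charges) wins
    entry_table <- if (is.null(entry$parameters)) table
                   else read_parameter_table(entry$parameters)
    paths <- c(entry$pdb, entry$replicates)
    runs <- list()
    frame_counts <- integer()
    for (ri in seq_along(paths)) {
      stage <- sprintf("complex '%s', replicate %d", label, ri)
      parsed <- tryCatch(read_pdb(paths[ri], run_id = sprintf("run%d", ri)),
                         error = function(e)
                           stop("pipeline stage [read] ", stage, ": ",
                                conditionMessage(e), call. = FALSE))
      system <- tryCatch(apply_parameters(parsed$system, entry_table),
                         error = function(e)
                           stop("pipeline stage [parameterize] ", stage,
                                ": ", conditionMessage(e), call. = FALSE))
      if (config$method == "PB" && n_atoms(system) > 2000)
        stop("pipeline stage [guard] ", stage, ": PB method limited to ",
             "2000 atoms, got ", n_atoms(system), call. = FALSE)
      ens <- parsed$ensemble
      if (!is.null(config$window))
        ens <- frame_window(ens, config$window$start, config$window$end,
                            config$window$stride)
      frame_counts <- c(frame_counts, n_frames(ens))
      runs[[ri]] <- binding_energy(system, ens, config$receptor,
                                   config$ligand, model,
                                   polar_method = config$method,
                                   sasa_points = config$sasa_points,
                                   pb_spacing = config$pb$spacing,
                                   pb_padding = config$pb$padding)
      if (ri == 1L) {
        first_system <- system
        first_ens <- ens
      }
    }
    agg <- aggregate_runs(runs)
    decomp <- decompose_binding(first_system, first_ens, config$receptor,
                                config$ligand, model,
                                polar_method = config$method,
                                sasa_points = config$sasa_points,
                                pb_spacing = config$pb$spacing,
                                pb_padding = config$pb$padding)
    hb <- detect_hbonds(first_system, first_ens, config$receptor,
                        config$ligand,
                        dist_cutoff = config$hbond$dist_cutoff,
                        angle_cutoff = config$hbond$angle_cutoff,
                        min_occupancy = config$hbond$min_occupancy)
    sb <- detect_salt_bridges(first_system, first_ens, config$receptor,
                              config$ligand,
                              cutoff = config$saltbridge$cutoff)
    outdir <- file.path(config$output_dir, label)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_report(agg, file.path(outdir, "binding_energy.tsv"), "tsv")
    write_report(agg, file.path(outdir, "binding_energy.json"), "json")
    write_report(decomp, file.path(outdir, "decomposition.tsv"), "tsv")
    write_report(hb, file.path(outdir, "hbonds.tsv"), "tsv")
    write_report(sb, file.path(outdir, "salt_bridges.tsv"), "tsv")
    results[[label]] <- list(breakdown = agg, decomposition = decomp,
                             hbonds = hb, salt_bridges = sb)
    provenance$complexes[[label]] <-
      list(files = paths, replicates = length(paths),
           frames = frame_counts, atoms = n_atoms(first_system))
  }

  ranking <- NULL
  if (length(results) >= 2L) {
    ranking <- rank_ligands(lapply(results, `[[`, "breakdown"))
    write_report(ranking, file.path(config$output_dir, "ranking.tsv"),
                 "tsv")
    write_report(ranking, file.path(config$output_dir, "ranking.json"),
                 "json")
  }
  jsonlite::write_json(provenance,
                       file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(breakdowns = lapply(results, `[[`, "breakdown"),
                 decompositions = lapply(results, `[[`, "decomposition"),
                 hbonds = lapply(results, `[[`, "hbonds"),
                 salt_bridges = lapply(results, `[[`, "salt_bridges"),
                 ranking = ranking))
}
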