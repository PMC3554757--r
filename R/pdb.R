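#' Read a (multi-model) PDB file
#'
#' Parses `ATOM`/`HETATM` records of a PDB v3.3 file into an [mm_system()]
#' plus a [frame_ensemble()].  `MODEL`/`ENDMDL` blocks become frames, so a
#' multi-model PDB serves as a portable text trajectory; a file without
#' `MODEL` records yields a single frame.  Every model must contain the same
#' atoms in the same order.
#'
#' Frame times default to 1 ps spacing starting at 0; rescale with
#' [frame_ensemble()] if the models represent another stride.
#'
#' @param path PDB file path.
#' @param run_id replicate label stored on the ensemble.
#' @return list with elements `system` (unparameterized [mm_system()]) and
#'   `ensemble` ([frame_ensemble()]).
#' @export
read_pdb <- function(path, run_id = "run1") {
  if (!file.exists(path)) stop("read_pdb: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_end <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) stop("read_pdb: no ATOM/HETATM records in ", path)

  # assign a model id to every atom line
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_id[is_end] <- 0L
  atom_lines <- which(is_atom)
  atom_model <- model_id[atom_lines]
  if (any(is_model) && any(atom_model == 0L))
    stop("read_pdb: ATOM record outside MODEL/ENDMDL block at line ",
         atom_lines[which(atom_model == 0L)[1]])

  parse_num <- function(txt, what, lns) {
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.finite(out))
    if (length(bad))
      stop(sprintf("read_pdb: malformed %s field at line %d: '%s'",
                   what, lns[bad[1]], trimws(txt[bad[1]])))
    out
  }

  txt <- lines[atom_lines]
  serial <- as.integer(parse_num(substr(txt, 7, 11), "serial", atom_lines))
  name <- trimws(substr(txt, 13, 16))
  resname <- trimws(substr(txt, 18, 20))
  chain <- substr(txt, 22, 22)
  resid <- as.integer(parse_num(substr(txt, 23, 26), "residue id", atom_lines))
  x <- parse_num(substr(txt, 31, 38), "x coordinate", atom_lines)
  y <- parse_num(substr(txt, 39, 46), "y coordinate", atom_lines)
  z <- parse_num(substr(txt, 47, 54), "z coordinate", atom_lines)
  element <- trimws(substr(txt, 77, 78))
  guess <- toupper(substr(gsub("[^A-Za-z]", "", name), 1, 1))
  element <- ifelse(element == "", guess, element)

  models <- sort(unique(atom_model))
  per_model <- split(seq_along(atom_lines), atom_model)
  ref <- per_model[[1]]
  nref <- length(ref)
  ident <- function(i) paste(name[i], resname[i], chain[i], resid[i])
  ref_ident <- ident(ref)
  coords <- vector("list", length(models))
  for (m in seq_along(models)) {
    i <- per_model[[m]]
    if (length(i) != nref)
      stop(sprintf(
        "read_pdb: MODEL %d has %d atoms but MODEL %d has %d",
        models[m], length(i), models[1], nref))
    if (!identical(ident(i), ref_ident))
      stop(sprintf("read_pdb: MODEL %d atom records differ from MODEL %d",
                   models[m], models[1]))
    coords[[m]] <- cbind(x[i], y[i], z[i])
  }

  atoms <- data.frame(serial = serial[ref], name = name[ref],
                      element = element[ref], resname = resname[ref],
                      resid = resid[ref], chain = chain[ref],
                      stringsAsFactors = FALSE)
  list(system = mm_system(atoms),
       ensemble = frame_ensemble(coords, run_id = run_id))
}

#' Write a system + ensemble as a multi-model PDB file
#'
#' Inverse of [read_pdb()]: coordinates round-trip to the 1e-3 Angstrom
#' precision of the PDB fixed-width format.
#'
#' @param system an [mm_system()].
#' @param ensemble a [frame_ensemble()] over the same atoms (or a single
#'   coordinate matrix).
#' @param path output file.
#' @export
write_pdb <- function(system, ensemble, path) {
  if (is.matrix(ensemble)) ensemble <- frame_ensemble(ensemble)
  a <- system$atoms
  fmt_name <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                     sprintf(" %-3s", a$name))
  multi <- n_frames(ensemble) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- check_frame(system, ensemble$coords[[f]])
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$serial %% 100000L, fmt_name, substr(a$resname, 1, 3), a$chain,
      a$resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
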