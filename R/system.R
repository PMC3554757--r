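#' Molecular system container
#'
#' An `mm_system` holds the atom table (identity, bookkeeping and, once
#' [apply_parameters()] has run, per-atom energetic parameters) together with
#' an optional molecule partition (named groups of atom indices, e.g.
#' `receptor` / `ligand`) and a derived residue table.  Coordinates live in a
#' separate [frame_ensemble()] so one system can be evaluated on many frames.
#' Atom indices are 1-based throughout.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, and optionally the parameter columns
#'   `charge`, `rmin_half`, `epsilon`, `born_radius`, `screen` plus the
#'   chemistry flags `is_donor_heavy`, `is_acceptor`, `is_acid_oxygen`,
#'   `is_base_nitrogen`.
#' @param molecules named list of integer atom-index vectors.  When
#'   non-empty it must partition the atoms (cover every atom exactly once).
#' @return An object of class `mm_system`.
#' @export
mm_system <- function(atoms, molecules = list()) {
  required <- c("serial", "name", "element", "resname", "resid", "chain")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("mm_system: atom table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("mm_system: atom serial numbers must be unique")
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  n <- nrow(atoms)
  if (length(molecules)) {
    idx <- sort(unlist(molecules, use.names = FALSE))
    if (length(idx) != n || any(idx != seq_len(n)))
      stop("mm_system: molecule groups must partition the atoms exactly once")
  }
  # residue bookkeeping: consecutive runs of (chain, resid, resname)
  key <- paste(atoms$chain, atoms$resid, atoms$resname, sep = "|")
  runs <- rle(key)
  res_index <- rep(seq_along(runs$lengths), runs$lengths)
  atoms$residue_index <- res_index
  first <- which(!duplicated(res_index))
  residues <- data.frame(
    residue_index = res_index[first],
    chain = atoms$chain[first],
    resid = atoms$resid[first],
    resname = atoms$resname[first],
    first_atom = first,
    last_atom = c(first[-1] - 1L, n),
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, molecules = molecules, residues = residues),
            class = "mm_system")
}

#' @export
print.mm_system <- function(x, ...) {
  cat(sprintf("mm_system: %d atoms, %d residues, %d chain(s)%s\n",
              n_atoms(x), nrow(x$residues),
              length(unique(x$atoms$chain)),
              if (is_parameterized(x)) ", parameterized" else ""))
  if (length(x$molecules))
    cat("  molecules:",
        paste(sprintf("%s (%d)", names(x$molecules),
                      lengths(x$molecules)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a system
#' @param system an `mm_system`.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Does every atom carry energetic parameters?
#' @param system an `mm_system`.
#' @export
is_parameterized <- function(system) {
  cols <- c("charge", "rmin_half", "epsilon", "born_radius", "screen")
  all(cols %in% names(system$atoms)) &&
    !anyNA(system$atoms[cols])
}

#' Extract a sub-system by atom indices
#'
#' Keeps atom order; residue bookkeeping is rebuilt.  Molecule groups are
#' dropped (a sub-system is a single molecule for energetic purposes).
#'
#' @param system an `mm_system`.
#' @param indices integer atom indices (1-based).
#' @export
subset_system <- function(system, indices) {
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > n_atoms(system)))
    stop("subset_system: atom index out of range")
  mm_system(system$atoms[indices, , drop = FALSE])
}

#' Attach a receptor/ligand partition to a system
#'
#' @param system an `mm_system`.
#' @param receptor,ligand selection strings (see [select_atoms()]) or
#'   integer index vectors.  Must be disjoint.
#' @export
set_molecules <- function(system, receptor, ligand) {
  r <- resolve_selection(system, receptor)
  l <- resolve_selection(system, ligand)
  if (length(intersect(r, l)))
    stop("set_molecules: receptor and ligand selections overlap")
  keep <- sort(c(r, l))
  sub <- subset_system(system, keep)
  map <- match(seq_len(n_atoms(system)), keep)
  sub$molecules <- list(receptor = sort(map[r]), ligand = sort(map[l]))
  sub
}

resolve_selection <- function(system, sel) {
  if (is.character(sel) && length(sel) == 1L) return(select_atoms(system, sel))
  sel <- as.integer(sel)
  if (any(sel < 1L | sel > n_atoms(system)))
    stop("selection index out of range")
  sort(unique(sel))
}

#' Frame ensemble (ordered coordinate frames)
#'
#' @param coords list of numeric n-by-3 matrices (Angstrom), one per frame,
#'   or a single matrix for a one-frame ensemble.
#' @param times frame times in ps, strictly increasing.
#' @param run_id replicate label.
#' @return An object of class `frame_ensemble`.
#' @export
frame_ensemble <- function(coords, times = NULL, run_id = "run1") {
  if (is.matrix(coords)) coords <- list(coords)
  if (!length(coords)) stop("frame_ensemble: need at least one frame")
  nn <- vapply(coords, nrow, integer(1))
  if (length(unique(nn)) != 1L)
    stop("frame_ensemble: all frames must have the same atom count")
  coords <- lapply(coords, function(m) {
    m <- unname(as.matrix(m))
    if (ncol(m) != 3 || !all(is.finite(m)))
      stop("frame_ensemble: frames must be finite n-by-3 matrices")
    m
  })
  if (is.null(times)) times <- as.numeric(seq_along(coords) - 1L)
  if (length(times) != length(coords))
    stop("frame_ensemble: times length must match frame count")
  if (any(diff(times) <= 0))
    stop("frame_ensemble: times must be strictly increasing")
  structure(list(coords = coords, times = as.numeric(times), run_id = run_id),
            class = "frame_ensemble")
}

#' Number of frames in an ensemble
#' @param ensemble a `frame_ensemble`.
#' @export
n_frames <- function(ensemble) length(ensemble$coords)

#' @export
print.frame_ensemble <- function(x, ...) {
  cat(sprintf("frame_ensemble '%s': %d frame(s) x %d atoms, t = %g..%g ps\n",
              x$run_id, n_frames(x), nrow(x$coords[[1]]),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

check_frame <- function(system, coords) {
  coords <- unname(as.matrix(coords))
  if (nrow(coords) != n_atoms(system) || ncol(coords) != 3)
    stop("coordinate frame does not match system atom count")
  coords
}
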