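#' Per-atom parameter tables
#'
#' A `param_table` maps `(residue_name, atom_name)` keys to the per-atom
#' energetic parameters used throughout the package: partial charge (e),
#' Lennard-Jones `rmin/2` (Angstrom) and well depth epsilon (kcal/mol),
#' intrinsic Born radius (Angstrom) and the dimensionless pairwise
#' descreening scale factor.  Rows whose `residue_name` is `"*"` are
#' element-keyed defaults (matched on `atom_name` = element symbol) used for
#' atoms without a specific entry.
#'
#' @param entries data.frame with columns `resname`, `atom`, `charge`,
#'   `rmin_half`, `epsilon`, `born_radius`, `screen`.
#' @param defaults data.frame with columns `element`, `charge`, `rmin_half`,
#'   `epsilon`, `born_radius`, `screen` (may have zero rows).
#' @return An object of class `param_table`.
#' @export
param_table <- function(entries, defaults = NULL) {
  cols <- c("charge", "rmin_half", "epsilon", "born_radius", "screen")
  stopifnot(all(c("resname", "atom", cols) %in% names(entries)))
  if (is.null(defaults))
    defaults <- data.frame(element = character(), charge = numeric(),
                           rmin_half = numeric(), epsilon = numeric(),
                           born_radius = numeric(), screen = numeric(),
                           stringsAsFactors = FALSE)
  bad <- entries$born_radius <= 0 | entries$epsilon < 0
  if (any(bad))
    stop("param_table: born_radius must be > 0 and epsilon >= 0 (bad key: ",
         entries$resname[which(bad)[1]], "/", entries$atom[which(bad)[1]], ")")
  structure(list(entries = entries, defaults = defaults),
            class = "param_table")
}

#' @export
print.param_table <- function(x, ...) {
  cat(sprintf("param_table: %d keyed entries, %d element defaults\n",
              nrow(x$entries), nrow(x$defaults)))
  invisible(x)
}

TSV_COLS <- c(residue_name = "resname", atom_name = "atom",
              charge_e = "charge", rmin_half_A = "rmin_half",
              epsilon_kcal = "epsilon", born_radius_A = "born_radius",
              screen = "screen")

#' Read a parameter table from TSV or JSON
#'
#' TSV columns: `residue_name`, `atom_name`, `charge_e`, `rmin_half_A`,
#' `epsilon_kcal`, `born_radius_A`, `screen`; lines starting with `#` are
#' comments; `residue_name = "*"` rows are element defaults.  JSON files hold
#' the same records under keys `entries` and `defaults`.
#'
#' @param path file path (`.tsv`/`.txt` or `.json`).
#' @return A [param_table()].
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) stop("read_parameter_table: no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(param_table(as.data.frame(raw$entries),
                       if (!is.null(raw$defaults) && length(raw$defaults))
                         as.data.frame(raw$defaults) else NULL))
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(names(TSV_COLS), names(tab))
  if (length(missing))
    stop("read_parameter_table: missing column(s): ",
         paste(missing, collapse = ", "))
  names(tab)[match(names(TSV_COLS), names(tab))] <- TSV_COLS
  is_def <- tab$resname == "*"
  defaults <- tab[is_def, , drop = FALSE]
  names(defaults)[names(defaults) == "atom"] <- "element"
  defaults$resname <- NULL
  param_table(tab[!is_def, , drop = FALSE],
              if (nrow(defaults)) defaults else NULL)
}

#' Write a parameter table as TSV
#' @param table a [param_table()].
#' @param path output file.
#' @export
write_parameter_table <- function(table, path) {
  ent <- table$entries
  def <- table$defaults
  if (nrow(def)) {
    def2 <- data.frame(resname = "*", atom = def$element,
                       def[setdiff(names(def), "element")],
                       stringsAsFactors = FALSE)
    ent <- rbind(ent[names(def2)], def2)
  }
  out <- ent
  names(out) <- names(TSV_COLS)[match(names(out), TSV_COLS)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-atom parameter table (charges e, lengths A, energies kcal/mol)", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Built-in parameter table
#'
#' The synthetic, representative table shipped with the package: heavy atoms
#' of the 20 standard amino acids with element-typed Lennard-Jones values,
#' pairwise-descreening Born radii and scale factors in the style of the
#' standard GB parameterizations, rough integral-charge side chains, element
#' defaults, and the `TOY` pseudo-residue used by the synthetic-complex
#' generator.  It is not a reproduction of any published force field.
#'
#' @return A [param_table()].
#' @export
default_parameter_table <- function() {
  read_parameter_table(system.file("extdata", "standard_params.tsv",
                                   package = "mmgbsa", mustWork = TRUE))
}

#' Assign energetic parameters and chemistry flags to a system
#'
#' Looks every atom up by `(resname, name)`; atoms without a keyed entry fall
#' back to the table's element defaults when `use_defaults = TRUE`.  Also
#' sets the hydrogen-bond donor/acceptor and acid-oxygen/base-nitrogen flags
#' from the built-in residue/atom-name dictionaries.  Idempotent.
#'
#' @param system an [mm_system()].
#' @param table a [param_table()]; default [default_parameter_table()].
#' @param use_defaults allow element-default fallback.
#' @return The parameterized [mm_system()].
#' @export
apply_parameters <- function(system, table = default_parameter_table(),
                             use_defaults = TRUE) {
  a <- system$atoms
  key <- paste(a$resname, a$name, sep = "/")
  tkey <- paste(table$entries$resname, table$entries$atom, sep = "/")
  hit <- match(key, tkey)
  cols <- c("charge", "rmin_half", "epsilon", "born_radius", "screen")
  for (cl in cols) a[[cl]] <- table$entries[[cl]][hit]
  unmatched <- which(is.na(hit))
  if (length(unmatched)) {
    if (!use_defaults || !nrow(table$defaults))
      stop("apply_parameters: no parameters for: ",
           paste(unique(key[unmatched]), collapse = ", "))
    dhit <- match(a$element[unmatched], table$defaults$element)
    still <- unmatched[is.na(dhit)]
    if (length(still))
      stop("apply_parameters: no parameters for: ",
           paste(unique(key[still]), collapse = ", "))
    for (cl in cols) a[[cl]][unmatched] <- table$defaults[[cl]][dhit]
  }
  flags <- chem_flags(a)
  a[names(flags)] <- flags
  out <- system
  out$atoms <- a
  out
}
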