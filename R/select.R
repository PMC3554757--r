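#' Select atoms by expression
#'
#' Small selection grammar over the atom table.  Primaries are
#' `chain <id>...`, `resid <n>` / `resid <a>-<b>` (ranges and lists mix),
#' `resname <code>...`, `name <atom>...`, and `all`; they combine with
#' `and`, `or`, `not` and parentheses.  Multiple values after one keyword
#' are a union, e.g. `"chain A B"` or `"resid 1-5 12"`.
#'
#' @param system an [mm_system()].
#' @param expression selection string, e.g.
#'   `"chain A and resid 10-20 and not name CA"`.
#' @return Sorted integer vector of matching atom indices (1-based).  An
#'   empty result is allowed but raises a warning.
#' @examples
#' \dontrun{select_atoms(sys, "chain A and resid 10-20")}
#' @export
select_atoms <- function(system, expression) {
  toks <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, system)
  if (st$pos <= nrow(st$toks))
    sel_error(st, "unexpected token")
  idx <- which(mask)
  if (!length(idx))
    warning("select_atoms: expression '", expression,
            "' matched no atoms", call. = FALSE)
  idx
}

tokenize_selection <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L)
    stop("select_atoms: expression must be a single string")
  pat <- "[A-Za-z][A-Za-z0-9_'*]*|[0-9]+-[0-9]+|-?[0-9]+|\\(|\\)|[^ \t]"
  m <- gregexpr(pat, expression)[[1]]
  if (m[1] == -1) stop("select_atoms: empty expression")
  txt <- regmatches(expression, gregexpr(pat, expression))[[1]]
  bad <- !grepl("^([A-Za-z][A-Za-z0-9_'*]*|[0-9]+-[0-9]+|-?[0-9]+|\\(|\\))$", txt)
  if (any(bad))
    stop(sprintf("select_atoms: syntax error at position %d: '%s'",
                 m[which(bad)[1]], txt[which(bad)[1]]))
  data.frame(text = txt, pos = as.integer(m), stringsAsFactors = FALSE)
}

sel_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$text[st$pos] else NA_character_
sel_next <- function(st) { t <- sel_peek(st); st$pos <- st$pos + 1L; t }
sel_error <- function(st, msg) {
  at <- if (st$pos <= nrow(st$toks))
    sprintf("position %d ('%s')", st$toks$pos[st$pos], st$toks$text[st$pos])
  else "end of expression"
  stop("select_atoms: syntax error, ", msg, " at ", at, call. = FALSE)
}

KEYWORDS <- c("chain", "resid", "resname", "name", "and", "or", "not",
              "all", "(", ")")

parse_or <- function(st, system) {
  m <- parse_and(st, system)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "or") {
    sel_next(st)
    m <- m | parse_and(st, system)
  }
  m
}

parse_and <- function(st, system) {
  m <- parse_factor(st, system)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "and") {
    sel_next(st)
    m <- m & parse_factor(st, system)
  }
  m
}

parse_factor <- function(st, system) {
  t <- sel_peek(st)
  if (is.na(t)) sel_error(st, "expected a term")
  tl <- tolower(t)
  if (tl == "not") {
    sel_next(st)
    return(!parse_factor(st, system))
  }
  if (t == "(") {
    sel_next(st)
    m <- parse_or(st, system)
    if (is.na(sel_peek(st)) || sel_peek(st) != ")")
      sel_error(st, "expected ')'")
    sel_next(st)
    return(m)
  }
  if (tl == "all") {
    sel_next(st)
    return(rep(TRUE, n_atoms(system)))
  }
  if (tl %in% c("chain", "resid", "resname", "name")) {
    sel_next(st)
    vals <- character()
    while (!is.na(sel_peek(st)) &&
           !(tolower(sel_peek(st)) %in% KEYWORDS) && sel_peek(st) != ")")
      vals <- c(vals, sel_next(st))
    if (!length(vals)) sel_error(st, paste0("'", tl, "' needs a value"))
    a <- system$atoms
    m <- switch(tl,
      chain = a$chain %in% vals,
      resname = toupper(a$resname) %in% toupper(vals),
      name = toupper(a$name) %in% toupper(vals),
      resid = {
        hit <- rep(FALSE, nrow(a))
        for (v in vals) {
          if (grepl("^[0-9]+-[0-9]+$", v)) {
            rg <- as.integer(strsplit(v, "-", fixed = TRUE)[[1]])
            hit <- hit | (a$resid >= rg[1] & a$resid <= rg[2])
          } else if (grepl("^-?[0-9]+$", v)) {
            hit <- hit | a$resid == as.integer(v)
          } else sel_error(st, paste0("bad resid value '", v, "'"))
        }
        hit
      })
    return(m)
  }
  sel_error(st, paste0("unknown keyword '", t, "'"))
}
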