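# Minimal fixed-width PDB reader/writer (ATOM/HETATM/MODEL records).  No
# pre-installed R package in this stack parses PDB, so the subset needed
# here (coordinates, names, numbering, multi-MODEL) is implemented directly.

#' Read a PDB file
#'
#' Parses ATOM/HETATM records; multi-MODEL files yield a list of atom
#' tables (a trajectory), single-model files a single atom table.
#'
#' @param path File path.
#' @return Atom table, or list of atom tables for multi-MODEL files.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  models <- list()
  cur <- list()
  in_model <- FALSE
  flush <- function(cur) {
    if (length(cur) == 0) return(NULL)
    do.call(rbind, cur)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    tag <- substr(line, 1, 6)
    if (tag == "MODEL ") {
      in_model <- TRUE
      if (length(cur) > 0) { models[[length(models) + 1]] <- flush(cur); cur <- list() }
    } else if (trimws(tag) == "ENDMDL") {
      models[[length(models) + 1]] <- flush(cur); cur <- list()
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      if (nchar(line) < 54) stop("malformed ATOM record at line ", ln, " of ", path)
      fields <- list(
        name = trimws(substr(line, 13, 16)),
        residue_name = trimws(substr(line, 18, 20)),
        chain_id = trimws(substr(line, 22, 22)),
        residue_index = suppressWarnings(as.integer(substr(line, 23, 26))),
        x = suppressWarnings(as.numeric(substr(line, 31, 38))),
        y = suppressWarnings(as.numeric(substr(line, 39, 46))),
        z = suppressWarnings(as.numeric(substr(line, 47, 54))),
        element = trimws(substr(line, 77, 78))
      )
      if (any(vapply(fields[c("x", "y", "z", "residue_index")],
                     function(v) is.na(v), logical(1)))) {
        stop("malformed ATOM record at line ", ln, " of ", path)
      }
      if (fields$element == "") fields$element <- .element_from_name(fields$name)
      cur[[length(cur) + 1]] <- as.data.frame(fields, stringsAsFactors = FALSE)
    }
  }
  if (length(cur) > 0) models[[length(models) + 1]] <- flush(cur)
  if (length(models) == 0) stop("no ATOM records found in ", path)
  models <- lapply(models, function(m) {
    m <- m[, c("name", "element", "x", "y", "z", "residue_index",
               "residue_name", "chain_id")]
    .as_atom_table(m)
  })
  if (length(models) == 1) models[[1]] else models
}

.format_pdb_atom <- function(i, a) {
  name <- a$name[i]
  # atom-name column convention: 1-char element names start in column 14
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i, name_f, a$residue_name[i], a$chain_id[i], a$residue_index[i],
          a$x[i], a$y[i], a$z[i], 1, 0, a$element[i])
}

#' Write atom tables to a PDB file
#'
#' @param structure Atom table, or list of atom tables (written as MODELs).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(structure, path) {
  if (inherits(structure, "atom_table") || is.data.frame(structure)) {
    structure <- list(structure)
  }
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(structure) > 1
  for (m in seq_along(structure)) {
    a <- structure[[m]]
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    writeLines(vapply(seq_len(nrow(a)), .format_pdb_atom, character(1), a = a), con)
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
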