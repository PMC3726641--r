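## PDB reading and writing (fixed-column ATOM/HETATM/MODEL/ENDMDL records).
## Multi-model files are the package's canonical trajectory interchange.

parse_atom_line <- function(line, lineno) {
  # fixed columns per the PDB format; returns list(record, position)
  w <- nchar(line)
  if (w < 54)
    stop("malformed ATOM/HETATM record at line ", lineno,
         ": fewer than 54 columns", call. = FALSE)
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(line, from, to)))
    if (is.na(v))
      stop("malformed ATOM/HETATM record at line ", lineno,
           ": non-numeric ", what, call. = FALSE)
    v
  }
  serial <- num(7, 11, "serial")
  name <- trimws(substr(line, 13, 16))
  resname <- trimws(substr(line, 18, 21))
  chain <- trimws(substr(line, 22, 22))
  resseq <- num(23, 26, "residue number")
  x <- num(31, 38, "x"); y <- num(39, 46, "y"); z <- num(47, 54, "z")
  element <- if (w >= 77) trimws(substr(line, 77, 78)) else ""
  if (element == "") element <- element_from_name(name)
  if (name == "")
    stop("malformed ATOM/HETATM record at line ", lineno,
         ": empty atom name", call. = FALSE)
  list(atom = data.frame(atom_id = as.integer(serial), name = name,
                         element = element, residue_name = resname,
                         residue_index = as.integer(resseq),
                         chain_id = chain, stringsAsFactors = FALSE),
       xyz = c(x, y, z))
}

# fall back on the first alphabetic character of the atom name; good enough
# for the organic + Ca/Na/S alphabet this package touches
element_from_name <- function(name) {
  if (grepl("^CA$", name)) return("C")  # alpha carbon; Ca ions carry element
  two <- c("CL", "NA", "MG", "ZN", "FE", "BR")
  up <- toupper(name)
  if (up %in% two) return(substr(up, 1, 1))
  first <- regmatches(name, regexpr("[A-Za-z]", name))
  toupper(first)
}

#' Read a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records. A single-model file yields a
#' [new_structure()]; a file with `MODEL`/`ENDMDL` blocks yields a
#' [new_trajectory()] whose frames are the models in file order, with times
#' `0, timestep, 2 timestep, ...` (the PDB format carries no time stamps).
#'
#' @param path file path.
#' @param timestep frame spacing in ps used for multi-model files.
#' @return a `Structure` or a `Trajectory`.
#' @export
read_pdb <- function(path, timestep = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    substr(rec, 1, 4) == "ATOM" & substr(rec, 5, 6) %in% c("  ", "")
  is_atom <- startsWith(rec, "ATOM") | startsWith(rec, "HETATM")
  model_starts <- which(startsWith(rec, "MODEL"))

  parse_block <- function(idx) {
    atoms <- vector("list", length(idx)); xyz <- matrix(0, length(idx), 3)
    for (k in seq_along(idx)) {
      p <- parse_atom_line(lines[idx[k]], idx[k])
      atoms[[k]] <- p$atom; xyz[k, ] <- p$xyz
    }
    list(atoms = do.call(rbind, atoms), xyz = xyz)
  }

  if (length(model_starts) == 0L) {
    idx <- which(is_atom)
    if (length(idx) == 0L) stop("no ATOM/HETATM records in ", path)
    b <- parse_block(idx)
    return(new_structure(b$atoms, b$xyz))
  }

  model_ends <- which(startsWith(rec, "ENDMDL"))
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL blocks in ", path)
  frames <- vector("list", length(model_starts))
  atoms0 <- NULL
  for (m in seq_along(model_starts)) {
    idx <- which(is_atom & seq_along(lines) > model_starts[m] &
                   seq_along(lines) < model_ends[m])
    if (length(idx) == 0L) stop("MODEL block ", m, " contains no atoms")
    b <- parse_block(idx)
    if (is.null(atoms0)) {
      atoms0 <- b$atoms
    } else if (nrow(b$atoms) != nrow(atoms0)) {
      stop("MODEL block ", m, " has ", nrow(b$atoms),
           " atoms; previous blocks have ", nrow(atoms0))
    }
    frames[[m]] <- new_frame(time = (m - 1) * timestep, positions = b$xyz)
  }
  new_trajectory(atoms0, frames, timestep = timestep)
}

format_atom_line <- function(a, xyz) {
  sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          a$atom_id %% 100000L,
          if (nchar(a$name) < 4) paste0(" ", a$name) else a$name,
          a$residue_name, substr(a$chain_id, 1, 1), a$residue_index %% 10000L,
          xyz[1], xyz[2], xyz[3], a$element)
}

#' Write a structure or trajectory as PDB
#'
#' Coordinates are serialised in the format's 8.3 columns, i.e. rounded to
#' three decimals; a trajectory becomes one `MODEL`/`ENDMDL` block per frame.
#' `read_pdb(write_pdb(x))` reproduces names, residues and coordinates to the
#' printed precision.
#'
#' @param x a `Structure` or `Trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  emit_block <- function(atoms, xyz) {
    out <- character(nrow(atoms))
    for (i in seq_len(nrow(atoms)))
      out[i] <- format_atom_line(atoms[i, ], xyz[i, ])
    writeLines(out, con)
  }
  if (inherits(x, "Structure")) {
    emit_block(x$atoms, x$positions)
  } else if (inherits(x, "Trajectory")) {
    for (m in seq_along(x$frames)) {
      writeLines(sprintf("MODEL     %4d", m), con)
      emit_block(x$atoms, x$frames[[m]]$positions)
      writeLines("ENDMDL", con)
    }
  } else stop("write_pdb() expects a Structure or Trajectory")
  writeLines("END", con)
  invisible(path)
}
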