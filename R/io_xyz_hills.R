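## XYZ trajectories (light fixture format) and PLUMED-style HILLS files.

#' Read an XYZ trajectory
#'
#' Plain XYZ frames with a constant atom count. If the comment line carries a
#' `time=<ps>` token it is used as the frame time; otherwise times are filled
#' as `frame_index * timestep` (0-based index).
#'
#' @param path file path.
#' @param atoms atom table describing the same atoms in the same order (XYZ
#'   stores only element symbols); typically `structure$atoms` from the
#'   matching topology. `NULL` builds a minimal table from the element column.
#' @param timestep fallback frame spacing, ps.
#' @return a `Trajectory`.
#' @export
read_xyz_trajectory <- function(path, atoms = NULL, timestep = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  frames <- list(); i <- 1L; fi <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na <= 0L)
      stop("bad atom count at line ", i, " of ", path)
    if (i + 1L + na > length(lines))
      stop("truncated frame at line ", i, " of ", path)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexpr("time=\\s*[-0-9.eE+]+", comment))
    time <- if (length(tm) == 1L)
      as.numeric(sub("time=\\s*", "", tm)) else fi * timestep
    body <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4L)
    if (length(bad) > 0L)
      stop("malformed XYZ atom line at line ", i + 1L + bad[1], " of ", path)
    el <- vapply(parts, `[[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("non-numeric coordinate in frame starting at line ", i, " of ", path)
    if (length(frames) > 0L && nrow(xyz) != nrow(frames[[1]]$positions))
      stop("atom count changes mid-file at line ", i, " of ", path)
    frames[[length(frames) + 1L]] <- new_frame(time, xyz)
    if (length(frames) == 1L && is.null(atoms))
      atoms <- data.frame(atom_id = seq_len(na), name = el, element = el,
                          residue_name = "UNK", residue_index = 1L,
                          chain_id = "A", stringsAsFactors = FALSE)
    i <- i + 2L + na; fi <- fi + 1L
  }
  if (length(frames) == 0L) stop("no frames in ", path)
  new_trajectory(atoms, frames, timestep = timestep)
}

#' Write an XYZ trajectory
#'
#' @param trajectory a `Trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(trajectory, path) {
  con <- file(path, "w"); on.exit(close(con))
  el <- trajectory$atoms$element
  for (f in trajectory$frames) {
    writeLines(c(as.character(length(el)),
                 sprintf("time=%.6g", f$time)), con)
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", el,
                       f$positions[, 1], f$positions[, 2], f$positions[, 3]),
               con)
  }
  invisible(path)
}

#' Read a PLUMED-style HILLS file
#'
#' Whitespace-separated columns declared by a leading `#! FIELDS time cv...
#' sigma_cv... height biasf` header; the CV dimensionality is inferred from
#' the header. This is the dialect [run_wt_metad()] writes.
#'
#' @param path file path.
#' @return a `hills` data.frame (see [new_hills()]).
#' @export
read_hills <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (length(hdr) == 0L)
    stop("HILLS file ", path, " has no '#! FIELDS' header")
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", hdr[1])), "\\s+")[[1]]
  need <- c("time", "height", "biasf")
  if (!all(need %in% fields))
    stop("HILLS header must declare columns: ", paste(need, collapse = ", "))
  cvn <- fields[!fields %in% need & !startsWith(fields, "sigma_")]
  sgn <- paste0("sigma_", cvn)
  if (!all(sgn %in% fields))
    stop("HILLS header lacks sigma_ columns for: ",
         paste(cvn[!sgn %in% fields], collapse = ", "))
  data_lines <- lines[!startsWith(trimws(lines), "#") & trimws(lines) != ""]
  if (length(data_lines) == 0L)
    return(new_hills(numeric(0), matrix(numeric(0), 0, length(cvn)),
                     matrix(numeric(0), 0, length(cvn)), numeric(0), numeric(0)))
  parts <- strsplit(trimws(data_lines), "\\s+")
  arity <- vapply(parts, length, integer(1))
  if (any(arity != length(fields)))
    stop("HILLS row ", which(arity != length(fields))[1], " has ",
         arity[arity != length(fields)][1], " columns; header declares ",
         length(fields))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = length(fields), byrow = TRUE)
  if (any(!is.finite(m)))
    stop("non-numeric value in HILLS data row ",
         which(rowSums(!is.finite(m)) > 0)[1])
  colnames(m) <- fields
  new_hills(time = m[, "time"],
            center = m[, cvn, drop = FALSE],
            sigma = m[, sgn, drop = FALSE],
            height = m[, "height"],
            bias_factor = m[, "biasf"])
}

#' Write hills in the PLUMED-style dialect
#'
#' Numeric fields are printed with enough digits to round-trip through
#' [read_hills()] to at least 6 significant digits.
#'
#' @param hills a `hills` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  k <- hills_dim(hills)
  cvn <- paste0("cv", seq_len(k))
  cols <- c("time", cvn, paste0("sigma_", cvn), "height", "biasf")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(cols, collapse = " ")), con)
  if (nrow(hills) > 0) {
    m <- as.matrix(hills[, c("time", cvn, paste0("sigma_", cvn),
                             "height", "biasf")])
    writeLines(apply(m, 1, function(r)
      paste(sprintf("%.10g", r), collapse = " ")), con)
  }
  invisible(path)
}
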