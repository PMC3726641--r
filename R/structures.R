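#' @useDynLib cleftscope, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd setNames aggregate
#' @importFrom utils read.table write.table head tail
"_PACKAGE"

# Units used throughout the package: coordinates in Angstrom, times in ps,
# energies in kcal/mol, angles in degrees unless stated otherwise.

#' Boltzmann constant in kcal/(mol K)
#'
#' Fixed project-wide; used by the well-tempered height damping, the
#' free-energy scaling and the Boltzmann projection.
#' @export
KB_KCAL <- 0.0019872

## ---- Structure ------------------------------------------------------------

#' Create a molecular structure
#'
#' A `Structure` is the static atom table plus one set of coordinates. It is
#' the return type of [read_pdb()] for single-model files and the input of
#' [annotate_topology()].
#'
#' @param atoms data.frame with columns `atom_id` (integer, unique),
#'   `name`, `element`, `residue_name`, `residue_index`, `chain_id`.
#' @param positions numeric matrix, one row per atom, columns x/y/z in
#'   Angstrom. All values must be finite.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, positions) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("atom_id", "name", "element", "residue_name", "residue_index",
            "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L)
    stop("atoms table is missing columns: ", paste(miss, collapse = ", "))
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 3L)
    stop("positions must be a numeric n x 3 matrix")
  if (nrow(positions) != nrow(atoms))
    stop("positions (", nrow(positions), " rows) and atoms (", nrow(atoms),
         " rows) disagree")
  if (anyDuplicated(atoms$atom_id))
    stop("atom_id values must be unique within a structure")
  if (!all(is.finite(positions)))
    stop("all atom positions must be finite")
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, positions = positions), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("<Structure> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$residue_index)), " residues\n", sep = "")
  invisible(x)
}

n_atoms <- function(x) nrow(x$atoms)

## ---- Frame and Trajectory -------------------------------------------------

#' Create a trajectory frame
#'
#' @param time time stamp in ps.
#' @param positions numeric n x 3 coordinate matrix (Angstrom), index-aligned
#'   with the trajectory's atom table.
#' @param box optional 3-vector of box lengths (Angstrom).
#' @return object of class `Frame`.
#' @export
new_frame <- function(time, positions, box = NULL) {
  positions <- as.matrix(positions)
  stopifnot(is.numeric(time), length(time) == 1L, is.finite(time),
            is.numeric(positions), ncol(positions) == 3L)
  if (!is.null(box)) stopifnot(is.numeric(box), length(box) == 3L)
  structure(list(time = as.numeric(time), positions = positions, box = box),
            class = "Frame")
}

#' Create a trajectory
#'
#' Ordered frames over a fixed atom table. Frame times must be strictly
#' increasing and every frame must carry one position per atom.
#'
#' @param atoms atom table (as in [new_structure()]).
#' @param frames list of [new_frame()] objects.
#' @param timestep nominal spacing between frames, ps.
#' @param topology optional [annotate_topology()] result to carry along.
#' @return object of class `Trajectory`.
#' @export
new_trajectory <- function(atoms, frames, timestep = 1, topology = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (length(frames) < 1L) stop("a Trajectory needs at least one frame")
  na <- nrow(atoms)
  for (i in seq_along(frames)) {
    if (!inherits(frames[[i]], "Frame"))
      stop("frames[[", i, "]] is not a Frame")
    if (nrow(frames[[i]]$positions) != na)
      stop("frame ", i, " has ", nrow(frames[[i]]$positions),
           " positions for ", na, " atoms")
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(atoms = atoms, frames = frames,
                 timestep = as.numeric(timestep), topology = topology),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("<Trajectory> ", length(x$frames), " frames x ", nrow(x$atoms),
      " atoms, t = ", x$frames[[1]]$time, " .. ",
      x$frames[[length(x$frames)]]$time, " ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a `Trajectory`.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Frame time stamps of a trajectory (ps)
#' @param trajectory a `Trajectory`.
#' @export
frame_times <- function(trajectory)
  vapply(trajectory$frames, function(f) f$time, numeric(1))

#' Restrict a trajectory to an analysis window
#'
#' Selects the frames with `start < time <= end` (half-open on the left, so
#' "the final 45 ns" of a 50 ns run is `window = c(5000, 50000)`).
#'
#' @param trajectory a `Trajectory`.
#' @param window numeric length-2, `c(start, end)` in ps; `NULL` keeps all
#'   frames.
#' @return a `Trajectory` containing only the selected frames.
#' @export
trajectory_window <- function(trajectory, window = NULL) {
  if (is.null(window)) return(trajectory)
  stopifnot(length(window) == 2L, window[1] < window[2])
  times <- frame_times(trajectory)
  keep <- times > window[1] & times <= window[2]
  if (!any(keep)) stop("analysis window contains no frames")
  new_trajectory(trajectory$atoms, trajectory$frames[keep],
                 timestep = trajectory$timestep,
                 topology = trajectory$topology)
}

#' Default analysis window: skip the first 10 percent of frames
#'
#' Mirrors the common practice of discarding the initial segment of a
#' production run (e.g. analysing the final 45 ns of a 50 ns trajectory).
#'
#' @param trajectory a `Trajectory`.
#' @return numeric `c(start, end)` in ps.
#' @export
default_window <- function(trajectory) {
  times <- frame_times(trajectory)
  t0 <- times[1]; t1 <- times[length(times)]
  c(t0 + 0.10 * (t1 - t0) - 1e-9, t1)
}

# dense n_atoms x 3 x n_frames array; internal convenience for the
# geometry module
coords_array <- function(trajectory) {
  na <- nrow(trajectory$atoms); nf <- length(trajectory$frames)
  arr <- array(NA_real_, dim = c(na, 3L, nf))
  for (i in seq_len(nf)) arr[, , i] <- trajectory$frames[[i]]$positions
  arr
}

## ---- Hills ----------------------------------------------------------------

#' Create a table of metadynamics hills
#'
#' One row per deposited Gaussian. This is the in-memory form of a
#' PLUMED-style HILLS file (see [read_hills()]).
#'
#' @param time deposit times, ps (non-decreasing).
#' @param center matrix of hill centres (rows = hills, columns = CVs), or a
#'   vector for one CV.
#' @param sigma widths, same shape as `center` (all > 0).
#' @param height Gaussian heights, kcal/mol (all >= 0).
#' @param bias_factor well-tempered bias factor gamma.
#' @return data.frame of class `hills` with columns `time`, `cv1..cvK`,
#'   `sigma_cv1..sigma_cvK`, `height`, `biasf`.
#' @export
new_hills <- function(time, center, sigma, height, bias_factor) {
  center <- as.matrix(center); sigma <- as.matrix(sigma)
  k <- ncol(center)
  stopifnot(nrow(center) == length(time), all(dim(sigma) == dim(center)),
            length(height) == length(time))
  if (any(sigma <= 0)) stop("hill widths (sigma) must be positive")
  if (any(height < 0)) stop("hill heights must be non-negative")
  if (is.unsorted(time)) stop("hill times must be non-decreasing")
  df <- data.frame(time = as.numeric(time))
  for (j in seq_len(k)) df[[paste0("cv", j)]] <- center[, j]
  for (j in seq_len(k)) df[[paste0("sigma_cv", j)]] <- sigma[, j]
  df$height <- as.numeric(height)
  df$biasf <- rep_len(as.numeric(bias_factor), length(time))
  class(df) <- c("hills", "data.frame")
  df
}

hills_dim <- function(hills) sum(grepl("^cv[0-9]+$", names(hills)))

hills_centers <- function(hills)
  as.matrix(hills[, grep("^cv[0-9]+$", names(hills)), drop = FALSE])

hills_sigmas <- function(hills)
  as.matrix(hills[, grep("^sigma_cv[0-9]+$", names(hills)), drop = FALSE])
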