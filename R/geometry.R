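## Superposition-based trajectory geometry: Kabsch RMSD, RMSF about the
## iteratively superposed average structure, calcium-site displacement
## distributions and ligand dihedral populations.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `mobile[selection, ] %*% R + t` onto `reference[selection, ]`. The
#' improper-rotation (reflection) case is handled by the usual determinant
#' sign correction, so `R` is always a pure rotation.
#'
#' @param reference,mobile n x 3 coordinate matrices.
#' @param selection atom indices used for the fit (default: all). At least
#'   3 non-collinear atoms are required.
#' @return object of class `Superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (3-vector) and `rmsd` (Angstrom, over the
#'   selection).
#' @export
superpose <- function(reference, mobile, selection = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (is.null(selection)) selection <- seq_len(nrow(reference))
  if (length(selection) < 3L)
    stop("superposition needs at least 3 selected atoms")
  X <- mobile[selection, , drop = FALSE]
  Y <- reference[selection, , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- tryCatch(svd(crossprod(Xc, Yc)),
                 error = function(e) stop("degenerate selection: ",
                                          conditionMessage(e)))
  if (sv$d[2] < 1e-12)
    stop("degenerate (collinear) selection for superposition")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_ <- cy - as.numeric(cx %*% R)
  fitted <- Xc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  structure(list(rotation = R, translation = t_, rmsd = rmsd),
            class = "Superposition")
}

#' Apply a superposition to coordinates
#' @param sp a `Superposition`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords)
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, "+")

#' Per-frame superposed RMSD series
#'
#' Each frame is superposed on the reference over `selection`; one RMSD per
#' frame is returned together with the mean and standard deviation over the
#' analysis window.
#'
#' @param trajectory a `Trajectory`.
#' @param selection atom indices to fit and measure (default all).
#' @param reference reference coordinates (n x 3) or a frame index into the
#'   trajectory (default: first frame).
#' @param window optional `c(start, end)` ps.
#' @return data.frame `time`, `rmsd` with attributes `mean` and `sd`.
#' @export
rmsd_series <- function(trajectory, selection = NULL, reference = 1L,
                        window = NULL) {
  tw <- trajectory_window(trajectory, window)
  ref <- if (is.numeric(reference) && length(reference) == 1L)
    trajectory$frames[[reference]]$positions else as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(ref))
  vals <- vapply(tw$frames, function(f)
    superpose(ref, f$positions, selection)$rmsd, numeric(1))
  out <- data.frame(time = frame_times(tw), rmsd = vals)
  attr(out, "mean") <- mean(vals)
  attr(out, "sd") <- stats::sd(vals)
  out
}

#' Root-mean-square fluctuation about the average structure
#'
#' Frames are iteratively superposed (default 2 passes, or until the average
#' structure moves by less than `tol`): align on the running average,
#' recompute the average, realign. The RMSF of an atom is the root mean
#' square deviation of its aligned position from the converged average.
#' Per-residue values average the squared fluctuations of the selected atoms
#' in each residue.
#'
#' @param trajectory a `Trajectory` (>= 2 frames in the window).
#' @param selection atoms to align on and report (default all).
#' @param window optional `c(start, end)` ps.
#' @param n_iter alignment passes.
#' @param tol convergence threshold on the average structure, Angstrom.
#' @return list with `per_atom` (data.frame atom, rmsf) and `per_residue`
#'   (data.frame residue, rmsf).
#' @export
rmsf <- function(trajectory, selection = NULL, window = NULL, n_iter = 2L,
                 tol = 1e-4) {
  tw <- trajectory_window(trajectory, window)
  nf <- n_frames(tw)
  if (nf < 2L) stop("RMSF needs at least 2 frames in the window")
  if (is.null(selection)) selection <- seq_len(nrow(tw$atoms))
  if (length(selection) == 0L) stop("empty selection")
  coords <- lapply(tw$frames, function(f)
    f$positions[selection, , drop = FALSE])
  ref <- coords[[1]]
  for (pass in seq_len(n_iter)) {
    aligned <- lapply(coords, function(x)
      apply_superposition(superpose(ref, x), x))
    avg <- Reduce(`+`, aligned) / nf
    shift <- sqrt(mean(rowSums((avg - ref)^2)))
    ref <- avg
    if (shift < tol && pass > 1L) break
  }
  dev2 <- matrix(0, length(selection), 1)
  dev2 <- rowSums(vapply(aligned, function(x) rowSums((x - ref)^2),
                         numeric(length(selection)))) / nf
  per_atom <- data.frame(atom = selection, rmsf = sqrt(dev2))
  tagf <- atom_residue_tag_from_atoms(tw$atoms)[selection]
  agg <- tapply(dev2, tagf, mean)
  per_residue <- data.frame(residue = names(agg), rmsf = sqrt(as.numeric(agg)),
                            stringsAsFactors = FALSE)
  list(per_atom = per_atom, per_residue = per_residue)
}

atom_residue_tag_from_atoms <- function(atoms)
  paste0(atoms$residue_name, atoms$residue_index)

#' Terminal-strand RMSF summary
#'
#' Averages backbone fluctuations over the `n_terminal` last residues at
#' each end of a chain (the "terminal strands" convention).
#'
#' @param trajectory a `Trajectory`.
#' @param chain chain identifier.
#' @param n_terminal residues per strand.
#' @param backbone_only restrict to backbone atoms?
#' @param window optional window, ps.
#' @return data.frame with one row per strand (`N`, `C`) and its mean RMSF.
#' @export
terminal_strand_rmsf <- function(trajectory, chain, n_terminal = 8L,
                                 backbone_only = TRUE, window = NULL) {
  at <- trajectory$atoms
  resn <- sort(unique(at$residue_index[at$chain_id == chain]))
  if (length(resn) < n_terminal)
    stop("chain ", chain, " has fewer than ", n_terminal, " residues")
  strands <- list(N = utils::head(resn, n_terminal),
                  C = utils::tail(resn, n_terminal))
  sel_all <- which(at$chain_id == chain &
                     (!backbone_only | at$name %in% BACKBONE_NAMES))
  rf <- rmsf(trajectory, selection = sel_all, window = window)
  out <- data.frame(strand = names(strands), rmsf = NA_real_)
  for (s in seq_along(strands)) {
    sel <- which(at$chain_id == chain &
                   at$residue_index %in% strands[[s]] &
                   (!backbone_only | at$name %in% BACKBONE_NAMES))
    out$rmsf[s] <- sqrt(mean(rf$per_atom$rmsf[rf$per_atom$atom %in% sel]^2))
  }
  out
}

#' Calcium-site displacement distributions
#'
#' Each frame is superposed on the alignment selection against the reference
#' frame; the displacement of every ion from its reference position is then
#' recorded, and a joint 2D histogram (site I vs site II) is built. The
#' histogram includes an overflow bin so its mass sums to exactly 1.
#'
#' @param trajectory a `Trajectory`.
#' @param sites named integer vector of ion atom indices (e.g.
#'   `c(I = ..., II = ...)` from a `ToyComplex$ion_sites`).
#' @param align_selection atom indices to superpose on (e.g. backbone).
#' @param reference reference frame index (default the first frame of the
#'   window, mirroring "positions at the end of equilibration").
#' @param window optional window, ps.
#' @param bin_width histogram bin width, Angstrom.
#' @param max_displacement histogram range; beyond it mass lands in the
#'   overflow bin.
#' @return list with `series` (data.frame time + one column per site),
#'   `histogram` (matrix, site I bins x site II bins, overflow included,
#'   sums to 1) and `breaks`.
#' @export
ion_displacement_distribution <- function(trajectory, sites, align_selection,
                                          reference = NULL, window = NULL,
                                          bin_width = 0.5,
                                          max_displacement = 10) {
  if (length(sites) < 1L) stop("no ion sites given")
  if (is.null(names(sites)) || any(names(sites) == ""))
    stop("sites must be a named vector of atom indices")
  if (anyNA(sites) || any(sites < 1) || any(sites > nrow(trajectory$atoms)))
    stop("ion atom index missing from the topology")
  tw <- trajectory_window(trajectory, window)
  nf <- n_frames(tw)
  ref_i <- if (is.null(reference)) 1L else reference
  ref <- tw$frames[[ref_i]]$positions
  disp <- matrix(NA_real_, nf, length(sites),
                 dimnames = list(NULL, names(sites)))
  for (i in seq_len(nf)) {
    p <- tw$frames[[i]]$positions
    sp <- superpose(ref, p, align_selection)
    moved <- apply_superposition(sp, p[sites, , drop = FALSE])
    disp[i, ] <- sqrt(rowSums((moved - ref[sites, , drop = FALSE])^2))
  }
  series <- data.frame(time = frame_times(tw), disp)
  breaks <- seq(0, max_displacement, by = bin_width)
  hist2 <- NULL
  if (length(sites) >= 2L) {
    bin_of <- function(x) pmin(findInterval(x, breaks,
                                            rightmost.closed = FALSE),
                               length(breaks))       # last bin = overflow
    bi <- bin_of(disp[, 1]); bj <- bin_of(disp[, 2])
    hist2 <- matrix(0, length(breaks), length(breaks))
    for (i in seq_len(nf)) hist2[bi[i], bj[i]] <- hist2[bi[i], bj[i]] + 1
    hist2 <- hist2 / nf
    dimnames(hist2) <- list(site_a = c(sprintf("[%.2f,%.2f)",
                                               breaks[-length(breaks)],
                                               breaks[-1]), "overflow"),
                            site_b = c(sprintf("[%.2f,%.2f)",
                                               breaks[-length(breaks)],
                                               breaks[-1]), "overflow"))
  }
  list(series = series, histogram = hist2, breaks = breaks)
}

# signed torsion angle in (-180, 180], degrees; 0 = cis, 180 = trans
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) return(NA_real_)
  ang <- atan2(sum(cx(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Dihedral angle series, circular histogram and mode report
#'
#' Signed torsions in `(-180, 180]` per frame (0 = cis, 180 = trans; the
#' angle is invariant under reversing the four-atom order and negates under
#' mirror reflection). Frames with a collinear triple yield `NA` and are
#' flagged. Modes are local maxima of the circularly smoothed histogram
#' (3-bin moving average); each mode's population is the total probability
#' mass of its basin (the histogram split at the smoothed local minima).
#'
#' @param trajectory a `Trajectory`.
#' @param definition four atom indices, or the name of a topology dihedral
#'   (e.g. `"chi1"`).
#' @param window optional window, ps.
#' @param bin_width histogram bin width, degrees.
#' @param fold fold two-fold ring symmetry (angle modulo 180)?
#' @return list with `angles` (data.frame time, angle), `histogram`
#'   (data.frame mid, prob; sums to 1 over non-NA frames), `modes`
#'   (data.frame angle, fraction) and `n_flagged` collinear frames.
#' @export
dihedral_series <- function(trajectory, definition, window = NULL,
                            bin_width = 5, fold = FALSE) {
  if (is.character(definition)) {
    topo <- trajectory$topology
    if (is.null(topo) || is.null(topo$dihedrals[[definition]]))
      stop("unknown dihedral '", definition, "'")
    definition <- topo$dihedrals[[definition]]
  }
  stopifnot(length(definition) == 4L, !anyDuplicated(definition))
  tw <- trajectory_window(trajectory, window)
  ang <- vapply(tw$frames, function(f) {
    p <- f$positions
    torsion_angle(p[definition[1], ], p[definition[2], ],
                  p[definition[3], ], p[definition[4], ])
  }, numeric(1))
  n_flagged <- sum(is.na(ang))
  a <- ang[!is.na(ang)]
  if (length(a) == 0L) stop("all frames have collinear dihedral geometry")
  span <- if (fold) c(0, 180) else c(-180, 180)
  av <- if (fold) a %% 180 else a
  breaks <- seq(span[1], span[2], by = bin_width)
  bins <- findInterval(av, breaks, rightmost.closed = TRUE)
  bins[bins == 0] <- 1L
  nb <- length(breaks) - 1L
  prob <- tabulate(bins, nb) / length(av)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # circular 3-bin smoothing, then basin decomposition at local minima
  sm <- (prob + c(prob[-1], prob[1]) + c(prob[nb], prob[-nb])) / 3
  nxt <- c(sm[-1], sm[1]); prv <- c(sm[nb], sm[-nb])
  is_max <- sm > prv & sm >= nxt & sm > 0
  modes <- data.frame(angle = numeric(0), fraction = numeric(0))
  if (any(is_max)) {
    # assign each bin to the nearest mode walking uphill on the smoothed curve
    lab <- integer(nb)
    mode_bins <- which(is_max)
    for (b in seq_len(nb)) {
      cur <- b
      for (step in seq_len(nb)) {
        if (is_max[cur]) break
        up <- if (nxt[cur] >= prv[cur]) (cur %% nb) + 1L
              else ((cur - 2L) %% nb) + 1L
        if (sm[up] < sm[cur]) break
        cur <- up
      }
      lab[b] <- if (is_max[cur]) cur else mode_bins[
        which.min(pmin(abs(mid[mode_bins] - mid[b]),
                       diff(span) - abs(mid[mode_bins] - mid[b])))]
    }
    frac <- tapply(prob, lab, sum)
    modes <- data.frame(angle = mid[as.integer(names(frac))],
                        fraction = as.numeric(frac))
    modes <- modes[order(-modes$fraction), , drop = FALSE]
    rownames(modes) <- NULL
  }
  list(angles = data.frame(time = frame_times(tw), angle = ang),
       histogram = data.frame(mid = mid, prob = prob),
       modes = modes, n_flagged = n_flagged, fold = fold)
}
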