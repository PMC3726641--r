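## Geometric interaction detectors and Table-1/Table-3-style summaries.
##
## A hydrogen bond is a (donor heavy, H, acceptor) triple with donor-acceptor
## distance strictly smaller than 3.5 A (4.0 A when the acceptor is a
## methionine-type sulphur) and a donor-H-acceptor angle, vertex at the
## hydrogen, strictly larger than 120 degrees (180 = linear). A pi-pi contact
## is an unordered pair of aromatic rings with centroid distance strictly
## below 5 A and an inter-normal angle, folded to [0, 90], strictly below
## 45 degrees. Strict inequalities follow the "smaller than"/"larger than"
## wording so boundary fixtures are unambiguous.

#' Hydrogen-bond geometric criteria
#'
#' @param da_cutoff donor-acceptor distance cutoff, Angstrom.
#' @param da_cutoff_sulphur cutoff when the acceptor is a sulphur
#'   (methionine SD class), Angstrom.
#' @param dha_min_angle minimal donor-H-acceptor angle, degrees, vertex at
#'   the hydrogen.
#' @return object of class `HBondCriteria`.
#' @export
hbond_criteria <- function(da_cutoff = 3.5, da_cutoff_sulphur = 4.0,
                           dha_min_angle = 120) {
  stopifnot(da_cutoff > 0, da_cutoff_sulphur > 0,
            dha_min_angle > 0, dha_min_angle <= 180)
  structure(list(da_cutoff = da_cutoff,
                 da_cutoff_sulphur = da_cutoff_sulphur,
                 dha_min_angle = dha_min_angle), class = "HBondCriteria")
}

#' Pi-pi stacking geometric criteria
#'
#' @param centroid_cutoff ring centre-to-centre cutoff, Angstrom.
#' @param normal_max_angle maximal angle between ring normals, degrees
#'   (folded to `[0, 90]`).
#' @return object of class `PiPiCriteria`.
#' @export
pipi_criteria <- function(centroid_cutoff = 5.0, normal_max_angle = 45) {
  stopifnot(centroid_cutoff > 0, normal_max_angle > 0, normal_max_angle <= 90)
  structure(list(centroid_cutoff = centroid_cutoff,
                 normal_max_angle = normal_max_angle), class = "PiPiCriteria")
}

check_annotated <- function(topology) {
  if (!inherits(topology, "Topology"))
    stop("an annotated Topology is required; run annotate_topology() first")
}

# partner class of a contact relative to the focus molecule class
partner_class_of <- function(mol_a, mol_b, focus = "ligand") {
  ifelse(mol_a == focus & mol_b == focus, "intramolecular",
    ifelse(mol_a == focus | mol_b == focus,
      ifelse(mol_a == focus,
             ifelse(mol_b == "solvent", "solvent",
                    ifelse(mol_b == "protein", "protein", mol_b)),
             ifelse(mol_a == "solvent", "solvent",
                    ifelse(mol_a == "protein", "protein", mol_a))),
      "other"))
}

#' Detect hydrogen bonds in one frame
#'
#' Every donor (heavy, H) pair is tested independently against every
#' acceptor; one record is emitted per satisfying (H, acceptor) combination,
#' matching the "average number of hydrogen bonds" convention of counting
#' events. Donor and acceptor within the same residue are excluded unless
#' `intramolecular = TRUE`.
#'
#' @param topology an annotated `Topology`.
#' @param frame a `Frame` (or an n x 3 coordinate matrix).
#' @param criteria a [hbond_criteria()].
#' @param intramolecular also report same-residue bonds?
#' @param focus molecule class used to assign `partner_class`.
#' @return data.frame with one row per bond: `donor`, `hydrogen`, `acceptor`
#'   atom indices, `distance`, `angle`, `donor_residue`, `acceptor_residue`,
#'   `partner_class`.
#' @export
hbond_frame <- function(topology, frame, criteria = hbond_criteria(),
                        intramolecular = FALSE, focus = "ligand") {
  check_annotated(topology)
  pos <- if (inherits(frame, "Frame")) frame$positions else as.matrix(frame)
  dn <- topology$donors; ac <- topology$acceptors
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0), donor_residue = character(0),
                      acceptor_residue = character(0),
                      partner_class = character(0), stringsAsFactors = FALSE)
  if (nrow(dn) == 0L || nrow(ac) == 0L) return(empty)

  D <- pos[dn$heavy, , drop = FALSE]
  H <- pos[dn$hydrogen, , drop = FALSE]
  A <- pos[ac$atom, , drop = FALSE]
  # donor x acceptor distance matrix
  d2 <- outer(rowSums(D^2), rowSums(A^2), "+") - 2 * D %*% t(A)
  d2[d2 < 0] <- 0
  dda <- sqrt(d2)
  cut <- matrix(criteria$da_cutoff, nrow(dn), nrow(ac))
  cut[, ac$class == "S"] <- criteria$da_cutoff_sulphur
  cand <- which(dda < cut, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)

  di <- cand[, 1]; ai <- cand[, 2]
  same_atom <- dn$heavy[di] == ac$atom[ai] | dn$hydrogen[di] == ac$atom[ai]
  res_d <- paste(topology$atoms$chain_id[dn$heavy[di]],
                 topology$atoms$residue_index[dn$heavy[di]])
  res_a <- paste(topology$atoms$chain_id[ac$atom[ai]],
                 topology$atoms$residue_index[ac$atom[ai]])
  keep <- !same_atom & (intramolecular | res_d != res_a)
  di <- di[keep]; ai <- ai[keep]
  if (length(di) == 0L) return(empty)

  hd <- D[di, , drop = FALSE] - H[di, , drop = FALSE]
  ha <- A[ai, , drop = FALSE] - H[di, , drop = FALSE]
  cosang <- rowSums(hd * ha) /
    (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  ok <- ang > criteria$dha_min_angle
  di <- di[ok]; ai <- ai[ok]; ang <- ang[ok]
  if (length(di) == 0L) return(empty)

  mol <- atom_molecule_class(topology)
  tag <- atom_residue_tag(topology)
  data.frame(
    donor = dn$heavy[di], hydrogen = dn$hydrogen[di], acceptor = ac$atom[ai],
    distance = dda[cbind(di, ai)], angle = ang,
    donor_residue = tag[dn$heavy[di]], acceptor_residue = tag[ac$atom[ai]],
    partner_class = partner_class_of(mol[dn$heavy[di]], mol[ac$atom[ai]],
                                     focus),
    stringsAsFactors = FALSE)
}

#' Detect pi-pi stacking contacts in one frame
#'
#' Ring normals are least-squares plane fits to the ring atoms; the
#' inter-normal angle is folded to `[0, 90]` so the result is independent of
#' normal orientation and of ring-pair ordering. Rings within the same
#' residue are never paired.
#'
#' @inheritParams hbond_frame
#' @param criteria a [pipi_criteria()].
#' @return data.frame with one row per contact: `ring_a`, `ring_b` (ring
#'   names, alphabetical order), `distance`, `angle`, `partner_class`.
#' @export
pipi_frame <- function(topology, frame, criteria = pipi_criteria(),
                       focus = "ligand") {
  check_annotated(topology)
  pos <- if (inherits(frame, "Frame")) frame$positions else as.matrix(frame)
  rings <- topology$rings
  empty <- data.frame(ring_a = character(0), ring_b = character(0),
                      distance = numeric(0), angle = numeric(0),
                      partner_class = character(0), stringsAsFactors = FALSE)
  if (length(rings) < 2L) return(empty)
  cent <- t(vapply(rings, function(ix) colMeans(pos[ix, , drop = FALSE]),
                   numeric(3)))
  nrm <- t(vapply(rings, function(ix) {
    coords <- pos[ix, , drop = FALSE]
    if (sum(rowSums(is.finite(coords)) == 3L) < 3L)
      stop("ring with fewer than 3 finite atoms")
    plane_normal(coords)
  }, numeric(3)))
  mol <- atom_molecule_class(topology)
  ring_mol <- vapply(rings, function(ix) mol[ix[1]], character(1))
  out <- empty
  nr <- length(rings)
  for (i in seq_len(nr - 1L)) for (j in (i + 1L):nr) {
    ix <- rings[[i]]; jx <- rings[[j]]
    same_res <- topology$atoms$residue_index[ix[1]] ==
      topology$atoms$residue_index[jx[1]] &&
      topology$atoms$chain_id[ix[1]] == topology$atoms$chain_id[jx[1]]
    if (same_res) next
    d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
    if (d >= criteria$centroid_cutoff) next
    cosang <- abs(sum(nrm[i, ] * nrm[j, ]))
    ang <- acos(pmin(1, cosang)) * 180 / pi        # folded to [0, 90]
    if (ang >= criteria$normal_max_angle) next
    nms <- sort(c(names(rings)[i], names(rings)[j]))
    out <- rbind(out, data.frame(
      ring_a = nms[1], ring_b = nms[2], distance = d, angle = ang,
      partner_class = partner_class_of(ring_mol[i], ring_mol[j], focus),
      stringsAsFactors = FALSE))
  }
  out
}

#' Summarise interactions over an analysis window
#'
#' Runs the hydrogen-bond (and optionally pi-pi) detector on every frame of
#' the window and aggregates: mean counts per frame split by partner class,
#' per-residue mean counts (filtered at `occupancy_threshold` mean bonds, the
#' "listed residues" convention), per-pair occupancy (fraction of window
#' frames present) and maximal contiguous lifetime fraction.
#'
#' @param trajectory a `Trajectory` with a topology.
#' @param criteria a [hbond_criteria()].
#' @param pipi a [pipi_criteria()], or `NULL` to skip ring stacking.
#' @param window `c(start, end)` ps, or `NULL` for all frames.
#' @param occupancy_threshold per-residue mean-count filter.
#' @param focus molecule class whose contacts are summarised.
#' @param intramolecular include same-residue hydrogen bonds?
#' @return object of class `InteractionSummary`.
#' @export
summarize_interactions <- function(trajectory, criteria = hbond_criteria(),
                                   pipi = NULL, window = NULL,
                                   occupancy_threshold = 0.3,
                                   focus = "ligand",
                                   intramolecular = FALSE) {
  topo <- trajectory$topology
  if (is.null(topo)) stop("trajectory carries no topology; annotate first")
  tw <- trajectory_window(trajectory, window)
  nf <- n_frames(tw)
  per_frame <- vector("list", nf)
  pipi_count <- numeric(nf)
  for (i in seq_len(nf)) {
    hb <- hbond_frame(topo, tw$frames[[i]], criteria,
                      intramolecular = intramolecular, focus = focus)
    hb$frame <- rep(i, nrow(hb))
    per_frame[[i]] <- hb
    if (!is.null(pipi))
      pipi_count[i] <- nrow(pipi_frame(topo, tw$frames[[i]], pipi, focus))
  }
  rec <- do.call(rbind, per_frame)

  classes <- c("solvent", "protein", "intramolecular", "ion", "other")
  class_means <- vapply(classes, function(cl)
    sum(rec$partner_class == cl) / nf, numeric(1))
  total_mean <- nrow(rec) / nf

  pair_key <- paste(rec$donor, rec$hydrogen, rec$acceptor, sep = "-")
  pairs <- unique(data.frame(key = pair_key, donor = rec$donor,
                             hydrogen = rec$hydrogen, acceptor = rec$acceptor,
                             donor_residue = rec$donor_residue,
                             acceptor_residue = rec$acceptor_residue,
                             partner_class = rec$partner_class,
                             stringsAsFactors = FALSE))
  occ <- lifetime <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    fr <- rec$frame[pair_key == pairs$key[p]]
    present <- logical(nf); present[fr] <- TRUE
    occ[p] <- mean(present)
    runs <- rle(present)
    lifetime[p] <- max(c(0, runs$lengths[runs$values])) / nf
  }
  pairs$occupancy <- occ
  pairs$mean_count <- occ
  pairs$lifetime_fraction <- lifetime
  pairs <- pairs[order(-pairs$occupancy), ]
  rownames(pairs) <- NULL

  # per-residue means on the partner (non-focus) side
  mol <- atom_molecule_class(topo)
  part_res <- ifelse(mol[rec$donor] == focus, rec$acceptor_residue,
                     rec$donor_residue)
  touches_focus <- mol[rec$donor] == focus | mol[rec$acceptor] == focus
  res_tab <- if (any(touches_focus)) {
    t0 <- table(part_res[touches_focus]) / nf
    df <- data.frame(residue = names(t0), mean_count = as.numeric(t0),
                     stringsAsFactors = FALSE)
    df[order(-df$mean_count), , drop = FALSE]
  } else data.frame(residue = character(0), mean_count = numeric(0))
  rownames(res_tab) <- NULL

  structure(list(
    n_frames = nf, total_mean = total_mean,
    class_means = class_means,
    pipi_mean = if (is.null(pipi)) NA_real_ else mean(pipi_count),
    pairs = pairs,
    per_residue = res_tab,
    listed_residues = res_tab[res_tab$mean_count > occupancy_threshold, ,
                              drop = FALSE],
    occupancy_threshold = occupancy_threshold,
    records = rec, focus = focus), class = "InteractionSummary")
}

#' @export
print.InteractionSummary <- function(x, ...) {
  cat("<InteractionSummary> over", x$n_frames, "frames\n")
  cat(sprintf("  mean H-bonds/frame: %.2f (solvent %.2f, protein %.2f, intramolecular %.2f)\n",
              x$total_mean, x$class_means["solvent"],
              x$class_means["protein"], x$class_means["intramolecular"]))
  if (!is.na(x$pipi_mean))
    cat(sprintf("  mean pi-pi contacts/frame: %.2f\n", x$pipi_mean))
  if (nrow(x$listed_residues) > 0) {
    cat("  residues above threshold", x$occupancy_threshold, ":\n")
    print(utils::head(x$listed_residues, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Filter hydrogen-bond records down to salt bridges
#'
#' A salt bridge is a hydrogen bond whose donor-side residue and
#' acceptor-side residue carry opposite charges, restricted to side-chain
#' atoms (backbone N/H/O excluded). This is a definitional choice: studies
#' often assert the dominance of salt bridges without defining them, so the
#' rule is configurable through `charge_pairs`.
#'
#' @param records hydrogen-bond records (from [hbond_frame()] or
#'   `summary$records`).
#' @param topology the annotated `Topology` the records refer to.
#' @param charge_pairs 2-column matrix of admissible (donor-side,
#'   acceptor-side) charge classes.
#' @return the subset of `records` that are salt bridges.
#' @export
salt_bridge_filter <- function(records, topology,
                               charge_pairs = rbind(c("positive", "negative"),
                                                    c("negative", "positive"))) {
  check_annotated(topology)
  if (nrow(records) == 0L) return(records)
  chg <- atom_charge_class(topology)
  nm <- topology$atoms$name
  side_chain <- !(nm[records$donor] %in% BACKBONE_NAMES) &
    !(nm[records$acceptor] %in% BACKBONE_NAMES)
  pair <- paste(chg[records$donor], chg[records$acceptor])
  ok <- pair %in% paste(charge_pairs[, 1], charge_pairs[, 2])
  records[side_chain & ok, , drop = FALSE]
}

#' Salt-bridge percentage of the hydrogen-bond total
#'
#' `100 * mean salt bridges / mean hydrogen bonds`, reported truncated to an
#' integer. Truncation (not rounding) is the convention that reproduces the
#' printed percentages of the reference bookkeeping (11.2 bonds of which 8.8
#' bridges gives 78); see the methods vignette for the one historical row
#' this convention cannot reproduce.
#'
#' @param mean_hbonds mean hydrogen bonds per frame.
#' @param mean_saltbridges mean salt bridges per frame.
#' @return list with `percentage` (integer) and `defined` (FALSE when there
#'   are no hydrogen bonds, in which case the percentage is `NA`, flagged
#'   rather than zero).
#' @export
salt_bridge_percentage <- function(mean_hbonds, mean_saltbridges) {
  if (mean_hbonds <= 0)
    return(list(percentage = NA_integer_, defined = FALSE))
  list(percentage = as.integer(trunc(100 * mean_saltbridges / mean_hbonds)),
       defined = TRUE)
}
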