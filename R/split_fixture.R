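## Partner-split fixture: plant a trajectory whose ligand hydrogen-bond
## means, split by partner class, equal stated targets exactly. This is how
## the package emulates the printed per-partner bookkeeping (e.g. a total of
## 19.2 ligand bonds of which 4.4 with the protein and 14.8 with water):
## the stated splits are the generator inputs, the detector is the
## measurement, and at zero jitter the closed loop is an identity.

# evenly spread unit vectors (golden-angle spiral), capped away from the
# protein side (+y); used so several planted partners can share an atom or a
# crowded region without clashing
dirs_hemisphere <- function(n, y_range = c(-0.95, 0.6)) {
  k <- seq_len(n)
  y <- seq(y_range[1], y_range[2], length.out = max(n, 2))[k]
  th <- k * 2.399963
  r <- sqrt(1 - y^2)
  cbind(r * cos(th), y, r * sin(th))
}

# split a target mean into per-pair occupancies <= 1 (full pairs + remainder)
split_occupancies <- function(total, capacity) {
  if (total > capacity + 1e-9)
    stop("target mean ", total, " exceeds pair capacity ", capacity)
  full <- floor(total + 1e-9)
  rem <- total - full
  occ <- rep(1, full)
  if (rem > 1e-9) occ <- c(occ, rem)
  occ
}

#' Plant a trajectory with target per-class hydrogen-bond means
#'
#' Builds planted interaction schedules so that, over `n_frames`, the mean
#' number of ligand hydrogen bonds with the solvent equals `solvent_mean`
#' and with the protein equals `protein_mean` (both exactly representable
#' when `target * n_frames` is an integer). Solvent bonds use the ligand
#' hydroxyls as donors first, then waters donating into ligand oxygens;
#' protein bonds use backbone amides donating into ligand oxygens. Approach
#' directions are spread on a hemisphere so shared acceptors never clash.
#'
#' @param solvent_mean target mean ligand-water bonds per frame (<= 20).
#' @param protein_mean target mean ligand-protein bonds per frame (<= 7).
#' @param spec a [fixture_spec()].
#' @param complex optional [make_toy_complex()] (needs enough waters).
#' @return a `Trajectory` (with the planted manifest attribute).
#' @export
plant_partner_split <- function(solvent_mean, protein_mean,
                                spec = fixture_spec(n_frames = 1000),
                                complex = NULL) {
  n_solvent_pairs <- length(split_occupancies(solvent_mean, 20))
  if (is.null(complex))
    complex <- make_toy_complex(n_water = min(30, max(20, n_solvent_pairs)))
  at <- complex$structure$atoms
  find <- function(res, name) which(at$residue_index == res & at$name == name)

  lig_oh <- list(c("O5A", "HO5A"), c("O7A", "HO7A"), c("O3B", "HO3B"),
                 c("O4B", "HO4B"), c("O5B", "HO5B"), c("O3G", "HO3G"),
                 c("O4G", "HO4G"), c("O5G", "HO5G"))
  lig_acceptors <- c("O1C", "O3C", "O7G", "O5A", "O7A", "O3B", "O4B",
                     "O5B", "O3G", "O4G", "O5G")
  waters <- sort(unique(at$residue_index[at$residue_name == "HOH"]))
  bb_donors <- c(120L, 136L, 156L, 158L, 159L, 160L)  # backbone amides

  occ_s <- split_occupancies(solvent_mean, 20)
  occ_p <- split_occupancies(protein_mean, length(bb_donors))
  if (length(occ_s) > length(waters))
    stop("need ", length(occ_s), " waters; complex has ", length(waters))

  dirs <- dirs_hemisphere(64)
  candidates <- list()
  for (j in seq_along(occ_s)) {
    candidates[[length(candidates) + 1L]] <- if (j <= length(lig_oh)) {
      d <- lig_oh[[j]]
      list(donor = find(201, d[1]), hydrogen = find(201, d[2]),
           acceptor = find(waters[j], "O"), mobile = "acceptor",
           occupancy = occ_s[j])
    } else {
      rot <- (seq_along(lig_acceptors) + j - length(lig_oh) - 2L) %%
        length(lig_acceptors) + 1L
      list(donor = find(waters[j], "O"), hydrogen = find(waters[j], "H1"),
           acceptor_options = vapply(lig_acceptors[rot], function(nm)
             find(201, nm), integer(1)),
           mobile = "donor", occupancy = occ_s[j])
    }
  }
  for (j in seq_along(occ_p)) {
    rot <- (seq_along(lig_acceptors) + j + 1L) %% length(lig_acceptors) + 1L
    candidates[[length(candidates) + 1L]] <-
      list(donor = find(bb_donors[j], "N"), hydrogen = find(bb_donors[j], "H"),
           acceptor_options = vapply(lig_acceptors[rot], function(nm)
             find(201, nm), integer(1)),
           mobile = "donor", occupancy = occ_p[j])
  }

  # choose an approach direction per pair so that the detector sees exactly
  # the planted set: each candidate direction is probed (all accepted pairs
  # "on" plus the new one "on", then the new one "off") before acceptance
  topo <- complex$topology
  probe_bonds <- function(plans, states) {
    P <- complex$structure$positions
    for (k in seq_along(plans))
      P[plans[[k]]$atoms, ] <- if (states[k]) plans[[k]]$on else plans[[k]]$off
    hb <- hbond_frame(topo, P)
    sort(paste(hb$donor, hb$hydrogen, hb$acceptor))
  }
  expected_key <- function(pairs)
    sort(vapply(pairs, function(p)
      paste(p$donor, p$hydrogen, p$acceptor), character(1)))

  accepted <- list(); plans <- list(); ints <- list()
  for (cand in candidates) {
    placed <- FALSE
    acc_opts <- if (is.null(cand$acceptor_options)) cand$acceptor
    else cand$acceptor_options
    for (acc in acc_opts) {
      cand$acceptor <- acc
      for (k in seq_len(nrow(dirs))) {
        it <- planted_interaction(
          "hbond", donor = cand$donor, hydrogen = cand$hydrogen,
          acceptor = acc, target_occupancy = cand$occupancy,
          episode_length = 25L, mobile = cand$mobile, direction = dirs[k, ])
        plan <- build_plant_plan(complex, it)
        trial_plans <- c(plans, list(plan))
        # complete pairwise state coverage: a spurious contact involves the
        # atoms of at most two planted pairs, so probing the four on/off
        # state combinations of the candidate against the accepted set is
        # exhaustive
        n_acc <- length(plans)
        ok <- identical(probe_bonds(trial_plans, rep(TRUE, n_acc + 1L)),
                        expected_key(c(accepted, list(cand)))) &&
          identical(probe_bonds(trial_plans, c(rep(TRUE, n_acc), FALSE)),
                    expected_key(accepted)) &&
          identical(probe_bonds(trial_plans, c(rep(FALSE, n_acc), TRUE)),
                    expected_key(list(cand))) &&
          identical(probe_bonds(trial_plans, rep(FALSE, n_acc + 1L)),
                    character(0))
        if (ok) {
          accepted <- c(accepted, list(cand))
          plans <- trial_plans
          ints[[length(ints) + 1L]] <- it
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed)
      stop("could not place a planted pair without side contacts; ",
           "reduce the target means")
  }

  # final sweep: every leave-one-out and the all-off state must also be
  # exactly what was planted (guards against mixed-state side contacts
  # involving pairs placed later)
  for (round in 1:3) {
    clean <- TRUE
    for (j in seq_along(plans)) {
      st <- rep(TRUE, length(plans)); st[j] <- FALSE
      if (!identical(probe_bonds(plans, st), expected_key(accepted[-j]))) {
        clean <- FALSE
        for (k in seq_len(nrow(dirs))) {
          it <- planted_interaction(
            "hbond", donor = accepted[[j]]$donor,
            hydrogen = accepted[[j]]$hydrogen,
            acceptor = accepted[[j]]$acceptor,
            target_occupancy = accepted[[j]]$occupancy,
            episode_length = 25L, mobile = accepted[[j]]$mobile,
            direction = dirs[k, ])
          trial <- plans; trial[[j]] <- build_plant_plan(complex, it)
          on_ok <- identical(probe_bonds(trial, rep(TRUE, length(trial))),
                             expected_key(accepted))
          off_ok <- identical(probe_bonds(trial, st),
                              expected_key(accepted[-j]))
          if (on_ok && off_ok) { plans <- trial; ints[[j]] <- it; break }
        }
      }
    }
    if (clean) break
  }
  if (!identical(probe_bonds(plans, rep(FALSE, length(plans))),
                 character(0)))
    stop("all-off probe frame still shows contacts; fixture geometry bug")
  plant_trajectory(spec, ints, complex = complex)
}
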