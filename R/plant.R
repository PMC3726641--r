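## Planted-interaction trajectory generator. Geometries are constructed
## analytically (donor-H-acceptor collinear at 2.9 A for "on" frames,
## stretched to 4.5 A for "off"), never energy-minimised: the pipeline
## tests detectors, not physics. Episodes are contiguous so lifetime
## statistics are recoverable too.

#' Fixture specification
#'
#' @param seed RNG seed; every generator downstream is deterministic in it.
#' @param n_frames number of frames (>= 1).
#' @param timestep frame spacing, ps.
#' @param jitter_sigma per-axis Gaussian positional noise, Angstrom (>= 0).
#' @return object of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1L, n_frames = 100L, timestep = 10,
                         jitter_sigma = 0) {
  stopifnot(n_frames >= 1, jitter_sigma >= 0, timestep > 0)
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 timestep = timestep, jitter_sigma = jitter_sigma),
            class = "FixtureSpec")
}

#' Declare a planted interaction
#'
#' For `kind = "hbond"` and `"saltbridge"` give the donor heavy atom, its
#' hydrogen and the acceptor; for `"pipi"` give a topology ring name
#' (`ring_a`, e.g. `"PHE156.ring"`) and a mobile ligand ring unit name
#' (`ring_b`, one of `"A"`, `"B"`, `"G"`).
#'
#' @param kind one of `"hbond"`, `"saltbridge"`, `"pipi"`.
#' @param donor,hydrogen,acceptor atom indices (H-bond kinds).
#' @param ring_a,ring_b ring identifiers (pi-pi kind).
#' @param target_occupancy fraction of frames in the "on" state, in `[0, 1]`.
#' @param episode_length length of each contiguous "on" episode, frames.
#' @param mobile which side is repositioned: `"acceptor"` (default) or
#'   `"donor"`. The mobile atom moves along the rest-geometry axis joining
#'   the pair, together with its bonded hydrogens.
#' @param direction optional unit 3-vector replacing the rest-geometry
#'   approach axis; lets several partners share one atom from distinct
#'   directions without clashing.
#' @return object of class `PlantedInteraction`.
#' @export
planted_interaction <- function(kind = c("hbond", "saltbridge", "pipi"),
                                donor = NULL, hydrogen = NULL,
                                acceptor = NULL, ring_a = NULL, ring_b = NULL,
                                target_occupancy = 0.5, episode_length = 10L,
                                mobile = c("acceptor", "donor"),
                                direction = NULL) {
  kind <- match.arg(kind)
  mobile <- match.arg(mobile)
  if (!is.null(direction)) {
    stopifnot(length(direction) == 3, sum(direction^2) > 0)
    direction <- direction / sqrt(sum(direction^2))
  }
  if (target_occupancy < 0 || target_occupancy > 1)
    stop("target_occupancy must be in [0, 1]")
  if (episode_length < 1) stop("episode_length must be >= 1")
  if (kind == "pipi") {
    if (is.null(ring_a) || is.null(ring_b))
      stop("pipi interactions need ring_a and ring_b")
  } else if (is.null(donor) || is.null(hydrogen) || is.null(acceptor)) {
    stop(kind, " interactions need donor, hydrogen and acceptor atom indices")
  }
  structure(list(kind = kind, donor = donor, hydrogen = hydrogen,
                 acceptor = acceptor, ring_a = ring_a, ring_b = ring_b,
                 target_occupancy = target_occupancy,
                 episode_length = as.integer(episode_length), mobile = mobile,
                 direction = direction),
            class = "PlantedInteraction")
}

#' Ion mobility model for a calcium site
#'
#' Positions are sampled as `anchor + drift * t_ns + N(0, sigma^2 I3)`; a
#' non-zero drift emulates a site that relocates over the run.
#'
#' @param site_label `"I"` or `"II"`.
#' @param anchor 3-vector, Angstrom; `NULL` uses the site's rest position.
#' @param sigma isotropic positional spread, Angstrom (>= 0).
#' @param drift 3-vector, Angstrom per ns.
#' @return object of class `IonSiteModel`.
#' @export
ion_site_model <- function(site_label = c("I", "II"), anchor = NULL,
                           sigma = 0.5, drift = c(0, 0, 0)) {
  site_label <- match.arg(site_label)
  stopifnot(sigma >= 0, length(drift) == 3)
  structure(list(site_label = site_label, anchor = anchor, sigma = sigma,
                 drift = as.numeric(drift)), class = "IonSiteModel")
}

# contiguous-episode on/off schedule; exact: ceiling(occ * n) "on" frames
make_schedule <- function(n_frames, occupancy, episode_length) {
  # epsilon guards the exact-representability cases (0.8 * 400 is 320 + 2e-13
  # in floating point and must not ceiling up to 321)
  n_on <- as.integer(ceiling(occupancy * n_frames - 1e-9))
  n_on <- max(n_on, 0L)
  if (n_on == 0L) return(rep(FALSE, n_frames))
  if (n_on > n_frames)
    stop("infeasible occupancy schedule: ", n_on, " on-frames > ",
         n_frames, " frames")
  L <- min(episode_length, n_on)
  k <- as.integer(ceiling(n_on / L))
  ep_len <- c(rep(L, k - 1L), n_on - (k - 1L) * L)
  off <- n_frames - n_on
  # spread the off frames evenly over the k+1 gaps (cumulative rounding),
  # so episodes merge uniformly when off frames are scarce
  gap <- diff(round((0:(k + 1L)) * off / (k + 1L)))
  out <- logical(0)
  for (j in seq_len(k)) out <- c(out, rep(FALSE, gap[j]), rep(TRUE, ep_len[j]))
  c(out, rep(FALSE, gap[k + 1L]))
}

# hydrogens bonded to a heavy atom, by rest-geometry distance < 1.3 A within
# the same residue; used to carry a mobile acceptor's protons along
attached_hydrogens <- function(complex, atom) {
  at <- complex$structure$atoms; pos <- complex$structure$positions
  same <- which(at$residue_index == at$residue_index[atom] &
                  at$chain_id == at$chain_id[atom] & at$element == "H")
  if (length(same) == 0L) return(integer(0))
  d <- sqrt(rowSums((pos[same, , drop = FALSE] -
                       matrix(pos[atom, ], length(same), 3, TRUE))^2))
  same[d < 1.3]
}

plane_normal <- function(coords) {
  c0 <- colMeans(coords)
  sv <- svd(sweep(coords, 2, c0))
  n <- sv$v[, 3]
  n / sqrt(sum(n^2))
}

rot_between <- function(u, v) {
  # rotation matrix taking unit vector u onto unit vector v
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {                     # pick any perpendicular axis
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- a - sum(a * u) * u; ax <- ax / sqrt(sum(ax^2))
    return(rot_axis_angle(ax, pi))
  }
  ax <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2)); ax <- ax / s
  rot_axis_angle(ax, atan2(s, c_))
}

rot_axis_angle <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# geometric realisation of one planted interaction: which atoms move and
# their "on"/"off" coordinates; shared by plant_trajectory() and the
# self-verifying fixture builders
build_plant_plan <- function(complex, it) {
  st <- complex$structure; topo <- complex$topology
  P0 <- st$positions; na <- nrow(P0)
  if (it$kind == "pipi") {
    ra <- topo$rings[[it$ring_a]]
    if (is.null(ra)) stop("unknown topology ring '", it$ring_a, "'")
    unit <- complex$ring_units[[it$ring_b]]
    if (is.null(unit)) stop("unknown ligand ring unit '", it$ring_b, "'")
    ring_b_atoms <- unit[1:6]
    ca <- colMeans(P0[ra, , drop = FALSE])
    na_ <- plane_normal(P0[ra, , drop = FALSE])
    cb <- colMeans(P0[ring_b_atoms, , drop = FALSE])
    nb <- plane_normal(P0[ring_b_atoms, , drop = FALSE])
    R_on <- rot_between(nb, na_)
    base <- sweep(P0[unit, , drop = FALSE], 2, cb)
    on_pos <- base %*% t(R_on) +
      matrix(ca + 3.5 * na_, length(unit), 3, byrow = TRUE)
    perp <- if (abs(na_[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * na_) * na_; perp <- perp / sqrt(sum(perp^2))
    R_off <- rot_axis_angle(perp, pi / 3) %*% R_on
    off_pos <- base %*% t(R_off) +
      matrix(ca + 6.5 * na_, length(unit), 3, byrow = TRUE)
    return(list(kind = "pipi", atoms = unit, on = on_pos, off = off_pos,
                ring_b_atoms = ring_b_atoms))
  }
  d <- it$donor; h <- it$hydrogen; a <- it$acceptor
  for (ix in c(d, h, a)) if (ix < 1 || ix > na)
    stop("planted atom index ", ix, " outside the complex")
  if (!is.null(it$direction)) {
    u <- it$direction
  } else {
    u <- P0[a, ] - P0[d, ]
    ru <- sqrt(sum(u^2))
    if (ru < 1e-9)
      stop("donor and acceptor coincide in the rest geometry")
    u <- u / ru
  }
  # two O-H directions at ~104 deg, both leaning along `axis`; keeps a
  # mobile water's own protons pointed away from the partner
  h_dirs <- function(axis) {
    p <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    p <- p - sum(p * axis) * axis; p <- p / sqrt(sum(p^2))
    v1 <- axis + 0.9 * p; v2 <- axis - 0.9 * p
    rbind(v1 / sqrt(sum(v1^2)), v2 / sqrt(sum(v2^2)))
  }
  carried_at <- function(tgt, hd, carried) {
    if (length(carried) == 0L) return(matrix(numeric(0), 0, 3))
    matrix(tgt, length(carried), 3, byrow = TRUE) +
      0.96 * hd[seq_along(carried), , drop = FALSE]
  }
  if (it$mobile == "acceptor") {
    carried <- setdiff(attached_hydrogens(complex, a), a)
    hd <- h_dirs(u)
    mk <- function(r) {
      tgt <- P0[d, ] + r * u
      rbind(P0[d, ] + 1.0 * u,                       # donor hydrogen
            matrix(tgt, 1, 3),
            carried_at(tgt, hd, carried))
    }
    atoms_moved <- c(h, a, carried)
  } else {
    carried <- setdiff(attached_hydrogens(complex, d), c(d, h))
    hd <- h_dirs(-u)
    mk <- function(r) {
      tgt <- P0[a, ] - r * u                          # donor heavy
      rbind(matrix(tgt, 1, 3),
            tgt + 1.0 * u,                            # hydrogen, toward A
            carried_at(tgt, hd, carried))
    }
    atoms_moved <- c(d, h, carried)
  }
  list(kind = "hb", atoms = atoms_moved, on = mk(2.9), off = mk(4.5),
       donor = d, hydrogen = h, acceptor = a)
}

#' Generate a trajectory with planted interactions
#'
#' Starting from the rest geometry of a [make_toy_complex()], each frame (i)
#' realises every planted interaction's on/off state per its contiguous
#' episode schedule, (ii) adds iid per-axis Gaussian jitter of
#' `spec$jitter_sigma` to all atoms, then (iii) samples the ion positions
#' from their [ion_site_model()]s. "On" hydrogen bonds are collinear with a
#' donor-acceptor distance of 2.9 A; "off" frames are stretched to 4.5 A
#' along the same axis. "On" pi-pi contacts are parallel rings 3.5 A apart
#' along the fixed ring's normal; "off" rings are tilted by 60 degrees at
#' 6.5 A. Generation is seed-deterministic.
#'
#' The planted truth is attached as `attr(, "planted")`: one entry per
#' interaction with its atom indices, schedule and realised occupancy.
#'
#' @param spec a [fixture_spec()].
#' @param interactions list of [planted_interaction()]s.
#' @param ions list of [ion_site_model()]s.
#' @param complex a [make_toy_complex()]; built with defaults if omitted.
#' @return a `Trajectory` carrying the complex's topology.
#' @export
plant_trajectory <- function(spec, interactions = list(), ions = list(),
                             complex = make_toy_complex()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  if (inherits(interactions, "PlantedInteraction"))
    interactions <- list(interactions)
  if (inherits(ions, "IonSiteModel")) ions <- list(ions)
  st <- complex$structure; topo <- complex$topology
  P0 <- st$positions; na <- nrow(P0)
  n <- spec$n_frames
  set.seed(spec$seed)

  planted <- vector("list", length(interactions))
  plans <- vector("list", length(interactions))
  for (q in seq_along(interactions)) {
    it <- interactions[[q]]
    if (!inherits(it, "PlantedInteraction"))
      stop("interactions[[", q, "]] is not a PlantedInteraction")
    sched <- make_schedule(n, it$target_occupancy, it$episode_length)
    plan <- build_plant_plan(complex, it)
    plan$sched <- sched
    plans[[q]] <- plan
    planted[[q]] <- if (it$kind == "pipi") {
      list(kind = "pipi", ring_a = it$ring_a,
           ring_b_atoms = plan$ring_b_atoms, schedule = sched,
           target_occupancy = it$target_occupancy,
           realized_occupancy = mean(sched))
    } else {
      list(kind = it$kind, donor = it$donor, hydrogen = it$hydrogen,
           acceptor = it$acceptor, schedule = sched,
           target_occupancy = it$target_occupancy,
           realized_occupancy = mean(sched))
    }
  }

  ion_plan <- list()
  for (m in ions) {
    stopifnot(inherits(m, "IonSiteModel"))
    atom <- complex$ion_sites[[m$site_label]]
    anchor <- if (is.null(m$anchor)) P0[atom, ] else as.numeric(m$anchor)
    ion_plan[[length(ion_plan) + 1L]] <-
      list(atom = atom, anchor = anchor, sigma = m$sigma, drift = m$drift)
  }

  frames <- vector("list", n)
  for (i in seq_len(n)) {
    P <- P0
    for (pl in plans) {
      P[pl$atoms, ] <- if (pl$sched[i]) pl$on else pl$off
    }
    if (spec$jitter_sigma > 0)
      P <- P + matrix(rnorm(3 * na, 0, spec$jitter_sigma), na, 3)
    t_ps <- (i - 1) * spec$timestep
    for (ip in ion_plan) {
      P[ip$atom, ] <- ip$anchor + ip$drift * (t_ps / 1000) +
        rnorm(3, 0, ip$sigma)
    }
    frames[[i]] <- new_frame(time = t_ps, positions = P)
  }
  traj <- new_trajectory(st$atoms, frames, timestep = spec$timestep,
                         topology = topo)
  attr(traj, "planted") <- planted
  traj
}
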