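# Independent brute-force oracles and random fixtures. These deliberately
# use plain scalar loops and a different normal construction than the
# package implementation, so agreement is informative.

# exhaustive hydrogen-bond oracle: plain triple loop over donors x acceptors
oracle_hbonds <- function(topology, pos, criteria = hbond_criteria(),
                          intramolecular = FALSE) {
  dn <- topology$donors
  ac <- topology$acceptors
  res <- paste(topology$atoms$chain_id, topology$atoms$residue_index)
  out <- character(0)
  for (i in seq_len(nrow(dn))) {
    d <- dn$heavy[i]; h <- dn$hydrogen[i]
    for (j in seq_len(nrow(ac))) {
      a <- ac$atom[j]
      if (a == d || a == h) next
      if (!intramolecular && res[a] == res[d]) next
      cutoff <- if (ac$class[j] == "S") criteria$da_cutoff_sulphur
      else criteria$da_cutoff
      dist <- sqrt(sum((pos[d, ] - pos[a, ])^2))
      if (dist >= cutoff) next
      v1 <- pos[d, ] - pos[h, ]; v2 <- pos[a, ] - pos[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang > criteria$dha_min_angle)
        out <- c(out, paste(d, h, a))
    }
  }
  sort(out)
}

# exhaustive pi-pi oracle; ring normal from an edge cross product (valid for
# the planar rings the fixtures generate), folded angle
oracle_pipi <- function(topology, pos, criteria = pipi_criteria()) {
  rings <- topology$rings
  res <- paste(topology$atoms$chain_id, topology$atoms$residue_index)
  nm <- names(rings)
  out <- character(0)
  ring_normal <- function(ix) {
    e1 <- pos[ix[2], ] - pos[ix[1], ]
    e2 <- pos[ix[3], ] - pos[ix[1], ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    n / sqrt(sum(n^2))
  }
  for (i in seq_along(rings)) for (j in seq_along(rings)) {
    if (j <= i) next
    if (res[rings[[i]][1]] == res[rings[[j]][1]]) next
    ci <- colMeans(pos[rings[[i]], , drop = FALSE])
    cj <- colMeans(pos[rings[[j]], , drop = FALSE])
    if (sqrt(sum((ci - cj)^2)) >= criteria$centroid_cutoff) next
    ang <- acos(min(1, abs(sum(ring_normal(rings[[i]]) *
                                 ring_normal(rings[[j]]))))) * 180 / pi
    if (ang < criteria$normal_max_angle)
      out <- c(out, paste(sort(c(nm[i], nm[j])), collapse = "|"))
  }
  sort(out)
}

# random annotated fixture: donors, ON/S acceptors and planar hexagon rings
# scattered in a box; everything is placed directly, no templates
random_contact_fixture <- function(seed, n_extra = 60, n_donors = 15,
                                   n_acceptors = 15, n_rings = 4,
                                   box = 14) {
  set.seed(seed)
  atoms <- list(); pos <- list(); donors <- list()
  acc_atom <- integer(0); acc_class <- character(0); rings <- list()
  idx <- 0L
  push <- function(name, element, resi) {
    idx <<- idx + 1L
    atoms[[idx]] <<- data.frame(atom_id = idx, name = name,
                                element = element, residue_name = "UNK",
                                residue_index = resi, chain_id = "A",
                                stringsAsFactors = FALSE)
    idx
  }
  resi <- 0L
  for (i in seq_len(n_donors)) {
    resi <- resi + 1L
    d <- push("DN", "N", resi); h <- push("DH", "H", resi)
    p <- runif(3, 0, box)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    pos[[d]] <- p; pos[[h]] <- p + u
    donors[[i]] <- c(d, h)
  }
  for (i in seq_len(n_acceptors)) {
    resi <- resi + 1L
    cls <- if (i %% 4 == 0) "S" else "ON"
    a <- push(if (cls == "S") "SD" else "AO",
              if (cls == "S") "S" else "O", resi)
    pos[[a]] <- runif(3, 0, box)
    acc_atom <- c(acc_atom, a); acc_class <- c(acc_class, cls)
  }
  hexagon_at <- function(center, axis, phase = 0) {
    axis <- axis / sqrt(sum(axis^2))
    ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    th <- phase + (0:5) * pi / 3
    t(vapply(th, function(a) center + 1.39 * (cos(a) * e1 + sin(a) * e2),
             numeric(3)))
  }
  for (r in seq_len(n_rings)) {
    resi <- resi + 1L
    coords <- hexagon_at(runif(3, 2, box - 2), rnorm(3), runif(1, 0, pi))
    ix <- integer(6)
    for (k in 1:6) { ix[k] <- push(paste0("C", k), "C", resi); pos[[ix[k]]] <- coords[k, ] }
    rings[[paste0("ring", r)]] <- ix
  }
  for (i in seq_len(n_extra)) {
    resi <- resi + 1L
    a <- push("CX", "C", resi); pos[[a]] <- runif(3, 0, box)
  }
  atoms <- do.call(rbind, atoms)
  pos <- do.call(rbind, pos)
  residues <- data.frame(residue_index = unique(atoms$residue_index),
                         residue_name = "UNK", chain_id = "A",
                         charge_class = "neutral",
                         molecule_class = "protein",
                         stringsAsFactors = FALSE)
  topo <- structure(list(
    atoms = atoms,
    donors = data.frame(heavy = vapply(donors, `[`, integer(1), 1),
                        hydrogen = vapply(donors, `[`, integer(1), 2)),
    acceptors = data.frame(atom = acc_atom, class = acc_class,
                           stringsAsFactors = FALSE),
    rings = rings, residues = residues,
    equivalence_groups = list(), dihedrals = list()), class = "Topology")
  list(topology = topo, positions = pos)
}

hbond_keys <- function(records)
  sort(paste(records$donor, records$hydrogen, records$acceptor))

pipi_keys <- function(records)
  sort(paste(records$ring_a, records$ring_b, sep = "|"))

# 4-atom trajectory realising a given torsion-angle series (degrees)
dihedral_trajectory <- function(angles) {
  atoms <- data.frame(atom_id = 1:4, name = c("A", "B", "C", "D"),
                      element = "C", residue_name = "UNK",
                      residue_index = 1L, chain_id = "A",
                      stringsAsFactors = FALSE)
  frames <- lapply(seq_along(angles), function(i) {
    th <- angles[i] * pi / 180
    new_frame(i - 1, rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1.5, 0),
                           c(0, 1.5, 0) + c(cos(th), 0, -sin(th))))
  })
  new_trajectory(atoms, frames)
}

toy_atom <- function(complex, residue, name)
  which(complex$structure$atoms$residue_index == residue &
          complex$structure$atoms$name == name)
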