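## Deterministic toy protein-ligand complex used by every fixture generator.
## The scaffold carries the residues that matter for a catechin/troponin-C
## style analysis: a methionine (sulphur acceptor + methyl CV group), leucine
## and valine (methyl CV groups), a phenylalanine (aromatic ring), a lysine
## and a glutamate (salt-bridge partners), a glycine, a three-ring catechin
## ligand with labelled aromatic protons (H12/H13, H16/H17, H9/H10) and three
## named rotatable dihedrals, two calcium sites and an optional water shell.
## Geometry is idealised and analytic - the package tests detectors, not
## physics - and repeated calls are bit-identical.

hexagon <- function(center, radius = 1.39, normal = c(0, 0, 1), phase = 0) {
  # 6 vertices of a planar hexagon; normal fixed to z here, callers rotate
  th <- phase + (0:5) * pi / 3
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th),
        center[3] + rep(0, 6))
}

#' Build the deterministic toy complex
#'
#' Constructs an idealised protein-like scaffold (Met120, Leu136, Phe156,
#' Lys158, Gly159, Val160, Glu161), a three-ring catechin ligand (`EGC`,
#' rings A, B and B'/G with aromatic protons H12/H13, H16/H17, H9/H10 and
#' dihedrals chi1/chi2/chi3), two calcium ions (sites I and II) and an
#' optional water shell, then annotates it with [annotate_topology()].
#'
#' Rest-state geometry is chosen so that no hydrogen bond, salt bridge or
#' pi-pi contact exists before interactions are planted by
#' [plant_trajectory()].
#'
#' @param n_water number of water molecules (0 to 30).
#' @return object of class `ToyComplex`: list with `structure`, `topology`,
#'   `ion_sites` (named atom indices for sites I and II), `ring_units`
#'   (atom-index sets that move rigidly with each ligand ring) and
#'   `cv_groups` (the three group-distance collective variables).
#' @export
make_toy_complex <- function(n_water = 20) {
  stopifnot(n_water >= 0, n_water <= 30)
  nm <- character(0); el <- character(0); rn <- character(0)
  ri <- integer(0); ch <- character(0); xyz <- NULL
  add <- function(names, elements, resname, resindex, chain, pos) {
    nm <<- c(nm, names); el <<- c(el, elements)
    rn <<- c(rn, rep(resname, length(names)))
    ri <<- c(ri, rep(resindex, length(names)))
    ch <<- c(ch, rep(chain, length(names)))
    xyz <<- rbind(xyz, pos)
  }
  backbone <- function(x0) rbind(
    c(x0 - 0.7, 0.6, 0),          # N
    c(x0 - 0.7, 1.6, 0),          # H
    c(x0, 0, 0),                  # CA
    c(x0 + 1.2, -0.6, 0),         # C
    c(x0 + 1.2, -1.8, 0))         # O
  bb_names <- c("N", "H", "CA", "C", "O")
  bb_el <- c("N", "H", "C", "C", "O")
  methyl_h <- function(c0) rbind(c0 + c(1.04, 0.37, 0),
                                 c0 + c(-0.52, 0.37, 0.90),
                                 c0 + c(-0.52, 0.37, -0.90))

  # --- protein chain A -------------------------------------------------------
  # MET120
  x0 <- 0
  add(bb_names, bb_el, "MET", 120L, "A", backbone(x0))
  ce <- c(x0, 6.3, 0)
  add(c("CB", "CG", "SD", "CE", "HE1", "HE2", "HE3"),
      c("C", "C", "S", "C", "H", "H", "H"), "MET", 120L, "A",
      rbind(c(x0, 1.5, 0), c(x0, 3.0, 0), c(x0, 4.8, 0), ce, methyl_h(ce)))
  # LEU136
  x0 <- 9
  add(bb_names, bb_el, "LEU", 136L, "A", backbone(x0))
  cd1 <- c(x0 + 0.9, 4.2, 0); cd2 <- c(x0 - 0.9, 4.2, 0)
  add(c("CB", "CG", "CD1", "HD11", "HD12", "HD13",
        "CD2", "HD21", "HD22", "HD23"),
      c("C", "C", "C", "H", "H", "H", "C", "H", "H", "H"), "LEU", 136L, "A",
      rbind(c(x0, 1.5, 0), c(x0, 3.0, 0), cd1, methyl_h(cd1),
            cd2, methyl_h(cd2)))
  # PHE156: ring in the x-y plane, CG at the bottom vertex
  x0 <- 18
  add(bb_names, bb_el, "PHE", 156L, "A", backbone(x0))
  ring <- hexagon(c(x0, 4.4, 0), phase = -pi / 2)
  add(c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
      c("C", "C", "C", "C", "C", "C", "C"), "PHE", 156L, "A",
      rbind(c(x0, 1.5, 0), ring))
  # LYS158
  x0 <- 27
  add(bb_names, bb_el, "LYS", 158L, "A", backbone(x0))
  nz <- c(x0, 7.5, 0)
  add(c("CB", "CG", "CD", "CE", "NZ", "HZ1", "HZ2", "HZ3"),
      c("C", "C", "C", "C", "N", "H", "H", "H"), "LYS", 158L, "A",
      rbind(c(x0, 1.5, 0), c(x0, 3.0, 0), c(x0, 4.5, 0), c(x0, 6.0, 0), nz,
            methyl_h(nz)))
  # GLY159
  add(bb_names, bb_el, "GLY", 159L, "A", backbone(33))
  # VAL160
  x0 <- 39
  add(bb_names, bb_el, "VAL", 160L, "A", backbone(x0))
  cg1 <- c(x0 + 0.9, 2.7, 0); cg2 <- c(x0 - 0.9, 2.7, 0)
  add(c("CB", "CG1", "HG11", "HG12", "HG13", "CG2", "HG21", "HG22", "HG23"),
      c("C", "C", "H", "H", "H", "C", "H", "H", "H"), "VAL", 160L, "A",
      rbind(c(x0, 1.5, 0), cg1, methyl_h(cg1), cg2, methyl_h(cg2)))
  # GLU161
  x0 <- 45
  add(bb_names, bb_el, "GLU", 161L, "A", backbone(x0))
  add(c("CB", "CG", "CD", "OE1", "OE2"),
      c("C", "C", "C", "O", "O"), "GLU", 161L, "A",
      rbind(c(x0, 1.5, 0), c(x0, 3.0, 0), c(x0, 4.5, 0),
            c(x0 + 1.0, 5.25, 0), c(x0 - 1.0, 5.25, 0)))

  # --- ligand (chain L, residue EGC 201) ------------------------------------
  oh <- function(cpos, center) {
    # hydroxyl O at 1.4 A radially out from the ring carbon, H 0.96 beyond
    u <- (cpos - center) / sqrt(sum((cpos - center)^2))
    rbind(cpos + 1.4 * u, cpos + 2.36 * u)
  }
  arh <- function(cpos, center) {
    u <- (cpos - center) / sqrt(sum((cpos - center)^2))
    cpos + 1.09 * u
  }
  cA <- c(18, -12, 0)
  rA <- hexagon(cA)                     # C1A..C6A at phases 0,60,...
  cB <- c(22.2, -8.2, 0)
  rB <- hexagon(cB, phase = -pi / 2)    # C1B at bottom vertex
  o1c <- rA[1, ] + c(1.4, 0, 0)
  c2c <- o1c + c(1.1, 1.0, 0)
  c3c <- c2c + c(1.4, -0.6, 0.2)
  o3c <- c3c + c(0.3, -1.3, 0.3)
  c7g <- o3c + c(1.2, -0.6, 0.2)
  o7g <- c7g + c(0.6, 1.05, 0)
  c1g_dir <- c(0.63, -0.77, 0)
  c1g <- c7g + 1.45 * c1g_dir
  cG <- c1g + 1.39 * c1g_dir
  phG <- atan2(c1g[2] - cG[2], c1g[1] - cG[1])
  rG <- hexagon(cG, phase = phG)        # C1G at the vertex facing C7G

  lig <- function(names, elements, pos) add(names, elements, "EGC", 201L, "L", pos)
  lig(paste0("C", 1:6, "A"), rep("C", 6), rA)
  lig(c("H12", "H13"), c("H", "H"), rbind(arh(rA[2, ], cA), arh(rA[3, ], cA)))
  lig(c("O5A", "HO5A"), c("O", "H"), oh(rA[5, ], cA))
  lig(c("O7A", "HO7A"), c("O", "H"), oh(rA[6, ], cA))
  lig(c("O1C", "C2C", "H2C", "C3C", "H3C"), c("O", "C", "H", "C", "H"),
      rbind(o1c, c2c, c2c + c(-0.4, 0.4, 0.9), c3c, c3c + c(0.4, 0.5, 0.85)))
  lig(paste0("C", 1:6, "B"), rep("C", 6), rB)
  lig(c("H16", "H17"), c("H", "H"), rbind(arh(rB[2, ], cB), arh(rB[6, ], cB)))
  lig(c("O3B", "HO3B"), c("O", "H"), oh(rB[3, ], cB))
  lig(c("O4B", "HO4B"), c("O", "H"), oh(rB[4, ], cB))
  lig(c("O5B", "HO5B"), c("O", "H"), oh(rB[5, ], cB))
  lig(c("O3C", "C7G", "O7G"), c("O", "C", "O"), rbind(o3c, c7g, o7g))
  lig(paste0("C", 1:6, "G"), rep("C", 6), rG)
  lig(c("H9", "H10"), c("H", "H"), rbind(arh(rG[2, ], cG), arh(rG[6, ], cG)))
  lig(c("O3G", "HO3G"), c("O", "H"), oh(rG[3, ], cG))
  lig(c("O4G", "HO4G"), c("O", "H"), oh(rG[4, ], cG))
  lig(c("O5G", "HO5G"), c("O", "H"), oh(rG[5, ], cG))

  # --- ions (chain I) --------------------------------------------------------
  add("CA", "Ca", "CA", 301L, "I", rbind(c(10, 2, 8)))
  add("CA", "Ca", "CA", 302L, "I", rbind(c(40, 2, 8)))

  # --- water shell (chain W), 4 A spacing, protons pointing +z --------------
  if (n_water > 0) {
    for (w in seq_len(n_water)) {
      o <- c(2 + 4 * (w - 1), -24, 0)
      add(c("O", "H1", "H2"), c("O", "H", "H"), "HOH", 400L + w, "W",
          rbind(o, o + c(0.6, 0, 0.76), o + c(-0.6, 0, 0.76)))
    }
  }

  atoms <- data.frame(atom_id = seq_along(nm), name = nm, element = el,
                      residue_name = rn, residue_index = ri, chain_id = ch,
                      stringsAsFactors = FALSE)
  st <- new_structure(atoms, xyz)
  topo <- annotate_topology(st)

  idx_of <- function(resindex, names)
    match(paste(resindex, names), paste(atoms$residue_index, atoms$name))
  ring_units <- list(
    A = idx_of(201L, c(paste0("C", 1:6, "A"), "H12", "H13",
                       "O5A", "HO5A", "O7A", "HO7A")),
    B = idx_of(201L, c(paste0("C", 1:6, "B"), "H16", "H17", "O3B", "HO3B",
                       "O4B", "HO4B", "O5B", "HO5B")),
    G = idx_of(201L, c(paste0("C", 1:6, "G"), "H9", "H10", "O3G", "HO3G",
                       "O4G", "HO4G", "O5G", "HO5G")))
  cv_groups <- list(
    cv1 = list(group_a = idx_of(120L, c("HE1", "HE2", "HE3")),
               group_b = topo$equivalence_groups[["H12/H13"]],
               name = "CV1 Met120-A/C"),
    cv2 = list(group_a = idx_of(136L, c("HD11", "HD12", "HD13",
                                        "HD21", "HD22", "HD23")),
               group_b = topo$equivalence_groups[["H9/H10"]],
               name = "CV2 Leu136-B'"),
    cv3 = list(group_a = idx_of(160L, c("HG11", "HG12", "HG13",
                                        "HG21", "HG22", "HG23")),
               group_b = topo$equivalence_groups[["H16/H17"]],
               name = "CV3 Val160-B"))
  structure(list(structure = st, topology = topo,
                 ion_sites = c(I = idx_of(301L, "CA"), II = idx_of(302L, "CA")),
                 ring_units = ring_units, cv_groups = cv_groups),
            class = "ToyComplex")
}

#' @export
print.ToyComplex <- function(x, ...) {
  cat("<ToyComplex> ", nrow(x$structure$atoms), " atoms (",
      sum(x$topology$residues$molecule_class == "protein"), " protein residues, ",
      sum(x$topology$residues$molecule_class == "solvent"), " waters, 2 ions)\n",
      sep = "")
  invisible(x)
}
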