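## Residue templates: the static chemistry table behind annotate_topology().
## One entry per residue name: hydrogen-bond donors (heavy atom, attached H),
## acceptors with their class ("ON" for oxygen/nitrogen, "S" for sulphur,
## which gets the longer 4.0 A donor-acceptor cutoff), planar aromatic rings,
## charge class, molecule class, proton equivalence groups and named
## rotatable dihedrals. Atom names follow the AMBER/PDB v3 convention.

res_tpl <- function(charge = "neutral", mol = "protein", donors = list(),
                    acceptors_on = character(), acceptors_s = character(),
                    rings = list(), equiv = list(), dihedrals = list(),
                    backbone = TRUE) {
  if (backbone) {
    donors <- c(list(c("N", "H")), donors)
    acceptors_on <- c("O", "OXT", acceptors_on)
  }
  list(charge_class = charge, molecule_class = mol, donors = donors,
       acceptors_on = acceptors_on, acceptors_s = acceptors_s,
       rings = rings, equiv = equiv, dihedrals = dihedrals)
}

#' Residue template table
#'
#' The packaged annotation rules used by [annotate_topology()]: the 20
#' standard amino acids, water (`HOH`), the calcium and sodium ions and the
#' synthetic three-ring catechin ligand `EGC` built by [make_toy_complex()].
#' Unknown residue names are a hard error during annotation, never silently
#' skipped, because a skipped residue would silently corrupt interaction
#' counts.
#'
#' @return named list of residue templates.
#' @export
residue_templates <- function() {
  t <- list()
  t$ALA <- res_tpl()
  t$GLY <- res_tpl()
  t$VAL <- res_tpl(equiv = list(methyl1 = c("HG11", "HG12", "HG13"),
                                methyl2 = c("HG21", "HG22", "HG23")))
  t$LEU <- res_tpl(equiv = list(methyl1 = c("HD11", "HD12", "HD13"),
                                methyl2 = c("HD21", "HD22", "HD23")))
  t$ILE <- res_tpl()
  t$PRO <- res_tpl()
  t$PRO$donors <- list()            # no backbone amide proton
  t$PHE <- res_tpl(rings = list(ring = c("CG", "CD1", "CE1", "CZ",
                                         "CE2", "CD2")))
  t$TYR <- res_tpl(donors = list(c("OH", "HH")), acceptors_on = "OH",
                   rings = list(ring = c("CG", "CD1", "CE1", "CZ",
                                         "CE2", "CD2")))
  t$TRP <- res_tpl(donors = list(c("NE1", "HE1")),
                   rings = list(ring5 = c("CG", "CD1", "NE1", "CE2", "CD2"),
                                ring6 = c("CD2", "CE2", "CZ2", "CH2",
                                          "CZ3", "CE3")))
  t$SER <- res_tpl(donors = list(c("OG", "HG")), acceptors_on = "OG")
  t$THR <- res_tpl(donors = list(c("OG1", "HG1")), acceptors_on = "OG1")
  t$CYS <- res_tpl(donors = list(c("SG", "HG")), acceptors_s = "SG")
  t$MET <- res_tpl(acceptors_s = "SD",
                   equiv = list(methyl = c("HE1", "HE2", "HE3")))
  t$ASN <- res_tpl(donors = list(c("ND2", "HD21"), c("ND2", "HD22")),
                   acceptors_on = "OD1")
  t$GLN <- res_tpl(donors = list(c("NE2", "HE21"), c("NE2", "HE22")),
                   acceptors_on = "OE1")
  t$ASP <- res_tpl(charge = "negative", acceptors_on = c("OD1", "OD2"))
  t$GLU <- res_tpl(charge = "negative", acceptors_on = c("OE1", "OE2"))
  t$LYS <- res_tpl(charge = "positive",
                   donors = list(c("NZ", "HZ1"), c("NZ", "HZ2"),
                                 c("NZ", "HZ3")))
  t$ARG <- res_tpl(charge = "positive",
                   donors = list(c("NE", "HE"), c("NH1", "HH11"),
                                 c("NH1", "HH12"), c("NH2", "HH21"),
                                 c("NH2", "HH22")))
  t$HIS <- res_tpl(donors = list(c("ND1", "HD1")), acceptors_on = "NE2",
                   rings = list(ring = c("CG", "ND1", "CE1", "NE2", "CD2")))
  t$HOH <- res_tpl(charge = "water", mol = "solvent",
                   donors = list(c("O", "H1"), c("O", "H2")),
                   acceptors_on = "O", backbone = FALSE)
  t$CA <- res_tpl(charge = "ion", mol = "ion", backbone = FALSE)
  t[["NA"]] <- res_tpl(charge = "ion", mol = "ion", backbone = FALSE)

  # Synthetic catechin-like ligand: benzenediol ring A fused to a pyran-like
  # linker C, a pyrogallol ring B on C2, and a galloyl ester ring B' ("G").
  # Aromatic proton labels and equivalence groups mirror the usual catechin
  # numbering: H12/H13 on A, H16/H17 on B, H9/H10 on B'.
  t$EGC <- res_tpl(
    mol = "ligand", backbone = FALSE,
    donors = list(c("O5A", "HO5A"), c("O7A", "HO7A"),
                  c("O3B", "HO3B"), c("O4B", "HO4B"), c("O5B", "HO5B"),
                  c("O3G", "HO3G"), c("O4G", "HO4G"), c("O5G", "HO5G")),
    acceptors_on = c("O5A", "O7A", "O3B", "O4B", "O5B",
                     "O3G", "O4G", "O5G", "O1C", "O3C", "O7G"),
    rings = list(A = c("C1A", "C2A", "C3A", "C4A", "C5A", "C6A"),
                 B = c("C1B", "C2B", "C3B", "C4B", "C5B", "C6B"),
                 G = c("C1G", "C2G", "C3G", "C4G", "C5G", "C6G")),
    equiv = list("H12/H13" = c("H12", "H13"),
                 "H16/H17" = c("H16", "H17"),
                 "H9/H10" = c("H9", "H10")),
    dihedrals = list(chi1 = c("O1C", "C2C", "C1B", "C2B"),
                     chi2 = c("C2C", "C3C", "O3C", "C7G"),
                     chi3 = c("C3C", "O3C", "C7G", "C1G")))
  t
}

#' Annotate a structure into a topology
#'
#' Applies the residue template table to a structure: populates hydrogen-bond
#' donors and acceptors (with the sulphur class tag that triggers the longer
#' 4.0 A cutoff, e.g. the Met SD atom), aromatic rings, per-residue charge
#' classes (GLU/ASP negative, LYS/ARG positive, HOH water, ions), molecule
#' classes (protein/ligand/solvent/ion), proton equivalence groups and named
#' dihedrals. Annotation is deterministic; an unknown residue name is an
#' error naming the residue.
#'
#' @param x a `Structure` (or a `Trajectory`, whose atom table and first
#'   frame are used).
#' @param templates template table, default [residue_templates()].
#' @return object of class `Topology`: list with `atoms`, `donors`
#'   (data.frame of atom row indices `heavy`, `hydrogen`), `acceptors`
#'   (data.frame `atom`, `class`), `rings` (named list of atom index
#'   vectors), `residues` (per-residue classes), `equivalence_groups` and
#'   `dihedrals` (named lists of atom index vectors).
#' @export
annotate_topology <- function(x, templates = residue_templates()) {
  if (inherits(x, "Trajectory")) {
    atoms <- x$atoms; pos <- x$frames[[1]]$positions
  } else if (inherits(x, "Structure")) {
    atoms <- x$atoms; pos <- x$positions
  } else stop("annotate_topology() expects a Structure or Trajectory")

  key <- paste(atoms$chain_id, atoms$residue_index)
  ukey <- unique(key)
  donors <- list(); acc_atom <- integer(0); acc_class <- character(0)
  rings <- list(); equiv <- list(); dihed <- list()
  res_rows <- list()

  for (k in ukey) {
    rows <- which(key == k)
    rname <- atoms$residue_name[rows[1]]
    tpl <- templates[[rname]]
    if (is.null(tpl))
      stop("no residue template for residue '", rname, "' (",
           k, "); extend the template table or fix the input")
    rtag <- paste0(rname, atoms$residue_index[rows[1]])
    find <- function(nm) rows[match(nm, atoms$name[rows])]
    for (d in tpl$donors) {
      hi <- find(d[1]); hh <- find(d[2])
      if (!is.na(hi) && !is.na(hh)) {
        dist <- sqrt(sum((pos[hi, ] - pos[hh, ])^2))
        if (dist > 1.8)
          stop("donor hydrogen ", d[2], " of ", rtag,
               " is not bonded to ", d[1], " (", round(dist, 2), " A)")
        donors[[length(donors) + 1L]] <- c(hi, hh)
      }
    }
    for (a in tpl$acceptors_on) {
      ai <- find(a)
      if (!is.na(ai)) { acc_atom <- c(acc_atom, ai); acc_class <- c(acc_class, "ON") }
    }
    for (a in tpl$acceptors_s) {
      ai <- find(a)
      if (!is.na(ai)) { acc_atom <- c(acc_atom, ai); acc_class <- c(acc_class, "S") }
    }
    for (rn in names(tpl$rings)) {
      idx <- vapply(tpl$rings[[rn]], find, integer(1))
      if (!anyNA(idx)) rings[[paste(rtag, rn, sep = ".")]] <- unname(idx)
    }
    for (en in names(tpl$equiv)) {
      idx <- vapply(tpl$equiv[[en]], find, integer(1))
      idx <- idx[!is.na(idx)]
      if (length(idx) > 0L) {
        nm <- if (startsWith(en, "H")) en else paste(rtag, en, sep = ".")
        equiv[[nm]] <- unname(idx)
      }
    }
    for (dn in names(tpl$dihedrals)) {
      idx <- vapply(tpl$dihedrals[[dn]], find, integer(1))
      if (!anyNA(idx)) dihed[[dn]] <- unname(idx)
    }
    res_rows[[length(res_rows) + 1L]] <- data.frame(
      residue_index = atoms$residue_index[rows[1]], residue_name = rname,
      chain_id = atoms$chain_id[rows[1]], charge_class = tpl$charge_class,
      molecule_class = tpl$molecule_class, stringsAsFactors = FALSE)
  }

  groups <- equiv
  if (length(groups) > 1L) {
    all_idx <- unlist(groups)
    if (anyDuplicated(all_idx))
      stop("equivalence groups overlap; templates are inconsistent")
  }
  topo <- structure(list(
    atoms = atoms,
    donors = if (length(donors) > 0)
      data.frame(heavy = vapply(donors, `[`, integer(1), 1L),
                 hydrogen = vapply(donors, `[`, integer(1), 2L))
    else data.frame(heavy = integer(0), hydrogen = integer(0)),
    acceptors = data.frame(atom = acc_atom, class = acc_class,
                           stringsAsFactors = FALSE),
    rings = rings,
    residues = do.call(rbind, res_rows),
    equivalence_groups = groups,
    dihedrals = dihed), class = "Topology")
  topo
}

#' @export
print.Topology <- function(x, ...) {
  cat("<Topology> ", nrow(x$atoms), " atoms, ", nrow(x$residues),
      " residues; ", nrow(x$donors), " donors, ", nrow(x$acceptors),
      " acceptors, ", length(x$rings), " rings\n", sep = "")
  invisible(x)
}

# molecule class of the residue each atom belongs to ("protein", "ligand",
# "solvent", "ion"); internal
atom_molecule_class <- function(topology) {
  key <- paste(topology$atoms$chain_id, topology$atoms$residue_index)
  rkey <- paste(topology$residues$chain_id, topology$residues$residue_index)
  topology$residues$molecule_class[match(key, rkey)]
}

atom_charge_class <- function(topology) {
  key <- paste(topology$atoms$chain_id, topology$atoms$residue_index)
  rkey <- paste(topology$residues$chain_id, topology$residues$residue_index)
  topology$residues$charge_class[match(key, rkey)]
}

# residue tag like "GLU161" per atom; internal
atom_residue_tag <- function(topology)
  paste0(topology$atoms$residue_name, topology$atoms$residue_index)

BACKBONE_NAMES <- c("N", "H", "CA", "C", "O", "OXT")
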