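# In-code fixtures: tiny structure files written to tempfiles on demand.

fixture_file <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# three-residue toy protein: GLY - LYS - GLY, one chain, plus a water
toy_pdb_lines <- c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
  "ATOM      4  O   GLY A   1       1.400   2.400   0.000  1.00  0.00           O",
  "ATOM      5  N   LYS A   2       3.300   1.500   0.000  1.00  0.00           N",
  "ATOM      6  CA  LYS A   2       4.000   2.700   0.000  1.00  0.00           C",
  "ATOM      7  CB  LYS A   2       5.500   2.500   0.200  1.00  0.00           C",
  "ATOM      8  CG  LYS A   2       6.300   3.700   0.500  1.00  0.00           C",
  "ATOM      9  CD  LYS A   2       7.800   3.500   0.600  1.00  0.00           C",
  "ATOM     10  CE  LYS A   2       8.600   4.700   0.900  1.00  0.00           C",
  "ATOM     11  NZ  LYS A   2      10.000   4.500   1.000  1.00  0.00           N",
  "ATOM     12  C   LYS A   2       3.500   3.600   1.100  1.00  0.00           C",
  "ATOM     13  O   LYS A   2       3.600   3.300   2.300  1.00  0.00           O",
  "ATOM     14  N   GLY A   3       3.000   4.800   0.700  1.00  0.00           N",
  "ATOM     15  CA  GLY A   3       2.400   5.800   1.600  1.00  0.00           C",
  "ATOM     16  C   GLY A   3       1.000   6.200   1.100  1.00  0.00           C",
  "ATOM     17  O   GLY A   3       0.600   5.900   0.000  1.00  0.00           O",
  "HETATM   18  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
  "END"
)

toy_pdb <- function() fixture_file(toy_pdb_lines, ".pdb")

# altloc fixture: CB in two conformations, B has the higher occupancy
altloc_pdb <- function() {
  fixture_file(c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB ASER A   1       2.000   1.400   0.000  0.40  0.00           C",
    "ATOM      4  CB BSER A   1       2.100   1.300   0.100  0.60  0.00           C",
    "ATOM      5  OG  SER A   1       3.000   2.000   1.000  1.00  0.00           O",
    "END"
  ), ".pdb")
}

sdf_v2000 <- function(atoms, bonds, name = "fixture") {
  # atoms: data.frame(element, x, y, z); bonds: data.frame(from, to, order)
  c(
    name, "  test", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(atoms), nrow(bonds)),
    sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      atoms$x, atoms$y, atoms$z, atoms$element
    ),
    if (nrow(bonds)) sprintf("%3d%3d%3d  0", bonds$from, bonds$to, bonds$order),
    "M  END", "$$$$"
  )
}

benzene_sdf <- function() {
  ang <- (0:5) * pi / 3
  atoms <- data.frame(
    element = "C", x = round(1.39 * cos(ang), 4),
    y = round(1.39 * sin(ang), 4), z = 0
  )
  bonds <- data.frame(from = 1:6, to = c(2:6, 1), order = 4L)
  fixture_file(sdf_v2000(atoms, bonds, "benzene"), ".sdf")
}

ethanol_sdf <- function() {
  atoms <- data.frame(
    element = c("C", "C", "O"),
    x = c(0, 1.52, 2.2), y = c(0, 0, 1.2), z = 0
  )
  bonds <- data.frame(from = c(1, 2), to = c(2, 3), order = 1L)
  fixture_file(sdf_v2000(atoms, bonds, "ethanol"), ".sdf")
}

methane_sdf <- function() {
  atoms <- data.frame(
    element = c("C", "H", "H", "H", "H"),
    x = c(0, 1.09, -0.36, -0.36, -0.36),
    y = c(0, 0, 1.03, -0.51, -0.51),
    z = c(0, 0, 0, 0.89, -0.89)
  )
  bonds <- data.frame(from = 1L, to = 2:5, order = 1L)
  fixture_file(sdf_v2000(atoms, bonds, "methane"), ".sdf")
}

# single-residue protein built in memory (side-chain geometry is arbitrary)
single_residue_protein <- function(resid, atom_names, elements = NULL) {
  elements <- elements %||% substr(atom_names, 1, 1)
  atom <- data.frame(
    serial = seq_along(atom_names), element = elements, name = atom_names,
    x = seq_along(atom_names) * 1.5, y = 0, z = 0,
    chain = "A", resno = 1L, resid = resid, stringsAsFactors = FALSE
  )
  distaff:::new_protein_structure(atom, "<fixture>")
}

residue_atoms <- list(
  GLY = c("N", "CA", "C", "O"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  SER = c("N", "CA", "C", "O", "CB", "OG")
)

multi_residue_protein <- function(resids) {
  frames <- lapply(seq_along(resids), function(i) {
    nms <- residue_atoms[[resids[i]]]
    data.frame(
      serial = 0L, element = substr(nms, 1, 1), name = nms,
      x = seq_along(nms) * 1.5 + i * 20, y = i * 5, z = 0,
      chain = "A", resno = i, resid = resids[i], stringsAsFactors = FALSE
    )
  })
  atom <- do.call(rbind, frames)
  atom$serial <- seq_len(nrow(atom))
  distaff:::new_protein_structure(atom, "<fixture>")
}

# typed-atom-set constructor for synthetic geometry tests
typed_set_at <- function(coords, cls = "hydrophobic", side = "protein",
                         element = "C") {
  coords <- matrix(coords, ncol = 3)
  element <- rep_len(element, nrow(coords))
  atoms <- data.frame(
    serial = seq_len(nrow(coords)), element = element,
    name = paste0(element, seq_len(nrow(coords))),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    is_heavy = rep_len(TRUE, nrow(coords))
  )
  distaff:::new_typed_atom_set(cls, atoms, side)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force pocket-vector oracle: an independent reimplementation of
# distance -> threshold -> bin -> flatten (loops and plain arithmetic only)
oracle_pocket_vector <- function(protein, ligand, rules = atom_typing_rules(),
                                 length_out = 1000L) {
  pt <- classify_protein_atoms(protein, rules)
  lt <- classify_ligand_atoms(ligand, rules)
  bin1 <- function(d) if (d >= 20) 41L else as.integer(floor(d / 0.5) + 1)
  pair_codes <- function(pa, la, thr) {
    codes <- integer(0)
    if (nrow(pa) == 0 || nrow(la) == 0) return(codes)
    for (i in seq_len(nrow(pa))) {
      for (j in seq_len(nrow(la))) {
        d <- sqrt((pa$x[i] - la$x[j])^2 + (pa$y[i] - la$y[j])^2 +
                    (pa$z[i] - la$z[j])^2)
        if (d < thr) codes <- c(codes, bin1(d))
      }
    }
    codes
  }
  acc <- lt$acceptor$atoms
  if (nrow(acc) == 0) acc <- ligand$atoms[ligand$atoms$is_heavy, ]
  codes <- c(
    pair_codes(pt$donor$atoms, acc, Inf),
    pair_codes(pt$pi_stacking$atoms, lt$pi_stacking$atoms, 4.0),
    pair_codes(pt$hydrophobic$atoms, lt$hydrophobic$atoms, 4.5)
  )
  length(codes) <- length_out
  codes[is.na(codes)] <- 0L
  codes
}
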