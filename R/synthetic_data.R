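# Residue templates used by the generator: side-chain atom names per
# residue (backbone N/CA/C/O always present). The pool mixes donor-rich
# (LYS, SER, HIS, TRP), hydrophobic (LEU, PHE), aromatic (PHE, TRP, HIS)
# and feature-less (GLY) residues so every typing rule fires.
.synth_side_chains <- list(
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  SER = c("CB", "OG"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  GLY = character(),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2")
)

.synth_element <- function(name) substr(name, 1, 1)

#' Specification of a synthetic protein-ligand complex
#'
#' Defines the study conditions of the toy-complex generator: geometry
#' (residue/atom counts, box size) and the ground-truth affinity function
#' `pKd = 2 + w_DA * c_DA + w_HP * c_HP + w_PS * c_PS + noise`, clipped to
#' `[2, 12]`, where the `c` are contact counts below 3.5 / 4.5 / 4.0
#' Angstrom for donor-acceptor, hydrophobic and pi-stacking pairs.
#'
#' @param n_residues Number of protein residues.
#' @param n_ligand_atoms Number of ligand heavy atoms (>= 7: a 6-carbon
#'   aromatic ring plus a heteroatom chain).
#' @param box_size Edge length (Angstrom) of the cubic placement box.
#' @param contact_weights Weights `(w_DA, w_HP, w_PS)` of the affinity
#'   function.
#' @param noise_sd Gaussian noise SD on the true pKd.
#' @param seed Integer seed.
#' @param residue_pool Residue names the protein is drawn from (a subset
#'   of LYS, SER, PHE, LEU, GLY, TRP, HIS).
#' @return A `synthetic_complex_spec` list.
#' @export
synthetic_complex_spec <- function(n_residues = 10L, n_ligand_atoms = 9L,
                                   box_size = 20,
                                   contact_weights = c(0.8, 0.3, 0.5),
                                   noise_sd = 0.1, seed = 1L,
                                   residue_pool = names(.synth_side_chains)) {
  stopifnot(
    n_residues >= 1, n_ligand_atoms >= 7, box_size > 0,
    length(contact_weights) == 3, noise_sd >= 0,
    all(residue_pool %in% names(.synth_side_chains))
  )
  structure(
    list(
      n_residues = as.integer(n_residues),
      n_ligand_atoms = as.integer(n_ligand_atoms),
      box_size = box_size,
      contact_weights = as.numeric(contact_weights),
      noise_sd = noise_sd, seed = as.integer(seed),
      residue_pool = residue_pool
    ),
    class = "synthetic_complex_spec"
  )
}

synth_protein <- function(spec, residue_names) {
  per_res <- lapply(seq_along(residue_names), function(i) {
    nm <- residue_names[i]
    atoms <- c("N", "CA", "C", "O", .synth_side_chains[[nm]])
    center <- runif(3, 0, spec$box_size)
    xyz <- round(
      matrix(center, length(atoms), 3, byrow = TRUE) +
        matrix(rnorm(3 * length(atoms), sd = 0.9), ncol = 3),
      3
    )
    list(names = atoms, resno = rep(i, length(atoms)),
         resid = rep(nm, length(atoms)), xyz = xyz)
  })
  names <- unlist(lapply(per_res, `[[`, "names"))
  xyz <- do.call(rbind, lapply(per_res, `[[`, "xyz"))
  atom <- data.frame(
    serial = seq_along(names), element = .synth_element(names), name = names,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    chain = "A",
    resno = unlist(lapply(per_res, `[[`, "resno")),
    resid = unlist(lapply(per_res, `[[`, "resid")),
    stringsAsFactors = FALSE
  )
  new_protein_structure(atom, "<synthetic>")
}

synth_ligand <- function(spec) {
  n <- spec$n_ligand_atoms
  center <- spec$box_size / 2
  coords <- matrix(round(runif(n * 3, center - spec$box_size / 2,
                               center + spec$box_size / 2), 3), n, 3)
  # atoms 1-6: aromatic carbon ring; the rest: a C/N/O chain off atom 1
  elements <- c(rep("C", 6L), sample(c("C", "N", "O"), n - 6L,
    replace = TRUE, prob = c(0.4, 0.3, 0.3)
  ))
  atoms <- data.frame(
    serial = seq_len(n), element = elements,
    name = paste0(elements, seq_len(n)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    from = c(1:6, if (n > 6) c(1L, if (n > 7) 7:(n - 1L))),
    to = c(2:6, 1L, if (n > 6) 7:n),
    order = c(rep(4L, 6L), rep(1L, max(0L, n - 6L)))
  )
  bonds$aromatic <- bonds$order == 4L
  new_ligand_structure(atoms, bonds, NULL, "<synthetic>")
}

synth_smiles <- function(n_atoms) {
  # decorative random SMILES-like string over common organic characters
  len <- max(5L, n_atoms + sample.int(6L, 1L))
  paste(sample(c("C", "N", "O", "c", "n", "1", "(", ")", "="), len,
    replace = TRUE, prob = c(0.35, 0.1, 0.1, 0.15, 0.05, 0.1, 0.05, 0.05, 0.05)
  ), collapse = "")
}

count_contacts <- function(protein, ligand, rules = atom_typing_rules(),
                           da_threshold = 3.5, hp_threshold = 4.5,
                           ps_threshold = 4.0) {
  pt <- classify_protein_atoms(protein, rules)
  lt <- classify_ligand_atoms(ligand, rules)
  below <- function(a, b, thr) {
    d <- cross_distances(a$atoms, b$atoms)
    sum(d < thr)
  }
  c(
    da = below(pt$donor, lt$acceptor, da_threshold),
    hp = below(pt$hydrophobic, lt$hydrophobic, hp_threshold),
    ps = below(pt$pi_stacking, lt$pi_stacking, ps_threshold)
  )
}

#' Ground-truth affinity of a synthetic complex
#'
#' `pKd = 2 + w_DA * c_DA + w_HP * c_HP + w_PS * c_PS + N(0, noise_sd)`,
#' clipped to `[2, 12]`. Contacts are counted below 3.5 A (donor-
#' acceptor), 4.5 A (hydrophobic) and 4.0 A (pi-stacking).
#'
#' @param complex A `synthetic_complex` (or any list with
#'   `contact_counts`).
#' @param spec The generating [synthetic_complex_spec()].
#' @param noise Optional pre-drawn noise value (default: drawn from the
#'   current RNG stream with `spec$noise_sd`).
#' @return The true pKd.
#' @export
synthetic_affinity <- function(complex, spec, noise = NULL) {
  cc <- complex$contact_counts
  noise <- noise %||% rnorm(1, 0, spec$noise_sd)
  min(12, max(2, 2 + sum(spec$contact_weights * cc) + noise))
}

#' Generate one synthetic protein-ligand complex
#'
#' Residues are drawn from a 7-residue pool (LYS, SER, PHE, LEU, GLY,
#' TRP, HIS) with correct side-chain atom names so every typing rule can
#' fire; ligand heavy atoms (an aromatic 6-ring plus a C/N/O chain) are
#' placed uniformly in the box. The true pKd is a linear function of the
#' realized contact counts (see [synthetic_affinity()]).
#'
#' @param spec A [synthetic_complex_spec()].
#' @return A `synthetic_complex`: `protein`, `ligand`, `hhm`, `smiles`,
#'   `true_pkd`, `contact_counts`.
#' @export
generate_complex <- function(spec = synthetic_complex_spec()) {
  with_seed(spec$seed, {
    pool <- spec$residue_pool %||% names(.synth_side_chains)
    residue_names <- sample(pool, spec$n_residues, replace = TRUE)
    protein <- synth_protein(spec, residue_names)
    ligand <- synth_ligand(spec)
    smiles <- synth_smiles(spec$n_ligand_atoms)
    hhm <- synthetic_hhm(spec$n_residues, seed = spec$seed + 1L)
    cc <- count_contacts(protein, ligand)
    out <- list(
      protein = protein, ligand = ligand, hhm = hhm, smiles = smiles,
      contact_counts = cc, spec = spec
    )
    out$true_pkd <- synthetic_affinity(out, spec)
    structure(out, class = "synthetic_complex")
  })
}

#' @export
print.synthetic_complex <- function(x, ...) {
  cat(
    "<synthetic_complex> ", length(x$protein$residues), " residues, ",
    nrow(x$ligand$atoms), " ligand atoms; contacts DA/HP/PS = ",
    paste(x$contact_counts, collapse = "/"),
    "; true pKd ", round(x$true_pkd, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Generate a synthetic dataset
#'
#' `n` complexes with per-complex seeds derived deterministically from the
#' master seed. With `dir` set, writes each complex in the real input
#' formats (toy PDB, SDF V2000, `.hhm`) plus a tab-separated manifest, so
#' the file-parsing code paths can be exercised end to end; otherwise the
#' complexes stay in memory.
#'
#' @param n Number of complexes.
#' @param spec Template [synthetic_complex_spec()] (its `seed` is the
#'   master seed).
#' @param dir Output directory, or `NULL` for in-memory generation.
#' @return A list with `complexes` (list of `synthetic_complex`) and
#'   `manifest` (data.frame: complex_id, file paths when written, smiles,
#'   pkd).
#' @export
generate_dataset <- function(n, spec = synthetic_complex_spec(), dir = NULL) {
  stopifnot(n >= 1)
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, n))
  complexes <- lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- seeds[i]
    generate_complex(s)
  })
  ids <- sprintf("cpx%05d", seq_len(n))
  manifest <- data.frame(
    complex_id = ids,
    smiles = vapply(complexes, function(x) x$smiles, ""),
    pkd = vapply(complexes, function(x) x$true_pkd, 1.0),
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    manifest$pdb <- file.path(dir, paste0(ids, ".pdb"))
    manifest$sdf <- file.path(dir, paste0(ids, ".sdf"))
    manifest$hhm <- file.path(dir, paste0(ids, ".hhm"))
    for (i in seq_len(n)) {
      write_toy_pdb(complexes[[i]]$protein, manifest$pdb[i])
      write_toy_sdf(complexes[[i]]$ligand, manifest$sdf[i])
      write_hhm(complexes[[i]]$hhm, manifest$hhm[i])
    }
    write.table(manifest, file.path(dir, "manifest.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  list(complexes = complexes, manifest = manifest)
}

#' Write a ligand as a minimal SDF (V2000) file
#'
#' Fixture-grade writer: atom block with 3-D coordinates and element
#' symbols, bond block with bond orders (4 = aromatic).
#'
#' @param ligand A `ligand_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toy_sdf <- function(ligand, path) {
  at <- ligand$atoms
  bd <- ligand$bonds
  lines <- c(
    "synthetic ligand", "  distaff", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(at), nrow(bd)),
    sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      at$x, at$y, at$z, at$element
    ),
    if (nrow(bd)) sprintf("%3d%3d%3d  0", bd$from, bd$to, bd$order),
    "M  END", "$$$$"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Featurize synthetic complexes into a model dataset
#'
#' Convenience wrapper chaining [featurize_complex()] over the output of
#' [generate_dataset()].
#'
#' @param generated Output of [generate_dataset()].
#' @param ... Passed to [featurize_complex()].
#' @return A labelled `affinity_dataset`.
#' @export
featurize_synthetic <- function(generated, ...) {
  feats <- lapply(generated$complexes, function(cx) {
    featurize_complex(cx$protein, cx$ligand,
      hhm = cx$hhm, smiles = cx$smiles, ...
    )
  })
  make_model_dataset(feats,
    pkd = generated$manifest$pkd,
    ids = generated$manifest$complex_id
  )
}
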