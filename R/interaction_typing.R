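#' Load atom-typing rule tables
#'
#' The rules drive which heavy atoms count as hydrogen-bond donors,
#' hydrophobic atoms and pi-stacking atoms. Protein-side rules are explicit
#' side-chain atom-name tables over the 20 standard residues; ligand-side
#' rules are structural predicates (acceptor: heavy N/O; hydrophobic:
#' carbon bonded only to carbon/hydrogen; pi-stacking: atom on an aromatic
#' bond). The shipped tables follow the conventions of standard
#' protein-ligand interaction fingerprints; supply `path` to swap in your
#' own JSON file with the same keys.
#'
#' @param path Path to a rules JSON file; default: the packaged table.
#' @return An object of class `atom_typing_rules`.
#' @export
atom_typing_rules <- function(path = NULL) {
  path <- path %||% dist_extdata("atom_typing_rules.json")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("protein_donor", "protein_hydrophobic", "protein_pi_stacking")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("rules file lacks tables: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      protein_donor = lapply(raw$protein_donor, as.character),
      protein_hydrophobic = lapply(raw$protein_hydrophobic, as.character),
      protein_pi_stacking = lapply(raw$protein_pi_stacking, as.character),
      backbone_atoms = as.character(
        raw$backbone_atoms %||% c("N", "CA", "C", "O", "OXT")
      ),
      source_path = path
    ),
    class = "atom_typing_rules"
  )
}

#' @export
print.atom_typing_rules <- function(x, ...) {
  cat("<atom_typing_rules> (", x$source_path, ")\n", sep = "")
  cat(
    " donors:", length(x$protein_donor), "residues;",
    "hydrophobic:", length(x$protein_hydrophobic), "residues;",
    "pi-stacking:", length(x$protein_pi_stacking), "residues\n"
  )
  invisible(x)
}

new_typed_atom_set <- function(cls, atoms, side) {
  structure(
    list(cls = cls, atoms = atoms, side = side),
    class = "typed_atom_set"
  )
}

#' @export
print.typed_atom_set <- function(x, ...) {
  cat(
    "<typed_atom_set> ", x$cls, " (", x$side, "): ",
    nrow(x$atoms), " atoms\n", sep = ""
  )
  invisible(x)
}

protein_table_match <- function(at, table) {
  hit <- rep(FALSE, nrow(at))
  idx <- match(at$resid, names(table))
  has <- !is.na(idx)
  if (any(has)) {
    hit[has] <- mapply(
      function(name, i) name %in% table[[i]],
      at$name[has], idx[has]
    )
  }
  hit
}

#' Classify protein heavy atoms into interaction sets
#'
#' Side-chain heavy atoms are matched against the donor, hydrophobic and
#' pi-stacking rule tables. Backbone atoms never qualify; an atom may sit
#' in more than one set (e.g. TRP ring carbons are both hydrophobic and
#' pi-stacking capable). Residues absent from a table simply contribute
#' nothing.
#'
#' @param protein A `protein_structure`.
#' @param rules An `atom_typing_rules` object.
#' @return Named list of three `typed_atom_set`s: `donor`, `hydrophobic`,
#'   `pi_stacking`.
#' @export
classify_protein_atoms <- function(protein, rules = atom_typing_rules()) {
  at <- heavy_atoms(protein)
  side <- at[!(at$name %in% rules$backbone_atoms), , drop = FALSE]
  pick <- function(table, cls) {
    new_typed_atom_set(cls, side[protein_table_match(side, table), , drop = FALSE],
      side = "protein"
    )
  }
  list(
    donor = pick(rules$protein_donor, "donor"),
    hydrophobic = pick(rules$protein_hydrophobic, "hydrophobic"),
    pi_stacking = pick(rules$protein_pi_stacking, "pi_stacking")
  )
}

#' Classify ligand heavy atoms into interaction sets
#'
#' Acceptors are all heavy nitrogen/oxygen atoms; hydrophobic atoms are
#' carbons whose bonded neighbours are all carbon or hydrogen; pi-stacking
#' atoms are heavy atoms participating in at least one aromatic bond.
#'
#' @param ligand A `ligand_structure` (bonds required for the hydrophobic
#'   and pi-stacking rules).
#' @param rules An `atom_typing_rules` object (reserved for overrides; the
#'   ligand rules are structural predicates).
#' @return Named list of three `typed_atom_set`s: `acceptor`,
#'   `hydrophobic`, `pi_stacking`.
#' @export
classify_ligand_atoms <- function(ligand, rules = atom_typing_rules()) {
  at <- ligand$atoms
  heavy <- at$is_heavy
  acceptor <- heavy & at$element %in% c("N", "O")

  nbr_elements <- vector("list", nrow(at))
  if (nrow(ligand$bonds) > 0) {
    for (i in seq_len(nrow(ligand$bonds))) {
      f <- ligand$bonds$from[i]
      t <- ligand$bonds$to[i]
      nbr_elements[[f]] <- c(nbr_elements[[f]], at$element[t])
      nbr_elements[[t]] <- c(nbr_elements[[t]], at$element[f])
    }
  }
  hydrophobic <- heavy & at$element == "C" & vapply(
    nbr_elements,
    function(e) all(e %in% c("C", .hydrogen_symbols)), TRUE
  )

  aromatic_rows <- unique(c(
    ligand$bonds$from[ligand$bonds$aromatic],
    ligand$bonds$to[ligand$bonds$aromatic]
  ))
  pi <- heavy & seq_len(nrow(at)) %in% aromatic_rows

  list(
    acceptor = new_typed_atom_set(
      "acceptor", at[acceptor, , drop = FALSE], "ligand"
    ),
    hydrophobic = new_typed_atom_set(
      "hydrophobic", at[hydrophobic, , drop = FALSE], "ligand"
    ),
    pi_stacking = new_typed_atom_set(
      "pi_stacking", at[pi, , drop = FALSE], "ligand"
    )
  )
}

#' Select the protein residues that carry interaction-capable atoms
#'
#' Keeps every residue whose side chain contains at least one donor,
#' hydrophobic, or pi-stacking heavy atom. Each residue appears exactly
#' once, in the original sequence order; these are the residues whose
#' sequence features enter the protein feature matrix.
#'
#' @inheritParams classify_protein_atoms
#' @return The `protein_structure`'s residue list, filtered (possibly
#'   empty, with a warning).
#' @export
select_interaction_residues <- function(protein, rules = atom_typing_rules()) {
  tables <- c(
    rules$protein_donor, rules$protein_hydrophobic,
    rules$protein_pi_stacking
  )
  qualifying <- function(res) {
    a <- res$atoms
    a <- a[a$is_heavy & !(a$name %in% rules$backbone_atoms), , drop = FALSE]
    if (nrow(a) == 0L) {
      return(FALSE)
    }
    idx <- which(names(tables) == res$name)
    any(vapply(idx, function(i) any(a$name %in% tables[[i]]), TRUE))
  }
  keep <- vapply(protein$residues, qualifying, TRUE)
  if (!any(keep)) {
    warning(
      "no interaction-capable residues selected; ",
      "downstream feature matrix will be all padding"
    )
  }
  sel <- protein$residues[keep]
  attr(sel, "positions") <- which(keep)
  sel
}
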