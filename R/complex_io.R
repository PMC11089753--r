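#' Read a protein structure from a PDB or mol2 file
#'
#' Parses the file into a light-weight residue/atom model. Only `ATOM`
#' records are kept for PDB input (waters, ions and other `HETATM` records
#' are dropped); alternate locations are collapsed to the highest-occupancy
#' copy, ties broken by first occurrence. Coordinates are in Angstrom.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"` or `"mol2"`. Defaults from the file extension.
#' @return An object of class `protein_structure`: a list with `residues`
#'   (list of residues, each with `chain`, `seq_index`, `name`,
#'   `is_standard` and an atom data.frame) and `source_path`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' prot <- generate_complex(synthetic_complex_spec(seed = 1))$protein
#' write_toy_pdb(prot, pdb)
#' read_protein(pdb)
#' @export
read_protein <- function(path, format = c("auto", "pdb", "mol2")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "pdb"
  }
  if (!file.exists(path)) {
    stop("protein file does not exist: ", path, call. = FALSE)
  }
  atom <- switch(format,
    pdb = read_protein_pdb(path),
    mol2 = read_protein_mol2(path)
  )
  if (nrow(atom) == 0L) {
    stop("no protein atoms parsed from ", path, call. = FALSE)
  }
  new_protein_structure(atom, path)
}

read_protein_pdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) {
      stop("failed to parse PDB file ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) {
    return(empty_atom_frame())
  }
  at$o[is.na(at$o)] <- 1
  at$alt[is.na(at$alt)] <- ""
  # collapse altlocs: highest occupancy wins, first occurrence breaks ties
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, unique(key))),
    function(i) i[which.max(at$o[i])]
  ), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(elem)
  elem[bad] <- element_from_atom_name(at$elety[bad])
  data.frame(
    serial = at$eleno, element = toupper(elem), name = at$elety,
    x = at$x, y = at$y, z = at$z,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, resid = at$resid,
    stringsAsFactors = FALSE
  )
}

read_protein_mol2 <- function(path) {
  m <- tryCatch(bio3d::read.mol2(path),
    error = function(e) {
      stop("failed to parse mol2 file ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  at <- m$atom
  # mol2 fields: elena = atom name (e.g. "NZ"), elety = SYBYL type ("N.4")
  elem <- toupper(sub("\\..*$", "", at$elety))
  resid3 <- toupper(substr(at$resid, 1, 3))
  resno <- suppressWarnings(as.integer(at$resno))
  resno[is.na(resno)] <- 1L
  data.frame(
    serial = at$eleno, element = elem, name = at$elena,
    x = at$x, y = at$y, z = at$z,
    chain = "A", resno = resno, resid = resid3,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

element_from_atom_name <- function(name) {
  n <- gsub("[0-9'\"]", "", trimws(name))
  two <- toupper(substr(n, 1, 2))
  one <- toupper(substr(n, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "SE"), two, one)
}

empty_atom_frame <- function() {
  data.frame(
    serial = integer(), element = character(), name = character(),
    x = numeric(), y = numeric(), z = numeric(), chain = character(),
    resno = integer(), resid = character(), stringsAsFactors = FALSE
  )
}

new_protein_structure <- function(atom, path) {
  stopifnot(all(is.finite(atom$x)), all(is.finite(atom$y)),
            all(is.finite(atom$z)))
  atom$is_heavy <- !(atom$element %in% .hydrogen_symbols)
  key <- paste(atom$chain, atom$resno, sep = "\r")
  ord <- factor(key, levels = unique(key))
  residues <- lapply(split(atom, ord), function(a) {
    list(
      chain = a$chain[1], seq_index = a$resno[1], name = a$resid[1],
      is_standard = a$resid[1] %in% .standard_residues,
      atoms = a[, c("serial", "element", "name", "x", "y", "z", "is_heavy")]
    )
  })
  names(residues) <- NULL
  structure(
    list(residues = residues, source_path = path),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  natoms <- sum(vapply(x$residues, function(r) nrow(r$atoms), 1L))
  cat(
    "<protein_structure> ", length(x$residues), " residues, ",
    natoms, " atoms (", x$source_path, ")\n", sep = ""
  )
  invisible(x)
}

#' Read a ligand structure from an SDF or mol2 file
#'
#' Atoms, bonds and aromatic flags are populated; hydrogens are retained but
#' flagged non-heavy. Aromaticity comes from the bond table (SDF bond type
#' 4, mol2 type `"ar"`); no ring perception is attempted, so Kekule-encoded
#' rings are not re-aromatized.
#'
#' @param path Path to the ligand file.
#' @param format `"sdf"` or `"mol2"` (default: from extension).
#' @param smiles Optional SMILES string to attach to the structure.
#' @return An object of class `ligand_structure` with `atoms` (data.frame),
#'   `bonds` (data.frame with `from`, `to`, `order`, `aromatic`) and
#'   `smiles` (string or `NULL`).
#' @export
read_ligand <- function(path, format = c("auto", "sdf", "mol2"),
                        smiles = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "sdf"
  }
  if (!file.exists(path)) {
    stop("ligand file does not exist: ", path, call. = FALSE)
  }
  lig <- switch(format, sdf = read_ligand_sdf(path), mol2 = read_ligand_mol2(path))
  lig$smiles <- smiles %||% lig$smiles
  lig
}

read_ligand_sdf <- function(path) {
  set <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) {
      stop("failed to parse SDF file ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (length(set) == 0L) {
    stop("failed to parse SDF file ", path, ": no molecule block",
      call. = FALSE
    )
  }
  sdf <- set[[1]]
  ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
  if (!is.matrix(ab) || nrow(ab) == 0L || ncol(ab) < 3L) {
    stop("failed to parse SDF file ", path, ": no valid atom block",
      call. = FALSE
    )
  }
  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  elem <- toupper(sub("_.*$", "", rownames(ab)))
  atoms <- data.frame(
    serial = seq_len(nrow(ab)), element = elem,
    name = paste0(elem, seq_len(nrow(ab))),
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(bb) && is.null(dim(bb)) && length(bb) >= 3L) {
    bb <- matrix(bb, nrow = 1)
  }
  bonds <- if (is.null(bb) || length(bb) == 0L || nrow(bb) == 0L) {
    data.frame(from = integer(), to = integer(), order = integer())
  } else {
    data.frame(
      from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
      order = as.integer(bb[, 3]), stringsAsFactors = FALSE
    )
  }
  bonds$aromatic <- bonds$order == 4L
  new_ligand_structure(atoms, bonds, NULL, path)
}

read_ligand_mol2 <- function(path) {
  m <- tryCatch(bio3d::read.mol2(path),
    error = function(e) {
      stop("failed to parse mol2 file ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  at <- m$atom
  atoms <- data.frame(
    serial = at$eleno, element = toupper(sub("\\..*$", "", at$elety)),
    name = at$elena, x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  bd <- m$bond
  bonds <- data.frame(
    from = as.integer(bd$origin), to = as.integer(bd$target),
    order = suppressWarnings(as.integer(bd$type)), stringsAsFactors = FALSE
  )
  bonds$aromatic <- tolower(as.character(bd$type)) == "ar"
  bonds$order[is.na(bonds$order)] <- 1L
  new_ligand_structure(atoms, bonds, NULL, path)
}

new_ligand_structure <- function(atoms, bonds, smiles, path = NA_character_) {
  if (nrow(bonds) > 0) {
    # normalize bond endpoints from atom ids to row indices
    bonds$from <- match(bonds$from, atoms$serial)
    bonds$to <- match(bonds$to, atoms$serial)
    if (anyNA(bonds$from) || anyNA(bonds$to)) {
      stop("ligand bond references a missing atom", call. = FALSE)
    }
  }
  atoms$is_heavy <- !(atoms$element %in% .hydrogen_symbols)
  structure(
    list(atoms = atoms, bonds = bonds, smiles = smiles, source_path = path),
    class = "ligand_structure"
  )
}

#' @export
print.ligand_structure <- function(x, ...) {
  cat(
    "<ligand_structure> ", nrow(x$atoms), " atoms (",
    sum(x$atoms$is_heavy), " heavy), ", nrow(x$bonds), " bonds\n", sep = ""
  )
  invisible(x)
}

#' Extract heavy atoms from a structure
#'
#' Order-preserving filter: every atom whose element is not hydrogen, in the
#' order they appear in the source structure.
#'
#' @param structure A `protein_structure` or `ligand_structure`.
#' @return A data.frame of atoms (columns `serial`, `element`, `name`, `x`,
#'   `y`, `z`, plus `chain`/`resno`/`resid` for proteins).
#' @export
heavy_atoms <- function(structure) {
  at <- flatten_atoms(structure)
  at[at$is_heavy, , drop = FALSE]
}

#' Flatten a structure into a single atom table
#'
#' @param structure A `protein_structure` or `ligand_structure`.
#' @return data.frame of all atoms in file order.
#' @export
flatten_atoms <- function(structure) {
  if (inherits(structure, "protein_structure")) {
    frames <- lapply(structure$residues, function(r) {
      cbind(r$atoms,
        chain = r$chain, resno = r$seq_index, resid = r$name,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, frames)
    rownames(out) <- NULL
    out
  } else if (inherits(structure, "ligand_structure")) {
    structure$atoms
  } else {
    stop("expected a protein_structure or ligand_structure", call. = FALSE)
  }
}

#' Obtain a SMILES string for a ligand
#'
#' Returns the SMILES stored on the ligand, or delegates to an external
#' converter function; this package never derives SMILES itself.
#'
#' @param ligand A `ligand_structure`.
#' @param converter Optional function taking the ligand source path and
#'   returning a SMILES string (see [make_obabel_converter()]).
#' @return A SMILES string.
#' @export
ligand_to_smiles <- function(ligand, converter = NULL) {
  if (!is.null(ligand$smiles)) {
    return(ligand$smiles)
  }
  if (!is.null(converter)) {
    out <- converter(ligand$source_path)
    if (!is.character(out) || length(out) != 1L || !nzchar(out)) {
      stop("SMILES converter returned an invalid result", call. = FALSE)
    }
    return(out)
  }
  stop(
    "SMILES unavailable: the ligand carries no SMILES and no converter was ",
    "given; supply SMILES directly (read_ligand(..., smiles=)) or pass a ",
    "converter function",
    call. = FALSE
  )
}

#' Build a SMILES converter backed by the Open Babel command line tool
#'
#' @param obabel Path to the `obabel` executable.
#' @return A function usable as the `converter` argument of
#'   [ligand_to_smiles()], or an error if the tool is missing.
#' @export
make_obabel_converter <- function(obabel = Sys.which("obabel")) {
  if (!nzchar(obabel)) {
    stop("obabel executable not found on PATH", call. = FALSE)
  }
  force(obabel)
  function(path) {
    out <- suppressWarnings(system2(obabel, c(shQuote(path), "-osmi"),
      stdout = TRUE, stderr = FALSE
    ))
    smi <- strsplit(trimws(out[1]), "[ \t]")[[1]][1]
    if (is.na(smi) || !nzchar(smi)) {
      stop("obabel produced no SMILES for ", path, call. = FALSE)
    }
    smi
  }
}

#' Write a protein structure as a minimal PDB file
#'
#' Fixture-grade writer covering standard `ATOM` records only (single
#' model, no insertion codes or altlocs). Round-trips through
#' [read_protein()] with coordinates preserved to 1e-3 Angstrom.
#'
#' @param protein A `protein_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toy_pdb <- function(protein, path) {
  at <- flatten_atoms(protein)
  name4 <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
    sprintf(" %-3s", at$name)
  )
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$serial %% 100000L, name4, at$resid, at$chain, at$resno,
    at$x, at$y, at$z, 1, 0, at$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
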