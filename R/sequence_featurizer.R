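#' One-hot encode a residue name
#'
#' 21-dimensional vector: positions 1..20 index the standard amino acids in
#' alphabetical three-letter-code order (ALA..VAL); position 21 flags any
#' non-standard residue.
#'
#' @param name Three-letter residue code (e.g. `"LYS"`).
#' @return Numeric vector of length 21 summing to 1.
#' @export
one_hot_residue <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  v <- numeric(21)
  idx <- match(toupper(name), .standard_residues)
  v[if (is.na(idx)) 21L else idx] <- 1
  v
}

#' Load the physicochemical descriptor table
#'
#' Seven per-residue descriptors: steric parameter (graph shape index),
#' hydrophobicity, volume, polarisability, isoelectric point, helix
#' probability and sheet probability. The packaged file carries the widely
#' used descriptor set of Meiler and colleagues; it is data, not code —
#' point `path` at your own CSV (same columns) to substitute values.
#'
#' @param path CSV path; default: the packaged table.
#' @return A `physchem_table`: 20 x 7 numeric matrix with residue rownames.
#' @export
physchem_table <- function(path = NULL) {
  path <- path %||% dist_extdata("physchem_table.csv")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(ncol(tab) == 8L)
  m <- as.matrix(tab[, -1])
  rownames(m) <- toupper(tab[[1]])
  if (!setequal(rownames(m), .standard_residues)) {
    stop("physicochemical table must cover exactly the 20 standard residues",
      call. = FALSE
    )
  }
  class(m) <- c("physchem_table", class(m))
  m
}

#' Physicochemical descriptor vector for one residue
#'
#' Table lookup for standard residues; the all-zero vector for
#' non-standard residues.
#'
#' @param name Three-letter residue code.
#' @param table A [physchem_table()].
#' @return Numeric vector of length 7.
#' @export
physchem_vector <- function(name, table = physchem_table()) {
  name <- toupper(name)
  if (name %in% rownames(table)) {
    as.numeric(table[name, ])
  } else {
    numeric(7)
  }
}

#' Parse an HH-suite .hhm profile file
#'
#' Reads the per-residue profile block of the HH-suite text format: for
#' each residue, 20 match-emission scores followed by 7 transition scores
#' and 3 alignment-diversity values — 30 raw pseudo-count columns in
#' total. The `*` entries (zero emission frequency) are stored as `Inf`
#' so that the frequency transform maps them to 0.
#'
#' @param path Path to a `.hhm` file.
#' @return An `hhm_profile`: list with `rows` (n x 30 numeric matrix) and
#'   `length` (residue count).
#' @export
parse_hhm <- function(path) {
  if (!file.exists(path)) {
    stop("hhm file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  start <- grep("^HMM\\b", lines)
  if (length(start) == 0L) {
    stop("malformed .hhm file (no HMM header line): ", path, call. = FALSE)
  }
  i <- start[1] + 3L # skip HMM header, transition header, BEGIN-state line
  end <- grep("^//", lines)
  end <- end[end > i]
  if (length(end) == 0L) {
    stop("malformed .hhm file (missing // footer): ", path, call. = FALSE)
  }
  end <- end[1]
  body <- lines[i:(end - 1L)]
  body <- body[nzchar(trimws(body))]
  if (length(body) %% 2L != 0L) {
    stop(
      "malformed .hhm profile block near line ", i + length(body) - 1L,
      " of ", path,
      call. = FALSE
    )
  }
  n <- length(body) %/% 2L
  parse_vals <- function(tokens, want, line_no) {
    if (length(tokens) < want) {
      stop("malformed .hhm row at line ", line_no, " of ", path, call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(tokens[seq_len(want)]))
    vals[tokens[seq_len(want)] == "*"] <- Inf
    if (anyNA(vals)) {
      stop("malformed .hhm value at line ", line_no, " of ", path, call. = FALSE)
    }
    vals
  }
  rows <- matrix(NA_real_, n, 30L)
  for (r in seq_len(n)) {
    l1 <- strsplit(trimws(body[2L * r - 1L]), "[ \t]+")[[1]]
    l2 <- strsplit(trimws(body[2L * r]), "[ \t]+")[[1]]
    # emission line: residue char, position, 20 scores (trailing position
    # repeat is ignored); transition line: 7 transitions + 3 diversities
    rows[r, 1:20] <- parse_vals(l1[-(1:2)], 20L, i + 2L * r - 2L)
    rows[r, 21:30] <- parse_vals(l2, 10L, i + 2L * r - 1L)
  }
  structure(list(rows = rows, length = n), class = "hhm_profile")
}

#' @export
print.hhm_profile <- function(x, ...) {
  cat("<hhm_profile> ", x$length, " residues x 30 columns\n", sep = "")
  invisible(x)
}

#' Transform raw HHM pseudo-counts into frequencies
#'
#' Columns 1-27 (emissions and transitions) map through
#' `f = 2^(-0.001 * p)`, so `p = 0` gives 1 and the `*` sentinel
#' (`p = Inf`) gives 0. Columns 28-30 (alignment diversities) are scaled as
#' `f = 0.001 * p / 20`.
#'
#' @param raw Numeric vector of 30 raw values, or an n x 30 matrix.
#' @return Transformed values, same shape as `raw`.
#' @export
transform_hhm_row <- function(raw) {
  m <- if (is.matrix(raw)) raw else matrix(raw, nrow = 1)
  stopifnot(ncol(m) == 30L)
  out <- m
  out[, 1:27] <- 2^(-0.001 * m[, 1:27])
  out[, 28:30] <- 0.001 * m[, 28:30] / 20
  if (is.matrix(raw)) out else as.numeric(out)
}

#' Build the 500 x 58 protein feature matrix
#'
#' Row k holds the 58 features of the k-th selected residue: 21 one-hot,
#' 30 transformed HHM columns looked up by the residue's position in the
#' full sequence, and 7 physicochemical descriptors. More than
#' `n_rows` selected residues are truncated from the initial position;
#' fewer are zero-padded. Non-standard residues get the 21st one-hot slot
#' and zeros for the HHM and physicochemical blocks.
#'
#' @param selected Residue list from [select_interaction_residues()] (its
#'   `positions` attribute indexes the full-length profile), or a character
#'   vector of residue names (positions default to `seq_along`).
#' @param hhm An `hhm_profile` covering the full protein, or `NULL` for a
#'   zero profile (with a warning).
#' @param table A [physchem_table()].
#' @param n_rows Fixed number of rows (default 500).
#' @return A `protein_feature_matrix`: `n_rows` x 58 matrix with attribute
#'   `n_real` (number of non-padding rows).
#' @export
build_protein_matrix <- function(selected, hhm = NULL,
                                 table = physchem_table(), n_rows = 500L) {
  if (is.character(selected)) {
    selected <- lapply(seq_along(selected), function(i) {
      list(name = selected[[i]], seq_index = i)
    })
    attr(selected, "positions") <- seq_along(selected)
  }
  positions <- attr(selected, "positions") %||% seq_along(selected)
  names <- vapply(selected, function(r) r$name, "")
  if (is.null(hhm)) {
    warning("no HHM profile supplied; HHM feature block set to zero")
    # rows that transform to all-zero features: '*' sentinels for the
    # emission/transition columns, zero pseudo-counts for the diversities
    zero_rows <- cbind(
      matrix(Inf, max(positions, 0L), 27L),
      matrix(0, max(positions, 0L), 3L)
    )
    hhm <- structure(
      list(rows = zero_rows, length = max(positions, 0L)),
      class = "hhm_profile"
    )
  }
  if (length(positions) > 0 && max(positions) > hhm$length) {
    stop(
      "HHM profile length (", hhm$length, ") shorter than protein ",
      "(selected residue at position ", max(positions), "); ",
      "profile and structure are misaligned",
      call. = FALSE
    )
  }
  out <- matrix(0, n_rows, 58L)
  n_real <- min(length(selected), n_rows)
  for (k in seq_len(n_real)) {
    nm <- names[k]
    hrow <- if (nm %in% .standard_residues) {
      transform_hhm_row(hhm$rows[positions[k], ])
    } else {
      numeric(30) # zeroed like the physicochemical block
    }
    out[k, ] <- c(one_hot_residue(nm), hrow, physchem_vector(nm, table))
  }
  attr(out, "n_real") <- n_real
  class(out) <- c("protein_feature_matrix", class(out))
  out
}

#' Load the SMILES character vocabulary
#'
#' 64 single-character tokens mapped to the integer codes 1..64.
#' Tokenization is strictly per character (no multi-character element
#' tokens). Code 64 doubles as the catch-all for characters missing from
#' the table. The packaged table pins the seven assignments recoverable
#' from the formamide worked example (`H`→12, `C`→42, `(`→1, `O`→48,
#' `=`→40, `)`→31, `N`→14); the remaining codes are a fixed arbitrary
#' listing.
#'
#' @param path CSV path with columns `character`, `code`; default: the
#'   packaged vocabulary.
#' @return A `smiles_vocab`: named integer vector (names are characters).
#' @export
smiles_vocab <- function(path = NULL) {
  path <- path %||% dist_extdata("smiles_vocab.csv")
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = c("character", "integer"))
  v <- setNames(tab$code, tab$character)
  if (length(v) != 64L || anyDuplicated(tab$character) ||
      !setequal(v, 1:64)) {
    stop("SMILES vocabulary must map 64 distinct characters to codes 1..64",
      call. = FALSE
    )
  }
  class(v) <- "smiles_vocab"
  v
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("<smiles_vocab> 64 characters -> codes 1..64\n")
  invisible(x)
}

#' Integer-encode a SMILES string
#'
#' Character-level encoding against a 64-entry vocabulary; the result is
#' truncated to `length_out` codes or zero-padded (code 0 is padding).
#' Characters missing from the vocabulary map to the catch-all code 64
#' with a warning.
#'
#' @param smiles A SMILES string.
#' @param vocab A [smiles_vocab()].
#' @param length_out Fixed output length (default 150).
#' @return Integer vector of length `length_out`, values in 0..64.
#' @examples
#' head(encode_smiles("HC(O=)N"), 7) # 12 42 1 48 40 31 14
#' @export
encode_smiles <- function(smiles, vocab = smiles_vocab(), length_out = 150L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  codes <- unname(unclass(vocab)[chars])
  unknown <- is.na(codes)
  if (any(unknown)) {
    warning(
      "SMILES characters not in vocabulary mapped to catch-all code 64: ",
      paste(unique(chars[unknown]), collapse = " ")
    )
    codes[unknown] <- 64L
  }
  if (length(codes) >= length_out) {
    codes[seq_len(length_out)]
  } else {
    c(codes, integer(length_out - length(codes)))
  }
}

#' Synthetic HHM profile provider
#'
#' Generates a random but well-formed profile (integer pseudo-counts in
#' the ranges HHblits emits) for testing without running any sequence
#' search. Use [write_hhm()] to serialize it in the `.hhm` text layout.
#'
#' @param n_residues Number of residues.
#' @param seed Integer seed.
#' @return An `hhm_profile`.
#' @export
synthetic_hhm <- function(n_residues, seed = 1L) {
  with_seed(seed, {
    rows <- matrix(0, n_residues, 30L)
    # emission/transition scores: -1000*log2(freq), a few '*' (Inf) sentinels
    rows[, 1:27] <- round(runif(n_residues * 27L, 0, 8000))
    star <- runif(n_residues * 27L) < 0.1
    rows[, 1:27][star] <- Inf
    # diversities: Neff * 1000, Neff in [1, 12]
    rows[, 28:30] <- round(runif(n_residues * 3L, 1000, 12000))
    structure(list(rows = rows, length = n_residues), class = "hhm_profile")
  })
}

# evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Write an HHM profile in the HH-suite text layout
#'
#' Fixture-grade writer for the profile block actually consumed by
#' [parse_hhm()]; sequence names and null-model lines are synthetic.
#'
#' @param hhm An `hhm_profile`.
#' @param path Output path.
#' @param residue_chars Optional per-residue one-letter codes.
#' @return `path`, invisibly.
#' @export
write_hhm <- function(hhm, path, residue_chars = NULL) {
  n <- hhm$length
  residue_chars <- residue_chars %||% rep("A", n)
  fmt <- function(v) {
    ifelse(is.infinite(v), "*", format(round(v), scientific = FALSE, trim = TRUE))
  }
  header <- c(
    "HHsearch 1.5",
    "NAME  synthetic profile",
    "LENG  " %+% n %+% " match states",
    "#",
    "NULL   " %+% paste(rep("3000", 20), collapse = "\t"),
    "HMM    " %+% paste(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], collapse = "\t"),
    "       " %+% paste(
      c("M->M", "M->I", "M->D", "I->M", "I->I", "D->M", "D->D",
        "Neff", "Neff_I", "Neff_D"),
      collapse = "\t"
    ),
    "       0\t*\t*\t0\t*\t*\t*\t1000\t0\t0"
  )
  body <- character(2L * n)
  for (r in seq_len(n)) {
    body[2L * r - 1L] <- paste(
      c(residue_chars[r], r, fmt(hhm$rows[r, 1:20]), r),
      collapse = "\t"
    )
    body[2L * r] <- "       " %+% paste(fmt(hhm$rows[r, 21:30]), collapse = "\t")
  }
  writeLines(c(header, body, "//"), path)
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)
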