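#' Distance binning scheme for pocket featurization
#'
#' Distances in `[0, 20)` Angstrom are discretized into 40 half-Angstrom
#' bins (codes 1..40, left-closed right-open); anything at or beyond 20 A
#' falls in the overflow bin 41. Code 0 is reserved for padding so that
#' embedding layers can treat padding distinctly.
#'
#' @param cap Upper distance cap in Angstrom.
#' @param width Bin width in Angstrom.
#' @return A `binning_scheme` list.
#' @export
binning_scheme <- function(cap = 20, width = 0.5) {
  n <- cap / width
  stopifnot(n == round(n), cap > 0, width > 0)
  structure(
    list(
      cap = cap, width = width, n_regular_bins = as.integer(n),
      overflow_code = as.integer(n) + 1L, pad_code = 0L
    ),
    class = "binning_scheme"
  )
}

#' Discretize a distance into its bin code
#'
#' `floor(d / width) + 1` for `d < cap`; the overflow code for `d >= cap`.
#' Vectorized over `d`.
#'
#' @param d Non-negative distances in Angstrom.
#' @param scheme A [binning_scheme()].
#' @return Integer codes in `1..overflow_code`.
#' @examples
#' bin_distance(c(0.2, 10, 25)) # 1, 21, 41
#' @export
bin_distance <- function(d, scheme = binning_scheme()) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  code <- floor(d / scheme$width) + 1
  code[d >= scheme$cap] <- scheme$overflow_code
  as.integer(code)
}

atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

cross_distances <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(numeric(), nrow(a), nrow(b)))
  }
  pa <- atom_coords(a)
  pb <- atom_coords(b)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  sqrt(pmax(d2, 0))
}

new_distance_map <- function(cls, prot_atoms, lig_atoms, threshold = Inf) {
  d <- cross_distances(prot_atoms, lig_atoms)
  present <- is.finite(d) & d < threshold
  structure(
    list(
      cls = cls,
      protein_atom_ids = prot_atoms$serial,
      ligand_atom_ids = lig_atoms$serial,
      d = d, present = present, threshold = threshold
    ),
    class = "distance_map"
  )
}

#' @export
print.distance_map <- function(x, ...) {
  cat(
    "<distance_map> ", x$cls, ": ", nrow(x$d), " x ", ncol(x$d),
    " (", sum(x$present), " present pairs",
    if (is.finite(x$threshold)) paste0(", d < ", x$threshold, " A"), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Donor-acceptor distance map
#'
#' Rows are protein donor atoms (structure order), columns ligand acceptor
#' atoms. No distance cutoff is applied. If the ligand carries no acceptor
#' atoms at all, every heavy ligand atom is used as a column instead, so
#' all ligands contribute to the map.
#'
#' @param protein_donors Protein donor `typed_atom_set`.
#' @param ligand The `ligand_structure` (for the all-heavy-atom fallback).
#' @param ligand_acceptors Ligand acceptor `typed_atom_set`.
#' @return A `distance_map`.
#' @export
donor_acceptor_map <- function(protein_donors, ligand, ligand_acceptors) {
  cols <- ligand_acceptors$atoms
  if (nrow(cols) == 0L) {
    cols <- ligand$atoms[ligand$atoms$is_heavy, , drop = FALSE]
  }
  new_distance_map("DA", protein_donors$atoms, cols, threshold = Inf)
}

#' Hydrophobic distance map
#'
#' Pairs of hydrophobic protein and ligand atoms; only pairs strictly
#' closer than 4.5 Angstrom are present.
#'
#' @param protein_hp,ligand_hp Hydrophobic `typed_atom_set`s.
#' @param threshold Cutoff in Angstrom (default 4.5, strict `<`).
#' @return A `distance_map`.
#' @export
hydrophobic_map <- function(protein_hp, ligand_hp, threshold = 4.5) {
  new_distance_map("HP", protein_hp$atoms, ligand_hp$atoms, threshold)
}

#' Pi-stacking distance map
#'
#' Atom-to-atom distances between aromatic protein and ligand atoms; only
#' pairs strictly closer than 4.0 Angstrom are present.
#'
#' @param protein_pi,ligand_pi Pi-stacking `typed_atom_set`s.
#' @param threshold Cutoff in Angstrom (default 4.0, strict `<`).
#' @return A `distance_map`.
#' @export
pi_stacking_map <- function(protein_pi, ligand_pi, threshold = 4.0) {
  new_distance_map("PS", protein_pi$atoms, ligand_pi$atoms, threshold)
}

map_codes <- function(map, scheme) {
  if (length(map$d) == 0L) {
    return(integer())
  }
  # row-major (protein-major) flattening of the present pairs
  dt <- t(map$d)
  pt <- t(map$present)
  bin_distance(dt[pt], scheme)
}

#' Build the fixed-length pocket feature vector
#'
#' Each distance map is binned and flattened row-major (protein atoms as
#' rows); absent (threshold-excluded) pairs are skipped, so the vector
#' lists realized interactions only. The three blocks are concatenated in
#' the order donor-acceptor, pi-stacking, hydrophobic, then truncated to
#' the first `length_out` codes or zero-padded up to `length_out`.
#'
#' @param da,pis,hp `distance_map`s from [donor_acceptor_map()],
#'   [pi_stacking_map()], [hydrophobic_map()].
#' @param scheme A [binning_scheme()].
#' @param length_out Fixed output length (default 1000).
#' @return Integer vector of length `length_out`, values in
#'   `0..overflow_code` with padding zeros only as a suffix.
#' @export
build_pocket_vector <- function(da, pis, hp, scheme = binning_scheme(),
                                length_out = 1000L) {
  codes <- c(map_codes(da, scheme), map_codes(pis, scheme), map_codes(hp, scheme))
  if (length(codes) >= length_out) {
    codes <- codes[seq_len(length_out)]
  } else {
    codes <- c(codes, integer(length_out - length(codes)))
  }
  codes
}
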