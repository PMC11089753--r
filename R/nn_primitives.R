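#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V`: attention scores are
#' the dot products of queries and keys scaled by the square root of the
#' key dimensionality, row-normalized with a softmax, and used to take a
#' weighted sum of the value rows.
#'
#' @param q,k Query and key matrices with `d_k` columns (`k` and `v` must
#'   have the same number of rows).
#' @param v Value matrix.
#' @param d_k Key dimensionality used in the scaling factor (default:
#'   `ncol(k)`).
#' @return Matrix with `nrow(q)` rows and `ncol(v)` columns. The attention
#'   weight matrix is attached as attribute `"weights"`; its rows sum to 1.
#' @examples
#' # a single token attends only to itself: the output is v
#' scaled_dot_product_attention(matrix(1), matrix(1), matrix(5))
#' @export
scaled_dot_product_attention <- function(q, k, v, d_k = ncol(k)) {
  q <- as.matrix(q)
  k <- as.matrix(k)
  v <- as.matrix(v)
  if (!is.numeric(d_k) || length(d_k) != 1L || d_k <= 0) {
    stop("d_k must be a positive scalar", call. = FALSE)
  }
  if (ncol(q) != ncol(k)) {
    stop("q and k must share the inner dimension", call. = FALSE)
  }
  if (nrow(k) != nrow(v)) {
    stop("k and v must have the same number of rows", call. = FALSE)
  }
  s <- tcrossprod(q, k) / sqrt(d_k)
  s <- s - apply(s, 1, max) # row-wise stabilization
  w <- exp(s)
  w <- w / rowSums(w)
  out <- w %*% v
  attr(out, "weights") <- w
  out
}

#' Log-cosh loss
#'
#' Mean over samples of `log(cosh(pred - act))`: quadratic for small
#' errors, linear for large ones. Evaluated in the overflow-safe form
#' `|e| + log1p(exp(-2|e|)) - log(2)`.
#'
#' @param pred,act Numeric vectors of equal, non-zero length.
#' @return The scalar loss.
#' @export
log_cosh_loss <- function(pred, act) {
  stopifnot(is.numeric(pred), is.numeric(act))
  if (length(pred) != length(act) || length(pred) == 0L) {
    stop("pred and act must be non-empty vectors of equal length",
      call. = FALSE
    )
  }
  e <- abs(pred - act)
  mean(e + log1p(exp(-2 * e)) - log(2))
}

#' Convert a dissociation constant to pKd
#'
#' @param kd Dissociation constant in molar units.
#' @return `-log10(kd)`.
#' @examples
#' pkd_from_kd(1e-9) # 9
#' @export
pkd_from_kd <- function(kd) {
  stopifnot(is.numeric(kd), all(kd > 0))
  -log10(kd)
}

#' Build a table of affinity records
#'
#' @param complex_id Character ids.
#' @param kd Optional dissociation constants (molar).
#' @param pkd Optional pKd values; when both are given they must agree
#'   (`pkd == -log10(kd)` to 1e-9).
#' @return data.frame with columns `complex_id`, `kd`, `pkd`.
#' @export
affinity_records <- function(complex_id, kd = NULL, pkd = NULL) {
  if (is.null(kd) && is.null(pkd)) {
    stop("supply kd or pkd", call. = FALSE)
  }
  if (is.null(pkd)) pkd <- pkd_from_kd(kd)
  if (!is.null(kd) && any(abs(pkd - pkd_from_kd(kd)) > 1e-9)) {
    stop("inconsistent kd/pkd pair (pkd must equal -log10(kd))", call. = FALSE)
  }
  data.frame(
    complex_id = as.character(complex_id),
    kd = if (is.null(kd)) 10^(-pkd) else kd,
    pkd = pkd,
    stringsAsFactors = FALSE
  )
}

#' Run one CNN branch on an embedded sequence
#'
#' Three bias-free same-padded 1D convolutions with ReLU, each followed by
#' max pooling (width 2 after the first two, global over positions after
#' the third), reducing an `L x embed_dim` sequence to a vector with as
#' many entries as the last layer has filters.
#'
#' @param seq Embedded sequence, `L x embed_dim` matrix (`L >= 4`).
#' @param weights List of the three kernel matrices (as from
#'   [init_branch_weights()]).
#' @param kernels Integer triple of filter lengths.
#' @return Numeric vector of length `ncol(weights[[3]])` (128 by default).
#' @export
cnn_branch <- function(seq, weights, kernels = c(4L, 8L, 12L)) {
  seq <- as.matrix(seq)
  if (nrow(seq) < 4L) {
    stop("input shorter than the conv/pool stack's receptive field",
      call. = FALSE
    )
  }
  stopifnot(length(weights) == 3L, length(kernels) == 3L)
  cpp_cnn_branch(seq, weights, as.integer(kernels))
}

#' Initialize kernel matrices for one CNN branch
#'
#' Glorot-uniform kernels of shape `(kernel * channels_in) x filters`.
#'
#' @param embed_dim Input channel count of the first layer.
#' @param filters Integer triple of filter counts.
#' @param kernels Integer triple of filter lengths.
#' @return List of three kernel matrices.
#' @export
init_branch_weights <- function(embed_dim = 128L, filters = c(32L, 64L, 128L),
                                kernels = c(4L, 8L, 12L)) {
  cin <- c(embed_dim, filters[1], filters[2])
  lapply(1:3, function(i) {
    glorot(kernels[i] * cin[i], filters[i])
  })
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Embed the three model inputs
#'
#' Integer pocket and SMILES codes pass through lookup embeddings whose
#' padding row (code 0) is frozen at zero; the real-valued protein rows
#' pass through a bias-free linear projection, so padding rows stay zero
#' there too.
#'
#' @param pocket Integer pocket vector (length 1000 by default).
#' @param protein Protein feature matrix (500 x 58 by default).
#' @param smiles Integer SMILES encoding (length 150 by default).
#' @param model A `trained_affinity_model` (or a bare weight list with
#'   `emb_pocket`, `emb_smiles`, `Wproj`).
#' @return List of three embedded matrices: `pocket` (1000 x 128),
#'   `protein` (500 x 128), `smiles` (150 x 128).
#' @export
embed_inputs <- function(pocket, protein, smiles, model) {
  w <- if (inherits(model, "trained_affinity_model")) model$weights else model
  lookup <- function(codes, emb) {
    out <- matrix(0, length(codes), ncol(emb))
    nz <- codes > 0
    out[nz, ] <- emb[codes[nz] + 1L, , drop = FALSE]
    out
  }
  list(
    pocket = lookup(as.integer(pocket), w$emb_pocket),
    protein = unclass(protein)[, , drop = FALSE] %*% w$Wproj,
    smiles = lookup(as.integer(smiles), w$emb_smiles)
  )
}
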