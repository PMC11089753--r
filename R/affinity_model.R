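#' Model configuration
#'
#' Architecture and optimization hyperparameters of the three-branch
#' CNN + attention regressor. The defaults are the selected values of the
#' tuning grid: 32/64/128 filters of lengths 4/8/12 (4/6/8 on the SMILES
#' branch), 128-dimensional embeddings, two FC layers of 256 and 128
#' nodes, dropout 0.2, Adam with learning rate 0.001, batch size 16, 200
#' epochs with best-validation-loss checkpointing, log-cosh loss.
#'
#' @param embed_dim Embedding dimension.
#' @param cnn_filters Filter counts of the three conv layers.
#' @param kernel_protein_pocket Filter lengths for the pocket and protein
#'   branches.
#' @param kernel_smiles Filter lengths for the SMILES branch.
#' @param fc_nodes Nodes of the two fully connected layers.
#' @param dropout Dropout rate applied after each FC layer in training.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Integer seed governing initialization, shuffling, dropout.
#' @param pocket_len,protein_rows,protein_cols,smiles_len Input shapes.
#' @return A `model_config` list.
#' @export
model_config <- function(embed_dim = 128L, cnn_filters = c(32L, 64L, 128L),
                         kernel_protein_pocket = c(4L, 8L, 12L),
                         kernel_smiles = c(4L, 6L, 8L),
                         fc_nodes = c(256L, 128L), dropout = 0.2,
                         lr = 0.001, batch_size = 16L, epochs = 200L,
                         seed = 1L, pocket_len = 1000L, protein_rows = 500L,
                         protein_cols = 58L, smiles_len = 150L) {
  cfg <- list(
    embed_dim = as.integer(embed_dim),
    cnn_filters = as.integer(cnn_filters),
    kernel_protein_pocket = as.integer(kernel_protein_pocket),
    kernel_smiles = as.integer(kernel_smiles),
    fc_nodes = as.integer(fc_nodes),
    dropout = dropout, lr = lr,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    seed = as.integer(seed),
    pocket_len = as.integer(pocket_len),
    protein_rows = as.integer(protein_rows),
    protein_cols = as.integer(protein_cols),
    smiles_len = as.integer(smiles_len),
    pocket_vocab = 41L, smiles_vocab = 64L
  )
  stopifnot(
    cfg$embed_dim > 0, all(cfg$cnn_filters > 0),
    length(cfg$cnn_filters) == 3L,
    length(cfg$kernel_protein_pocket) == 3L,
    length(cfg$kernel_smiles) == 3L,
    cfg$dropout >= 0, cfg$dropout < 1, cfg$lr > 0, cfg$batch_size > 0,
    cfg$epochs > 0
  )
  structure(cfg, class = "model_config")
}

#' Initialize model weights
#'
#' Glorot-uniform kernels and FC weights, uniform(-0.5, 0.5) embedding
#' rows with the padding row (code 0) frozen at zero (the scale puts the
#' integer-coded branches on the same activation footing as the
#' real-valued protein branch), zero biases, and a
#' deterministic starting point for the attention projections
#' (`wq = wk = 0.5`, `wv = 1`, zero biases) so that attention neither
#' collapses to uniform mixing nor saturates at initialization.
#'
#' @param cfg A [model_config()].
#' @return Named list of weight matrices.
#' @export
init_affinity_model <- function(cfg = model_config()) {
  with_seed(cfg$seed, {
    f <- cfg$cnn_filters
    kp <- cfg$kernel_protein_pocket
    ks <- cfg$kernel_smiles
    e <- cfg$embed_dim
    emb <- function(nrow) {
      m <- matrix(runif(nrow * e, -0.5, 0.5), nrow, e)
      m[1, ] <- 0
      m
    }
    branch <- function(kern) {
      w <- init_branch_weights(e, f, kern)
      names(w) <- paste0("W", 1:3)
      w
    }
    pk <- branch(kp)
    pr <- branch(kp)
    sm <- branch(ks)
    list(
      emb_pocket = emb(cfg$pocket_vocab + 1L),
      emb_smiles = emb(cfg$smiles_vocab + 1L),
      Wproj = glorot(cfg$protein_cols, e),
      pkW1 = pk$W1, pkW2 = pk$W2, pkW3 = pk$W3,
      prW1 = pr$W1, prW2 = pr$W2, prW3 = pr$W3,
      smW1 = sm$W1, smW2 = sm$W2, smW3 = sm$W3,
      att = matrix(c(0.5, 0, 0.5, 0, 1, 0), 1, 6,
        dimnames = list(NULL, c("wq", "bq", "wk", "bk", "wv", "bv"))
      ),
      Wf1 = glorot(3L * f[3], cfg$fc_nodes[1]),
      bf1 = matrix(0, 1, cfg$fc_nodes[1]),
      Wf2 = glorot(cfg$fc_nodes[1], cfg$fc_nodes[2]),
      bf2 = matrix(0, 1, cfg$fc_nodes[2]),
      Wo = glorot(cfg$fc_nodes[2], 1L),
      bo = matrix(0, 1, 1)
    )
  })
}

#' Train an affinity model
#'
#' Minimizes the log-cosh loss with Adam (learning rate, batch size and
#' epoch count from `cfg`), evaluating the validation loss after every
#' epoch and returning the weights of the epoch with the lowest validation
#' loss. Fully seeded: the same `cfg$seed` reproduces weights bit for bit.
#'
#' @param dataset A labelled `affinity_dataset`.
#' @param cfg A [model_config()].
#' @param val_fraction Fraction of complexes held out for validation
#'   (ignored when `val_indices` is given).
#' @param val_indices Explicit validation indices into `dataset`.
#' @return A `trained_affinity_model`: weights, config, training history,
#'   `best_epoch` and the validation indices used.
#' @export
train_affinity_model <- function(dataset, cfg = model_config(),
                                 val_fraction = 0.1, val_indices = NULL) {
  stopifnot(inherits(dataset, "affinity_dataset"))
  if (is.null(dataset$pkd)) {
    stop("dataset carries no pKd labels", call. = FALSE)
  }
  n <- length(dataset)
  if (is.null(val_indices)) {
    n_val <- max(1L, round(val_fraction * n))
    if (n_val >= n) stop("validation split leaves no training data", call. = FALSE)
    val_indices <- with_seed(cfg$seed, sample.int(n, n_val))
  }
  val_indices <- sort(unique(as.integer(val_indices)))
  if (length(val_indices) == 0L) {
    stop("validation set must be non-empty", call. = FALSE)
  }
  tr_idx <- setdiff(seq_len(n), val_indices)
  if (length(tr_idx) == 0L) stop("training set is empty", call. = FALSE)
  lengths <- crop_lengths(dataset)
  tr <- dataset_tensors(subset_dataset(dataset, tr_idx), lengths)
  va <- dataset_tensors(subset_dataset(dataset, val_indices), lengths)
  weights <- init_affinity_model(cfg)
  # start the output bias at the training-target mean so early epochs are
  # not spent walking the (Adam-step-bounded) bias towards the pKd scale
  weights$bo[1, 1] <- mean(tr$y)
  fit <- with_seed(cfg$seed + 1L, cpp_train(weights, tr, va, cfg))
  structure(
    list(
      weights = fit$weights, final_weights = fit$final_weights, config = cfg,
      history = data.frame(
        epoch = seq_along(fit$train_loss),
        train_loss = fit$train_loss, val_loss = fit$val_loss
      ),
      best_epoch = fit$best_epoch,
      best_val_loss = fit$best_val_loss,
      val_indices = val_indices,
      crop = lengths
    ),
    class = "trained_affinity_model"
  )
}

#' @export
print.trained_affinity_model <- function(x, ...) {
  cat(
    "<trained_affinity_model> best epoch ", x$best_epoch, "/",
    nrow(x$history), ", val loss ",
    signif(x$best_val_loss, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Predict pKd for featurized complexes
#'
#' @param object A `trained_affinity_model`.
#' @param newdata An `affinity_dataset`, a `complex_features` object, or a
#'   list of them.
#' @param weights `"best"` (the minimum-validation-loss checkpoint, the
#'   deployment default) or `"final"` (the weights after the last epoch,
#'   useful for capacity/overfitting analyses).
#' @param ... Unused.
#' @return Numeric vector of predicted pKd values.
#' @export
predict.trained_affinity_model <- function(object, newdata,
                                           weights = c("best", "final"),
                                           ...) {
  weights <- match.arg(weights)
  w <- if (weights == "final") object$final_weights else object$weights
  ds <- as_affinity_dataset(newdata)
  tensors <- dataset_tensors(ds)
  as.numeric(cpp_predict(w, tensors, object$config))
}

as_affinity_dataset <- function(x) {
  if (inherits(x, "affinity_dataset")) {
    return(x)
  }
  if (inherits(x, "complex_features")) {
    return(make_model_dataset(list(x)))
  }
  if (is.list(x) && all(vapply(x, inherits, TRUE, "complex_features"))) {
    return(make_model_dataset(x))
  }
  stop("cannot interpret newdata as featurized complexes", call. = FALSE)
}

#' Single-complex forward pass
#'
#' @param pocket,protein,smiles Features as built by [featurize_complex()].
#' @param model A `trained_affinity_model`.
#' @return The predicted pKd (finite scalar).
#' @export
forward_affinity <- function(pocket, protein, smiles, model) {
  feats <- structure(
    list(
      pocket = pocket, protein = protein, smiles = smiles,
      meta = list(n_residues = max(1L, sum(rowSums(abs(protein)) > 0)))
    ),
    class = "complex_features"
  )
  predict(model, feats)
}

#' Bootstrap training subsets
#'
#' Samples `k` subsets with replacement, each of the original dataset
#' size, for bootstrap ensembling.
#'
#' @param dataset An `affinity_dataset` (or anything with a length).
#' @param k Number of subsets.
#' @param seed Integer seed.
#' @return List of `k` integer index vectors.
#' @export
bootstrap_subsets <- function(dataset, k = 5L, seed = 1L) {
  n <- length(dataset)
  stopifnot(n >= 1L, k >= 1L)
  with_seed(seed, lapply(seq_len(k), function(i) sample.int(n, n, replace = TRUE)))
}

#' Train a five-model average ensemble
#'
#' Trains five models that differ in their random seed (weights,
#' shuffling, dropout) and, in the `bootstrap` regime, in their training
#' subset (sampled with replacement to the original size). Member seeds
#' are `cfg$seed + 0:4`. Prediction is the arithmetic mean of the member
#' predictions.
#'
#' @param dataset Labelled `affinity_dataset`.
#' @param cfg A [model_config()].
#' @param regime `"same_data"` (members share the full training set) or
#'   `"bootstrap"`.
#' @param val_fraction,val_indices Validation split, as in
#'   [train_affinity_model()]; the split is fixed across members.
#' @param n_members Ensemble size (the deployment contract is 5).
#' @return An `affinity_ensemble`.
#' @export
train_ensemble <- function(dataset, cfg = model_config(),
                           regime = c("same_data", "bootstrap"),
                           val_fraction = 0.1, val_indices = NULL,
                           n_members = 5L) {
  regime <- match.arg(regime)
  n <- length(dataset)
  if (is.null(val_indices)) {
    n_val <- max(1L, round(val_fraction * n))
    val_indices <- with_seed(cfg$seed, sample.int(n, n_val))
  }
  val_indices <- sort(unique(as.integer(val_indices)))
  tr_idx <- setdiff(seq_len(n), val_indices)
  subsets <- if (regime == "bootstrap") {
    lapply(
      bootstrap_subsets(subset_dataset(dataset, tr_idx), n_members, cfg$seed),
      function(i) tr_idx[i]
    )
  } else {
    rep(list(tr_idx), n_members)
  }
  members <- lapply(seq_len(n_members), function(m) {
    mcfg <- cfg
    mcfg$seed <- cfg$seed + m - 1L
    sub <- subset_dataset(dataset, c(subsets[[m]], val_indices))
    nsub <- length(subsets[[m]])
    train_affinity_model(sub, mcfg,
      val_indices = nsub + seq_along(val_indices)
    )
  })
  structure(
    list(members = members, regime = regime, config = cfg),
    class = "affinity_ensemble"
  )
}

#' @export
print.affinity_ensemble <- function(x, ...) {
  cat(
    "<affinity_ensemble> ", length(x$members), " members, regime '",
    x$regime, "'\n",
    sep = ""
  )
  invisible(x)
}

#' Average-ensemble prediction
#'
#' Arithmetic mean of the five member predictions.
#'
#' @param ens An `affinity_ensemble` with exactly 5 members.
#' @param newdata As in [predict.trained_affinity_model()].
#' @return Numeric vector of ensemble pKd predictions.
#' @export
ensemble_predict <- function(ens, newdata) {
  stopifnot(inherits(ens, "affinity_ensemble"))
  if (length(ens$members) != 5L) {
    stop("ensemble must have exactly 5 members, got ", length(ens$members),
      call. = FALSE
    )
  }
  preds <- vapply(
    ens$members, function(m) predict(m, newdata),
    numeric(length(as_affinity_dataset(newdata)))
  )
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' @export
predict.affinity_ensemble <- function(object, newdata, ...) {
  ensemble_predict(object, newdata)
}
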