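# The two-arm MLP drug response model: configuration, training protocol,
# evaluation metrics, drug-arm embeddings and the collapse diagnostic.

#' Configure the two-arm MLP
#'
#' The model embeds cell features and drug fingerprints through separate
#' stacks of affine+ReLU layers with strictly decreasing widths, then
#' concatenates the two embeddings into a ReLU head ending in a single
#' linear output.  Trained with minibatch Adam on mean-squared error and
#' early stopping on validation loss (ties broken toward the earlier
#' epoch).  Defaults follow the full-scale configuration (cell arm
#' 1000/750/500, batch 16, learning rate 1e-4, up to 100 epochs with
#' patience 10); see [modelConfigSynthetic()] for the desk-scale variant.
#'
#' @param cell_arm_widths,drug_arm_widths,head_widths strictly decreasing
#'   positive integer vectors of hidden-layer widths.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs,patience early-stopping protocol: training stops after
#'   `patience` epochs without validation improvement.
#' @param seed integer seed for weight initialization and batch order.
#' @param cell_entry_layer number of leading cell-arm layers to skip, for
#'   precomputed cell embeddings that should enter the arm at a deeper
#'   layer (0 = use the full arm).
#' @param standardize_cells z-score cell features per-feature using
#'   training-partition statistics.
#' @param snapshot_epochs integer vector of epochs at which to checkpoint
#'   parameters for embedding snapshots.
#' @return A named list of class `ModelConfig`.
#' @export
modelConfig <- function(cell_arm_widths = c(1000L, 750L, 500L),
                        drug_arm_widths = c(512L, 256L, 128L),
                        head_widths = c(256L, 64L),
                        learning_rate = 1e-4, batch_size = 16L,
                        max_epochs = 100L, patience = 10L, seed = 1L,
                        cell_entry_layer = 0L, standardize_cells = TRUE,
                        snapshot_epochs = integer()) {
  for (w in list(cell_arm_widths, drug_arm_widths, head_widths)) {
    if (length(w) && any(diff(w) >= 0))
      stop("arm widths must be strictly decreasing")
    if (length(w) && any(w < 1)) stop("all widths must be >= 1")
  }
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (cell_entry_layer < 0 || cell_entry_layer >= length(cell_arm_widths))
    stop("cell_entry_layer must index into the cell arm")
  structure(list(cell_arm_widths = as.integer(cell_arm_widths),
                 drug_arm_widths = as.integer(drug_arm_widths),
                 head_widths = as.integer(head_widths),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 cell_entry_layer = as.integer(cell_entry_layer),
                 standardize_cells = isTRUE(standardize_cells),
                 snapshot_epochs = as.integer(snapshot_epochs)),
            class = "ModelConfig")
}

#' Desk-scale model configuration for synthetic panels
#'
#' Shrunken arms (cell 128/64, drug 64/32, head 32) and a faster training
#' protocol (learning rate 1e-3, batch 32, up to 60 epochs, patience 6)
#' sized for synthetic panels of a few thousand tuples, where the larger
#' full-scale arms add runtime but no accuracy.
#'
#' @param ... overrides passed on to [modelConfig()].
#' @return A `ModelConfig` list.
#' @export
modelConfigSynthetic <- function(...) {
  args <- list(cell_arm_widths = c(128L, 64L), drug_arm_widths = c(64L, 32L),
               head_widths = 32L, learning_rate = 1e-3, batch_size = 32L,
               max_epochs = 60L, patience = 6L)
  override <- list(...)
  args[names(override)] <- override
  do.call(modelConfig, args)
}

.active_cell_widths <- function(config) {
  w <- config$cell_arm_widths
  if (config$cell_entry_layer > 0L)
    w <- w[-seq_len(config$cell_entry_layer)]
  w
}

#' Build an (untrained) two-arm MLP
#'
#' Initializes all layer parameters from `config$seed` (He-scaled normal
#' weights, zero biases).  With `cell_entry_layer > 0` the leading cell-arm
#' layers are removed so precomputed embeddings enter the arm at a deeper
#' layer.
#'
#' @param config a [modelConfig()] list.
#' @param cell_width,drug_width input feature widths.
#' @return An untrained [TrainedDRPModel-class].
#' @export
buildModel <- function(config, cell_width, drug_width) {
  net <- .mlp_init(as.integer(cell_width), as.integer(drug_width),
                   .active_cell_widths(config), config$drug_arm_widths,
                   config$head_widths, config$seed)
  new("TrainedDRPModel", config = unclass(config), net = net,
      history = data.frame(), bestEpoch = 0L, snapshots = list(),
      preprocessing = list(), trained = FALSE)
}

.gather_features <- function(tuples, drugs, cells) {
  xc <- featureMatrix(cells)
  xd <- featureMatrix(drugs)
  miss_c <- setdiff(unique(tuples$cell_id), rownames(xc))
  miss_d <- setdiff(unique(tuples$drug_id), rownames(xd))
  if (length(miss_c)) stop("no features for cell id: ", miss_c[1L])
  if (length(miss_d)) stop("no features for drug id: ", miss_d[1L])
  list(Xc = xc[tuples$cell_id, , drop = FALSE],
       Xd = xd[tuples$drug_id, , drop = FALSE])
}

#' Train a two-arm MLP on one split of a panel
#'
#' Minimizes mean-squared error with Adam; validation loss is recorded once
#' per epoch and the parameters of the best validation epoch are restored
#' at the end.  If `standardize_cells`, per-feature mean/SD are computed on
#' the training partition only and applied to all partitions; fingerprints
#' are used raw.
#'
#' @param model an untrained model from [buildModel()], or a
#'   [modelConfig()] list (a model is then built to match the features).
#' @param panel a [ResponsePanel-class].
#' @param drugs a [DrugFeatureSet-class] covering the split's drugs.
#' @param cells a [CellFeatureSet-class] covering the split's cells.
#' @param split a [SplitAssignment-class] over `panel`.
#' @return A trained [TrainedDRPModel-class].
#' @export
trainModel <- function(model, panel, drugs, cells, split) {
  if (inherits(model, "ModelConfig"))
    model <- buildModel(model, featureWidth(cells), featureWidth(drugs))
  config <- model@config
  t <- panel@tuples
  if (length(split@partition) != nrow(t))
    stop("split does not match the panel")
  idx_tr <- partitionIndices(split, "train")
  idx_val <- partitionIndices(split, "val")
  if (!length(idx_val)) stop("validation partition is empty")
  if (!length(idx_tr)) stop("training partition is empty")

  tr <- .gather_features(t[idx_tr, ], drugs, cells)
  va <- .gather_features(t[idx_val, ], drugs, cells)
  prep <- list(center = NULL, scale = NULL)
  if (config$standardize_cells) {
    ctr <- colMeans(tr$Xc)
    scl <- apply(tr$Xc, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    tr$Xc <- scale(tr$Xc, center = ctr, scale = scl)
    va$Xc <- scale(va$Xc, center = ctr, scale = scl)
    prep <- list(center = ctr, scale = scl)
  }
  fit <- .mlp_train(model@net, tr$Xc, tr$Xd, t$response[idx_tr],
                    va$Xc, va$Xd, t$response[idx_val],
                    config$learning_rate, config$batch_size,
                    config$max_epochs, config$patience, config$seed,
                    config$snapshot_epochs)
  history <- data.frame(epoch = seq_along(fit$train_loss),
                        train_loss = fit$train_loss,
                        val_loss = fit$val_loss)
  snaps <- fit$snapshots
  names(snaps) <- as.character(fit$snapshot_epochs)
  new("TrainedDRPModel", config = config, net = fit$net, history = history,
      bestEpoch = as.integer(fit$best_epoch), snapshots = snaps,
      preprocessing = prep, trained = TRUE)
}

.apply_cell_prep <- function(model, Xc) {
  prep <- model@preprocessing
  if (!is.null(prep$center))
    Xc <- scale(Xc, center = prep$center, scale = prep$scale)
  Xc
}

#' Predict responses for (cell, drug) pairs
#'
#' @param model a trained [TrainedDRPModel-class].
#' @param pairs data.frame with columns `cell_id`, `drug_id` (duplicates
#'   allowed; output order matches input order).
#' @param drugs,cells feature sets covering all ids in `pairs`.
#' @return numeric vector of predictions, one per row of `pairs`.
#' @export
predictPairs <- function(model, pairs, drugs, cells) {
  if (!model@trained) stop("model is not trained")
  f <- .gather_features(pairs, drugs, cells)
  as.numeric(.mlp_predict(model@net, .apply_cell_prep(model, f$Xc), f$Xd))
}

#' Evaluate predictions globally and per drug
#'
#' Computes the Pearson correlation between predictions and true responses
#' over all pairs and within each drug.  Drugs with fewer than two
#' evaluated tuples, or with constant truth or constant predictions, are
#' flagged undefined (`NA`) rather than propagating NaN, and are excluded
#' from aggregates.
#'
#' @param predictions numeric vector.
#' @param truth data.frame with columns `cell_id`, `drug_id`, `response`,
#'   aligned with `predictions`.
#' @return An [EvaluationResult-class].
#' @export
evaluatePredictions <- function(predictions, truth) {
  if (length(predictions) != nrow(truth))
    stop("predictions and truth tuples have different lengths")
  if (length(predictions) < 2L) stop("need at least 2 pairs to evaluate")
  safe_cor <- function(a, b) {
    if (length(a) < 2L || sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }
  global <- safe_cor(predictions, truth$response)
  per <- lapply(split(seq_len(nrow(truth)), truth$drug_id), function(idx) {
    data.frame(pearson = safe_cor(predictions[idx], truth$response[idx]),
               n = length(idx))
  })
  perDrug <- do.call(rbind, per)
  perDrug <- data.frame(drug_id = names(per), pearson = perDrug$pearson,
                        n = perDrug$n, row.names = NULL)
  new("EvaluationResult", globalPearson = global, perDrug = perDrug)
}

#' Extract drug-arm embeddings
#'
#' Returns the post-activation output of the final drug-arm layer for every
#' drug in the feature set, either for the stored (best-epoch) parameters
#' or for a checkpointed snapshot epoch.
#'
#' @param model a [TrainedDRPModel-class] (snapshots must have been enabled
#'   via `snapshot_epochs` if `at_epoch` is given).
#' @param drugs a [DrugFeatureSet-class].
#' @param at_epoch optional checkpoint epoch.
#' @return numeric matrix, drugs x embedding width.
#' @export
extractDrugEmbeddings <- function(model, drugs, at_epoch = NULL) {
  net <- model@net
  if (!is.null(at_epoch)) {
    key <- as.character(at_epoch)
    if (!key %in% names(model@snapshots))
      stop("epoch ", at_epoch, " was not checkpointed")
    net <- model@snapshots[[key]]
  }
  emb <- .mlp_drug_embed(net, featureMatrix(drugs))
  rownames(emb) <- drugIds(drugs)
  emb
}

#' Drug-mean collapse diagnostic
#'
#' For each drug with at least two evaluated tuples, reports the ratio of
#' the standard deviation of its predictions to the standard deviation of
#' its true responses, plus the absolute gap between mean prediction and
#' mean truth.  Ratios near zero diagnose collapse to the per-drug mean —
#' predictions that ignore the cell line entirely.
#'
#' @param predictions numeric vector aligned with `panel`'s tuples (or with
#'   `tuples` if given).
#' @param panel a [ResponsePanel-class], or a tuple data.frame.
#' @return data.frame with `drug_id`, `sd_ratio`, `mean_gap`, `n`.
#' @export
collapseDiagnostic <- function(predictions, panel) {
  t <- if (is(panel, "ResponsePanel")) panel@tuples else panel
  if (length(predictions) != nrow(t))
    stop("predictions are not aligned with the panel tuples")
  rows <- lapply(split(seq_len(nrow(t)), t$drug_id), function(idx) {
    if (length(idx) < 2L) return(NULL)
    sd_truth <- sd(t$response[idx])
    data.frame(sd_ratio = if (sd_truth == 0) NA_real_ else
                 sd(predictions[idx]) / sd_truth,
               mean_gap = abs(mean(predictions[idx]) - mean(t$response[idx])),
               n = length(idx))
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  data.frame(drug_id = names(rows)[keep], sd_ratio = out$sd_ratio,
             mean_gap = out$mean_gap, n = out$n, row.names = NULL)
}

#' Per-drug-mean baseline predictor
#'
#' The oracle a collapsed model converges to: predicts each drug's mean
#' training response (the global training mean for drugs never seen in
#' training).  Used as the reference point for permutation experiments.
#'
#' @param train_tuples data.frame of training tuples (`drug_id`,
#'   `response`).
#' @param pairs data.frame of pairs to predict (`drug_id` column used).
#' @return numeric vector of predictions.
#' @export
drugMeanBaseline <- function(train_tuples, pairs) {
  means <- tapply(train_tuples$response, train_tuples$drug_id, mean)
  out <- unname(means[pairs$drug_id])
  out[is.na(out)] <- mean(train_tuples$response)
  as.numeric(out)
}
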