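# Train/validation/test designs and the two permutation nulls.
#
# Every operation here is a pure function of (panel, parameters, seed);
# fractional partition sizes use the largest-remainder method with residual
# tuples assigned to train.

.largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    ord <- order(raw - sizes, decreasing = TRUE)
    # residual goes to train first on exact ties
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1L
  }
  as.integer(sizes)
}

.new_split <- function(mode, partition, tuples, frozen = FALSE,
                       params = list(), seed = 0L) {
  new("SplitAssignment", mode = mode, partition = partition,
      trainingDrugs = sort(unique(tuples$drug_id[partition == "train"])),
      frozenTest = frozen, params = params, seed = as.integer(seed))
}

#' Mixed-set split: tuples assigned at random
#'
#' Drugs and cells may appear in every partition; this is the standard
#' (least drug-blind) evaluation design.
#'
#' @param panel a [ResponsePanel-class] with at least 10 tuples.
#' @param fractions train/val/test proportions, positive and summing to 1.
#' @param seed integer seed.
#' @return A [SplitAssignment-class] with mode `"mixed"`.
#' @export
splitMixed <- function(panel, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- nTuples(panel)
  if (n < 10L) stop("mixed split needs a panel with at least 10 tuples")
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be positive and sum to 1 (val/test nonempty)")
  sizes <- .largest_remainder(n, fractions)
  part <- .with_seed(seed, sample(rep(c("train", "val", "test"), sizes)))
  .new_split("mixed", part, panel@tuples, params = list(fractions = fractions),
             seed = seed)
}

.partition_drugs <- function(drugs, fractions, seed) {
  nd <- length(drugs)
  sizes <- .largest_remainder(nd, fractions)
  # every partition needs at least one drug; steal from the largest (train)
  while (any(sizes == 0L)) {
    i <- which(sizes == 0L)[1L]
    j <- which.max(sizes)
    sizes[i] <- 1L
    sizes[j] <- sizes[j] - 1L
  }
  shuffled <- .with_seed(seed, sample(drugs))
  split(shuffled, rep(c("train", "val", "test"), sizes))
}

#' Drug-blind split: unique drugs disjoint across partitions
#'
#' Partitions the unique drugs by the given fractions; every tuple follows
#' its drug, so train, val and test drug sets are pairwise disjoint.
#'
#' @param panel a [ResponsePanel-class] with at least 3 unique drugs.
#' @param drug_fractions train/val/test proportions over unique drugs.
#' @param seed integer seed.
#' @return A [SplitAssignment-class] with mode `"drug_blind"`.
#' @export
splitDrugBlind <- function(panel, drug_fractions = c(0.8, 0.1, 0.1),
                           seed = 1L) {
  drugs <- drugIds(panel)
  if (length(drugs) < 3L)
    stop("drug-blind split needs at least as many drugs as partitions")
  groups <- .partition_drugs(drugs, drug_fractions, seed)
  lookup <- setNames(rep(names(groups), lengths(groups)),
                     unlist(groups, use.names = FALSE))
  part <- unname(lookup[panel@tuples$drug_id])
  .new_split("drug_blind", part, panel@tuples,
             params = list(drug_fractions = drug_fractions), seed = seed)
}

#' Fixed-test composition split
#'
#' The design behind the composition sweep: the test and validation drug
#' sets are drawn once from `base_seed` and frozen across the sweep, while
#' the training drugs are a fresh uniform subset of the remaining pool for
#' every sweep `seed`.  Drugs outside all three sets are excluded.
#'
#' @param panel a [ResponsePanel-class].
#' @param n_test_drugs,n_val_drugs sizes of the frozen test/val drug sets.
#' @param train_count number of training drugs drawn per sweep run.
#' @param seed sweep seed (varies per run).
#' @param base_seed seed freezing the test/val drug sets.
#' @return A [SplitAssignment-class] with mode `"fixed_test_composition"`
#'   and `frozenTest = TRUE`.
#' @export
splitFixedTest <- function(panel, n_test_drugs, n_val_drugs, train_count,
                           seed = 1L, base_seed = 1000L) {
  drugs <- drugIds(panel)
  if (n_test_drugs + n_val_drugs + train_count > length(drugs))
    stop("training drug pool is too small: test + val + train counts ",
         "exceed the number of unique drugs")
  frozen <- .with_seed(base_seed, {
    test <- sample(drugs, n_test_drugs)
    val <- sample(setdiff(drugs, test), n_val_drugs)
    list(test = test, val = val)
  })
  pool <- setdiff(drugs, c(frozen$test, frozen$val))
  if (train_count > length(pool))
    stop("training drug pool is smaller than train_count")
  train <- .with_seed(seed, sample(pool, train_count))
  lookup <- setNames(rep("excluded", length(drugs)), drugs)
  lookup[frozen$test] <- "test"
  lookup[frozen$val] <- "val"
  lookup[train] <- "train"
  part <- unname(lookup[panel@tuples$drug_id])
  .new_split("fixed_test_composition", part, panel@tuples, frozen = TRUE,
             params = list(n_test_drugs = n_test_drugs,
                           n_val_drugs = n_val_drugs,
                           train_count = train_count, base_seed = base_seed),
             seed = seed)
}

#' Partially drug-blind split
#'
#' A random fraction of the unique drugs becomes the training set; their
#' tuples are divided into train/val/test by `within_fractions`.  Every
#' tuple of every non-training drug is held out, divided between val and
#' test at the val:test ratio implied by `within_fractions`, so the held-out
#' partitions jointly contain every drug — each drug is drug-blind in some
#' sweep runs and seen in others.
#'
#' @param panel a [ResponsePanel-class] with at least 4 unique drugs.
#' @param train_drug_fraction fraction of drugs trained on (default 0.5).
#' @param within_fractions train/val/test proportions for training drugs.
#' @param seed integer seed.
#' @return A [SplitAssignment-class] with mode `"partial_blind"`.
#' @export
splitPartialBlind <- function(panel, train_drug_fraction = 0.5,
                              within_fractions = c(0.8, 0.1, 0.1),
                              seed = 1L) {
  drugs <- drugIds(panel)
  if (length(drugs) < 4L)
    stop("partial-blind split needs at least 4 unique drugs")
  t <- panel@tuples
  part <- character(nrow(t))
  singletons <- character()
  .with_seed(seed, {
    train_drugs <- sample(drugs, floor(train_drug_fraction * length(drugs)))
    heldout_fracs <- within_fractions[2:3] / sum(within_fractions[2:3])
    for (d in drugs) {
      idx <- which(t$drug_id == d)
      n <- length(idx)
      if (d %in% train_drugs) {
        sizes <- .largest_remainder(n, within_fractions)
        if (sizes[3] == 0L && n >= 2L) {  # every drug must reach the test set
          j <- which.max(sizes)
          sizes[j] <- sizes[j] - 1L
          sizes[3] <- 1L
        }
        part[idx] <- sample(rep(c("train", "val", "test"), sizes))
      } else if (n == 1L) {
        part[idx] <- "test"
        singletons <- c(singletons, d)
      } else {
        sizes <- .largest_remainder(n, heldout_fracs)
        if (sizes[2] == 0L) {
          sizes[1] <- sizes[1] - 1L
          sizes[2] <- 1L
        }
        part[idx] <- sample(rep(c("val", "test"), sizes))
      }
    }
  })
  if (length(singletons))
    warning("drugs with a single measured cell assigned wholly to test: ",
            paste(singletons, collapse = ", "))
  .new_split("partial_blind", part, t,
             params = list(train_drug_fraction = train_drug_fraction,
                           within_fractions = within_fractions), seed = seed)
}

#' Cap the number of training cells per drug
#'
#' Reproduces the dataset-diversity design: drugs measured on fewer than
#' `min_cells` cell lines are removed from the split entirely (so the drug
#' pool is identical across all cap levels), and each surviving drug's
#' training tuples are subsampled uniformly down to at most `k`.  The val
#' and test partitions are untouched.
#'
#' @param split a [SplitAssignment-class] built on `panel`.
#' @param panel the [ResponsePanel-class] the split was built on.
#' @param k maximum training tuples per drug, `k >= 1`.
#' @param min_cells minimum total measured cells for a drug to survive; use
#'   500 for the large public screens, or about 80% of the panel's cell
#'   count on small synthetic panels.
#' @param seed integer seed for the subsampling.
#' @return A new [SplitAssignment-class] with capped train partition.
#' @export
capTrainingCells <- function(split, panel, k, min_cells = 500L, seed = 1L) {
  stopifnot(k >= 1L)
  t <- panel@tuples
  if (length(split@partition) != nrow(t))
    stop("split and panel do not match")
  part <- split@partition
  counts <- table(t$drug_id)
  dropped <- names(counts)[counts < min_cells]
  part[t$drug_id %in% dropped] <- "excluded"
  if (all(part == "excluded"))
    stop("all drugs removed by the min_cells filter")
  .with_seed(seed, {
    for (d in setdiff(unique(t$drug_id), dropped)) {
      idx <- which(part == "train" & t$drug_id == d)
      if (length(idx) > k)
        part[sample(idx, length(idx) - k)] <- "excluded"
    }
  })
  .new_split(split@mode, part, t, frozen = split@frozenTest,
             params = c(split@params, list(cap_k = k, min_cells = min_cells,
                                           cap_seed = seed)),
             seed = split@seed)
}

#' Intradrug response shuffle (permutation null)
#'
#' For each drug independently, permutes its response values uniformly
#' across the cell lines it was measured on: the drug's response
#' distribution is exactly preserved while the cell pairing is destroyed.
#' A model trained on this null can only learn per-drug distributions.
#'
#' @param panel a [ResponsePanel-class].
#' @param seed integer seed.
#' @return A shuffled [ResponsePanel-class] with identical tuple order.
#' @export
shuffleIntradrug <- function(panel, seed = 1L) {
  t <- panel@tuples
  .with_seed(seed, {
    for (d in unique(t$drug_id)) {
      idx <- which(t$drug_id == d)
      if (length(idx) > 1L) t$response[idx] <- t$response[sample(idx)]
    }
  })
  ResponsePanel(t, metric = panel@metric)
}

#' Intracell response shuffle (permutation null)
#'
#' For each cell line independently, permutes its response values across
#' the drugs measured on it, destroying drug identity while preserving each
#' cell's response multiset.
#'
#' @param panel a [ResponsePanel-class].
#' @param seed integer seed.
#' @return A shuffled [ResponsePanel-class] with identical tuple order.
#' @export
shuffleIntracell <- function(panel, seed = 1L) {
  t <- panel@tuples
  .with_seed(seed, {
    for (cl in unique(t$cell_id)) {
      idx <- which(t$cell_id == cl)
      if (length(idx) > 1L) t$response[idx] <- t$response[sample(idx)]
    }
  })
  ResponsePanel(t, metric = panel@metric)
}

#' Serialize a SplitAssignment to JSON
#'
#' Writes mode, seed, parameters and per-partition tuple indices so any
#' external model can consume identical splits.
#'
#' @param split a [SplitAssignment-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeSplit <- function(split, path) {
  obj <- list(mode = split@mode, seed = split@seed, params = split@params,
              frozen_test = split@frozenTest,
              training_drugs = split@trainingDrugs,
              partitions = lapply(c(train = "train", val = "val",
                                    test = "test", excluded = "excluded"),
                                  function(w) which(split@partition == w)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a SplitAssignment from JSON
#'
#' @param path file written by [writeSplit()].
#' @return A [SplitAssignment-class].
#' @export
readSplit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- sum(lengths(obj$partitions))
  part <- character(n)
  for (w in names(obj$partitions)) part[obj$partitions[[w]]] <- w
  new("SplitAssignment", mode = obj$mode, partition = part,
      trainingDrugs = as.character(obj$training_drugs),
      frozenTest = isTRUE(obj$frozen_test),
      params = as.list(obj$params), seed = as.integer(obj$seed))
}
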