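# The four experiment families: permutation suite, diversity sweep,
# composition sweeps, mechanism-isolated training.

.eval_on <- function(model, panel, drugs, cells, idx) {
  tt <- panel@tuples[idx, , drop = FALSE]
  pred <- predictPairs(model, tt, drugs, cells)
  list(eval = evaluatePredictions(pred, tt), pred = pred, tuples = tt)
}

.train_and_test <- function(panel, drugs, cells, split, config) {
  model <- trainModel(config, panel, drugs, cells, split)
  res <- .eval_on(model, panel, drugs, cells, partitionIndices(split, "test"))
  list(model = model, eval = res$eval, pred = res$pred, tuples = res$tuples)
}

#' Permutation suite: control, intradrug, intracell and one-hot conditions
#'
#' For each replicate, trains and tests four models on the same mixed
#' split: (i) the unshuffled control, (ii) an intradrug-shuffled panel,
#' (iii) an intracell-shuffled panel, (iv) the unshuffled panel with
#' one-hot cell identity features.  Shuffles are applied to the full panel
#' before splitting, so all partitions carry permuted labels — the model is
#' asked what it can learn under the null.  Reports test Pearson and the
#' drop relative to the control.
#'
#' @param panel a [ResponsePanel-class].
#' @param drugs,cells feature sets for the panel.
#' @param config a [modelConfig()] list.
#' @param replicates number of replicate seeds.
#' @param seed base seed; replicate r uses `seed + r` for its split, its
#'   shuffles and its model.
#' @param permute_scope `"full"` permutes the whole panel; `"train_val"`
#'   restricts the permutation to train+val tuples, leaving test labels
#'   intact.
#' @return data.frame with condition, replicate, seed, pearson, rel_drop.
#' @export
runPermutationSuite <- function(panel, drugs, cells,
                                config = modelConfigSynthetic(),
                                replicates = 3L, seed = 1L,
                                permute_scope = c("full", "train_val")) {
  permute_scope <- match.arg(permute_scope)
  rows <- list()
  for (r in seq_len(replicates)) {
    s <- seed + r
    split <- splitMixed(panel, seed = s)
    cfg <- config
    cfg$seed <- s
    shuffled <- list(intradrug = shuffleIntradrug(panel, seed = s),
                     intracell = shuffleIntracell(panel, seed = s))
    if (permute_scope == "train_val") {
      test_idx <- partitionIndices(split, "test")
      for (nm in names(shuffled)) {
        t <- shuffled[[nm]]@tuples
        t$response[test_idx] <- panel@tuples$response[test_idx]
        shuffled[[nm]] <- ResponsePanel(t, metric = panel@metric)
      }
    }
    one_hot <- oneHotCells(cellIds(panel))
    runs <- list(
      control = .train_and_test(panel, drugs, cells, split, cfg),
      intradrug = .train_and_test(shuffled$intradrug, drugs, cells, split, cfg),
      intracell = .train_and_test(shuffled$intracell, drugs, cells, split, cfg),
      one_hot = .train_and_test(panel, drugs, one_hot, split, cfg))
    ctrl <- globalPearson(runs$control$eval)
    for (nm in names(runs)) {
      p <- globalPearson(runs[[nm]]$eval)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = nm, replicate = r, seed = s, pearson = p,
                   rel_drop = (ctrl - p) / ctrl)
    }
  }
  do.call(rbind, rows)
}

#' Diversity sweep: performance versus training cells per drug
#'
#' For each cap level `k`, split mode and replicate, caps the number of
#' training tuples per drug at `k` (val/test untouched, so the test set is
#' constant across `k` within a replicate), trains and evaluates.  Drugs
#' measured on fewer than `min_cells` cells are removed for all `k`, so the
#' drug pool is identical along each curve.
#'
#' @param panel a [ResponsePanel-class].
#' @param drugs,cells feature sets.
#' @param k_grid ascending integer vector of cap levels (use `Inf` for the
#'   uncapped reference).
#' @param modes subset of `c("mixed", "drug_blind")`.
#' @param replicates replicate splits per condition (default 5).
#' @param config a [modelConfig()] list.
#' @param min_cells minimum measured cells per surviving drug; defaults to
#'   80% of the panel's cell count (suited to dense synthetic panels; use
#'   500 on the large public screens).
#' @param annotations optional [AnnotationTable-class]; when given, per-
#'   pathway mean test Pearson is also returned (drugs lacking labels are
#'   excluded from per-mechanism aggregation only).
#' @param seed base seed.
#' @return list with `runs` (one row per trained model), `summary`
#'   (mean/sd over replicates per k and mode) and optionally
#'   `per_mechanism`.
#' @export
runDiversitySweep <- function(panel, drugs, cells, k_grid,
                              modes = c("mixed", "drug_blind"),
                              replicates = 5L,
                              config = modelConfigSynthetic(),
                              min_cells = NULL, annotations = NULL,
                              seed = 1L) {
  if (is.unsorted(k_grid)) stop("k_grid must be ascending")
  if (is.null(min_cells))
    min_cells <- ceiling(0.8 * length(cellIds(panel)))
  rows <- list()
  mech_rows <- list()
  for (mode in modes) {
    for (r in seq_len(replicates)) {
      s <- seed + 100L * match(mode, modes) + r
      base <- if (mode == "mixed") splitMixed(panel, seed = s)
              else splitDrugBlind(panel, seed = s)
      cfg <- config
      cfg$seed <- s
      for (k in k_grid) {
        capped <- capTrainingCells(base, panel, min(k, nTuples(panel)),
                                   min_cells = min_cells, seed = s)
        run <- .train_and_test(panel, drugs, cells, capped, cfg)
        rows[[length(rows) + 1L]] <-
          data.frame(k = k, mode = mode, replicate = r, seed = s,
                     pearson = globalPearson(run$eval),
                     n_train = length(partitionIndices(capped, "train")))
        if (!is.null(annotations)) {
          pd <- perDrugPearson(run$eval)
          path <- setNames(annotationRows(annotations)$pathway,
                           annotationRows(annotations)$drug_id)
          pd$pathway <- path[pd$drug_id]
          pd <- pd[!is.na(pd$pathway) & !is.na(pd$pearson), , drop = FALSE]
          if (nrow(pd)) {
            agg <- aggregate(pearson ~ pathway, pd, mean)
            agg$k <- k; agg$mode <- mode; agg$replicate <- r
            mech_rows[[length(mech_rows) + 1L]] <- agg
          }
        }
      }
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(runs, runs[c("k", "mode")], drop = TRUE),
    function(g) data.frame(k = g$k[1], mode = g$mode[1],
                           mean_pearson = mean(g$pearson),
                           sd_pearson = sd(g$pearson), n = nrow(g))))
  rownames(summ) <- NULL
  out <- list(runs = runs, summary = summ)
  if (length(mech_rows)) out$per_mechanism <- do.call(rbind, mech_rows)
  out
}

#' Composition sweep: many models with varying training drug sets
#'
#' Runs `n_runs` independent train/evaluate cycles under one of two
#' designs.  `fixed_test`: the test and validation drug sets are frozen
#' (10% of drugs each by default) and each run trains on a fresh random
#' half of the remaining pool; the record carries global test Pearson.
#' `partial_blind`: each run trains on a fresh random half of all drugs
#' while val/test jointly span every drug; the record carries per-drug test
#' Pearson for the full drug universe.  Failed runs are recorded with a
#' failure flag, never dropped, so the composition design stays balanced.
#'
#' @param panel a [ResponsePanel-class].
#' @param drugs,cells feature sets.
#' @param design `"fixed_test"` or `"partial_blind"`.
#' @param n_runs number of models (>= 2).
#' @param config a [modelConfig()] list.
#' @param base_seed run i uses seed `base_seed + i`; the fixed-test design
#'   freezes its test/val drugs from `base_seed` itself.
#' @param train_fraction fraction of (pool) drugs trained per run.
#' @param test_fraction,val_fraction fixed-test design: fractions of the
#'   drug universe frozen as test and validation drugs.
#' @return list of run records (class `drpRunRecords`): each has `run_id`,
#'   `design`, `seed`, `composition` (named 0/1 vector over the drug
#'   universe), `global_pearson`, `per_drug`, `epochs`, `failed`.
#' @export
runCompositionSweep <- function(panel, drugs, cells,
                                design = c("fixed_test", "partial_blind"),
                                n_runs = 60L,
                                config = modelConfigSynthetic(),
                                base_seed = 1L, train_fraction = 0.5,
                                test_fraction = 0.1, val_fraction = 0.1) {
  design <- match.arg(design)
  if (n_runs < 2L) stop("a composition sweep needs at least 2 runs")
  universe <- drugIds(panel)
  nd <- length(universe)
  records <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    s <- base_seed + i
    rec <- list(run_id = i, design = design, seed = s, failed = FALSE,
                error = NULL)
    res <- tryCatch({
      split <- if (design == "fixed_test") {
        splitFixedTest(panel,
                       n_test_drugs = max(1L, round(test_fraction * nd)),
                       n_val_drugs = max(1L, round(val_fraction * nd)),
                       train_count = round(train_fraction * nd),
                       seed = s, base_seed = base_seed)
      } else {
        splitPartialBlind(panel, train_drug_fraction = train_fraction,
                          seed = s)
      }
      cfg <- config
      cfg$seed <- s
      run <- .train_and_test(panel, drugs, cells, split, cfg)
      comp <- as.integer(universe %in% trainingDrugs(split))
      names(comp) <- universe
      pd <- perDrugPearson(run$eval)
      list(composition = comp,
           global_pearson = globalPearson(run$eval),
           per_drug = setNames(pd$pearson, pd$drug_id),
           epochs = nrow(trainingHistory(run$model)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rec$failed <- TRUE
      rec$error <- conditionMessage(res)
      warning(sprintf("run %d failed: %s", i, rec$error))
    } else rec <- c(rec, res)
    records[[i]] <- rec
  }
  structure(records, class = "drpRunRecords", drug_universe = universe)
}

#' Composition matrix of a sweep
#'
#' @param records a `drpRunRecords` list from [runCompositionSweep()].
#' @return binary matrix, runs x drugs (failed runs excluded).
#' @export
compositionMatrix <- function(records) {
  ok <- Filter(function(r) !r$failed, records)
  do.call(rbind, lapply(ok, function(r) r$composition))
}

#' Write run records as JSON lines
#'
#' @param records a `drpRunRecords` list.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeRunRecords <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    # named vectors must serialize as JSON objects, not bare arrays
    if (!is.null(r$composition)) r$composition <- as.list(r$composition)
    if (!is.null(r$per_drug)) r$per_drug <- as.list(r$per_drug)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Read run records written by [writeRunRecords()]
#'
#' @param path JSON-lines file.
#' @param drug_universe optional character vector; defaults to the
#'   composition names of the first record.
#' @return a `drpRunRecords` list.
#' @export
readRunRecords <- function(path, drug_universe = NULL) {
  lines <- readLines(path)
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  records <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l)
    r$composition <- unlist(r$composition)
    if (!is.null(r$per_drug))  # nulls mark undefined per-drug correlations
      r$per_drug <- vapply(r$per_drug, num_or_na, numeric(1))
    r$global_pearson <- num_or_na(r$global_pearson)
    r
  })
  if (is.null(drug_universe))
    drug_universe <- names(records[[1L]]$composition)
  structure(records, class = "drpRunRecords", drug_universe = drug_universe)
}

#' Mechanism-isolated versus all-drug training
#'
#' Compares (a) a model trained only on one mechanism's drugs (mixed split
#' within them) against (b) a model trained on all drugs whose test tuples
#' are forced to be exactly the isolated model's test pairs, plus (c) an
#' intradrug-shuffled isolated baseline.  Also reports the mean pairwise
#' cosine similarity of the final drug-arm embeddings within the mechanism
#' for (a) and (b): lower similarity means the model resolves individual
#' drugs rather than collapsing them to the mechanism.
#'
#' @param panel a [ResponsePanel-class].
#' @param drugs,cells feature sets.
#' @param annotations an [AnnotationTable-class]; drugs whose
#'   `putative_target` equals `mechanism` form the isolated set.
#' @param mechanism target label with at least 2 drugs.
#' @param config a [modelConfig()] list.
#' @param seed integer seed.
#' @return one-row data.frame: pearson_isolated, pearson_all,
#'   pearson_shuffled, cosine_isolated, cosine_all, n_test.
#' @export
runMechanismSpecific <- function(panel, drugs, cells, annotations, mechanism,
                                 config = modelConfigSynthetic(), seed = 1L) {
  targets <- drugTargets(annotations)
  mech_drugs <- names(targets)[!is.na(targets) & targets == mechanism]
  if (!length(mech_drugs))
    stop("mechanism not present in the annotations: ", mechanism)
  if (length(mech_drugs) < 2L)
    stop("mechanism needs at least 2 drugs: ", mechanism)

  t <- panel@tuples
  in_mech <- t$drug_id %in% mech_drugs
  iso_panel <- ResponsePanel(t[in_mech, , drop = FALSE], panel@metric)
  iso_split <- splitMixed(iso_panel, seed = seed)
  cfg <- config
  cfg$seed <- seed
  iso <- .train_and_test(iso_panel, drugs, cells, iso_split, cfg)

  # all-drug split whose test set is exactly the isolated test pairs
  iso_test_global <- which(in_mech)[partitionIndices(iso_split, "test")]
  part <- rep(NA_character_, nrow(t))
  part[iso_test_global] <- "test"
  rest <- which(is.na(part))
  sizes <- .largest_remainder(length(rest), c(8, 1) / 9)
  part[rest] <- .with_seed(seed, sample(rep(c("train", "val"), sizes)))
  all_split <- .new_split("mixed", part, t, params = list(forced_test = TRUE),
                          seed = seed)
  all_model <- trainModel(cfg, panel, drugs, cells, all_split)
  all_eval <- .eval_on(all_model, panel, drugs, cells, iso_test_global)

  shuf_panel <- shuffleIntradrug(iso_panel, seed = seed)
  shuf <- .train_and_test(shuf_panel, drugs, cells, iso_split, cfg)

  mech_fp <- DrugFeatureSet(featureMatrix(drugs)[mech_drugs, , drop = FALSE])
  groups <- setNames(rep(mechanism, length(mech_drugs)), mech_drugs)
  cos_iso <- groupCosine(extractDrugEmbeddings(iso$model, mech_fp), groups)
  cos_all <- groupCosine(extractDrugEmbeddings(all_model, mech_fp), groups)

  data.frame(mechanism = mechanism,
             pearson_isolated = globalPearson(iso$eval),
             pearson_all = globalPearson(all_eval$eval),
             pearson_shuffled = globalPearson(shuf$eval),
             cosine_isolated = unname(cos_iso[mechanism]),
             cosine_all = unname(cos_all[mechanism]),
             n_test = length(iso_test_global))
}

#' Training-set uniqueness versus performance
#'
#' For each run, counts the distinct putative targets among its training
#' drugs, and correlates the count with global performance across runs — a
#' control for whether sheer target diversity (rather than specific
#' drug-to-drug sharing) explains performance.
#'
#' @param records a `drpRunRecords` list.
#' @param annotations an [AnnotationTable-class] covering training drugs;
#'   drugs without annotations are skipped with a warning.
#' @return list with `per_run` (run_id, unique_targets, global_pearson)
#'   and `correlation`.
#' @export
trainingSetUniqueness <- function(records, annotations) {
  targets <- drugTargets(annotations)
  warned <- FALSE
  rows <- lapply(Filter(function(r) !r$failed, records), function(r) {
    tr <- names(r$composition)[r$composition == 1]
    miss <- setdiff(tr, names(targets))
    if (length(miss) && !warned) {
      warning("drugs without annotations skipped: ",
              paste(miss, collapse = ", "))
      warned <<- TRUE
    }
    data.frame(run_id = r$run_id,
               unique_targets = length(unique(na.omit(
                 targets[intersect(tr, names(targets))]))),
               global_pearson = r$global_pearson)
  })
  per_run <- do.call(rbind, rows)
  corr <- if (sd(per_run$unique_targets) == 0 ||
              sd(per_run$global_pearson) == 0) NA_real_
          else cor(per_run$unique_targets, per_run$global_pearson)
  list(per_run = per_run, correlation = corr)
}
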