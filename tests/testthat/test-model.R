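# fixtures shared across blocks in this file
sim <- small_sim(seed = 31)
split <- splitMixed(sim$panel, seed = 31)
tuples <- responseTuples(sim$panel)

test_that("model configuration enforces its invariants", {
  expect_error(modelConfig(cell_arm_widths = c(100, 200)), "decreasing")
  expect_error(modelConfig(learning_rate = 0), "positive")
  expect_error(modelConfig(cell_entry_layer = 3), "cell_entry_layer")
  cfg <- modelConfig()
  expect_equal(cfg$cell_arm_widths, c(1000L, 750L, 500L))
  expect_equal(cfg$batch_size, 16L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$max_epochs, 100L)
})

test_that("buildModel structure: embedding width, entry layer, determinism", {
  cfg <- tiny_model(seed = 8)
  m <- buildModel(cfg, cell_width = 20, drug_width = 16)
  emb <- extractDrugEmbeddings(m, DrugFeatureSet(
    matrix(rbinom(32, 1, 0.3), 2, 16,
           dimnames = list(c("a", "b"), NULL))))
  expect_equal(ncol(emb), 8L)  # last drug-arm width

  # same seed -> identical initial parameters
  m2 <- buildModel(cfg, cell_width = 20, drug_width = 16)
  expect_identical(m@net, m2@net)
  m3 <- buildModel(tiny_model(seed = 9), cell_width = 20, drug_width = 16)
  expect_false(identical(m@net, m3@net))

  # precomputed embeddings entering at a deeper layer skip leading widths
  deep <- modelConfig(cell_arm_widths = c(100L, 75L, 50L),
                      cell_entry_layer = 2L)
  md <- buildModel(deep, cell_width = 50, drug_width = 16)
  expect_length(md@net$W, 1 + 3 + 2 + 1)  # 1 cell layer remains
  expect_equal(dim(md@net$W[[1]]), c(50L, 50L))
})

test_that("training is deterministic and early stopping restores the best
           epoch", {
  cfg <- tiny_model(seed = 12)
  m1 <- trainModel(cfg, sim$panel, sim$drugs, sim$cells, split)
  m2 <- trainModel(cfg, sim$panel, sim$drugs, sim$cells, split)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(m1@net, m2@net)

  h <- trainingHistory(m1)
  expect_equal(bestEpoch(m1), which.min(h$val_loss))
  expect_true(all(h$val_loss >= h$val_loss[bestEpoch(m1)]))
  expect_lte(nrow(h), cfg$max_epochs)
})

test_that("trained model beats the per-drug-mean baseline on a mixed split", {
  cfg <- tiny_model(seed = 12)
  m <- trainModel(cfg, sim$panel, sim$drugs, sim$cells, split)
  idx <- partitionIndices(split, "val")
  tt <- tuples[idx, ]
  model_p <- globalPearson(evaluatePredictions(
    predictPairs(m, tt, sim$drugs, sim$cells), tt))
  base_p <- globalPearson(evaluatePredictions(
    drugMeanBaseline(tuples[partitionIndices(split, "train"), ], tt), tt))
  expect_gt(model_p, base_p)
})

test_that("noiseless panel is predicted almost exactly (ridge oracle agrees
           the target is reachable)", {
  nsim <- generatePanel(simConfig(sigma2_noise = 0, seed = 41))
  nsplit <- splitMixed(nsim$panel, seed = 41)
  nt <- responseTuples(nsim$panel)
  tr_idx <- partitionIndices(nsplit, "train")
  val_idx <- partitionIndices(nsplit, "val")

  # independent oracle: per-drug ridge on cell features (equivalent to
  # ridge on cell-features x drug-one-hot interactions)
  x <- cbind(1, featureMatrix(nsim$cells))
  oracle <- numeric(length(val_idx))
  for (d in drugIds(nsim$panel)) {
    tr_d <- nt[tr_idx, ][nt$drug_id[tr_idx] == d, ]
    xd <- x[tr_d$cell_id, , drop = FALSE]
    beta <- solve(crossprod(xd) + diag(1e-2, ncol(x)),
                  crossprod(xd, tr_d$response))
    sel <- nt$drug_id[val_idx] == d
    oracle[sel] <- x[nt$cell_id[val_idx][sel], , drop = FALSE] %*% beta
  }
  oracle_p <- cor(oracle, nt$response[val_idx])
  expect_gte(oracle_p, 0.95)

  m <- trainModel(modelConfigSynthetic(seed = 41), nsim$panel, nsim$drugs,
                  nsim$cells, nsplit)
  val_t <- nt[val_idx, ]
  model_p <- globalPearson(evaluatePredictions(
    predictPairs(m, val_t, nsim$drugs, nsim$cells), val_t))
  expect_gte(model_p, 0.95)
})

test_that("predictPairs is order-equivariant and handles duplicates", {
  cfg <- tiny_model(seed = 12)
  m <- trainModel(cfg, sim$panel, sim$drugs, sim$cells, split)
  pairs <- tuples[1:10, ]
  p1 <- predictPairs(m, pairs, sim$drugs, sim$cells)
  ord <- c(5:1, 10:6)
  expect_equal(predictPairs(m, pairs[ord, ], sim$drugs, sim$cells), p1[ord])
  dup <- pairs[c(1, 1), ]
  pd <- predictPairs(m, dup, sim$drugs, sim$cells)
  expect_equal(pd[1], pd[2])
  expect_error(predictPairs(m, data.frame(cell_id = "nope",
                                          drug_id = pairs$drug_id[1]),
                            sim$drugs, sim$cells), "nope")
})

test_that("evaluatePredictions handles exact, inverted and degenerate cases", {
  tt <- tuples[1:20, ]
  expect_equal(globalPearson(evaluatePredictions(tt$response, tt)), 1.0)
  expect_equal(globalPearson(evaluatePredictions(-tt$response, tt)), -1.0)
  ev <- evaluatePredictions(rep(1, 20), tt)
  expect_true(is.na(globalPearson(ev)))
  expect_true(all(is.na(perDrugPearson(ev)$pearson)))
  expect_error(evaluatePredictions(1:3, tt), "length")
  # per-drug entries only for drugs with >= 2 tuples and non-constant truth
  one <- data.frame(cell_id = c("C1", "C2", "C3"),
                    drug_id = c("A", "A", "B"), response = c(1, 2, 3))
  ev2 <- evaluatePredictions(c(1, 2, 3), one)
  pd <- perDrugPearson(ev2)
  expect_true(is.na(pd$pearson[pd$drug_id == "B"]))
  expect_equal(pd$pearson[pd$drug_id == "A"], 1.0)
})

test_that("drug embeddings: identical fingerprints map identically, snapshots
           are retrievable", {
  fp <- featureMatrix(sim$drugs)
  fp2 <- rbind(fp, dupe = fp[1, ])
  dfs <- DrugFeatureSet(fp2)
  cfg <- tiny_model(seed = 12, snapshot_epochs = c(1L, 3L))
  m <- trainModel(cfg, sim$panel, sim$drugs, sim$cells, split)
  emb <- extractDrugEmbeddings(m, dfs)
  expect_equal(unname(emb["dupe", ]), unname(emb[rownames(fp)[1], ]))
  expect_equal(ncol(emb), tail(cfg$drug_arm_widths, 1))

  e1 <- extractDrugEmbeddings(m, dfs, at_epoch = 1)
  e3 <- extractDrugEmbeddings(m, dfs, at_epoch = 3)
  expect_false(identical(e1, e3))
  expect_error(extractDrugEmbeddings(m, dfs, at_epoch = 2),
               "not checkpointed")

  # untrained model with fixed seed embeds deterministically
  u1 <- extractDrugEmbeddings(buildModel(cfg, 60, 64), sim$drugs)
  u2 <- extractDrugEmbeddings(buildModel(cfg, 60, 64), sim$drugs)
  expect_identical(u1, u2)
})

test_that("collapseDiagnostic: exact ratios and affine invariance", {
  tt <- tuples[tuples$drug_id %in% drugIds(sim$panel)[1:3], ]
  means <- ave(tt$response, tt$drug_id)
  d0 <- collapseDiagnostic(means, tt)
  expect_true(all(d0$sd_ratio == 0))
  expect_true(all(d0$mean_gap < 1e-12))
  d1 <- collapseDiagnostic(tt$response, tt)
  expect_true(all(abs(d1$sd_ratio - 1) < 1e-12))
  # affine rescaling of both vectors leaves ratios unchanged
  pred <- means + 0.5 * (tt$response - means)
  a <- collapseDiagnostic(pred, tt)
  tt2 <- tt; tt2$response <- 3 * tt$response - 7
  b <- collapseDiagnostic(3 * pred - 7, tt2)
  expect_equal(a$sd_ratio, b$sd_ratio)
  # drugs with < 2 tuples are skipped
  one <- data.frame(cell_id = c("C1", "C2", "C3"),
                    drug_id = c("A", "A", "B"), response = c(1, 2, 3))
  expect_equal(collapseDiagnostic(c(1, 2, 3), one)$drug_id, "A")
})

test_that("training errors are informative", {
  cfg <- tiny_model(seed = 1)
  no_val <- splitDrugBlind(sim$panel, seed = 2)
  no_val@partition[no_val@partition == "val"] <- "test"
  expect_error(trainModel(cfg, sim$panel, sim$drugs, sim$cells, no_val),
               "validation partition is empty")
  # responses so large that the squared loss overflows to Inf
  huge <- responseTuples(sim$panel)
  huge$response <- huge$response * 1e200
  expect_error(trainModel(cfg, ResponsePanel(huge), sim$drugs, sim$cells,
                          split),
               "non-finite loss at epoch")
})

test_that("one-hot cells plus intradrug shuffle reduce the model to the
           drug-mean predictor", {
  deltas <- vapply(1:3, function(s) {
    sh <- shuffleIntradrug(sim$panel, seed = 100 + s)
    sp <- splitMixed(sh, seed = 100 + s)
    oh <- oneHotCells(cellIds(sh))
    m <- trainModel(tiny_model(seed = s), sh, sim$drugs, oh, sp)
    idx <- partitionIndices(sp, "test")
    tt <- responseTuples(sh)[idx, ]
    model_p <- globalPearson(evaluatePredictions(
      predictPairs(m, tt, sim$drugs, oh), tt))
    base_p <- globalPearson(evaluatePredictions(
      drugMeanBaseline(responseTuples(sh)[partitionIndices(sp, "train"), ],
                       tt), tt))
    abs(model_p - base_p)
  }, numeric(1))
  expect_lt(mean(deltas), 0.05)
})
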