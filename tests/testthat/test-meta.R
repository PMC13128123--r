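# hand-built 4x4 coefficient matrix used by several formula oracles
hand_matrix <- function() {
  v <- matrix(c(
    0.5, 0.1, 0.0, -0.1,
    1.0, 0.4, 0.2,  0.3,
    0.0, 0.3, 0.6,  0.0,
    0.2, -0.1, 0.1, 0.25), nrow = 4, byrow = TRUE,
    dimnames = list(paste0("D", 1:4), paste0("D", 1:4)))
  CoefficientMatrix(v)
}

# synthetic run records with planted per-drug and global effects
planted_records <- function(n_runs, drugs, global_fun, per_drug_fun = NULL,
                            seed = 1) {
  recs <- .with_seed(seed, lapply(seq_len(n_runs), function(i) {
    comp <- setNames(rbinom(length(drugs), 1, 0.5), drugs)
    list(run_id = i, design = "synthetic", seed = i, failed = FALSE,
         composition = comp, global_pearson = global_fun(comp),
         per_drug = if (is.null(per_drug_fun)) NULL else per_drug_fun(comp),
         epochs = 1L)
  }))
  structure(recs, class = "drpRunRecords", drug_universe = drugs)
}

test_that("oneToOne reproduces hand-computed values and flags undefined", {
  s <- oneToOne(hand_matrix())
  # D1: max non-self 1.0 over self 0.5 -> ln 2
  expect_equal(unname(s["D1"]), log(2))
  # D2: max non-self 0.3, self 0.4
  expect_equal(unname(s["D2"]), log(0.3 / 0.4))
  # D3: max non-self 0.2, self 0.6
  expect_equal(unname(s["D3"]), log(0.2 / 0.6))
  # base option
  expect_equal(unname(oneToOne(hand_matrix(), base = 2)["D1"]), 1)
  # max non-self equal to self -> exactly 0
  v <- diag(4) * 0.5
  v[2, 1] <- 0.5
  dimnames(v) <- list(paste0("D", 1:4), paste0("D", 1:4))
  expect_equal(unname(oneToOne(CoefficientMatrix(v))["D1"]), 0)
  # non-positive self -> undefined
  v[1, 1] <- -0.1
  expect_true(is.na(oneToOne(CoefficientMatrix(v))["D1"]))
})

test_that("manyToOne averages non-self column sums by N", {
  s <- manyToOne(hand_matrix())
  expect_equal(unname(s["D1"]), (1.0 + 0.0 + 0.2) / 4)
  expect_equal(unname(s["D2"]), (0.1 + 0.3 - 0.1) / 4)
  # non-self entries {0.2, 0.3, -0.1} over N = 4 drugs -> 0.1
  v <- matrix(0, 4, 4, dimnames = list(paste0("D", 1:4), paste0("D", 1:4)))
  v[2:4, 1] <- c(0.2, 0.3, -0.1)
  expect_equal(unname(manyToOne(CoefficientMatrix(v))["D1"]), 0.1)
  # the self entry never affects the score
  v[1, 1] <- 99
  expect_equal(unname(manyToOne(CoefficientMatrix(v))["D1"]), 0.1)
  expect_equal(unname(manyToOne(CoefficientMatrix(v), "N-1")["D1"]), 0.4 / 3)
})

test_that("classToClass averages interclass blocks with self-exclusion", {
  v <- matrix(0.5, 4, 4, dimnames = list(paste0("D", 1:4), paste0("D", 1:4)))
  diag(v) <- 1.0
  v[3:4, 1:2] <- 0.2  # class B predicting class A
  classes <- setNames(c("A", "A", "B", "B"), paste0("D", 1:4))
  cc <- classToClass(CoefficientMatrix(v), classes)
  get <- function(a, b) cc$score[cc$predictor_class == a &
                                 cc$target_class == b]
  expect_equal(get("A", "B"), 0.5)
  expect_equal(get("B", "A"), 0.2)
  # intraclass excludes only the self pairs, keeping cross-drug entries
  expect_equal(get("A", "A"), 0.5)
  # locality: entries outside the A x B block do not affect score(A, B)
  v2 <- v; v2[1, 1] <- -5; v2[3, 4] <- 9
  cc2 <- classToClass(CoefficientMatrix(v2), classes)
  expect_equal(cc2$score[cc2$predictor_class == "A" &
                         cc2$target_class == "B"], 0.5)
})

test_that("selfBestRate counts ties as self-best and lists exceptions", {
  ident <- CoefficientMatrix(
    diag(4) |> (\(m) {dimnames(m) <- list(paste0("D", 1:4),
                                          paste0("D", 1:4)); m})())
  r <- selfBestRate(ident)
  expect_equal(r$rate, 1.0)
  expect_equal(nrow(r$exceptions), 0L)

  # columns D1 (self 0.5 < 1.0) and D4 (self 0.25 < 0.3) are dominated by D2
  r2 <- selfBestRate(hand_matrix())
  expect_equal(r2$rate, 2 / 4)
  expect_equal(r2$exceptions$target, c("D1", "D4"))
  expect_equal(r2$exceptions$best_predictor, c("D2", "D2"))

  # exact tie counts as self-best
  v <- diag(4) * 0.3
  v[2, 1] <- 0.3
  dimnames(v) <- list(paste0("D", 1:4), paste0("D", 1:4))
  expect_equal(selfBestRate(CoefficientMatrix(v))$rate, 1.0)
})

test_that("one_to_one is non-positive wherever the self coefficient is
           maximal and positive", {
  set.seed(8)
  v <- matrix(rnorm(100), 10, 10,
              dimnames = list(paste0("D", 1:10), paste0("D", 1:10)))
  cm <- CoefficientMatrix(v)
  o <- oneToOne(cm)
  sb <- vapply(1:10, function(j) v[j, j] >= max(v[-j, j]) && v[j, j] > 0,
               logical(1))
  expect_true(all(o[sb] <= 0, na.rm = TRUE))
})

test_that("groupCosine matches hand computations", {
  vec <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(2, 2, 0),
               d = c(0, 0, 0))
  groups <- setNames(c("g", "g", "g", "g"), letters[1:4])
  expect_warning(g <- groupCosine(vec, groups), "zero vectors")
  # pairs: (a,b) = 0.5, (a,c) = 1, (b,c) = 0.5
  expect_equal(unname(g["g"]), mean(c(0.5, 1, 0.5)))
  # orthogonal binary vectors -> 0
  ortho <- rbind(x = c(1, 0), y = c(0, 1))
  expect_equal(unname(groupCosine(ortho, c(x = "g", y = "g"))["g"]), 0)
  # cross-group mode
  two <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  gr <- c(a = "A", b = "A", c = "B")
  expect_equal(unname(groupCosine(two, gr, across = c("A", "B"))), 0)
  expect_equal(unname(groupCosine(two, gr, across = c("A", "A"))), 1)
})

test_that("fitGlobalMeta recovers a planted linear effect near the OLS
           oracle", {
  drugs <- paste0("D", 1:8)
  recs <- planted_records(120, drugs,
                          function(comp) 0.1 + 0.5 * comp[["D3"]])
  gm <- fitGlobalMeta(recs, metaConfig())
  # OLS oracle on the same design is exactly 0.5 for D3, 0 elsewhere
  x <- compositionMatrix(recs)
  y <- vapply(recs, function(r) r$global_pearson, numeric(1))
  ols <- coef(lm(y ~ x))[-1]
  expect_equal(unname(ols[which(drugs == "D3")]), 0.5, tolerance = 1e-10)
  expect_lt(abs(gm$coefficients[["D3"]] - 0.5), 0.05)  # shrinkage band
  expect_true(all(abs(gm$coefficients[setdiff(drugs, "D3")]) < 0.05))
  # out-of-fold predictions track a noiseless planted effect
  expect_gt(cor(gm$oof$observed, gm$oof$predicted), 0.99)
})

test_that("fitGlobalMeta degenerate cases: constant y, duplication
           invariance, constant features", {
  drugs <- paste0("D", 1:5)
  const <- planted_records(30, drugs, function(comp) 0.42)
  gm <- fitGlobalMeta(const, metaConfig())
  expect_true(all(gm$coefficients == 0))
  expect_equal(gm$intercept, 0.42)

  recs <- planted_records(40, drugs, function(comp) 0.1 + 0.3 * comp[["D1"]])
  doubled <- structure(c(recs, recs), class = "drpRunRecords",
                       drug_universe = drugs)
  g1 <- fitGlobalMeta(recs, metaConfig())
  g2 <- fitGlobalMeta(doubled, metaConfig())
  expect_equal(g1$coefficients, g2$coefficients, tolerance = 1e-6)

  # a frozen (never-trained) drug is dropped with a notice
  frozen <- lapply(recs, function(r) {r$composition[["D5"]] <- 0L; r})
  frozen <- structure(frozen, class = "drpRunRecords",
                      drug_universe = drugs)
  expect_message(g3 <- fitGlobalMeta(frozen, metaConfig()), "D5")
  expect_false("D5" %in% names(g3$coefficients))

  same <- planted_records(10, drugs, function(comp) 0.5)
  same <- lapply(same, function(r) {
    r$composition[] <- c(1L, 1L, 0L, 0L, 1L); r})
  same <- structure(same, class = "drpRunRecords", drug_universe = drugs)
  expect_error(fitGlobalMeta(same, metaConfig()), "identical")
})

test_that("fitPerDrugMeta recovers planted self and shared effects", {
  drugs <- paste0("D", 1:6)
  per_drug_fun <- function(comp) {
    out <- setNames(rep(0.2, 6), drugs)
    out["D2"] <- 0.2 + 0.6 * comp[["D2"]]              # planted self effect
    out["D5"] <- 0.1 + 0.25 * comp[["D5"]] +
      0.25 * comp[["D6"]]                              # symmetric sharing
    out["D6"] <- 0.1 + 0.25 * comp[["D6"]] + 0.25 * comp[["D5"]]
    out
  }
  recs <- planted_records(150, drugs, function(comp) 0.3, per_drug_fun,
                          seed = 3)
  cm <- fitPerDrugMeta(recs, metaConfig())
  v <- coefValues(cm)
  expect_identical(rownames(v), colnames(v))
  # the self coefficient dominates column D2
  expect_equal(which.max(v[, "D2"]), which(rownames(v) == "D2"),
               ignore_attr = TRUE)
  expect_lt(abs(v["D2", "D2"] - 0.6), 0.06)
  # mechanism-mates with symmetric sharing both get positive mutual weight
  expect_gt(v["D5", "D6"], 0.05)
  expect_gt(v["D6", "D5"], 0.05)
  # record order does not change the matrix under a fixed fold seed: the
  # folds are assigned to the same run positions, so permuting records
  # permutes fold membership identically
  cm2 <- fitPerDrugMeta(recs, metaConfig())
  expect_identical(coefValues(cm2), v)
})

test_that("elastic net approaches the least-squares oracle as the penalty
           vanishes", {
  drugs <- paste0("D", 1:6)
  effects <- c(D1 = 0.4, D2 = -0.2, D3 = 0.1, D4 = 0, D5 = 0.05, D6 = 0.3)
  recs <- planted_records(80, drugs,
                          function(comp) 0.2 + sum(effects * comp))
  x <- compositionMatrix(recs)
  y <- vapply(recs, function(r) r$global_pearson, numeric(1))
  ols <- coef(lm(y ~ x))
  gm <- fitGlobalMeta(recs, metaConfig(alpha = 1e-6))
  expect_equal(unname(gm$coefficients), unname(ols[-1]), tolerance = 1e-3)
  expect_equal(gm$intercept, unname(ols[1]), tolerance = 1e-3)
})

test_that("clusterMatrix groups block structure and separates display from
           statistics", {
  v <- matrix(0, 6, 6, dimnames = list(paste0("D", 1:6), paste0("D", 1:6)))
  v[1:3, 1:3] <- 0.9
  v[4:6, 4:6] <- 0.8
  diag(v) <- 1.7  # above the display cap
  cm <- CoefficientMatrix(v)
  cl <- clusterMatrix(cm)
  pos <- match(paste0("D", 1:6), cl$order)
  expect_true(max(pos[1:3]) < min(pos[4:6]) ||
              min(pos[1:3]) > max(pos[4:6]))
  expect_equal(max(cl$display), 1)  # clipped for display
  # clipping is display-only: statistics computed on uncapped values
  expect_equal(selfBestRate(cm)$rate, 1.0)
  expect_equal(unname(manyToOne(cm)["D1"]), sum(v[-1, 1]) / 6)
  # deterministic leaf order
  expect_identical(clusterMatrix(cm)$order, cl$order)
})
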