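test_that("all random effects off collapses responses to drug means", {
  sim <- generatePanel(simConfig(n_mechanisms = 2, drugs_per_mechanism = 3,
                                 n_cells = 12, n_cell_features = 20,
                                 fingerprint_width = 32, sigma2_noise = 0,
                                 sigma2_slope = 0, sigma2_beta = 0, b0 = 0,
                                 seed = 3))
  t <- responseTuples(sim$panel)
  mu <- sim$truth@mu[sim$truth@mechanism[t$drug_id]]
  delta <- sim$truth@delta[t$drug_id]
  expect_equal(t$response, unname(mu + delta))
  within_var <- tapply(t$response, t$drug_id, var)
  expect_true(all(within_var < 1e-24))
})

test_that("a fixed seed reproduces the panel bit-identically", {
  cfg <- simConfig(n_mechanisms = 2, drugs_per_mechanism = 2, n_cells = 15,
                   n_cell_features = 25, fingerprint_width = 32, seed = 11)
  a <- generatePanel(cfg)
  b <- generatePanel(cfg)
  expect_identical(responseTuples(a$panel), responseTuples(b$panel))
  expect_identical(featureMatrix(a$drugs), featureMatrix(b$drugs))
  expect_identical(featureMatrix(a$cells), featureMatrix(b$cells))
})

test_that("generator output satisfies all core type invariants and labels", {
  sim <- small_sim(seed = 9)
  expect_valid(sim$panel)
  expect_valid(sim$drugs)
  expect_valid(sim$cells)
  expect_valid(sim$annotations)
  expect_valid(sim$truth)
  expect_setequal(drugIds(sim$panel), drugIds(sim$drugs))
  expect_setequal(cellIds(sim$panel), cellIds(sim$cells))
  # annotations carry mechanism as target and mechanism-group as pathway
  ann <- annotationRows(sim$annotations)
  expect_equal(setNames(ann$putative_target, ann$drug_id),
               sim$truth@mechanism[ann$drug_id])
})

test_that("pairing density and sparse-drug warning behave", {
  cfg <- simConfig(n_mechanisms = 2, drugs_per_mechanism = 2, n_cells = 20,
                   n_cell_features = 20, fingerprint_width = 32,
                   pairing_density = 0.5, seed = 4)
  sim <- generatePanel(cfg)
  expect_equal(nTuples(sim$panel), 40L)  # half of 4 x 20
  expect_warning(
    generatePanel(simConfig(n_mechanisms = 2, drugs_per_mechanism = 2,
                            n_cells = 20, n_cell_features = 20,
                            fingerprint_width = 32,
                            pairing_density = 0.05, seed = 4)),
    "fewer than 2 cells")
})

# expected Hamming distance between same-mechanism fingerprints is
# 2*eps*(1-eps)*F: each bit differs iff exactly one copy flipped
test_that("same-mechanism Hamming distance matches the closed form", {
  eps <- 0.05
  fw <- 256
  # 2 x 500 mechanisms with 2 drugs each: 1000 independent same-mech pairs,
  # so the pairwise standard error is valid
  ham_same <- unlist(lapply(c(21, 22), function(s) {
    sim <- generatePanel(simConfig(n_mechanisms = 500,
                                   drugs_per_mechanism = 2, n_cells = 3,
                                   n_cell_features = 5,
                                   fingerprint_width = fw, flip_rate = eps,
                                   seed = s))
    fp <- featureMatrix(sim$drugs)
    mech <- drugMechanisms(sim$drugs)
    vapply(unique(mech), function(m) {
      ids <- names(mech)[mech == m]
      sum(fp[ids[1], ] != fp[ids[2], ])
    }, numeric(1))
  }))
  expect_length(ham_same, 1000L)
  expected <- 2 * eps * (1 - eps) * fw
  se <- sd(ham_same) / sqrt(length(ham_same))
  expect_lt(abs(mean(ham_same) - expected), 3 * se)

  # different-mechanism pairs are strictly farther apart on average
  sim <- small_sim(seed = 23)
  fp <- featureMatrix(sim$drugs)
  mech <- drugMechanisms(sim$drugs)
  d <- as.matrix(dist(fp, method = "manhattan"))
  same_mask <- outer(mech, mech, "==")
  diag(same_mask) <- NA
  expect_gt(mean(d[!is.na(same_mask) & !same_mask]),
            mean(d[!is.na(same_mask) & same_mask]))
})

test_that("empirical variance shares match the law-of-total-variance oracle", {
  # brute-force oracle at ~1e5 tuples: decompose realized variance directly
  cfg <- simConfig(n_mechanisms = 5, drugs_per_mechanism = 10,
                   n_cells = 2000, n_cell_features = 10,
                   fingerprint_width = 32, seed = 13)
  sim <- generatePanel(cfg)
  expect_equal(nTuples(sim$panel), 100000L)
  rep <- varianceReport(sim$panel, sim$truth)
  shares <- setNames(rep$share, rep$component)
  expect_equal(sum(rep$share), 1, tolerance = 1e-9)

  # oracle 1: exact decomposition conditional on the realized effect draws
  # (only the s and noise sampling remains, O(1/sqrt(n)) at 1e5 tuples)
  tr <- sim$truth
  drug_mean <- tr@mu[tr@mechanism] + tr@delta
  slope2 <- (tr@beta[tr@mechanism] + tr@gamma)^2
  between_c <- mean((drug_mean - mean(drug_mean))^2)
  tot_c <- between_c + mean(slope2) + cfg@sigma2_noise
  expect_equal(unname(shares["between_drug"]), between_c / tot_c,
               tolerance = 0.02)
  expect_equal(unname(shares["interaction"]), mean(slope2) / tot_c,
               tolerance = 0.02)
  expect_equal(unname(shares["residual"]), cfg@sigma2_noise / tot_c,
               tolerance = 0.02)

  # oracle 2: unconditional closed form; loose band because the mechanism
  # means behind the between-drug share are only 5 draws
  expected <- expectedVarianceShares(cfg)
  expect_equal(unname(shares["between_drug"]),
               unname(expected["between_drug"]), tolerance = 0.35)
})

test_that("noiseless drug-means-only config yields between-drug share 1", {
  sim <- generatePanel(simConfig(n_mechanisms = 2, drugs_per_mechanism = 3,
                                 n_cells = 30, n_cell_features = 10,
                                 fingerprint_width = 32, sigma2_noise = 0,
                                 sigma2_slope = 0, sigma2_beta = 0, b0 = 0,
                                 seed = 7))
  rep <- varianceReport(sim$panel, sim$truth)
  expect_equal(rep$share[rep$component == "between_drug"], 1,
               tolerance = 1e-9)
})

test_that("cell sensitivities are linearly decodable from features", {
  # ridge decode of s from x must reach R^2 > 0.8 when features are
  # informative (sigma2_feat <= 0.1, G >= 10 M)
  cfg <- simConfig(n_mechanisms = 4, drugs_per_mechanism = 2, n_cells = 120,
                   n_cell_features = 40, fingerprint_width = 32,
                   sigma2_feat = 0.1, seed = 17)
  sim <- generatePanel(cfg)
  x <- featureMatrix(sim$cells)
  s <- sim$truth@sensitivities
  lambda <- 1e-3
  xtx <- crossprod(x) + diag(lambda, ncol(x))
  beta <- solve(xtx, crossprod(x, s))
  pred <- x %*% beta
  r2 <- 1 - colSums((s - pred)^2) / colSums(scale(s, scale = FALSE)^2)
  expect_true(all(r2 > 0.8))
})

test_that("confusable pairs share templates and negate slopes", {
  cfg <- simConfig(n_mechanisms = 4, drugs_per_mechanism = 2, n_cells = 10,
                   n_cell_features = 20, fingerprint_width = 64,
                   confusable_pairs = list(c("M1", "M3")), seed = 23)
  sim <- generatePanel(cfg)
  expect_equal(sim$truth@templates["M3", ], sim$truth@templates["M1", ])
  expect_equal(sim$truth@beta[["M3"]], -sim$truth@beta[["M1"]])
  expect_error(simConfig(n_mechanisms = 2,
                         confusable_pairs = list(c("M1", "M9"))),
               "confusable")
})

test_that("synthetic data round-trips through the delimited writers", {
  sim <- generatePanel(simConfig(n_mechanisms = 2, drugs_per_mechanism = 2,
                                 n_cells = 8, n_cell_features = 10,
                                 fingerprint_width = 16, seed = 2))
  dir <- file.path(tempdir(), "simdata")
  writeSyntheticData(sim, dir)
  p <- readResponseTable(file.path(dir, "response.csv"))
  expect_equal(nTuples(p), nTuples(sim$panel))
  expect_setequal(drugIds(p), drugIds(sim$panel))
  x <- readExpressionMatrix(file.path(dir, "expression.csv"))
  expect_equal(x, featureMatrix(sim$cells))
  a <- readAnnotations(file.path(dir, "annotations.csv"))
  expect_equal(annotationRows(a), annotationRows(sim$annotations))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$config$seed, 2L)
  expect_equal(unlist(truth$beta), sim$truth@beta)
})
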