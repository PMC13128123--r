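# Elastic-net meta-regression of model performance on training-set
# composition, coefficient clustering, and the relationship statistics.

#' Configure the composition meta-model
#'
#' The meta-model is an elastic net with objective
#' `1/(2n) * RSS + alpha * (l1_ratio * |b|_1 + (1 - l1_ratio)/2 * |b|_2^2)`
#' regressing performance on the binary training-composition vector.
#' Elastic net (rather than the lasso) is deliberate: correlated features —
#' mechanism-mates whose presence is informative for the same targets —
#' share weight instead of one being selected arbitrarily.
#'
#' @param alpha penalty strength (default 0.01).
#' @param l1_ratio L1/L2 mixing parameter in \[0,1\] (default 0.1).
#' @param folds cross-validation folds (default 10).
#' @param include_intercept fit an intercept (default TRUE).
#' @param fold_seed seed for fold assignment, independent of sweep seeds.
#' @return A named list of class `MetaModelConfig`.
#' @export
metaConfig <- function(alpha = 0.01, l1_ratio = 0.1, folds = 10L,
                       include_intercept = TRUE, fold_seed = 7L) {
  if (alpha <= 0) stop("alpha must be positive")
  if (l1_ratio < 0 || l1_ratio > 1) stop("l1_ratio must be in [0, 1]")
  if (folds < 2L) stop("folds must be >= 2")
  structure(list(alpha = alpha, l1_ratio = l1_ratio,
                 folds = as.integer(folds),
                 include_intercept = isTRUE(include_intercept),
                 fold_seed = as.integer(fold_seed)),
            class = "MetaModelConfig")
}

# Elastic net with the 1/(2n) RSS + alpha*(l1*|b|1 + (1-l1)/2*|b|2^2)
# objective.  glmnet standardizes y internally, so its lambda must be
# rescaled by the population SD of y to express this objective.
.enet_fit <- function(x, y, alpha, l1_ratio, intercept = TRUE) {
  sdy <- sqrt(mean((y - mean(y))^2))
  if (sdy == 0) {
    return(list(coef = setNames(numeric(ncol(x)), colnames(x)),
                intercept = mean(y)))
  }
  lam <- alpha * sdy
  fit <- glmnet::glmnet(x, y, alpha = l1_ratio,
                        lambda = lam * c(100, 10, 1),
                        standardize = FALSE, intercept = intercept,
                        thresh = 1e-12)
  b <- as.matrix(stats::coef(fit, s = lam))[, 1L]
  list(coef = b[-1L], intercept = unname(b[1L]))
}

.fold_ids <- function(n, folds, seed) {
  .with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

.sweep_xy <- function(records, value_fun) {
  ok <- Filter(function(r) !r$failed, records)
  x <- do.call(rbind, lapply(ok, function(r) r$composition))
  y <- vapply(ok, value_fun, numeric(1))
  keep <- !is.na(y)
  list(x = x[keep, , drop = FALSE], y = y[keep],
       run_id = vapply(ok, function(r) r$run_id, numeric(1))[keep])
}

#' Global meta-regression: performance on training composition
#'
#' Fits the elastic net of each run's global test Pearson on its binary
#' composition vector, and produces out-of-fold predictions (each run
#' predicted by a model fit on the other folds) for the predicted-versus-
#' actual comparison.  Constant composition features — e.g. the frozen test
#' drugs, which are never trained on — are dropped with a notice.
#'
#' @param records a `drpRunRecords` list from [runCompositionSweep()].
#' @param config a [metaConfig()] list.
#' @return list: `coefficients` (named, over varying drugs), `intercept`,
#'   `oof` (data.frame run_id/observed/predicted), `dropped` (constant
#'   features).
#' @export
fitGlobalMeta <- function(records, config = metaConfig()) {
  d <- .sweep_xy(records, function(r) r$global_pearson)
  if (nrow(d$x) < 2L) stop("need at least 2 usable runs")
  variance <- apply(d$x, 2, var)
  dropped <- colnames(d$x)[variance == 0]
  keep <- variance > 0
  if (!any(keep)) stop("all composition vectors are identical")
  if (length(dropped))
    message("dropping constant composition features: ",
            paste(dropped, collapse = ", "))
  x <- d$x[, keep, drop = FALSE]
  full <- .enet_fit(x, d$y, config$alpha, config$l1_ratio,
                    config$include_intercept)
  folds <- .fold_ids(length(d$y), config$folds, config$fold_seed)
  oof <- numeric(length(d$y))
  for (f in seq_len(config$folds)) {
    in_f <- folds == f
    fit <- .enet_fit(x[!in_f, , drop = FALSE], d$y[!in_f], config$alpha,
                     config$l1_ratio, config$include_intercept)
    oof[in_f] <- x[in_f, , drop = FALSE] %*% fit$coef + fit$intercept
  }
  list(coefficients = full$coef, intercept = full$intercept,
       oof = data.frame(run_id = d$run_id, observed = d$y, predicted = oof),
       dropped = dropped)
}

#' Per-drug meta-regression: the predictor-by-target coefficient matrix
#'
#' For each target drug, fits the elastic net of that drug's per-run test
#' Pearson on the composition vectors, once per cross-validation fold on
#' that fold's training portion, and averages the fold coefficient
#' vectors.  Column `j` of the result holds the averaged coefficients for
#' target `j`; entry `(j, j)` is the self (non-drug-blind) coefficient.
#' Targets with defined performance in fewer than `folds` runs are flagged
#' undefined and excluded (rows and columns restricted so the matrix stays
#' square).
#'
#' @param records a `drpRunRecords` list from a partial-blind sweep.
#' @param config a [metaConfig()] list.
#' @return A [CoefficientMatrix-class]; diagnostics list undefined targets
#'   and zero-variance (never/always trained) predictors.
#' @export
fitPerDrugMeta <- function(records, config = metaConfig()) {
  universe <- attr(records, "drug_universe")
  ok <- Filter(function(r) !r$failed, records)
  if (!length(ok)) stop("no usable runs")
  x_all <- do.call(rbind, lapply(ok, function(r) r$composition))
  pd <- do.call(rbind, lapply(ok, function(r) r$per_drug[universe]))
  colnames(pd) <- universe
  variance <- apply(x_all, 2, var)
  zero_var <- universe[variance == 0]
  if (length(zero_var))
    warning("drugs never or always in training (self column flagged): ",
            paste(zero_var, collapse = ", "))
  defined <- colSums(!is.na(pd)) >= config$folds
  undefined <- universe[!defined]
  targets <- universe[defined]
  if (length(undefined))
    message("targets with insufficient coverage excluded: ",
            paste(undefined, collapse = ", "))
  cols <- matrix(0, nrow = length(universe), ncol = length(targets),
                 dimnames = list(universe, targets))
  for (j in targets) {
    keep <- !is.na(pd[, j])
    xj <- x_all[keep, , drop = FALSE]
    yj <- pd[keep, j]
    folds <- .fold_ids(length(yj), config$folds, config$fold_seed)
    acc <- numeric(length(universe))
    for (f in seq_len(config$folds)) {
      tr <- folds != f
      vj <- apply(xj[tr, , drop = FALSE], 2, var)
      use <- vj > 0
      fit <- .enet_fit(xj[tr, use, drop = FALSE], yj[tr], config$alpha,
                       config$l1_ratio, config$include_intercept)
      acc[use] <- acc[use] + fit$coef
    }
    cols[, j] <- acc / config$folds
  }
  values <- cols[targets, , drop = FALSE]
  CoefficientMatrix(values,
                    diagnostics = list(n_runs = length(ok),
                                       folds = config$folds,
                                       undefined_targets = undefined,
                                       zero_variance = zero_var))
}

#' Hierarchically cluster the coefficient matrix
#'
#' Agglomerative clustering (average linkage on Euclidean distance) of
#' target columns by their predictor-coefficient profiles.  The returned
#' display matrix is clipped to \[-1, 1\] for plotting contrast only — all
#' statistics are always computed from uncapped values.
#'
#' @param matrix a [CoefficientMatrix-class] over at least 2 drugs.
#' @return list: `order` (leaf-ordered drug labels), `hclust` (the tree),
#'   `display` (reordered matrix clipped to \[-1, 1\]).
#' @export
clusterMatrix <- function(matrix) {
  v <- coefValues(matrix)
  if (ncol(v) < 2L) stop("clustering needs at least 2 drugs")
  hc <- stats::hclust(stats::dist(t(v), method = "euclidean"),
                      method = "average")
  ord <- hc$labels[hc$order]
  disp <- pmin(pmax(v[ord, ord, drop = FALSE], -1), 1)
  list(order = ord, hclust = hc, display = disp)
}

#' One-to-one relationship score
#'
#' For each target drug `j`: `log(max_{i != j} C[i, j] / C[j, j])` (natural
#' log).  Positive scores mean some other single drug predicts `j`'s
#' performance better than `j` itself.  Undefined (NA) when the self
#' coefficient or the maximal non-self coefficient is non-positive —
#' clamping would fabricate an ordering among failures.
#'
#' @param matrix a [CoefficientMatrix-class].
#' @param base logarithm base (default `exp(1)`).
#' @return named numeric vector over target drugs (NA where undefined).
#' @export
oneToOne <- function(matrix, base = exp(1)) {
  v <- coefValues(matrix)
  vapply(seq_len(ncol(v)), function(j) {
    self <- v[j, j]
    other <- max(v[-j, j])
    if (self <= 0 || other <= 0) NA_real_ else log(other / self, base = base)
  }, numeric(1)) |> setNames(colnames(v))
}

#' Many-to-one relationship score
#'
#' For each target drug `j`: the sum of all non-self coefficients in its
#' column, averaged by the number of unique drugs `N`.  Strongly negative
#' scores flag targets whose prediction is damaged by the rest of the
#' panel — the signature of structurally similar but pharmacologically
#' opposed drugs.
#'
#' @param matrix a [CoefficientMatrix-class].
#' @param divisor `"N"` (all drugs, default) or `"N-1"`.
#' @return named numeric vector over target drugs.
#' @export
manyToOne <- function(matrix, divisor = c("N", "N-1")) {
  divisor <- match.arg(divisor)
  v <- coefValues(matrix)
  n <- ncol(v)
  den <- if (divisor == "N") n else n - 1L
  vapply(seq_len(n), function(j) sum(v[-j, j]) / den, numeric(1)) |>
    setNames(colnames(v))
}

#' Class-to-class relationship scores
#'
#' For each ordered pair (predictor class A, target class B): the mean of
#' `C[i, j]` over `i` in A, `j` in B with `i != j` (within-class pairs keep
#' cross-drug entries; only self pairs are excluded).  Pairs with no
#' admissible entries are omitted; unlabeled drugs are excluded.
#'
#' @param matrix a [CoefficientMatrix-class].
#' @param classes named character vector, drug id -> class label.
#' @return data.frame with `predictor_class`, `target_class`, `score`, `n`.
#' @export
classToClass <- function(matrix, classes) {
  v <- coefValues(matrix)
  ids <- colnames(v)
  classes <- classes[intersect(names(classes), ids)]
  classes <- classes[!is.na(classes)]
  labs <- sort(unique(classes))
  rows <- list()
  for (a in labs) for (b in labs) {
    i <- which(ids %in% names(classes)[classes == a])
    j <- which(ids %in% names(classes)[classes == b])
    block <- v[i, j, drop = FALSE]
    if (a == b) diag(block) <- NA  # square block: drop self pairs only
    vals <- block[!is.na(block)]
    if (length(vals))
      rows[[length(rows) + 1L]] <-
        data.frame(predictor_class = a, target_class = b,
                   score = mean(vals), n = length(vals))
  }
  do.call(rbind, rows)
}

#' Self-best rate
#'
#' The fraction of target drugs whose strongest predictor of performance is
#' their own training presence (`C[j, j] >= max_{i != j} C[i, j]`; exact
#' ties count as self-best).  Exceptions are listed with their best
#' predictor.
#'
#' @param matrix a [CoefficientMatrix-class].
#' @return list: `rate` in \[0, 1\], `exceptions` (data.frame target /
#'   best_predictor / self_coef / best_coef).
#' @export
selfBestRate <- function(matrix) {
  v <- coefValues(matrix)
  ids <- colnames(v)
  exc <- list()
  self_best <- vapply(seq_len(ncol(v)), function(j) {
    best_other <- max(v[-j, j])
    if (v[j, j] >= best_other) return(TRUE)
    i <- setdiff(order(v[, j], decreasing = TRUE), j)[1L]
    exc[[length(exc) + 1L]] <<-
      data.frame(target = ids[j], best_predictor = ids[i],
                 self_coef = v[j, j], best_coef = v[i, j])
    FALSE
  }, logical(1))
  list(rate = mean(self_best),
       exceptions = if (length(exc)) do.call(rbind, exc) else
         data.frame(target = character(), best_predictor = character(),
                    self_coef = numeric(), best_coef = numeric()))
}

#' Mean pairwise cosine similarity within (or across) groups
#'
#' Within-group mode: for each reported group (>= 2 members), the mean
#' cosine similarity over all unordered within-group pairs of vectors.
#' Cross-group mode (`across` given): the mean over all pairs with one
#' vector in each group — used e.g. to compare fingerprints of a drug
#' class against another class.  Zero vectors are skipped with a warning.
#'
#' @param vectors numeric matrix with ids as rownames (e.g. embeddings or
#'   fingerprints).
#' @param groups named character vector, id -> group label.
#' @param across optional length-2 character vector of group labels for
#'   cross-group mode.
#' @return named numeric vector of mean cosines (per group, or one value
#'   named "A|B" in cross-group mode).
#' @export
groupCosine <- function(vectors, groups, across = NULL) {
  norms <- sqrt(rowSums(vectors^2))
  zero <- norms == 0
  if (any(zero)) {
    warning("zero vectors skipped: ",
            paste(rownames(vectors)[zero], collapse = ", "))
    vectors <- vectors[!zero, , drop = FALSE]
    norms <- norms[!zero]
  }
  unit <- vectors / norms
  cos_mean <- function(ids_a, ids_b, same) {
    s <- unit[ids_a, , drop = FALSE] %*% t(unit[ids_b, , drop = FALSE])
    if (same) mean(s[upper.tri(s)]) else mean(s)
  }
  groups <- groups[intersect(names(groups), rownames(vectors))]
  if (!is.null(across)) {
    a <- names(groups)[groups == across[1]]
    b <- names(groups)[groups == across[2]]
    if (!length(a) || !length(b)) stop("empty group in cross-group mode")
    return(setNames(cos_mean(a, b, same = FALSE),
                    paste(across, collapse = "|")))
  }
  labs <- sort(unique(groups))
  out <- vapply(labs, function(g) {
    ids <- names(groups)[groups == g]
    if (length(ids) < 2L) return(NA_real_)
    cos_mean(ids, ids, same = TRUE)
  }, numeric(1))
  setNames(out, labs)[!is.na(out)]
}
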