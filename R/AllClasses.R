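#' @import methods
#' @importFrom stats cor sd var rnorm runif rbinom setNames predict coef
#'   na.omit aggregate ave hclust dist
#' @importFrom utils read.delim write.csv read.csv modifyList head
#' @useDynLib drpaudit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.response_metrics <- c("EC50", "IC50", "AUC", "AOC", "GR50", "Emax",
                       "GRinf", "GRmax", "0.5uM fit")

#' ResponsePanel: a set of (cell, drug, response) measurements
#'
#' The basic unit of a pharmacogenomic screen: one finite response value per
#' measured (cell line, drug) pair, under a named response metric (EC50,
#' IC50, AUC, a growth-rate statistic, or any free label).  Each pair may
#' appear at most once; duplicate measurements are a construction error
#' because no principled resolution rule (averaging, first-wins) is assumed.
#'
#' @slot metric single character, the response metric name.
#' @slot tuples data.frame with character columns `cell_id`, `drug_id` and
#'   numeric column `response`.
#' @exportClass ResponsePanel
setClass("ResponsePanel",
         representation(metric = "character", tuples = "data.frame"))

setValidity("ResponsePanel", function(object) {
  t <- object@tuples
  if (length(object@metric) != 1L || !nzchar(object@metric))
    return("metric must be a single non-empty string")
  if (!all(c("cell_id", "drug_id", "response") %in% names(t)))
    return("tuples must have columns cell_id, drug_id, response")
  if (nrow(t) == 0L) return(TRUE)
  if (!is.numeric(t$response) || !all(is.finite(t$response)))
    return("all responses must be finite numbers")
  key <- paste(t$cell_id, t$drug_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- t[duplicated(key), , drop = FALSE][1L, ]
    return(sprintf("duplicate (cell, drug) pair: (%s, %s)",
                   d$cell_id, d$drug_id))
  }
  TRUE
})

#' Construct a ResponsePanel
#'
#' @param tuples data.frame with columns `cell_id`, `drug_id`, `response`.
#' @param metric response metric label (default `"EC50"`).
#' @return A [ResponsePanel-class] object.
#' @examples
#' ResponsePanel(data.frame(cell_id = c("C1", "C2"), drug_id = "D1",
#'                          response = c(0.2, -1.1)), metric = "IC50")
#' @export
ResponsePanel <- function(tuples, metric = "EC50") {
  tuples <- as.data.frame(tuples)
  tuples$cell_id <- as.character(tuples$cell_id)
  tuples$drug_id <- as.character(tuples$drug_id)
  tuples$response <- as.numeric(tuples$response)
  rownames(tuples) <- NULL
  new("ResponsePanel", metric = metric,
      tuples = tuples[, c("cell_id", "drug_id", "response")])
}

#' DrugFeatureSet: fixed-width binary drug fingerprints
#'
#' Holds one binary fingerprint per drug (rows of `features`), with optional
#' mechanism-of-action and pathway labels, plus the list of drugs excluded
#' during featurization (e.g. unparseable SMILES).
#'
#' @slot features binary matrix, drugs in rows (rownames = drug ids).
#' @slot mechanism named character vector (subset of drugs), may be empty.
#' @slot pathway named character vector (subset of drugs), may be empty.
#' @slot excluded character vector of drug ids dropped during featurization.
#' @exportClass DrugFeatureSet
setClass("DrugFeatureSet",
         representation(features = "matrix", mechanism = "character",
                        pathway = "character", excluded = "character"))

setValidity("DrugFeatureSet", function(object) {
  f <- object@features
  if (is.null(rownames(f)) || anyDuplicated(rownames(f)))
    return("features must have unique drug-id rownames")
  if (ncol(f) < 1L) return("fingerprint width must be positive")
  if (length(f) && !all(f %in% c(0, 1)))
    return("fingerprint entries must be 0 or 1")
  for (lab in c("mechanism", "pathway")) {
    v <- slot(object, lab)
    if (length(v) && !all(names(v) %in% rownames(f)))
      return(sprintf("%s labels refer to unknown drugs", lab))
  }
  TRUE
})

#' Construct a DrugFeatureSet
#'
#' @param features binary matrix with drug ids as rownames.
#' @param mechanism,pathway optional named character vectors of labels.
#' @param excluded drug ids dropped during featurization.
#' @return A [DrugFeatureSet-class] object.
#' @export
DrugFeatureSet <- function(features, mechanism = character(),
                           pathway = character(), excluded = character()) {
  storage.mode(features) <- "double"
  new("DrugFeatureSet", features = features, mechanism = mechanism,
      pathway = pathway, excluded = excluded)
}

#' CellFeatureSet: fixed-width cell-line feature vectors
#'
#' One real-valued feature vector per cell line: gene expression, a one-hot
#' identity encoding, or a precomputed embedding.  One-hot sets must form an
#' identity matrix over the cells.
#'
#' @slot features numeric matrix, cells in rows (rownames = cell ids).
#' @slot encoding one of `"expression"`, `"one_hot"`,
#'   `"precomputed_embedding"`.
#' @exportClass CellFeatureSet
setClass("CellFeatureSet",
         representation(features = "matrix", encoding = "character"))

setValidity("CellFeatureSet", function(object) {
  f <- object@features
  if (is.null(rownames(f)) || anyDuplicated(rownames(f)))
    return("features must have unique cell-id rownames")
  if (length(f) && !all(is.finite(f))) return("all entries must be finite")
  if (!object@encoding %in% c("expression", "one_hot",
                              "precomputed_embedding"))
    return("encoding must be expression, one_hot or precomputed_embedding")
  if (object@encoding == "one_hot") {
    if (ncol(f) != nrow(f))
      return("one_hot encoding requires width = number of cells")
    if (!all(f %in% c(0, 1)) || !all(rowSums(f) == 1))
      return("one_hot vectors must contain exactly one 1")
  }
  TRUE
})

#' Construct a CellFeatureSet
#'
#' @param features numeric matrix with cell ids as rownames.
#' @param encoding feature encoding label.
#' @return A [CellFeatureSet-class] object.
#' @export
CellFeatureSet <- function(features, encoding = "expression") {
  storage.mode(features) <- "double"
  new("CellFeatureSet", features = features, encoding = encoding)
}

#' AnnotationTable: drug target and pathway annotations
#'
#' Compound annotations in the style of public screen metadata: one row per
#' drug with a putative target and a pathway label.  Missing annotations are
#' stored as `NA`, never as empty strings.
#'
#' @slot table data.frame with columns `drug_id`, `putative_target`,
#'   `pathway`.
#' @exportClass AnnotationTable
setClass("AnnotationTable", representation(table = "data.frame"))

setValidity("AnnotationTable", function(object) {
  t <- object@table
  if (!all(c("drug_id", "putative_target", "pathway") %in% names(t)))
    return("table needs columns drug_id, putative_target, pathway")
  if (anyDuplicated(t$drug_id))
    return(sprintf("duplicate drug_id: %s",
                   t$drug_id[duplicated(t$drug_id)][1L]))
  for (col in c("putative_target", "pathway")) {
    v <- t[[col]]
    if (any(!is.na(v) & !nzchar(v)))
      return(sprintf("empty %s labels must be stored as NA", col))
  }
  TRUE
})

#' Construct an AnnotationTable
#'
#' @param table data.frame with columns `drug_id`, `putative_target`,
#'   `pathway`; empty strings are converted to `NA`.
#' @return An [AnnotationTable-class] object.
#' @export
AnnotationTable <- function(table) {
  table <- as.data.frame(table)
  for (col in c("putative_target", "pathway")) {
    v <- as.character(table[[col]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
    table[[col]] <- v
  }
  table$drug_id <- as.character(table$drug_id)
  rownames(table) <- NULL
  new("AnnotationTable",
      table = table[, c("drug_id", "putative_target", "pathway")])
}

#' SplitAssignment: a train/validation/test labeling of panel tuples
#'
#' Assigns every tuple of a [ResponsePanel-class] to `train`, `val`, `test`
#' or `excluded` under one of four blinding modes.  `drug_blind` guarantees
#' pairwise-disjoint drug sets across partitions; `partial_blind` guarantees
#' that non-training drugs never contribute training tuples while the
#' held-out partitions jointly span every drug.
#'
#' @slot mode one of `"mixed"`, `"drug_blind"`, `"fixed_test_composition"`,
#'   `"partial_blind"`.
#' @slot partition character vector over tuple indices, values in
#'   `train`/`val`/`test`/`excluded`.
#' @slot trainingDrugs drugs appearing in the train partition.
#' @slot frozenTest whether the test drug set is frozen across sweep seeds.
#' @slot params list of the parameters the split was built from.
#' @slot seed integer seed used.
#' @exportClass SplitAssignment
setClass("SplitAssignment",
         representation(mode = "character", partition = "character",
                        trainingDrugs = "character", frozenTest = "logical",
                        params = "list", seed = "integer"))

setValidity("SplitAssignment", function(object) {
  if (!object@mode %in% c("mixed", "drug_blind", "fixed_test_composition",
                          "partial_blind"))
    return("unknown split mode")
  if (!all(object@partition %in% c("train", "val", "test", "excluded")))
    return("partition labels must be train/val/test/excluded")
  TRUE
})

#' SimConfig: parameters of the synthetic pharmacogenomic panel generator
#'
#' See [simConfig()] for the meaning and defaults of every parameter.
#'
#' @exportClass SimConfig
setClass("SimConfig",
         representation(n_mechanisms = "integer", drugs_per_mechanism = "integer",
                        n_cells = "integer", n_cell_features = "integer",
                        fingerprint_width = "integer", p_on = "numeric",
                        flip_rate = "numeric", sigma2_mech = "numeric",
                        sigma2_drug = "numeric", b0 = "numeric",
                        sigma2_beta = "numeric", sigma2_slope = "numeric",
                        sigma2_noise = "numeric", sigma2_feat = "numeric",
                        confusable_pairs = "list", pairing_density = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  for (s in c("sigma2_mech", "sigma2_drug", "sigma2_beta", "sigma2_slope",
              "sigma2_noise", "sigma2_feat"))
    if (slot(object, s) < 0) return(sprintf("%s must be >= 0", s))
  if (object@p_on <= 0 || object@p_on >= 1) return("p_on must be in (0,1)")
  if (object@flip_rate < 0 || object@flip_rate >= 0.5)
    return("flip_rate must be in [0, 0.5)")
  if (object@pairing_density <= 0 || object@pairing_density > 1)
    return("pairing_density must be in (0, 1]")
  mechs <- paste0("M", seq_len(object@n_mechanisms))
  for (p in object@confusable_pairs) {
    if (length(p) != 2L || p[1] == p[2] || !all(p %in% mechs))
      return("confusable pairs must name two distinct declared mechanisms")
  }
  TRUE
})

#' SyntheticGroundTruth: latent structure behind a synthetic panel
#'
#' Everything the generator drew: mechanism assignments, fingerprint
#' templates, mechanism means/slopes, per-drug offsets, latent cell
#' sensitivities and the feature loading matrix — the oracle against which
#' downstream stages are validated.
#'
#' @slot mechanism named character, drug id -> mechanism label.
#' @slot templates binary matrix, mechanisms x fingerprint width.
#' @slot mu,beta named numeric, per-mechanism response mean and slope.
#' @slot delta,gamma named numeric, per-drug mean and slope offsets.
#' @slot sensitivities numeric matrix, cells x mechanisms.
#' @slot loading numeric matrix, cell features x mechanisms.
#' @slot config the [SimConfig-class] used.
#' @exportClass SyntheticGroundTruth
setClass("SyntheticGroundTruth",
         representation(mechanism = "character", templates = "matrix",
                        mu = "numeric", delta = "numeric", beta = "numeric",
                        gamma = "numeric", sensitivities = "matrix",
                        loading = "matrix", config = "SimConfig"))

setValidity("SyntheticGroundTruth", function(object) {
  if (ncol(object@sensitivities) != length(object@mu))
    return("sensitivity vectors must have one column per mechanism")
  cfg <- object@config
  for (p in cfg@confusable_pairs) {
    if (!isTRUE(all.equal(object@beta[[p[2]]], -object@beta[[p[1]]])))
      return("confusable partner must carry the negated slope")
    if (!all(object@templates[p[1], ] == object@templates[p[2], ]))
      return("confusable partner must share the fingerprint template")
  }
  TRUE
})

#' TrainedDRPModel: a two-arm MLP and its training provenance
#'
#' @slot config the [modelConfig()] list used to build/train the model.
#' @slot net opaque parameter list (layer weights/biases).
#' @slot history data.frame with per-epoch `train_loss`, `val_loss`.
#' @slot bestEpoch epoch whose parameters are stored (minimum val loss).
#' @slot snapshots list of parameter lists at checkpoint epochs.
#' @slot preprocessing list with per-feature cell scaling (`center`, `scale`).
#' @slot trained logical.
#' @exportClass TrainedDRPModel
setClass("TrainedDRPModel",
         representation(config = "list", net = "list", history = "data.frame",
                        bestEpoch = "integer", snapshots = "list",
                        preprocessing = "list", trained = "logical"))

setValidity("TrainedDRPModel", function(object) {
  h <- object@history
  if (object@trained && nrow(h)) {
    if (which.min(h$val_loss) != object@bestEpoch)
      return("bestEpoch must minimize recorded validation loss")
  }
  TRUE
})

#' EvaluationResult: global and per-drug Pearson of a prediction set
#'
#' @slot globalPearson Pearson correlation over all evaluated pairs (`NA`
#'   when undefined, e.g. constant predictions).
#' @slot perDrug data.frame with `drug_id`, `pearson` (NA when undefined)
#'   and `n` evaluated tuples.
#' @exportClass EvaluationResult
setClass("EvaluationResult",
         representation(globalPearson = "numeric", perDrug = "data.frame"))

#' CoefficientMatrix: predictor-drug by target-drug meta-model coefficients
#'
#' Square matrix whose column `j` holds the elastic-net coefficients of every
#' drug's training-presence feature in the meta-model for drug `j`'s
#' performance; entry `(j, j)` is the self (non-drug-blind) coefficient.
#'
#' @slot values square numeric matrix with identical row/column drug labels.
#' @slot diagnostics list: runs used, folds, undefined targets,
#'   zero-variance predictors.
#' @exportClass CoefficientMatrix
setClass("CoefficientMatrix",
         representation(values = "matrix", diagnostics = "list"))

setValidity("CoefficientMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("row and column drug labels must be identical")
  if (anyDuplicated(rownames(v))) return("drug labels must be unique")
  if (length(v) && !all(is.finite(v))) return("entries must be finite")
  TRUE
})

#' Construct a CoefficientMatrix
#'
#' @param values square numeric matrix, identical row/column drug labels.
#' @param diagnostics optional list of fit diagnostics.
#' @return A [CoefficientMatrix-class] object.
#' @export
CoefficientMatrix <- function(values, diagnostics = list()) {
  new("CoefficientMatrix", values = values, diagnostics = diagnostics)
}
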