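# Accessor generics shared across the core data classes.

#' Drug identifiers of an object
#' @param x an object holding drugs.
#' @return character vector of drug ids.
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' Cell identifiers of an object
#' @param x an object holding cells.
#' @return character vector of cell ids.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' Feature matrix of a feature set
#' @param x a feature-set object.
#' @return numeric matrix, entities in rows.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Feature width of a feature set
#' @param x a feature-set object.
#' @return integer width.
#' @export
setGeneric("featureWidth", function(x) standardGeneric("featureWidth"))

#' @describeIn ResponsePanel-class drug ids present in the panel.
#' @param x object.
#' @export
setMethod("drugIds", "ResponsePanel",
          function(x) sort(unique(x@tuples$drug_id)))

#' @describeIn ResponsePanel-class cell ids present in the panel.
#' @export
setMethod("cellIds", "ResponsePanel",
          function(x) sort(unique(x@tuples$cell_id)))

#' Response tuples of a panel
#' @param panel a [ResponsePanel-class].
#' @return data.frame with columns cell_id, drug_id, response.
#' @export
responseTuples <- function(panel) panel@tuples

#' Response metric label of a panel
#' @param panel a [ResponsePanel-class].
#' @return single character.
#' @export
responseMetric <- function(panel) panel@metric

#' Number of tuples in a panel
#' @param panel a [ResponsePanel-class].
#' @return integer count.
#' @export
nTuples <- function(panel) nrow(panel@tuples)

#' @describeIn DrugFeatureSet-class drug ids (fingerprint rownames).
#' @param x object.
#' @export
setMethod("drugIds", "DrugFeatureSet", function(x) rownames(x@features))

#' @describeIn DrugFeatureSet-class the fingerprint matrix.
#' @export
setMethod("featureMatrix", "DrugFeatureSet", function(x) x@features)

#' @describeIn DrugFeatureSet-class fingerprint width.
#' @export
setMethod("featureWidth", "DrugFeatureSet", function(x) ncol(x@features))

#' Mechanism labels of a drug feature set
#' @param x a [DrugFeatureSet-class].
#' @return named character vector (possibly empty).
#' @export
drugMechanisms <- function(x) x@mechanism

#' Drugs excluded during featurization
#' @param x a [DrugFeatureSet-class].
#' @return character vector of dropped drug ids.
#' @export
excludedDrugs <- function(x) x@excluded

#' @describeIn CellFeatureSet-class cell ids (feature rownames).
#' @param x object.
#' @export
setMethod("cellIds", "CellFeatureSet", function(x) rownames(x@features))

#' @describeIn CellFeatureSet-class the feature matrix.
#' @export
setMethod("featureMatrix", "CellFeatureSet", function(x) x@features)

#' @describeIn CellFeatureSet-class feature width.
#' @export
setMethod("featureWidth", "CellFeatureSet", function(x) ncol(x@features))

#' Encoding label of a cell feature set
#' @param x a [CellFeatureSet-class].
#' @return one of expression/one_hot/precomputed_embedding.
#' @export
cellEncoding <- function(x) x@encoding

#' @describeIn AnnotationTable-class annotated drug ids.
#' @param x object.
#' @export
setMethod("drugIds", "AnnotationTable", function(x) x@table$drug_id)

#' Annotation rows of a table
#' @param x an [AnnotationTable-class].
#' @return data.frame with drug_id, putative_target, pathway.
#' @export
annotationRows <- function(x) x@table

#' Putative targets as a named vector
#' @param x an [AnnotationTable-class].
#' @return named character, drug id -> target.
#' @export
drugTargets <- function(x) setNames(x@table$putative_target, x@table$drug_id)

#' Training drugs of a split
#' @param split a [SplitAssignment-class].
#' @return character vector of drug ids in the train partition.
#' @export
trainingDrugs <- function(split) split@trainingDrugs

#' Split mode label
#' @param split a [SplitAssignment-class].
#' @return single character.
#' @export
splitMode <- function(split) split@mode

#' Tuple indices of one partition of a split
#' @param split a [SplitAssignment-class].
#' @param which one of `"train"`, `"val"`, `"test"`, `"excluded"`.
#' @return integer vector of tuple indices.
#' @export
partitionIndices <- function(split,
                             which = c("train", "val", "test", "excluded")) {
  which <- match.arg(which)
  which(split@partition == which)
}

#' Coefficient values of a CoefficientMatrix
#' @param x a [CoefficientMatrix-class].
#' @return square numeric matrix.
#' @export
coefValues <- function(x) x@values

#' Global Pearson of an evaluation
#' @param x an [EvaluationResult-class].
#' @return numeric scalar (NA if undefined).
#' @export
globalPearson <- function(x) x@globalPearson

#' Per-drug Pearson table of an evaluation
#' @param x an [EvaluationResult-class].
#' @return data.frame with drug_id, pearson, n.
#' @export
perDrugPearson <- function(x) x@perDrug

#' Training history of a model
#' @param model a [TrainedDRPModel-class].
#' @return data.frame with epoch, train_loss, val_loss.
#' @export
trainingHistory <- function(model) model@history

#' Best (early-stopping) epoch of a model
#' @param model a [TrainedDRPModel-class].
#' @return integer epoch.
#' @export
bestEpoch <- function(model) model@bestEpoch

setMethod("show", "ResponsePanel", function(object) {
  cat(sprintf("ResponsePanel: %d tuples, %d drugs x %d cells, metric %s\n",
              nrow(object@tuples), length(drugIds(object)),
              length(cellIds(object)), object@metric))
})

setMethod("show", "DrugFeatureSet", function(object) {
  cat(sprintf("DrugFeatureSet: %d drugs, width %d%s\n",
              nrow(object@features), ncol(object@features),
              if (length(object@excluded))
                sprintf(" (%d excluded)", length(object@excluded)) else ""))
})

setMethod("show", "CellFeatureSet", function(object) {
  cat(sprintf("CellFeatureSet: %d cells, width %d, encoding %s\n",
              nrow(object@features), ncol(object@features), object@encoding))
})

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf("AnnotationTable: %d drugs\n", nrow(object@table)))
})

setMethod("show", "SplitAssignment", function(object) {
  p <- table(factor(object@partition,
                    levels = c("train", "val", "test", "excluded")))
  cat(sprintf("SplitAssignment (%s): train %d / val %d / test %d%s\n",
              object@mode, p[["train"]], p[["val"]], p[["test"]],
              if (p[["excluded"]]) sprintf(" (excluded %d)", p[["excluded"]])
              else ""))
})

setMethod("show", "TrainedDRPModel", function(object) {
  if (object@trained)
    cat(sprintf("TrainedDRPModel: %d epochs, best epoch %d (val MSE %.4g)\n",
                nrow(object@history), object@bestEpoch,
                object@history$val_loss[object@bestEpoch]))
  else cat("TrainedDRPModel: untrained\n")
})

setMethod("show", "CoefficientMatrix", function(object) {
  cat(sprintf("CoefficientMatrix: %d x %d drugs\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult: global Pearson %.3f, %d drugs evaluated\n",
              object@globalPearson, sum(!is.na(object@perDrug$pearson))))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d mechanisms x %d drugs, %d cells, ",
                     "%d features, fingerprint width %d\n"),
              object@n_mechanisms, object@drugs_per_mechanism,
              object@n_cells, object@n_cell_features,
              object@fingerprint_width))
})

setMethod("show", "SyntheticGroundTruth", function(object) {
  cat(sprintf("SyntheticGroundTruth: %d drugs over %d mechanisms\n",
              length(object@mechanism), length(object@mu)))
})
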