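# Readers and featurization for response tables, expression matrices,
# SMILES and compound annotations.

.read_delimited <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read a long-format drug response table
#'
#' Reads a delimited text file (CSV or TSV, autodetected from the
#' extension) with one measured (cell line, drug, response) tuple per row,
#' as exported by the large public pharmacogenomic screens.
#'
#' @param path file path; header required.
#' @param metric response metric label to record (e.g. `"EC50"`).
#' @param column_map named character vector mapping the roles `cell`,
#'   `drug`, `value` to column names in the file.
#' @param log10_transform take log10 of the response values (useful for
#'   EC50-family metrics spanning many orders of magnitude).
#' @return A [ResponsePanel-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(cell_line = c("C1", "C2"), drug = "D1",
#'                      value = c(1.5, 0.3)), f, row.names = FALSE)
#' readResponseTable(f, metric = "AUC")
#' @export
readResponseTable <- function(path, metric = "EC50",
                              column_map = c(cell = "cell_line",
                                             drug = "drug", value = "value"),
                              log10_transform = FALSE) {
  stopifnot(file.exists(path))
  raw <- .read_delimited(path)
  miss <- setdiff(unname(column_map[c("cell", "drug", "value")]), names(raw))
  if (length(miss))
    stop("response table is missing column(s): ", paste(miss, collapse = ", "))
  val <- raw[[column_map[["value"]]]]
  num <- suppressWarnings(as.numeric(val))
  bad <- which(is.na(num) | !is.finite(num))
  if (length(bad))
    stop(sprintf("non-numeric or missing response value at row %d", bad[1L]))
  if (log10_transform) {
    if (any(num <= 0)) stop("log10 transform requires positive responses")
    num <- log10(num)
  }
  tuples <- data.frame(cell_id = as.character(raw[[column_map[["cell"]]]]),
                       drug_id = as.character(raw[[column_map[["drug"]]]]),
                       response = num, stringsAsFactors = FALSE)
  key <- paste(tuples$cell_id, tuples$drug_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tuples[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (cell, drug) pair: (%s, %s)",
                 d$cell_id, d$drug_id))
  }
  ResponsePanel(tuples, metric = metric)
}

#' Filter a panel to an open response interval
#'
#' Drops tuples whose response falls outside `(lower, upper)`, the rule used
#' to remove physically implausible potency values (e.g. apparent-molar EC50
#' fits beyond 1e14 or below 1e-26) before training.
#'
#' @param panel a [ResponsePanel-class].
#' @param lower,upper open interval bounds, `lower < upper`. The defaults
#'   are the extreme-EC50 bounds; whether they are molar or the screen's
#'   apparent-micromolar scale is a property of the source table, so they
#'   are plain configurable numbers here.
#' @return The filtered [ResponsePanel-class]; a message reports counts
#'   removed, and a warning is raised if nothing survives.
#' @export
filterResponseRange <- function(panel, lower = 1e-26, upper = 1e14) {
  if (!is.finite(lower) && lower > 0) stop("lower bound must be < upper")
  if (lower >= upper) stop("lower bound must be strictly below upper bound")
  t <- panel@tuples
  keep <- t$response > lower & t$response < upper
  removed <- sum(!keep)
  if (removed) message(sprintf("filterResponseRange: removed %d of %d tuples",
                               removed, nrow(t)))
  if (!any(keep) && nrow(t) > 0)
    warning("all tuples removed by response-range filter")
  ResponsePanel(t[keep, , drop = FALSE], metric = panel@metric)
}

#' Read a two-column drug SMILES table
#'
#' @param path delimited file with columns `drug_id` and `smiles`.
#' @return named character vector, drug id -> SMILES.
#' @export
readSmilesTable <- function(path) {
  raw <- .read_delimited(path)
  if (!all(c("drug_id", "smiles") %in% names(raw)))
    stop("SMILES table needs columns drug_id, smiles")
  if (anyDuplicated(raw$drug_id)) stop("duplicate drug_id in SMILES table")
  setNames(as.character(raw$smiles), as.character(raw$drug_id))
}

.fold_fingerprint <- function(bits, width) {
  # OR-fold a longer binary vector down to the requested width
  if (length(bits) == width) return(bits)
  if (length(bits) %% width != 0)
    stop("fingerprint length is not a multiple of the requested width")
  m <- matrix(bits, nrow = width)
  as.numeric(rowSums(m) > 0)
}

#' Compute circular (Morgan-type) binary fingerprints from SMILES
#'
#' Generates extended-connectivity fingerprints (ECFP, diameter = 2 *
#' `radius`) for each drug via Open Babel and folds them to the requested
#' width.  Drugs whose SMILES cannot be parsed are dropped with a warning
#' and listed in the result's exclusion log; if no drug parses, an error is
#' raised.
#'
#' @param smiles named character vector, drug id -> SMILES string.
#' @param radius circular neighborhood radius (default 2, i.e. ECFP4).
#' @param width fingerprint length after folding (default 2048).
#' @return A [DrugFeatureSet-class]; see [excludedDrugs()] for the
#'   exclusion log.
#' @export
featurizeDrugs <- function(smiles, radius = 2, width = 2048) {
  if (is.null(names(smiles)) || !length(smiles))
    stop("smiles must be a named character vector")
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("featurizeDrugs requires the ChemmineOB package")
  fp_name <- paste0("ECFP", 2L * as.integer(radius))
  rows <- list()
  excluded <- character()
  for (d in names(smiles)) {
    bits <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", smiles[[d]], identity)
      as.numeric(ChemmineOB::fingerprint_OB(mol, fp_name))
    }, error = function(e) NULL)
    if (is.null(bits)) excluded <- c(excluded, d)
    else rows[[d]] <- .fold_fingerprint(bits, width)
  }
  if (!length(rows)) stop("no drug had a parseable SMILES string")
  if (length(excluded))
    warning("dropped drugs with unparseable SMILES: ",
            paste(excluded, collapse = ", "))
  features <- do.call(rbind, rows)
  rownames(features) <- names(rows)
  DrugFeatureSet(features, excluded = excluded)
}

#' Read a cell-by-gene expression matrix
#'
#' @param path delimited file; first column `cell_id`, remaining columns
#'   gene symbols.
#' @return numeric matrix, cells in rows.
#' @export
readExpressionMatrix <- function(path) {
  raw <- .read_delimited(path)
  if (names(raw)[1L] != "cell_id")
    stop("expression matrix must have cell_id as its first column")
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(raw$cell_id)
  m
}

#' Restrict expression features to a reference gene set
#'
#' Keeps the genes present in both the matrix and the reference set (e.g.
#' the genes measured in a patient cohort), in sorted order so downstream
#' models are reproducible regardless of input column order.
#'
#' @param matrix numeric cell-by-gene matrix with gene column names.
#' @param reference_genes character set of gene symbols to intersect with.
#' @return A [CellFeatureSet-class] with `encoding = "expression"`.
#' @export
intersectGeneFeatures <- function(matrix, reference_genes) {
  if (is.null(colnames(matrix))) stop("matrix must have named gene columns")
  common <- sort(intersect(colnames(matrix), reference_genes))
  if (!length(common))
    stop("no genes shared between the matrix and the reference set")
  CellFeatureSet(matrix[, common, drop = FALSE], encoding = "expression")
}

#' One-hot identity encoding of cell lines
#'
#' Replaces biological cell features with a pure identity code, the control
#' used to measure how much performance survives with no cell biology at
#' all.
#'
#' @param cell_ids character vector of unique cell ids; their order fixes
#'   the feature order.
#' @return A [CellFeatureSet-class] with `encoding = "one_hot"`.
#' @export
oneHotCells <- function(cell_ids) {
  cell_ids <- as.character(cell_ids)
  if (!length(cell_ids) || anyDuplicated(cell_ids))
    stop("cell_ids must be nonempty and unique")
  m <- diag(length(cell_ids))
  dimnames(m) <- list(cell_ids, cell_ids)
  CellFeatureSet(m, encoding = "one_hot")
}

#' Read a compound annotation table
#'
#' @param path delimited file with columns `drug_id`, `putative_target`,
#'   `pathway`; empty fields are stored as missing, later duplicate drugs
#'   are an error.
#' @return An [AnnotationTable-class].
#' @export
readAnnotations <- function(path) {
  raw <- .read_delimited(path)
  need <- c("drug_id", "putative_target", "pathway")
  if (!all(need %in% names(raw)))
    stop("annotation table needs columns drug_id, putative_target, pathway")
  AnnotationTable(raw[, need])
}
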