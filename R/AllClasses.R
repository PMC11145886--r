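#' @import methods
#' @import stats
#' @importFrom utils head read.delim write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
NULL

#' QuantMatrix: a protein (or peptide) quantity matrix
#'
#' A features x samples intensity container built on
#' \linkS4class{SummarizedExperiment}, carrying a single assay \code{"quant"}
#' and a scale flag recording whether values are raw intensities or log2
#' intensities. Missing cells are \code{NA}; exact zeros are kept as zeros so
#' the complete-case cleaning rule ("missing or zero") stays auditable.
#'
#' @slot scale character, \code{"raw"} or \code{"log2"}.
#' @export
setClass("QuantMatrix",
  contains = "SummarizedExperiment",
  slots = c(scale = "character")
)

setValidity("QuantMatrix", function(object) {
  msg <- NULL
  if (length(object@scale) != 1L || !object@scale %in% c("raw", "log2"))
    msg <- c(msg, "scale must be one of 'raw', 'log2'")
  if (!"quant" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'quant' is required")
  fid <- rownames(object)
  sid <- colnames(object)
  if (nrow(object) > 0 && (is.null(fid) || anyDuplicated(fid)))
    msg <- c(msg, "feature ids must be present and unique")
  if (ncol(object) > 0 && (is.null(sid) || anyDuplicated(sid)))
    msg <- c(msg, "sample ids must be present and unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct a QuantMatrix
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids optional character vectors; default taken
#'   from \code{dimnames(values)}.
#' @param scale \code{"raw"} or \code{"log2"}.
#' @return A \linkS4class{QuantMatrix}.
#' @examples
#' m <- matrix(2^rnorm(6, 20), 2, 3,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2", "s3")))
#' QuantMatrix(m)
#' @export
QuantMatrix <- function(values, feature_ids = rownames(values),
                        sample_ids = colnames(values), scale = "raw") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  rownames(values) <- feature_ids
  colnames(values) <- sample_ids
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(quant = values))
  new("QuantMatrix", se, scale = scale)
}

#' @describeIn QuantMatrix the intensity matrix (features x samples)
#' @param x,object a QuantMatrix
#' @export
quantValues <- function(x) SummarizedExperiment::assay(x, "quant")

#' @describeIn QuantMatrix the scale flag ("raw" or "log2")
#' @export
quantScale <- function(x) x@scale

#' @describeIn QuantMatrix feature identifiers (possibly ";"-joined accessions)
#' @export
featureIds <- function(x) rownames(x)

#' @describeIn QuantMatrix sample identifiers
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "QuantMatrix", function(object) {
  v <- quantValues(object)
  cat(sprintf("QuantMatrix: %d features x %d samples (%s scale)\n",
              nrow(v), ncol(v), object@scale))
  cat(sprintf("  missing cells: %d, zero cells: %d\n",
              sum(is.na(v)), sum(v == 0, na.rm = TRUE)))
  callNextMethod()
})

# internal: replace the assay keeping class and scale
setQuantValues <- function(x, values, scale = x@scale) {
  QuantMatrix(values, scale = scale)
}

#' ClusterModel: Spearman/Ward correlation clustering of features
#'
#' Holds the training-set Spearman dissimilarities, the Ward merge tree, the
#' linkage-distance threshold used to cut it, flat cluster labels, and the
#' randomly chosen sentinel feature of each cluster.
#'
#' Merge-tree encoding: leaves are nodes \code{1..n}; the i-th merge creates
#' node \code{n+i}. \code{merges} has columns \code{left}, \code{right},
#' \code{height}, \code{size}.
#'
#' @slot featureIds character, clustered feature ids.
#' @slot distances numeric, condensed pairwise dissimilarities in canonical
#'   upper-triangle row-major order.
#' @slot merges numeric matrix, the agglomeration sequence.
#' @slot threshold numeric, linkage distance at which the tree was cut.
#' @slot labels integer, cluster index per feature (named).
#' @slot sentinels character, one feature id per cluster (named by cluster).
#' @slot seed integer seed used for sentinel selection.
#' @export
setClass("ClusterModel", slots = c(
  featureIds = "character",
  distances = "numeric",
  merges = "matrix",
  threshold = "numeric",
  labels = "integer",
  sentinels = "character",
  seed = "integer"
))

setValidity("ClusterModel", function(object) {
  msg <- NULL
  n <- length(object@featureIds)
  if (length(object@distances) != n * (n - 1) / 2)
    msg <- c(msg, "condensed distance length must be n(n-1)/2")
  h <- object@merges[, "height"]
  if (length(h) > 1 && any(diff(h) < -1e-10))
    msg <- c(msg, "merge heights must be non-decreasing")
  if (length(object@labels) != n)
    msg <- c(msg, "one label per feature required")
  k <- length(unique(object@labels))
  if (length(object@sentinels) != k)
    msg <- c(msg, "number of sentinels must equal number of clusters")
  for (cl in names(object@sentinels)) {
    members <- object@featureIds[object@labels == as.integer(cl)]
    if (!object@sentinels[[cl]] %in% members)
      msg <- c(msg, sprintf("sentinel of cluster %s not a member", cl))
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf(
    "ClusterModel: %d features, %d clusters at linkage distance %.3g\n",
    length(object@featureIds), length(object@sentinels), object@threshold))
})

#' @describeIn ClusterModel cluster labels, one per feature
#' @param x a ClusterModel
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn ClusterModel sentinel feature per cluster
#' @export
sentinels <- function(x) x@sentinels

#' @describeIn ClusterModel member feature ids of each cluster, as a list
#'   named by cluster index
#' @export
clusterMembers <- function(x) {
  split(x@featureIds, x@labels)
}

#' SweepResult: model-family x linkage-threshold selection grid
#'
#' One row per (classifier family, linkage threshold) cell with the number of
#' clusters and the mean cross-validated F1 of the best random-search
#' hyperparameters; \code{chosen} indexes the argmax row (ties broken toward
#' the lower threshold, then the family order supplied).
#'
#' @slot table data.frame with columns family, threshold, n_clusters,
#'   mean_cv_f1 and a list column best_params.
#' @slot chosen integer row index of the selected cell.
#' @slot clusterTree the \linkS4class{ClusterModel} (threshold set to the
#'   chosen one) built on training samples.
#' @slot sentinelSets list of sentinel vectors, one per threshold.
#' @export
setClass("SweepResult", slots = c(
  table = "data.frame",
  chosen = "integer",
  clusterTree = "ClusterModel",
  sentinelSets = "list"
))

setValidity("SweepResult", function(object) {
  msg <- NULL
  if (nrow(object@table) > 0) {
    if (length(object@chosen) != 1L ||
        object@chosen < 1L || object@chosen > nrow(object@table))
      msg <- c(msg, "chosen must index a row of table")
    else if (object@table$mean_cv_f1[object@chosen] <
             max(object@table$mean_cv_f1) - 1e-12)
      msg <- c(msg, "chosen row must attain the maximal mean CV F1")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SweepResult", function(object) {
  ch <- object@table[object@chosen, ]
  cat(sprintf("SweepResult: %d cells (%d families x %d thresholds)\n",
              nrow(object@table), length(unique(object@table$family)),
              length(unique(object@table$threshold))))
  cat(sprintf("  chosen: %s at linkage distance %.3g (%d clusters), mean CV F1 = %.3f\n",
              ch$family, ch$threshold, ch$n_clusters, ch$mean_cv_f1))
})

#' @describeIn SweepResult the full sweep grid as a data.frame
#' @param x a SweepResult
#' @export
sweepTable <- function(x) x@table

#' @describeIn SweepResult the selected (family, threshold) row
#' @export
chosenCell <- function(x) x@table[x@chosen, ]

#' TestReport: held-out classification metrics
#'
#' Minority-class-focused evaluation of the refitted chosen model on the 20\%
#' test partition.
#'
#' @slot accuracy,precision,recall,f1,prAuc numeric in [0, 1].
#' @slot positiveClass the label treated as positive (minority by default).
#' @export
setClass("TestReport", slots = c(
  accuracy = "numeric", precision = "numeric", recall = "numeric",
  f1 = "numeric", prAuc = "numeric", positiveClass = "character"
))

setValidity("TestReport", function(object) {
  vals <- c(object@accuracy, object@precision, object@recall,
            object@f1, object@prAuc)
  if (any(vals < -1e-12 | vals > 1 + 1e-12))
    "all metrics must lie in [0, 1]" else TRUE
})

setMethod("show", "TestReport", function(object) {
  cat(sprintf(paste0(
    "TestReport (positive class = %s)\n",
    "  accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | PR AUC %.3f\n"),
    object@positiveClass, object@accuracy, object@precision,
    object@recall, object@f1, object@prAuc))
})

#' @describeIn TestReport metrics as a named numeric vector
#' @param x a TestReport
#' @export
reportMetrics <- function(x) {
  c(accuracy = x@accuracy, precision = x@precision, recall = x@recall,
    f1 = x@f1, pr_auc = x@prAuc)
}
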