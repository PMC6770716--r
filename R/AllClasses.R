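#' @import methods
NULL

#' ExpressionDataset: samples-by-genes expression with optional class labels
#'
#' Container for a normalized expression matrix (samples in rows, genes in
#' columns), the gene identifiers and, when available, binary class labels
#' coded 1 / -1.
#'
#' @slot X numeric matrix, N samples by p genes; no missing values.
#' @slot geneNames character vector of length p, unique.
#' @slot y numeric vector of labels in \{1, -1\}; length 0 for
#'   prediction-only data.
#' @slot sampleIds character vector of length N.
#'
#' @exportClass ExpressionDataset
setClass("ExpressionDataset",
         representation(X = "matrix",
                        geneNames = "character",
                        y = "numeric",
                        sampleIds = "character"))

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!is.numeric(object@X))
    msg <- c(msg, "X must be a numeric matrix")
  if (anyNA(object@X) || any(!is.finite(object@X)))
    msg <- c(msg, "X contains missing or non-finite values")
  if (length(object@geneNames) != ncol(object@X))
    msg <- c(msg, "geneNames length must equal ncol(X)")
  if (anyDuplicated(object@geneNames))
    msg <- c(msg, "gene names must be unique")
  if (length(object@sampleIds) != nrow(object@X))
    msg <- c(msg, "sampleIds length must equal nrow(X)")
  if (length(object@y)) {
    if (length(object@y) != nrow(object@X))
      msg <- c(msg, "y length must equal nrow(X)")
    if (!all(object@y %in% c(-1, 1)))
      msg <- c(msg, "labels must be 1 or -1")
  }
  if (length(msg)) msg else TRUE
})

#' PathwayCollection: named gene sets, optionally mapped to expression columns
#'
#' @slot pathwayNames character vector of set identifiers (unique).
#' @slot members list of character vectors, member genes per set.
#' @slot indexMap list of integer vectors, column indices into the matched
#'   expression matrix; empty list until \code{\link{mapPathways}} is applied.
#'
#' @exportClass PathwayCollection
setClass("PathwayCollection",
         representation(pathwayNames = "character",
                        members = "list",
                        indexMap = "list"))

setValidity("PathwayCollection", function(object) {
  msg <- character()
  if (anyDuplicated(object@pathwayNames))
    msg <- c(msg, "pathway names must be unique")
  if (length(object@members) != length(object@pathwayNames))
    msg <- c(msg, "members must have one entry per pathway")
  if (length(object@indexMap) &&
      length(object@indexMap) != length(object@pathwayNames))
    msg <- c(msg, "indexMap, when present, must have one entry per pathway")
  if (length(msg)) msg else TRUE
})

#' KernelSpec: pathway kernel family with fixed bandwidth rule
#'
#' The bandwidth for pathway m is fixed at gamma_m = 1 / p_m (the inverse of
#' the number of genes in the pathway); it is not tuned.
#'
#' @slot family one of "rbf", "poly3", "linear".
#'
#' @exportClass KernelSpec
setClass("KernelSpec", representation(family = "character"))

setValidity("KernelSpec", function(object) {
  if (length(object@family) != 1L ||
      !object@family %in% c("rbf", "poly3", "linear"))
    "family must be one of 'rbf', 'poly3', 'linear'"
  else TRUE
})

#' PKBModel: a fitted pathway kernel boosting model
#'
#' Holds the constant initialization F0, the aggregated per-pathway kernel
#' coefficients (support points are the training samples), the accumulated
#' intercept, the iteration history and everything needed to score new
#' samples.
#'
#' @slot F0 numeric, optimal constant initialization log(n+/n-).
#' @slot nu learning rate in (0, 1].
#' @slot lambda penalty parameter used for base-learner fitting.
#' @slot penalty "L1" or "L2".
#' @slot wVariant curvature weight variant, "half" (q/2) or "squared" (q^2).
#' @slot kernel a \code{KernelSpec}.
#' @slot supportX training expression matrix (samples x genes).
#' @slot geneNames training gene identifiers.
#' @slot pathways mapped \code{PathwayCollection} used in fitting.
#' @slot betaAgg N x M matrix of aggregated (nu * d-scaled) coefficients,
#'   one column per pathway.
#' @slot cAgg accumulated intercept (same nu * d scaling).
#' @slot history data.frame with one row per boosting iteration: selected
#'   pathway, step length, intercept, regularized objective, training loss.
#' @slot trainLoss numeric vector, empirical log loss after each iteration
#'   (element 1 is the loss at F0).
#' @slot earlyStopped logical, TRUE if L1 fitting hit an all-zero solution
#'   before the iteration cap.
#'
#' @exportClass PKBModel
setClass("PKBModel",
         representation(F0 = "numeric",
                        nu = "numeric",
                        lambda = "numeric",
                        penalty = "character",
                        wVariant = "character",
                        kernel = "KernelSpec",
                        supportX = "matrix",
                        geneNames = "character",
                        pathways = "PathwayCollection",
                        betaAgg = "matrix",
                        cAgg = "numeric",
                        history = "data.frame",
                        trainLoss = "numeric",
                        earlyStopped = "logical"))

#' PKBCVResult: outer cross-validation result
#'
#' @slot folds list with one entry per outer fold (test indices, chosen
#'   lambda, chosen stopping iteration, test error, pathway weights,
#'   validation-loss curve).
#' @slot meanError mean held-out misclassification fraction.
#' @slot meanWeights per-pathway weights averaged across folds.
#' @slot config list echoing the configuration (kernel, penalty, nu, Tmax,
#'   folds, seed, lambda policy).
#'
#' @exportClass PKBCVResult
setClass("PKBCVResult",
         representation(folds = "list",
                        meanError = "numeric",
                        meanWeights = "numeric",
                        config = "list"))
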