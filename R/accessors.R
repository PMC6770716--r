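#' Construct an ExpressionDataset
#'
#' @param X numeric matrix, samples in rows, genes in columns.
#' @param geneNames gene identifiers; defaults to \code{colnames(X)}.
#' @param y optional labels in \{1, -1\} (or \{0, 1\}, remapped with a notice).
#' @param sampleIds sample identifiers; defaults to \code{rownames(X)}.
#' @return An \code{ExpressionDataset}.
#' @export
ExpressionDataset <- function(X, geneNames = colnames(X), y = numeric(0),
                              sampleIds = rownames(X)) {
  X <- as.matrix(X)
  if (is.null(geneNames)) geneNames <- paste0("g", seq_len(ncol(X)))
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(nrow(X)))
  if (length(y)) y <- remapLabels(y)
  dimnames(X) <- list(sampleIds, geneNames)
  new("ExpressionDataset", X = X, geneNames = as.character(geneNames),
      y = as.numeric(y), sampleIds = as.character(sampleIds))
}

remapLabels <- function(y) {
  y <- as.numeric(y)
  if (all(y %in% c(0, 1)) && any(y == 0)) {
    message("labels coded {0,1}; remapping 0 -> -1")
    y[y == 0] <- -1
  }
  y
}

#' Construct a PathwayCollection
#'
#' @param pathwayNames set identifiers.
#' @param members list of character vectors of member genes (duplicates
#'   within a set are removed).
#' @param indexMap optional list of column indices into an expression matrix.
#' @return A \code{PathwayCollection}.
#' @export
PathwayCollection <- function(pathwayNames, members, indexMap = list()) {
  members <- lapply(members, function(g) unique(as.character(g)))
  names(members) <- pathwayNames
  if (length(indexMap)) names(indexMap) <- pathwayNames
  new("PathwayCollection", pathwayNames = as.character(pathwayNames),
      members = members, indexMap = indexMap)
}

#' Construct a KernelSpec
#'
#' @param family kernel family: "rbf" (Gaussian, exp(-gamma ||a-b||^2)),
#'   "poly3" (inhomogeneous cubic, (gamma a'b + 1)^3) or "linear" (a'b).
#'   The bandwidth gamma is fixed per pathway at 1/p_m.
#' @return A \code{KernelSpec}.
#' @export
kernelSpec <- function(family = c("rbf", "poly3", "linear")) {
  new("KernelSpec", family = match.arg(family))
}

#' @rdname ExpressionDataset
#' @param object,x an object.
#' @export
setGeneric("exprMatrix", function(object) standardGeneric("exprMatrix"))

#' @rdname ExpressionDataset
#' @export
setMethod("exprMatrix", "ExpressionDataset", function(object) object@X)

#' @rdname ExpressionDataset
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))

#' @rdname ExpressionDataset
#' @export
setMethod("sampleLabels", "ExpressionDataset", function(object) object@y)

#' @rdname ExpressionDataset
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))

#' @rdname ExpressionDataset
#' @export
setMethod("geneNames", "ExpressionDataset", function(object) object@geneNames)

#' @rdname ExpressionDataset
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname ExpressionDataset
#' @export
setMethod("sampleIds", "ExpressionDataset", function(object) object@sampleIds)

#' @rdname PathwayCollection
#' @param object a \code{PathwayCollection}.
#' @export
setGeneric("pathwayNames", function(object) standardGeneric("pathwayNames"))

#' @rdname PathwayCollection
#' @export
setMethod("pathwayNames", "PathwayCollection",
          function(object) object@pathwayNames)

#' @rdname PathwayCollection
#' @export
setGeneric("pathwayMembers", function(object) standardGeneric("pathwayMembers"))

#' @rdname PathwayCollection
#' @export
setMethod("pathwayMembers", "PathwayCollection", function(object) object@members)

#' @rdname PathwayCollection
#' @export
setGeneric("pathwayIndexMap", function(object) standardGeneric("pathwayIndexMap"))

#' @rdname PathwayCollection
#' @export
setMethod("pathwayIndexMap", "PathwayCollection",
          function(object) object@indexMap)

#' Pathway sizes (mapped sizes when an index map is present)
#' @rdname PathwayCollection
#' @export
setGeneric("pathwaySizes", function(object) standardGeneric("pathwaySizes"))

#' @rdname PathwayCollection
#' @export
setMethod("pathwaySizes", "PathwayCollection", function(object) {
  if (length(object@indexMap))
    vapply(object@indexMap, length, 1L)
  else
    vapply(object@members, length, 1L)
})

setMethod("length", "PathwayCollection", function(x) length(x@pathwayNames))

setMethod("show", "ExpressionDataset", function(object) {
  cat("ExpressionDataset:", nrow(object@X), "samples x", ncol(object@X),
      "genes\n")
  if (length(object@y))
    cat("  labels: ", sum(object@y == 1), " positive / ",
        sum(object@y == -1), " negative\n", sep = "")
  else cat("  labels: none (prediction-only)\n")
})

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection:", length(object@pathwayNames), "gene sets",
      if (length(object@indexMap)) "(mapped)" else "(unmapped)", "\n")
  sz <- pathwaySizes(object)
  if (length(sz))
    cat("  sizes: min", min(sz), "median", stats::median(sz), "max", max(sz),
        "\n")
})

setMethod("show", "KernelSpec", function(object) {
  cat("KernelSpec:", object@family, "kernel, gamma_m = 1/p_m\n")
})

setMethod("show", "PKBModel", function(object) {
  cat("PKBModel (", object@penalty, " penalty, ", object@kernel@family,
      " kernel)\n", sep = "")
  cat("  iterations:", nrow(object@history),
      if (object@earlyStopped) "(early-stopped)" else "", "\n")
  cat("  lambda:", format(object@lambda), " nu:", object@nu, "\n")
  w <- pathwayWeights(object)
  cat("  pathways selected:", sum(w > 0), "of", length(w), "\n")
  if (any(w > 0)) {
    top <- sort(w, decreasing = TRUE)
    top <- top[seq_len(min(5, sum(top > 0)))]
    cat("  top weights:",
        paste(names(top), round(top, 4), collapse = ", "), "\n")
  }
})

setMethod("show", "PKBCVResult", function(object) {
  cat("PKBCVResult:", length(object@folds), "outer folds\n")
  cat("  mean test error:", round(object@meanError, 4), "\n")
  ts <- vapply(object@folds, function(f) f$Tstar, 1)
  cat("  T*: ", paste(ts, collapse = ", "), "; lambda: ",
      paste(signif(vapply(object@folds, function(f) f$lambda, 1), 3),
            collapse = ", "), "\n", sep = "")
})
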