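#' Pathway-restricted kernel matrix between two sample sets
#'
#' Computes K(A, B) using only one pathway's gene columns, with the fixed
#' bandwidth gamma = 1/p_m:
#' \itemize{
#'   \item rbf: \code{exp(-gamma * ||a - b||^2)}
#'   \item poly3: \code{(gamma * a'b + 1)^3}
#'   \item linear: \code{a'b}
#' }
#' When \code{B} is omitted the self-kernel K(A, A) is returned (symmetric,
#' positive semi-definite; rbf diagonal exactly 1).
#'
#' @param A n1 x p_m matrix (rows are samples, columns the pathway's genes).
#' @param B n2 x p_m matrix on the same columns; defaults to \code{A}.
#' @param spec a \code{\link{kernelSpec}}.
#' @param pm pathway size used in the bandwidth; defaults to \code{ncol(A)}.
#' @return n1 x n2 kernel matrix.
#' @export
pathwayKernel <- function(A, B = NULL, spec = kernelSpec("rbf"),
                          pm = ncol(A)) {
  A <- as.matrix(A)
  self <- is.null(B)
  B <- if (self) A else as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("column-count mismatch: A has ", ncol(A), ", B has ", ncol(B))
  stopifnot(pm >= 1)
  gamma <- 1 / pm
  switch(spec@family,
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
      d2[d2 < 0] <- 0
      if (self) diag(d2) <- 0
      exp(-gamma * d2)
    },
    poly3 = (gamma * tcrossprod(A, B) + 1)^3,
    linear = tcrossprod(A, B)
  )
}

# Kernel matrices for every pathway of a mapped collection; cached list,
# read-only after construction. With Xnew, returns cross-kernels
# K_m(Xnew, X) of dimension nrow(Xnew) x nrow(X).
pathwayKernelList <- function(X, coll, spec, Xnew = NULL) {
  idx <- pathwayIndexMap(coll)
  if (!length(idx)) stop("PathwayCollection must be mapped (see mapPathways)")
  lapply(idx, function(ix) {
    if (is.null(Xnew))
      pathwayKernel(X[, ix, drop = FALSE], NULL, spec, pm = length(ix))
    else
      pathwayKernel(Xnew[, ix, drop = FALSE], X[, ix, drop = FALSE], spec,
                    pm = length(ix))
  })
}
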