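#' @useDynLib pkboost, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Empirical log loss
#'
#' \code{L(y, F) = mean(log(1 + exp(-y * F)))}, computed overflow-safely.
#'
#' @param y labels in \{1, -1\}.
#' @param F fitted log-odds values.
#' @return scalar loss.
#' @export
logLoss <- function(y, F) cpp_logloss(as.numeric(y), as.numeric(F))

#' Optimal constant initialization
#'
#' The constant r minimizing the mean log loss is the logistic MLE intercept
#' \code{log(n+ / n-)}.
#'
#' @param y labels in \{1, -1\}, both classes present.
#' @return scalar F0.
#' @export
initF0 <- function(y) {
  npos <- sum(y == 1)
  nneg <- sum(y == -1)
  if (npos + nneg != length(y)) stop("labels must be 1 or -1")
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to initialize")
  log(npos / nneg)
}

#' First and second derivatives of the log loss
#'
#' \code{h_i = -y_i / (1 + exp(y_i F_i))},
#' \code{q_i = exp(y_i F_i) / (1 + exp(y_i F_i))^2}; overflow-safe for
#' \code{|F|} up to 1e4 and beyond.
#'
#' @param y labels in \{1, -1\}.
#' @param F fitted values (finite).
#' @return list with vectors \code{h} and \code{q}.
#' @export
lossDerivatives <- function(y, F) {
  stopifnot(all(is.finite(F)))
  drv <- cpp_derivatives(as.numeric(y), as.numeric(F))
  list(h = as.numeric(drv$h), q = as.numeric(drv$q))
}

# Curvature weight vector for a given variant: "half" = q/2 (consistent with
# the quadratic expansion), "squared" = q^2 (the printed alternative, kept
# switchable for audit).
curvatureWeights <- function(q, wVariant = c("half", "squared")) {
  wVariant <- match.arg(wVariant)
  q <- pmax(q, 1e-8)
  if (wVariant == "half") q / 2 else q^2
}

#' Weighted centering transform to an intercept-free problem
#'
#' Applies the projection \code{P = I - 1 w' / tr(W)} followed by the
#' \code{W^{1/2}} scaling, turning the weighted least-squares problem with a
#' free intercept into an intercept-free LASSO/ridge problem:
#' \code{etaTilde = W^{1/2} P eta}, \code{Ktilde = W^{1/2} P K}.
#'
#' @param eta working response vector (h/q).
#' @param w diagonal of the curvature weight matrix W (all > 0).
#' @param K N x N kernel matrix.
#' @return list with \code{etaTilde} and \code{Ktilde}.
#' @export
centeringTransform <- function(eta, w, K) {
  if (any(w <= 0)) stop("curvature weights must be strictly positive")
  tau <- sum(w)
  if (tau <= 0) stop("degenerate curvature: tr(W) = 0")
  s <- sqrt(w)
  etaTilde <- s * (eta - sum(w * eta) / tau)
  Ktilde <- s * (K - matrix(colSums(w * K) / tau, nrow(K), ncol(K),
                            byrow = TRUE))
  list(etaTilde = etaTilde, Ktilde = Ktilde)
}

#' Ridge base-learner fit (closed form)
#'
#' Minimizes \code{(1/N) ||etaTilde + Ktilde beta||^2 + lambda ||beta||^2}
#' via the closed form \code{beta = -(K'K + N lambda I)^{-1} K' etaTilde},
#' computed through a symmetric linear solve (never an explicit inverse).
#'
#' @param Ktilde transformed kernel matrix.
#' @param etaTilde transformed working response.
#' @param lambda penalty parameter > 0.
#' @param N sample-size normalizer; defaults to \code{nrow(Ktilde)}.
#' @return coefficient vector beta.
#' @export
fitL2 <- function(Ktilde, etaTilde, lambda, N = nrow(Ktilde)) {
  stopifnot(lambda > 0)
  if (!all(is.finite(Ktilde)) || !all(is.finite(etaTilde)))
    stop("non-finite entries in ridge system")
  A <- crossprod(Ktilde)
  diag(A) <- diag(A) + N * lambda
  drop(solve(A, -crossprod(Ktilde, etaTilde)))
}

#' LASSO base-learner fit
#'
#' Minimizes \code{(1/N) ||etaTilde + Ktilde beta||^2 + lambda ||beta||_1}
#' (a LASSO without intercept, no standardization, response
#' \code{-etaTilde}) by cyclic coordinate descent. For
#' \code{lambda >= lambdaMax = (2/N) ||Ktilde' etaTilde||_inf} the exact
#' zero solution is returned.
#'
#' @inheritParams fitL2
#' @param tol coordinate-update convergence tolerance.
#' @param maxit maximum coordinate-descent sweeps.
#' @return coefficient vector beta.
#' @export
fitL1 <- function(Ktilde, etaTilde, lambda, N = nrow(Ktilde), tol = 1e-6,
                  maxit = 100000L) {
  stopifnot(lambda > 0)
  if (!all(is.finite(Ktilde)) || !all(is.finite(etaTilde)))
    stop("non-finite entries in LASSO system")
  # rescale lambda when the caller's N differs from the system's row count
  drop(cpp_lasso_cd(Ktilde, -etaTilde, lambda * N / nrow(Ktilde), tol, maxit))
}

#' Recover the profiled-out intercept
#'
#' Given beta, the intercept minimizing the weighted quadratic objective is
#' \code{c = -[1' W (eta + K beta)] / tr(W)}.
#'
#' @param beta coefficient vector.
#' @param eta working response.
#' @param w diagonal curvature weights.
#' @param K kernel matrix.
#' @return scalar intercept.
#' @export
recoverIntercept <- function(beta, eta, w, K) {
  tau <- sum(w)
  if (tau <= 0) stop("degenerate curvature: tr(W) = 0")
  -sum(w * (eta + drop(K %*% beta))) / tau
}

#' Select the best base learner across pathways
#'
#' Fits every pathway's penalized base learner at the current boosting state
#' and returns the pathway minimizing the regularized (transformed)
#' objective; ties are broken by the lowest pathway index.
#'
#' @param y labels.
#' @param F current fitted values.
#' @param kernels list of per-pathway N x N kernel matrices.
#' @param penalty "L1" or "L2".
#' @param lambda penalty parameter.
#' @param wVariant curvature weight variant ("half" or "squared").
#' @return list: \code{selected} (pathway index), \code{beta},
#'   \code{intercept}, \code{fhat} (learner evaluated at the samples),
#'   \code{objectives} (all pathways' minimized objectives).
#' @export
selectBaseLearner <- function(y, F, kernels, penalty = c("L1", "L2"),
                              lambda, wVariant = c("half", "squared")) {
  penalty <- match.arg(penalty)
  wVariant <- match.arg(wVariant)
  if (!length(kernels)) stop("at least one pathway is required")
  drv <- lossDerivatives(y, F)
  K2 <- if (penalty == "L2") lapply(kernels, function(K) crossprod(K)) else list()
  cpp_eval_pathways(kernels, K2, drv$h, drv$q, lambda,
                    if (penalty == "L1") 1L else 2L,
                    if (wVariant == "half") 0L else 1L)
}

#' Exact line search for the step length
#'
#' Minimizes the exact empirical log loss \code{L(y, F + d * fhat)} over
#' \code{d} in \code{[0, dmax]} (1-D convex problem, golden-section search).
#' \code{d = 0} is always feasible, so the loss never increases.
#'
#' @param y labels.
#' @param F current fitted values.
#' @param fhat base-learner values at the samples.
#' @param dmax step cap (default 100, prevents divergence on separable data).
#' @return optimal step length.
#' @export
lineSearch <- function(y, F, fhat, dmax = 100) {
  if (all(fhat == 0)) stop("fhat must not be identically zero")
  cpp_line_search(as.numeric(y), as.numeric(F), as.numeric(fhat), dmax, 1e-9)
}

#' Fit a pathway kernel boosting model
#'
#' Runs the boosting algorithm: constant initialization
#' \code{F0 = log(n+/n-)}; then for T iterations: compute derivatives,
#' fit every pathway's penalized kernel base learner on the second-order
#' approximation, select the pathway with the lowest regularized objective,
#' find the exact-loss step length, and update
#' \code{F <- F + nu * d * fhat}. Coefficients are aggregated per pathway
#' (scaled by \code{nu * d}) for prediction and importance weights.
#'
#' @param ds an \code{ExpressionDataset} with labels (both classes present).
#' @param coll a mapped \code{PathwayCollection}.
#' @param spec a \code{KernelSpec}.
#' @param penalty "L1" or "L2".
#' @param lambda penalty parameter; \code{"auto"} uses
#'   \code{\link{autoLambda}}.
#' @param nu learning rate in (0, 1].
#' @param T number of boosting iterations (T = 0 returns the constant model).
#' @param wVariant curvature weight variant.
#' @param dmax line-search cap.
#' @param valData optional list(ds =, ...) \code{ExpressionDataset} whose
#'   per-iteration loss is monitored (used by nested CV).
#' @return A \code{\link{PKBModel}}.
#' @export
pkbFit <- function(ds, coll, spec = kernelSpec("rbf"),
                   penalty = c("L1", "L2"), lambda = "auto", nu = 0.05,
                   T = 500L, wVariant = c("half", "squared"), dmax = 100,
                   valData = NULL) {
  penalty <- match.arg(penalty)
  wVariant <- match.arg(wVariant)
  stopifnot(nu > 0, nu <= 1, T >= 0)
  y <- sampleLabels(ds)
  if (!length(y)) stop("training data must carry labels")
  if (length(unique(y)) < 2L || length(y) < 2L)
    stop("training data must contain both classes and N >= 2")
  X <- exprMatrix(ds)
  kernels <- pathwayKernelList(X, coll, spec)
  if (identical(lambda, "auto"))
    lambda <- autoLambda(ds, coll, spec, penalty, kernels = kernels,
                         wVariant = wVariant)
  stopifnot(is.numeric(lambda), lambda > 0)
  fitted <- pkbBoostRun(kernels, y, lambda, nu, T, penalty, wVariant, dmax,
                        valKernels = if (!is.null(valData))
                          pathwayKernelList(X, coll, spec,
                                            exprMatrix(valData)),
                        yval = if (!is.null(valData)) sampleLabels(valData))
  mdl <- new("PKBModel", F0 = initF0(y), nu = nu, lambda = lambda,
             penalty = penalty, wVariant = wVariant, kernel = spec,
             supportX = X, geneNames = geneNames(ds), pathways = coll,
             betaAgg = fitted$betaAgg, cAgg = fitted$cAgg,
             history = fitted$history, trainLoss = fitted$trainLoss,
             earlyStopped = fitted$earlyStopped)
  attr(mdl, "valLoss") <- fitted$valLoss
  mdl
}

# Shared driver around the C++ loop (kernels precomputed by the caller;
# K2 may be passed to reuse cached kernel squares across lambda values).
pkbBoostRun <- function(kernels, y, lambda, nu, T, penalty, wVariant, dmax,
                        valKernels = NULL, yval = NULL, K2 = NULL,
                        patience = -1L) {
  if (is.null(K2))
    K2 <- if (penalty == "L2") lapply(kernels, function(K) crossprod(K))
          else list()
  monitor <- !is.null(valKernels)
  res <- cpp_boost(kernels, K2, as.numeric(y), initF0(y), lambda, nu,
                   as.integer(T), if (penalty == "L1") 1L else 2L,
                   if (wVariant == "half") 0L else 1L,
                   if (monitor) valKernels else list(),
                   if (monitor) as.numeric(yval) else numeric(0),
                   monitor, dmax, patience = as.integer(patience))
  Tused <- length(res$selected)
  history <- data.frame(iteration = seq_len(Tused),
                        pathway = as.integer(res$selected),
                        d = as.numeric(res$d),
                        intercept = as.numeric(res$intercept),
                        objective = as.numeric(res$objective),
                        trainLoss = as.numeric(res$trainLoss)[-1])
  betaAgg <- res$betaAgg
  colnames(betaAgg) <- names(kernels)
  list(betaAgg = betaAgg, cAgg = res$cAgg, history = history,
       trainLoss = as.numeric(res$trainLoss),
       valLoss = if (monitor) as.numeric(res$valLoss),
       valErr = if (monitor) as.numeric(res$valErr),
       earlyStopped = res$earlyStopped, F = as.numeric(res$F))
}

#' Predict from a fitted model
#'
#' Scores are \code{F_T(x) = F0 + sum_m K_m(x, support) beta^(m) + C};
#' labels are \code{sign(score)} with a score of exactly 0 mapped to +1.
#'
#' @param object a \code{PKBModel}.
#' @param newdata an \code{ExpressionDataset} or samples x genes matrix
#'   containing all training genes (matched by name).
#' @return data.frame with \code{score} and \code{label}.
#' @export
setMethod("predict", "PKBModel", function(object, newdata) {
  Xnew <- if (is(newdata, "ExpressionDataset")) exprMatrix(newdata)
          else as.matrix(newdata)
  miss <- setdiff(object@geneNames, colnames(Xnew))
  if (length(miss))
    stop("newdata is missing training genes: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) ", ..." else "")
  Xnew <- Xnew[, object@geneNames, drop = FALSE]
  scores <- rep(object@F0 + object@cAgg, nrow(Xnew))
  active <- which(colSums(object@betaAgg != 0) > 0)
  if (length(active)) {
    idx <- pathwayIndexMap(object@pathways)
    for (m in active) {
      Kc <- pathwayKernel(Xnew[, idx[[m]], drop = FALSE],
                          object@supportX[, idx[[m]], drop = FALSE],
                          object@kernel, pm = length(idx[[m]]))
      scores <- scores + drop(Kc %*% object@betaAgg[, m])
    }
  }
  labels <- ifelse(scores >= 0, 1, -1)
  data.frame(score = scores, label = labels,
             row.names = rownames(Xnew) %||% NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pathway importance weights
#'
#' The Euclidean norm \code{||beta^(m)||_2} of each pathway's aggregated
#' kernel coefficients; zero exactly for pathways never selected.
#'
#' @param model a fitted \code{PKBModel}.
#' @return named nonnegative numeric vector.
#' @export
pathwayWeights <- function(model) {
  w <- sqrt(colSums(model@betaAgg^2))
  names(w) <- pathwayNames(model@pathways)
  w
}
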