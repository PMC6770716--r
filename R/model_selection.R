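#' Automatic penalty-parameter anchor
#'
#' At the initial state (F = F0), computes each pathway's
#' \code{lambdaMax^(m) = (2/N) ||Ktilde_m' etaTilde||_inf} — the smallest L1
#' penalty giving an all-zero solution — and returns
#' \code{lambda0 = median_m(lambdaMax^(m)) / 5}, which guarantees a
#' non-trivial first step for at least half the pathways. The same anchor is
#' used as the scale for the L2 penalty. This is a heuristic anchor, not a
#' tuned value; combine with \code{\link{lambdaGrid}}.
#'
#' @param ds labelled \code{ExpressionDataset}.
#' @param coll mapped \code{PathwayCollection}.
#' @param spec \code{KernelSpec}.
#' @param penalty "L1" or "L2" (same anchor for both).
#' @param kernels optional precomputed kernel list.
#' @param wVariant curvature weight variant.
#' @return scalar lambda0 > 0.
#' @export
autoLambda <- function(ds, coll, spec = kernelSpec("rbf"),
                       penalty = c("L1", "L2"), kernels = NULL,
                       wVariant = c("half", "squared")) {
  penalty <- match.arg(penalty)
  wVariant <- match.arg(wVariant)
  y <- sampleLabels(ds)
  if (length(unique(y)) < 2L) stop("both classes required")
  if (is.null(kernels))
    kernels <- pathwayKernelList(exprMatrix(ds), coll, spec)
  lmax <- lambdaMaxPerPathway(kernels, y, wVariant)
  if (all(lmax < 1e-12))
    stop("degenerate kernels: all pathways give zero gradient at F0")
  lambda0 <- stats::median(lmax) / 5
  if (lambda0 <= 0) stop("non-positive lambda anchor")
  lambda0
}

# (2/N) ||Ktilde' etaTilde||_inf per pathway at the F0 state.
lambdaMaxPerPathway <- function(kernels, y, wVariant = "half") {
  N <- length(y)
  F <- rep(initF0(y), N)
  drv <- lossDerivatives(y, F)
  w <- curvatureWeights(drv$q, wVariant)
  eta <- drv$h / pmax(drv$q, 1e-8)
  vapply(kernels, function(K) {
    tr <- centeringTransform(eta, w, K)
    (2 / N) * max(abs(crossprod(tr$Ktilde, tr$etaTilde)))
  }, 1.0)
}

#' Geometric penalty grid around an anchor
#'
#' @param lambda0 anchor value > 0.
#' @return ascending grid \code{lambda0 * c(1/25, 1/5, 1, 5, 25)}.
#' @export
lambdaGrid <- function(lambda0) {
  stopifnot(lambda0 > 0)
  lambda0 * c(1 / 25, 1 / 5, 1, 5, 25)
}

#' Stratified cross-validation plan
#'
#' Partitions samples into k folds, stratified by class so that every
#' training portion contains both classes; reproducible from the seed.
#'
#' @param y label vector in \{1, -1\}.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of disjoint, exhaustive test-index vectors.
#' @export
cvPlan <- function(y, k = 3L, seed = 1L) {
  set.seed(seed)
  folds <- vector("list", k)
  for (cls in c(1, -1)) {
    idx <- sample(which(y == cls))
    grp <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[grp == f])
  }
  lapply(folds, sort)
}

subsetDataset <- function(ds, idx) {
  ExpressionDataset(exprMatrix(ds)[idx, , drop = FALSE], geneNames(ds),
                    sampleLabels(ds)[idx], sampleIds(ds)[idx])
}

#' Select the stopping iteration by inner cross-validation
#'
#' For each inner fold, trains on the remaining folds for \code{Tmax}
#' iterations while recording the held-out log loss at every iteration;
#' \code{Tstar} minimizes the across-fold mean validation-loss curve (ties:
#' the smallest T). If a run stops early, its curve is padded with its last
#' value (the model no longer changes).
#'
#' @param dsTrain labelled training \code{ExpressionDataset}.
#' @param coll mapped \code{PathwayCollection}.
#' @param spec \code{KernelSpec}.
#' @param penalty "L1" or "L2".
#' @param lambda numeric penalty value.
#' @param nu learning rate.
#' @param Tmax iteration cap (>= 1).
#' @param innerFolds list of inner test-index partitions (from
#'   \code{\link{cvPlan}} on the training labels).
#' @param wVariant curvature weight variant.
#' @param context optional precomputed per-fold kernel caches (shared across
#'   a lambda grid).
#' @param patience stop a monitored run once the held-out loss has not
#'   improved for this many iterations (-1 disables); the curve is padded
#'   with its last value, so \code{Tstar} is unaffected in practice.
#' @return list: \code{Tstar}, \code{meanCurve} (length Tmax),
#'   \code{perFold} (k x Tmax matrix), \code{minLoss}.
#' @export
selectT <- function(dsTrain, coll, spec, penalty, lambda, nu, Tmax,
                    innerFolds, wVariant = "half", context = NULL,
                    patience = 15L) {
  stopifnot(Tmax >= 1)
  if (is.null(context))
    context <- innerKernelContext(dsTrain, coll, spec, innerFolds, penalty)
  perFold <- matrix(NA_real_, length(innerFolds), Tmax)
  perFoldErr <- matrix(NA_real_, length(innerFolds), Tmax)
  for (f in seq_along(innerFolds)) {
    ctx <- context[[f]]
    run <- pkbBoostRun(ctx$kernels, ctx$ytr, lambda, nu, Tmax, penalty,
                       wVariant, dmax = 100, valKernels = ctx$valKernels,
                       yval = ctx$yval, K2 = ctx$K2, patience = patience)
    pad <- function(curve, fallback) {
      if (!length(curve)) curve <- fallback
      if (length(curve) < Tmax)
        curve <- c(curve, rep(curve[length(curve)], Tmax - length(curve)))
      curve
    }
    F0v <- rep(initF0(ctx$ytr), length(ctx$yval))
    perFold[f, ] <- pad(run$valLoss, logLoss(ctx$yval, F0v))
    perFoldErr[f, ] <- pad(run$valErr,
                           mean(ifelse(F0v >= 0, 1, -1) != ctx$yval))
  }
  meanCurve <- colMeans(perFold)
  meanErrCurve <- colMeans(perFoldErr)
  Tstar <- which.min(meanCurve)
  list(Tstar = Tstar, meanCurve = meanCurve, perFold = perFold,
       minLoss = meanCurve[Tstar], errCurve = meanErrCurve,
       errAtTstar = meanErrCurve[Tstar])
}

# Per-inner-fold kernel caches (training kernels, their squares for L2, and
# validation cross-kernels), shared across a lambda grid.
innerKernelContext <- function(dsTrain, coll, spec, innerFolds, penalty) {
  X <- exprMatrix(dsTrain)
  y <- sampleLabels(dsTrain)
  lapply(innerFolds, function(val) {
    tr <- setdiff(seq_len(nrow(X)), val)
    kernels <- pathwayKernelList(X[tr, , drop = FALSE], coll, spec)
    list(kernels = kernels,
         K2 = if (penalty == "L2") lapply(kernels, function(K) crossprod(K)),
         valKernels = pathwayKernelList(X[tr, , drop = FALSE], coll, spec,
                                        X[val, , drop = FALSE]),
         ytr = y[tr], yval = y[val])
  })
}

#' Outer cross-validation with nested stopping-iteration selection
#'
#' For each outer fold: (optionally) pick the penalty parameter on the
#' training portion by running the \code{\link{lambdaGrid}} through inner
#' cross-validation and keeping the grid value with the lowest mean
#' validation loss at its own \code{Tstar}; refit on the full training
#' portion for \code{Tstar} iterations; record the held-out
#' misclassification fraction and the pathway weights.
#'
#' @param ds labelled \code{ExpressionDataset}.
#' @param coll mapped \code{PathwayCollection}.
#' @param spec \code{KernelSpec}.
#' @param penalty "L1" or "L2".
#' @param lambda \code{"auto"} (anchor + grid + inner-CV choice) or a fixed
#'   numeric value (grid skipped).
#' @param nu learning rate.
#' @param Tmax iteration cap for nested selection.
#' @param k number of outer (and inner) folds.
#' @param seed integer seed controlling all fold assignments.
#' @param wVariant curvature weight variant.
#' @param patience early-stop patience for the monitored inner-CV runs (see
#'   \code{\link{selectT}}).
#' @return A \code{\link{PKBCVResult}}.
#' @export
pkbCV <- function(ds, coll, spec = kernelSpec("rbf"), penalty = c("L1", "L2"),
                  lambda = "auto", nu = 0.05, Tmax = 500L, k = 3L, seed = 1L,
                  wVariant = "half", patience = 15L) {
  penalty <- match.arg(penalty)
  y <- sampleLabels(ds)
  if (!length(y)) stop("labelled data required")
  outer <- cvPlan(y, k, seed)
  foldRes <- vector("list", k)
  M <- length(coll)
  for (f in seq_len(k)) {
    test <- outer[[f]]
    train <- setdiff(seq_along(y), test)
    dsTr <- subsetDataset(ds, train)
    inner <- cvPlan(sampleLabels(dsTr), k, seed + 1000L * f)
    if (identical(lambda, "auto")) {
      lam0 <- autoLambda(dsTr, coll, spec, penalty, wVariant = wVariant)
      grid <- lambdaGrid(lam0)
    } else {
      grid <- as.numeric(lambda)
    }
    ctx <- innerKernelContext(dsTr, coll, spec, inner, penalty)
    sel <- lapply(grid, function(lam)
      selectT(dsTr, coll, spec, penalty, lam, nu, Tmax, inner, wVariant,
              context = ctx, patience = patience))
    # grid value with the lowest inner-CV misclassification at its own
    # Tstar; ties broken by the lower mean validation loss
    best <- order(vapply(sel, function(s) s$errAtTstar, 1.0),
                  vapply(sel, function(s) s$minLoss, 1.0))[1]
    lamStar <- grid[best]
    Tstar <- sel[[best]]$Tstar
    mdl <- pkbFit(dsTr, coll, spec, penalty, lamStar, nu, Tstar, wVariant)
    pred <- predict(mdl, subsetDataset(ds, test))
    err <- mean(pred$label != y[test])
    foldRes[[f]] <- list(testIdx = test, lambda = lamStar, Tstar = Tstar,
                         error = err, weights = pathwayWeights(mdl),
                         meanCurve = sel[[best]]$meanCurve,
                         predictions = data.frame(sample = sampleIds(ds)[test],
                                                  score = pred$score,
                                                  label = pred$label,
                                                  truth = y[test]))
  }
  meanW <- Reduce(`+`, lapply(foldRes, `[[`, "weights")) / k
  new("PKBCVResult", folds = foldRes,
      meanError = mean(vapply(foldRes, `[[`, 1.0, "error")),
      meanWeights = meanW,
      config = list(kernel = spec@family, penalty = penalty,
                    lambdaPolicy = if (identical(lambda, "auto")) "auto"
                                   else "fixed",
                    nu = nu, Tmax = Tmax, folds = k, seed = seed,
                    wVariant = wVariant, pathways = M,
                    lambdaNote = paste("auto anchor = median per-pathway",
                                       "lambdaMax / 5 at F0; heuristic",
                                       "substitute, see autoLambda()")))
}
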