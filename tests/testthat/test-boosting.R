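test_that("initF0 is the closed-form log-odds constant and matches a 1-D search", {
  expect_identical(initF0(rep(c(1, -1), 10)), 0)
  expect_equal(initF0(c(rep(1, 20), rep(-1, 10))), log(2))
  # golden-section / Brent oracle on the mean log loss
  set.seed(1)
  for (npos in c(3, 7, 15)) {
    y <- c(rep(1, npos), rep(-1, 20 - npos))
    opt <- optimize(function(r) logLoss(y, rep(r, 20)), c(-10, 10),
                    tol = 1e-10)
    expect_equal(initF0(y), opt$minimum, tolerance = 1e-6)
    expect_lte(logLoss(y, rep(initF0(y), 20)), opt$objective + 1e-8)
  }
  expect_error(initF0(rep(1, 5)), "both classes")
})

test_that("loss derivatives match the logistic formulas and finite differences", {
  expect_equal(lossDerivatives(1, 0), list(h = -0.5, q = 0.25))
  expect_equal(lossDerivatives(-1, 0), list(h = 0.5, q = 0.25))
  set.seed(2)
  n <- 1000
  y <- sample(c(1, -1), n, replace = TRUE)
  F <- rnorm(n, sd = 3)
  drv <- lossDerivatives(y, F)
  # per-sample central differences (the loss separates over samples);
  # a larger step for the second derivative keeps roundoff below 1e-6
  l <- function(yy, ff) log1p(exp(-yy * ff))
  h_fd <- (l(y, F + 1e-5) - l(y, F - 1e-5)) / (2e-5)
  q_fd <- (l(y, F + 1e-4) - 2 * l(y, F) + l(y, F - 1e-4)) / 1e-8
  expect_lt(max(abs(drv$h - h_fd)), 1e-6)
  expect_lt(max(abs(drv$q - q_fd)), 1e-6)
  # curvature bounds and sign structure
  expect_true(all(drv$q > 0 & drv$q <= 0.25))
  expect_true(all(abs(drv$h) < 1))
  expect_identical(sign(drv$h), -y)
  # overflow safety far in the tails
  big <- lossDerivatives(c(1, -1), c(1e4, -1e4))
  expect_true(all(is.finite(c(big$h, big$q))))
})

test_that("second-order expansion approximates the loss to cubic order", {
  set.seed(3)
  n <- 40
  y <- sample(c(1, -1), n, replace = TRUE)
  F <- rnorm(n)
  drv <- lossDerivatives(y, F)
  for (delta in c(1e-1, 1e-2)) {
    f <- delta * rnorm(n)
    approx <- logLoss(y, F) + mean(drv$h * f + 0.5 * drv$q * f^2)
    expect_lt(abs(logLoss(y, F + f) - approx), max(abs(f))^3)
  }
})

test_that("centering transform annihilates the weighted mean and reduces to ordinary centering", {
  set.seed(4)
  for (rep in 1:5) {
    inst <- makeSolverInstance(n = 12, seed = rep)
    tr <- centeringTransform(inst$eta, inst$w, inst$K)
    # sum_i sqrt(W_ii) etaTilde_i = 0 for any input
    expect_lt(abs(sum(sqrt(inst$w) * tr$etaTilde)), 1e-10)
  }
  eta <- rnorm(8)
  K <- diag(8)
  tr <- centeringTransform(eta, rep(1, 8), K)
  expect_equal(tr$etaTilde, eta - mean(eta))
  expect_error(centeringTransform(eta, rep(0, 8), K), "positive")
})

test_that("profiling out the intercept preserves the objective (transformation identity)", {
  # Eq5 objective at (beta, c*(beta)) equals the transformed objective at
  # beta, for arbitrary beta -- the algebraic identity behind the LASSO /
  # ridge conversion, checked numerically
  for (rep in 1:20) {
    inst <- makeSolverInstance(n = 10, seed = 100 + rep)
    beta <- rnorm(10)
    cc <- recoverIntercept(beta, inst$eta, inst$w, inst$K)
    expect_equal(
      eq5Objective(beta, cc, inst$eta, inst$w, inst$K),
      eq6Objective(beta, inst$etaTilde, inst$Ktilde),
      tolerance = 1e-10)
  }
})

test_that("recoverIntercept solves the 1-D weighted problem", {
  inst <- makeSolverInstance(n = 9, seed = 11)
  # eta + K beta = 0  =>  c = 0
  beta0 <- solve(inst$K + 1e-8 * diag(9), -inst$eta)
  expect_lt(abs(recoverIntercept(beta0, inst$eta, inst$w, inst$K)), 1e-4)
  # identity weights -> negative unweighted mean
  beta <- rnorm(9)
  expect_equal(recoverIntercept(beta, inst$eta, rep(1, 9), inst$K),
               -mean(inst$eta + drop(inst$K %*% beta)))
  # optimality: perturbing c increases the objective
  cc <- recoverIntercept(beta, inst$eta, inst$w, inst$K)
  base <- eq5Objective(beta, cc, inst$eta, inst$w, inst$K)
  for (d in c(-1e-3, 1e-3))
    expect_gte(eq5Objective(beta, cc + d, inst$eta, inst$w, inst$K), base)
})

test_that("ridge fit matches the closed form and a generic numeric minimizer", {
  for (rep in 1:10) {
    inst <- makeSolverInstance(n = 10, seed = 200 + rep)
    lambda <- 10^runif(1, -3, 0)
    beta <- fitL2(inst$Ktilde, inst$etaTilde, lambda)
    # naive closed form with explicit inverse
    A <- crossprod(inst$Ktilde) + 10 * lambda * diag(10)
    expect_equal(beta, drop(-solve(A) %*% crossprod(inst$Ktilde,
                                                    inst$etaTilde)),
                 tolerance = 1e-8)
    # generic gradient-based minimizer of the ridge objective
    opt <- optim(rep(0, 10), eq6Objective, etaTilde = inst$etaTilde,
                 Ktilde = inst$Ktilde, lambda = lambda, penalty = "L2",
                 method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-14))
    expect_equal(beta, opt$par, tolerance = 1e-4)
    expect_lte(eq6Objective(beta, inst$etaTilde, inst$Ktilde, lambda, "L2"),
               opt$value + 1e-9)
  }
  # extreme shrinkage and zero response
  inst <- makeSolverInstance(n = 10, seed = 999)
  expect_lt(max(abs(fitL2(inst$Ktilde, inst$etaTilde, 1e12))), 1e-6)
  expect_equal(fitL2(inst$Ktilde, rep(0, 10), 0.1), rep(0, 10))
})

test_that("LASSO fit satisfies KKT conditions and the lambdaMax zero threshold", {
  for (rep in 1:10) {
    inst <- makeSolverInstance(n = 12, seed = 300 + rep)
    n <- 12
    lamMax <- (2 / n) * max(abs(crossprod(inst$Ktilde, inst$etaTilde)))
    # at or above lambdaMax the solution is exactly zero (a hair above the
    # threshold guards the float comparison at the boundary itself)
    expect_identical(fitL1(inst$Ktilde, inst$etaTilde, lamMax * (1 + 1e-9)),
                     rep(0, n))
    expect_identical(fitL1(inst$Ktilde, inst$etaTilde, 2 * lamMax), rep(0, n))
    expect_lt(max(abs(fitL1(inst$Ktilde, inst$etaTilde, lamMax))), 1e-10)
    # below lambdaMax: KKT subgradient conditions at 1e-5
    lambda <- lamMax / 10
    beta <- fitL1(inst$Ktilde, inst$etaTilde, lambda, tol = 1e-12)
    g <- (2 / n) * crossprod(inst$Ktilde,
                             inst$etaTilde + inst$Ktilde %*% beta)
    active <- beta != 0
    expect_true(all(abs(g[active] + lambda * sign(beta[active])) < 1e-5))
    expect_true(all(abs(g[!active]) <= lambda + 1e-5))
    expect_true(any(active))
  }
})

test_that("LASSO agrees with glmnet at matched penalty", {
  skip_if_not_installed("glmnet")
  for (rep in 1:5) {
    inst <- makeSolverInstance(n = 15, seed = 400 + rep)
    n <- 15
    lamMax <- (2 / n) * max(abs(crossprod(inst$Ktilde, inst$etaTilde)))
    lambda <- lamMax / 8
    beta <- fitL1(inst$Ktilde, inst$etaTilde, lambda, tol = 1e-12)
    gfit <- glmnet::glmnet(inst$Ktilde, -inst$etaTilde, family = "gaussian",
                           lambda = lambda / 2, standardize = FALSE,
                           intercept = FALSE, thresh = 1e-14)
    expect_equal(beta, as.numeric(gfit$beta), tolerance = 1e-4)
  }
})

test_that("L1 solution is never beaten by the ridge solution under the L1 objective", {
  for (rep in 1:5) {
    inst <- makeSolverInstance(n = 10, seed = 500 + rep)
    n <- 10
    lamMax <- (2 / n) * max(abs(crossprod(inst$Ktilde, inst$etaTilde)))
    lambda <- lamMax / 5
    b1 <- fitL1(inst$Ktilde, inst$etaTilde, lambda, tol = 1e-12)
    b2 <- fitL2(inst$Ktilde, inst$etaTilde, lambda)
    expect_lte(eq6Objective(b1, inst$etaTilde, inst$Ktilde, lambda, "L1"),
               eq6Objective(b2, inst$etaTilde, inst$Ktilde, lambda, "L1") +
                 1e-9)
    expect_equal(fitL1(inst$Ktilde, rep(0, n), lambda), rep(0, n))
  }
})

test_that("base-learner selection equals exhaustive evaluation by definition", {
  ds <- makeToyDataset(N = 24, p = 6, seed = 21)
  coll <- makeToyCollection(p = 6, blockSize = 3)
  kernels <- pkboost:::pathwayKernelList(exprMatrix(ds), coll,
                                         kernelSpec("rbf"))
  y <- sampleLabels(ds)
  F <- rep(initF0(y), 24)
  for (pen in c("L1", "L2")) {
    sel <- selectBaseLearner(y, F, kernels, pen, lambda = 0.01)
    # recompute every pathway's minimized objective independently in R
    drv <- lossDerivatives(y, F)
    w <- pkboost:::curvatureWeights(drv$q, "half")
    eta <- drv$h / pmax(drv$q, 1e-8)
    objs <- vapply(kernels, function(K) {
      tr <- centeringTransform(eta, w, K)
      b <- if (pen == "L1") fitL1(tr$Ktilde, tr$etaTilde, 0.01, tol = 1e-12)
           else fitL2(tr$Ktilde, tr$etaTilde, 0.01)
      eq6Objective(b, tr$etaTilde, tr$Ktilde, 0.01, pen)
    }, 1.0)
    expect_equal(as.numeric(sel$objectives), unname(objs), tolerance = 1e-6)
    expect_identical(sel$selected, unname(which.min(objs)))
    # intercept consistent with the profiled solution
    expect_equal(sel$intercept,
                 recoverIntercept(sel$beta, eta, w,
                                  kernels[[sel$selected]]),
                 tolerance = 1e-8)
  }
  # single-pathway collection: that pathway is selected
  sel1 <- selectBaseLearner(y, F, kernels[1], "L2", lambda = 0.01)
  expect_identical(sel1$selected, 1L)
})

test_that("the first selected pathway is a truly relevant one in most simulations", {
  hits <- 0L
  for (seed in 1:50) {
    sim <- simulateModel(1, M = 20, pathwaySize = 5, N = 150, seed = seed)
    y <- sampleLabels(sim$dataset)
    kernels <- pkboost:::pathwayKernelList(exprMatrix(sim$dataset),
                                           sim$pathways, kernelSpec("rbf"))
    lam <- autoLambda(sim$dataset, sim$pathways, kernelSpec("rbf"), "L2")
    sel <- selectBaseLearner(y, rep(initF0(y), 150), kernels, "L2", lam)
    if (sel$selected %in% 1:3) hits <- hits + 1L
  }
  expect_gte(hits, 40L)
})

test_that("line search minimizes the exact loss on [0, dmax]", {
  set.seed(31)
  n <- 25
  y <- sample(c(1, -1), n, replace = TRUE)
  F <- rnorm(n, sd = 0.5)
  for (rep in 1:5) {
    fhat <- rnorm(n)
    d <- lineSearch(y, F, fhat)
    # never increases the loss (d = 0 feasible)
    expect_lte(logLoss(y, F + d * fhat), logLoss(y, F) + 1e-12)
    # dense grid oracle
    grid <- seq(0, 100, length.out = 1e5)
    lg <- vapply(grid, function(dd) logLoss(y, F + dd * fhat), 1.0)
    expect_lte(logLoss(y, F + d * fhat), min(lg) + 1e-9)
    expect_lt(abs(d - grid[which.min(lg)]), 1e-3 + 100 / 1e5)
  }
  # perfectly aligned direction on separable data: monotone decreasing loss
  ysep <- rep(c(1, -1), 10)
  dsep <- lineSearch(ysep, rep(0, 20), ysep)
  expect_gt(dsep, 99.9)
})

test_that("training loss is non-increasing for random configurations", {
  for (rep in 1:20) {
    set.seed(600 + rep)
    N <- sample(20:40, 1)
    ds <- makeToyDataset(N = N, p = 6, seed = 600 + rep,
                         balanced = rep %% 2 == 0)
    coll <- makeToyCollection(p = 6, blockSize = 3)
    pen <- sample(c("L1", "L2"), 1)
    mdl <- pkbFit(ds, coll, kernelSpec(sample(c("rbf", "poly3", "linear"),
                                              1)),
                  pen, lambda = 10^runif(1, -3, -1),
                  nu = runif(1, 0.05, 1), T = 8)
    expect_true(all(diff(mdl@trainLoss) <= 1e-10))
  }
})

test_that("one boosting iteration equals the manual composition of its steps", {
  ds <- makeToyDataset(N = 30, p = 6, seed = 51)
  coll <- makeToyCollection(p = 6, blockSize = 3)
  spec <- kernelSpec("rbf")
  y <- sampleLabels(ds)
  kernels <- pkboost:::pathwayKernelList(exprMatrix(ds), coll, spec)
  for (pen in c("L1", "L2")) {
    mdl <- pkbFit(ds, coll, spec, pen, lambda = 0.01, nu = 1, T = 1)
    # manual: init, select, line search, update
    F0 <- initF0(y)
    sel <- selectBaseLearner(y, rep(F0, 30), kernels, pen, 0.01)
    d <- lineSearch(y, rep(F0, 30), sel$fhat)
    expect_identical(mdl@history$pathway, sel$selected)
    expect_equal(mdl@history$d, d, tolerance = 1e-6)
    expect_equal(pathwayWeights(mdl)[[sel$selected]],
                 1 * d * sqrt(sum(sel$beta^2)), tolerance = 1e-6)
    expect_equal(tail(mdl@trainLoss, 1),
                 logLoss(y, rep(F0, 30) + d * sel$fhat), tolerance = 1e-6)
  }
})

test_that("an over-penalized L1 model stays at the constant and stops early", {
  ds <- makeToyDataset(N = 30, p = 6, seed = 61, balanced = FALSE)
  coll <- makeToyCollection(p = 6, blockSize = 3)
  kernels <- pkboost:::pathwayKernelList(exprMatrix(ds), coll,
                                         kernelSpec("rbf"))
  lamMax <- max(pkboost:::lambdaMaxPerPathway(kernels, sampleLabels(ds)))
  mdl <- pkbFit(ds, coll, kernelSpec("rbf"), "L1", lambda = lamMax * 1.01,
                nu = 0.5, T = 10)
  expect_true(mdl@earlyStopped)
  expect_identical(nrow(mdl@history), 0L)
  expect_true(all(pathwayWeights(mdl) == 0))
  pred <- predict(mdl, ds)
  expect_equal(pred$score, rep(initF0(sampleLabels(ds)), 30))
})

test_that("prediction is the constant F0 at T = 0, with ties classified +1", {
  ds <- makeToyDataset(N = 20, p = 6, seed = 71)  # balanced: F0 = 0
  coll <- makeToyCollection(p = 6, blockSize = 3)
  mdl <- pkbFit(ds, coll, kernelSpec("rbf"), "L2", lambda = 0.1, T = 0)
  pred <- predict(mdl, ds)
  expect_identical(pred$score, rep(0, 20))
  expect_identical(pred$label, rep(1, 20))   # exact zero maps to +1
})

test_that("predictions are deterministic and permutation-equivariant", {
  ds <- makeToyDataset(N = 30, p = 6, seed = 81, balanced = FALSE)
  coll <- makeToyCollection(p = 6, blockSize = 3)
  mdl <- pkbFit(ds, coll, kernelSpec("rbf"), "L2", lambda = 0.02, T = 5)
  Xnew <- matrix(rnorm(12 * 6), 12, 6,
                 dimnames = list(NULL, paste0("g", 1:6)))
  p1 <- predict(mdl, Xnew)
  # duplicated sample scores identically wherever it appears (up to the
  # last-ulp rounding differences of shape-dependent BLAS kernels)
  expect_equal(predict(mdl, Xnew[c(3, 3), ])$score, rep(p1$score[3], 2),
               tolerance = 1e-12)
  perm <- sample(12)
  expect_equal(predict(mdl, Xnew[perm, ])$score, p1$score[perm])
  # missing training genes are reported
  expect_error(predict(mdl, Xnew[, 1:4]), "missing training genes: g5")
})

test_that("pathway weights are norms of aggregated coefficients, zero iff never selected", {
  ds <- makeToyDataset(N = 24, p = 6, seed = 91, balanced = FALSE)
  coll <- makeToyCollection(p = 6, blockSize = 3)
  mdl <- pkbFit(ds, coll, kernelSpec("rbf"), "L2", lambda = 0.05, T = 6)
  w <- pathwayWeights(mdl)
  selected <- unique(mdl@history$pathway)
  expect_true(all(w[selected] > 0))
  expect_true(all(w[-selected] == 0))
  expect_equal(unname(w), unname(sqrt(colSums(mdl@betaAgg^2))))
  # a unit coefficient vector scaled by nu*d has weight nu*d
  mdl@betaAgg[, 1] <- c(0.3, rep(0, 23))
  expect_equal(pathwayWeights(mdl)[[1]], 0.3)
})

test_that("both curvature-weight variants run and the default is the expansion-consistent one", {
  ds <- makeToyDataset(N = 24, p = 6, seed = 95, balanced = FALSE)
  coll <- makeToyCollection(p = 6, blockSize = 3)
  m1 <- pkbFit(ds, coll, kernelSpec("rbf"), "L2", lambda = 0.05, T = 3)
  m2 <- pkbFit(ds, coll, kernelSpec("rbf"), "L2", lambda = 0.05, T = 3,
               wVariant = "squared")
  expect_identical(m1@wVariant, "half")
  expect_true(all(diff(m2@trainLoss) <= 1e-10))
  expect_false(identical(m1@trainLoss, m2@trainLoss))
})

test_that("models serialize to JSON and round-trip exactly", {
  ds <- makeToyDataset(N = 15, p = 6, seed = 101, balanced = FALSE)
  coll <- makeToyCollection(p = 6, blockSize = 3)
  mdl <- pkbFit(ds, coll, kernelSpec("poly3"), "L1", lambda = 0.01, T = 4)
  f <- tmpfile(".pkb")
  writePKBModel(mdl, f)
  mdl2 <- readPKBModel(f)
  expect_equal(mdl2@betaAgg, mdl@betaAgg)
  expect_identical(mdl2@F0, mdl@F0)
  expect_identical(mdl2@cAgg, mdl@cAgg)
  expect_identical(mdl2@penalty, mdl@penalty)
  expect_identical(mdl2@kernel@family, mdl@kernel@family)
  expect_equal(predict(mdl2, ds)$score, predict(mdl, ds)$score)
})
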