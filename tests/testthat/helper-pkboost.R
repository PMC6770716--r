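# Shared fixture builders. All randomness is seeded locally so tests are
# order-independent.

makeToyDataset <- function(N = 30, p = 6, seed = 1, balanced = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(N * p), N, p)
  y <- if (balanced) rep(c(1, -1), length.out = N) else
    c(rep(1, ceiling(2 * N / 3)), rep(-1, N - ceiling(2 * N / 3)))
  ExpressionDataset(X, paste0("g", seq_len(p)), y, paste0("s", seq_len(N)))
}

makeToyCollection <- function(p = 6, blockSize = 3) {
  M <- p %/% blockSize
  members <- lapply(seq_len(M), function(m)
    paste0("g", ((m - 1) * blockSize + 1):(m * blockSize)))
  PathwayCollection(paste0("pw", seq_len(M)), members,
                    lapply(seq_len(M), function(m)
                      ((m - 1) * blockSize + 1):(m * blockSize)))
}

# random transformed-problem instance for solver tests
makeSolverInstance <- function(n = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n, 3)
  K <- pathwayKernel(X, spec = kernelSpec("rbf"), pm = 3)
  y <- sample(c(1, -1), n, replace = TRUE)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  F <- rnorm(n)
  drv <- lossDerivatives(y, F)
  w <- pkboost:::curvatureWeights(drv$q, "half")
  eta <- drv$h / pmax(drv$q, 1e-8)
  tr <- centeringTransform(eta, w, K)
  list(K = K, y = y, F = F, w = w, eta = eta,
       Ktilde = tr$Ktilde, etaTilde = tr$etaTilde, n = n)
}

# quadratic objective of the weighted problem with free intercept
eq5Objective <- function(beta, cc, eta, w, K, lambda = 0,
                         penalty = c("none", "L1", "L2")) {
  penalty <- match.arg(penalty)
  v <- eta + drop(K %*% beta) + cc
  pen <- switch(penalty, none = 0, L1 = lambda * sum(abs(beta)),
                L2 = lambda * sum(beta^2))
  sum(w * v^2) / length(eta) + pen
}

# transformed intercept-free objective
eq6Objective <- function(beta, etaTilde, Ktilde, lambda = 0,
                         penalty = c("none", "L1", "L2")) {
  penalty <- match.arg(penalty)
  r <- etaTilde + drop(Ktilde %*% beta)
  pen <- switch(penalty, none = 0, L1 = lambda * sum(abs(beta)),
                L2 = lambda * sum(beta^2))
  sum(r^2) / length(etaTilde) + pen
}

tmpfile <- function(ext) tempfile(fileext = ext)
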