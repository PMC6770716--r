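#' True log-odds functions of the three simulation models
#'
#' Model 1: \code{2 x1(1) + 3 x2(1) + exp(0.8 x1(2) + 0.8 x2(2)) +
#' 4 x1(3) x2(3)} (first three pathways relevant, two genes each).
#' Model 2: \code{4 sin(x1(1) + x2(1)) + 3 |x1(2) - x2(2)| + 2 x1(3)^2 -
#' 2 x2(3)^2}.
#' Model 3: \code{2 sum_{m=1..10} ||x(m)||_2} (first ten pathways relevant).
#' Here xj(m) is the j-th gene of pathway m; pathways are consecutive
#' disjoint blocks of \code{pathwaySize} columns.
#'
#' @param model 1, 2 or 3.
#' @param X samples x genes matrix (one row is also accepted as a vector).
#' @param pathwaySize genes per pathway block (>= 2 for models 1-2).
#' @return numeric vector of log odds, one per sample.
#' @export
logOdds <- function(model, X, pathwaySize = 5L) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  model <- as.integer(model)
  stopifnot(model %in% 1:3)
  gene <- function(m, j) X[, (m - 1L) * pathwaySize + j]
  need <- if (model == 3L) 10L * pathwaySize else 2L * pathwaySize + 2L
  if (model %in% 1:2 && pathwaySize < 2L)
    stop("models 1-2 need at least 2 genes per pathway")
  if (ncol(X) < need)
    stop("model ", model, " needs at least ", need, " gene columns, got ",
         ncol(X))
  switch(model,
    `1` = 2 * gene(1, 1) + 3 * gene(1, 2) +
          exp(0.8 * gene(2, 1) + 0.8 * gene(2, 2)) +
          4 * gene(3, 1) * gene(3, 2),
    `2` = 4 * sin(gene(1, 1) + gene(1, 2)) +
          3 * abs(gene(2, 1) - gene(2, 2)) +
          2 * gene(3, 1)^2 - 2 * gene(3, 2)^2,
    `3` = {
      out <- 0
      for (m in 1:10) {
        block <- X[, ((m - 1L) * pathwaySize + 1L):(m * pathwaySize),
                   drop = FALSE]
        out <- out + sqrt(rowSums(block^2))
      }
      2 * out
    })
}

#' Simulate a benchmark dataset
#'
#' Generates iid standard-normal expression for \code{M} disjoint pathways
#' of \code{pathwaySize} genes, evaluates the chosen model's log odds F,
#' median-centers it (so classes are approximately balanced) and draws
#' labels. With \code{labels = "stochastic"} (default), y = 1 with
#' probability \code{1 / (1 + exp(-Fcentered))} — F is the true log odds, so
#' label noise matches the logistic model and the Bayes error is nonzero.
#' \code{labels = "deterministic"} uses \code{sign(Fcentered)} instead
#' (ties to +1).
#'
#' @param model 1, 2 or 3.
#' @param M number of pathways (models 1-2 need >= 3, model 3 >= 10).
#' @param pathwaySize genes per pathway.
#' @param N sample count.
#' @param seed integer seed.
#' @param labels label-generation mechanism.
#' @return list: \code{dataset} (labelled \code{ExpressionDataset}),
#'   \code{pathways} (mapped \code{PathwayCollection}, blocks named
#'   pw1..pwM), \code{F} (raw log odds), \code{Fcentered}.
#' @export
simulateModel <- function(model, M = 50L, pathwaySize = 5L, N = 900L,
                          seed = 1L, labels = c("stochastic",
                                                "deterministic")) {
  labels <- match.arg(labels)
  model <- as.integer(model)
  stopifnot(model %in% 1:3)
  if (model %in% 1:2 && M < 3L) stop("models 1-2 require at least 3 pathways")
  if (model == 3L && M < 10L) stop("model 3 requires at least 10 pathways")
  if (model %in% 1:2 && pathwaySize < 2L)
    stop("models 1-2 require pathwaySize >= 2")
  set.seed(seed)
  p <- M * pathwaySize
  X <- matrix(stats::rnorm(N * p), N, p)
  genes <- paste0("g", seq_len(p))
  samples <- paste0("s", seq_len(N))
  dimnames(X) <- list(samples, genes)
  F <- logOdds(model, X, pathwaySize)
  Fc <- F - stats::median(F)
  y <- if (labels == "stochastic") {
    ifelse(stats::runif(N) < stats::plogis(Fc), 1, -1)
  } else {
    ifelse(Fc >= 0, 1, -1)
  }
  ds <- ExpressionDataset(X, genes, y, samples)
  members <- lapply(seq_len(M), function(m)
    genes[((m - 1L) * pathwaySize + 1L):(m * pathwaySize)])
  coll <- PathwayCollection(paste0("pw", seq_len(M)), members,
                            lapply(seq_len(M), function(m)
                              ((m - 1L) * pathwaySize + 1L):(m * pathwaySize)))
  list(dataset = ds, pathways = coll, F = F, Fcentered = Fc)
}
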