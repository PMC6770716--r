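#' Run the simulation benchmark
#'
#' For every combination of model, pathway count and penalty: simulate a
#' dataset, run outer cross-validation with nested stopping-iteration
#' selection and the automatic penalty grid, and record the mean held-out
#' error. Per-replicate errors are reported alongside means so sampling
#' variability is visible.
#'
#' @param models subset of 1:3.
#' @param Mvalues pathway counts (e.g. c(50, 150)).
#' @param penalties subset of c("L1", "L2").
#' @param seed integer seed; replicate r of a scenario uses seed + r - 1 for
#'   data generation and fold assignment.
#' @param reps replicates per scenario.
#' @param N,pathwaySize simulation dimensions.
#' @param spec \code{KernelSpec} used for all runs.
#' @param nu learning rate.
#' @param Tmax iteration cap for nested selection.
#' @param patience early-stop patience for monitored inner-CV runs.
#' @return list: \code{table} (data.frame of mean errors, one row per
#'   scenario), \code{reps} (per-replicate errors), \code{weights} (named
#'   list of across-fold average weight vectors per scenario, last
#'   replicate), \code{cv} (per-scenario list of PKBCVResult for the last
#'   replicate).
#' @export
pkbBenchmark <- function(models = 1:3, Mvalues = 50L,
                         penalties = c("L1", "L2"), seed = 1L, reps = 1L,
                         N = 900L, pathwaySize = 5L,
                         spec = kernelSpec("rbf"), nu = 0.05, Tmax = 500L,
                         patience = 15L) {
  stopifnot(reps >= 1)
  rows <- list()
  repRows <- list()
  weights <- list()
  cvs <- list()
  for (model in models) for (M in Mvalues) for (pen in penalties) {
    errs <- numeric(reps)
    for (r in seq_len(reps)) {
      s <- seed + r - 1L
      sim <- simulateModel(model, M = M, pathwaySize = pathwaySize, N = N,
                           seed = s)
      cv <- pkbCV(sim$dataset, sim$pathways, spec, pen, lambda = "auto",
                  nu = nu, Tmax = Tmax, k = 3L, seed = s,
                  patience = patience)
      errs[r] <- cv@meanError
      repRows[[length(repRows) + 1L]] <-
        data.frame(model = model, M = M, penalty = pen, rep = r, seed = s,
                   error = cv@meanError)
      if (r == reps) {
        key <- sprintf("model%d_M%d_%s", model, M, pen)
        weights[[key]] <- cv@meanWeights
        cvs[[key]] <- cv
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(model = model, M = M, penalty = pen, reps = reps,
                 meanError = mean(errs))
  }
  list(table = do.call(rbind, rows), reps = do.call(rbind, repRows),
       weights = weights, cv = cvs)
}

#' Ranked pathway-weight table
#'
#' @param weights named weight vector (e.g. \code{pathwayWeights(model)} or
#'   a \code{PKBCVResult}'s \code{meanWeights}).
#' @param k number of top pathways to keep (capped at the total).
#' @return data.frame sorted by descending weight; all-zero weights give a
#'   stable name-sorted table.
#' @export
weightReport <- function(weights, k = 15L) {
  if (is(weights, "PKBCVResult")) weights <- weights@meanWeights
  if (is(weights, "PKBModel")) weights <- pathwayWeights(weights)
  ord <- order(-weights, names(weights))
  out <- data.frame(pathway = names(weights)[ord],
                    weight = unname(weights[ord]))
  utils::head(out, min(k, nrow(out)))
}

#' Write a cross-validation report as JSON
#'
#' Self-contained record: config echo (with seed), per-fold errors, chosen
#' lambda and stopping iterations, validation-loss curves and averaged
#' pathway weights. Re-running with the echoed config and seed reproduces
#' the result.
#'
#' @param cv a \code{PKBCVResult}.
#' @param path output path.
#' @export
writeCVReport <- function(cv, path) {
  rep <- list(
    config = cv@config,
    version = as.character(utils::packageVersion("pkboost")),
    meanError = cv@meanError,
    folds = lapply(cv@folds, function(f)
      list(lambda = f$lambda, Tstar = f$Tstar, error = f$error,
           lossCurve = f$meanCurve)),
    meanWeights = as.list(cv@meanWeights))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a fitted model to a self-describing JSON archive
#'
#' All metadata and dense coefficient arrays are stored at full precision;
#' \code{\link{readPKBModel}} restores an identical model (round-trip
#' exact).
#'
#' @param model a \code{PKBModel}.
#' @param path output path.
#' @export
writePKBModel <- function(model, path) {
  obj <- list(
    format = "pkboost-model",
    version = as.character(utils::packageVersion("pkboost")),
    F0 = model@F0, nu = model@nu, lambda = model@lambda,
    penalty = model@penalty, wVariant = model@wVariant,
    kernel = model@kernel@family,
    geneNames = model@geneNames,
    sampleIds = rownames(model@supportX),
    supportX = asplit2(model@supportX),
    pathwayNames = pathwayNames(model@pathways),
    members = pathwayMembers(model@pathways),
    indexMap = pathwayIndexMap(model@pathways),
    betaAgg = asplit2(model@betaAgg),
    cAgg = model@cAgg,
    history = model@history,
    trainLoss = model@trainLoss,
    earlyStopped = model@earlyStopped)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# row-wise list representation of a matrix for JSON round-trips
asplit2 <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))

#' @rdname writePKBModel
#' @param path archive written by \code{writePKBModel}.
#' @return A \code{PKBModel}.
#' @export
readPKBModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pkboost-model"))
    stop("not a pkboost model archive: ", path)
  toMatrix <- function(x) if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  supportX <- toMatrix(obj$supportX)
  dimnames(supportX) <- list(obj$sampleIds, obj$geneNames)
  betaAgg <- toMatrix(obj$betaAgg)
  colnames(betaAgg) <- obj$pathwayNames
  coll <- PathwayCollection(obj$pathwayNames,
                            as.list(obj$members),
                            lapply(obj$indexMap, as.integer))
  hist <- as.data.frame(obj$history)
  if (!nrow(hist))
    hist <- data.frame(iteration = integer(0), pathway = integer(0),
                       d = numeric(0), intercept = numeric(0),
                       objective = numeric(0), trainLoss = numeric(0))
  new("PKBModel", F0 = obj$F0, nu = obj$nu, lambda = obj$lambda,
      penalty = obj$penalty, wVariant = obj$wVariant,
      kernel = kernelSpec(obj$kernel), supportX = supportX,
      geneNames = obj$geneNames, pathways = coll, betaAgg = betaAgg,
      cAgg = obj$cAgg, history = hist, trainLoss = as.numeric(obj$trainLoss),
      earlyStopped = obj$earlyStopped)
}
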