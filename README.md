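# pkboost

Pathway-based kernel boosting for binary classification of genomic samples.

## The problem

Expression studies routinely have a few hundred samples and tens of
thousands of genes, and single-gene classifiers are hard to interpret and
unstable when individual signals are weak. `pkboost` leverages prior
knowledge — pathways, i.e. named gene sets — both to regularize the
classifier and to make its output interpretable: the fitted model is a sum
of pathway-level functions, and every pathway receives a nonnegative
importance weight, so the user learns *which* biological processes drive
the prediction, not just the prediction itself. It is aimed at
computational biologists analysing case/control or two-group phenotypes
(tumor grade, metastasis status, treatment response) from bulk or
single-cell expression matrices plus a GMT pathway database.

## The method

For samples $x_i \in \mathbb{R}^p$ with labels $y_i \in \{1,-1\}$ the
model estimates the log-odds function additively over pathways,

$$F(x) = \sum_{m=1}^{M} H_m(x^{(m)}), \qquad
\hat y = \mathrm{sign}[F(x)],$$

where each pathway contribution lives in the span of a kernel computed
only on that pathway's genes, $H_m(\cdot) = \sum_i K_m(x_i^{(m)},
\cdot)\beta_i^{(m)} + c$ (rbf, cubic polynomial or linear; bandwidth fixed
at $1/p_m$). Fitting is boosting on the empirical log loss
$L = \frac1N\sum_i \log(1+e^{-y_iF(x_i)})$: each iteration expands $L$ to
second order (Newton-style descent), solves a penalized weighted
least-squares problem in every pathway — L1 penalty
$\lambda\|\beta\|_1$ (a LASSO after a weighted centering transform) or L2
penalty $\lambda\|\beta\|_2^2$ (closed-form ridge) — adds the
best-fitting pathway's learner after an exact line search, damped by a
learning rate $\nu$. The stopping iteration is selected by nested
cross-validation; $\lambda$ comes from an automatic anchor with a
geometric grid $\{1/25, 1/5, 1, 5, 25\}$. Pathway importance is
$\|\beta^{(m)}\|_2$ of the aggregated coefficients — zero exactly for
pathways never selected.

## Worked example

```r
library(pkboost)

# simulate a benchmark dataset: 50 pathways of 5 genes, 900 samples,
# log odds from the first three pathways only
sim <- simulateModel(1, M = 50, pathwaySize = 5, N = 900, seed = 1)

# 3-fold cross-validation with nested selection of the stopping iteration
cv <- pkbCV(sim$dataset, sim$pathways, kernelSpec("rbf"), "L1",
            lambda = "auto", nu = 1, Tmax = 30, seed = 1, patience = 8)
cv
#> PKBCVResult: 3 outer folds
#>   mean test error: 0.1811
#>   T*: 4, 4, 3; lambda: 0.00184, 0.00173, 0.00183

head(weightReport(cv), 5)
#>   pathway    weight
#> 1     pw3 12.257270
#> 2     pw1  6.462932
#> 3     pw2  3.990226
#> 4    pw10  0.000000
#> 5    pw11  0.000000
```

The mean test error (~0.18 for this seed; ~0.15–0.18 across seeds) is the
3-fold held-out misclassification rate. The weight table shows that the
three truly informative pathways (pw1–pw3) dominate the ranking while
never-selected pathways have exactly zero weight — the model recovered the
planted signal. A fitted `PKBModel` from `pkbFit()` supports `predict()`
on new samples, `pathwayWeights()`, and JSON serialization
(`writePKBModel()` / `readPKBModel()`).

Real data enter through `readExpression()` (samples x genes TSV/CSV),
`readLabels()` and `readGMT()`, with `mapPathways()` matching gene sets to
expression columns (size and overlap filters included). A thin command
line lives in `inst/cli/pkb.R` with subcommands `simulate`, `fit`,
`predict`, `cv`, `weights`, `benchmark`.

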