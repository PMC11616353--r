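## Independent oracles and small generators shared across test files.

## Exact Poisson interval for the mean of an observed count, obtained by
## direct inversion of the Poisson CDF with uniroot -- independent of the
## chi-square-quantile route used by the package.
poissonCIByInversion <- function(observed, level = 0.95, tol = 1e-9) {
    alpha <- 1 - level
    upper <- uniroot(function(mu) ppois(observed, mu) - alpha / 2,
                     lower = observed + 1e-12,
                     upper = observed + 10 * sqrt(observed + 1) + 50,
                     tol = tol)$root
    lower <- if (observed == 0) 0 else
        uniroot(function(mu) 1 - ppois(observed - 1, mu) - alpha / 2,
                lower = 1e-12, upper = observed + 1, tol = tol)$root
    c(lower = lower, upper = upper)
}

## Random valid lineage count tables (strictly positive cells).
randomCountTable <- function(maxCount = 500) {
    k <- sample.int(maxCount, 4, replace = TRUE)
    LineageCountTable(k[1], k[2], k[3], k[4], label = "random")
}

## Random valid simulator configurations.
randomSimConfig <- function(seed) {
    SimConfig(nProbands = 100L,
              pFemale = runif(1, 0.2, 0.8),
              pMaternal = runif(1, 0.2, 0.8),
              baselineRate = runif(1, 1e-4, 0.05),
              rrAutosomal = runif(1, 0.5, 3),
              rrX = runif(1, 0.3, 3),
              rrY = runif(1, 0.3, 3),
              maternalEffect = runif(1, 0.5, 2),
              seed = seed)
}
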