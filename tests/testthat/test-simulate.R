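test_that("simulation is deterministic in the seed and RNG-clean", {
    cfg <- SimConfig(nProbands = 2000, rrX = 1.3, seed = 99)
    set.seed(123); outer <- runif(3)
    set.seed(123)
    p1 <- simulatePopulation(cfg)
    expect_identical(runif(3), outer)  # caller RNG state untouched
    p2 <- simulatePopulation(cfg)
    expect_identical(probandRecords(p1), probandRecords(p2))
    p3 <- simulatePopulation(SimConfig(nProbands = 2000, rrX = 1.3,
                                       seed = 100))
    expect_false(identical(probandRecords(p1), probandRecords(p3)))
})

test_that("cell-probability OR equals rrX/rrY whatever the nuisances", {
    set.seed(5)
    for (i in 1:20) {
        cfg <- randomSimConfig(seed = i)
        p <- cellProbabilities(cfg)
        or <- (p[["female.paternal"]] / p[["female.maternal"]]) /
            (p[["male.paternal"]] / p[["male.maternal"]])
        expect_equal(or, cfg@rrX / cfg@rrY, tolerance = 1e-12)
    }
    # X and Y effects of equal size exactly confound
    pc <- cellProbabilities(SimConfig(rrX = 2, rrY = 2, baselineRate = 0.01,
                                      rrAutosomal = 1, seed = 1))
    expect_equal((pc[[1]] / pc[[2]]) / (pc[[3]] / pc[[4]]), 1)
    # no genetic effect: all four cells at baseline
    flat <- cellProbabilities(SimConfig(rrAutosomal = 1, rrX = 1, rrY = 1,
                                        baselineRate = 0.01, seed = 1))
    expect_equal(unname(flat), rep(0.01, 4))
})

test_that("a maternal-lineage multiplier cancels from the OR", {
    pm <- cellProbabilities(SimConfig(rrX = 1.4, maternalEffect = 1.8,
                                      seed = 2))
    p0 <- cellProbabilities(SimConfig(rrX = 1.4, maternalEffect = 1,
                                      seed = 2))
    expect_equal(pm[["female.maternal"]] / p0[["female.maternal"]], 1.8)
    orOf <- function(p) (p[[1]] / p[[2]]) / (p[[3]] / p[[4]])
    expect_equal(orOf(pm), orOf(p0))
})

test_that("the analytic OR increases strictly with rrX", {
    ors <- vapply(c(0.5, 1, 1.5, 2.5), function(rx) {
        p <- cellProbabilities(SimConfig(rrX = rx, seed = 1))
        (p[[1]] / p[[2]]) / (p[[3]] / p[[4]])
    }, numeric(1))
    expect_true(all(diff(ors) > 0))
})

test_that("invalid configurations are rejected", {
    expect_error(SimConfig(seed = 1, baselineRate = 0),
                 "baselineRate")
    expect_error(SimConfig(seed = 1, baselineRate = 0.5, rrAutosomal = 3),
                 "exceed")
    expect_error(SimConfig(nProbands = 100), "mandatory")
    expect_error(SimConfig(seed = 1, pFemale = 1.2), "pFemale")
})

test_that("the estimator recovers the generative OR at large n", {
    pop <- simulatePopulation(SimConfig(nProbands = 1e6, rrX = 1.5,
                                        baselineRate = 0.01, seed = 314))
    res <- oddsRatio(tabulateLineage(probandRecords(pop)))
    ci <- confInt(res)
    expect_gt(1.5, ci[["lower"]])
    expect_lt(1.5, ci[["upper"]])
})

test_that("estimator bias shrinks as the population grows", {
    base <- SimConfig(nProbands = 2000, rrX = 1.25, seed = 271)
    small <- recoveryExperiment(base, nReps = 60)
    big <- recoveryExperiment(SimConfig(nProbands = 50000, rrX = 1.25,
                                        seed = 271), nReps = 60)
    expect_lt(abs(big$or_bias), abs(small$or_bias))
    # at the larger n the median is on target within Monte-Carlo error
    ok <- !is.na(big$or_points)
    mcse <- 1.2533 * sd(big$or_points[ok]) / sqrt(sum(ok))
    expect_lt(abs(big$or_median - 1.25), 4 * mcse)
})

test_that("null X effect centres the X-proportion estimate on zero", {
    summ <- recoveryExperiment(SimConfig(nProbands = 50000, rrX = 1,
                                         seed = 8), nReps = 40)
    ok <- !is.na(summ$or_points)
    pcts <- (summ$or_points[ok] - 1) / summ$or_points[ok] * 100
    mcse <- 1.2533 * sd(pcts) / sqrt(length(pcts))
    expect_lt(abs(summ$x_proportion_median), 4 * mcse)
})

test_that("zero-cell replicates are excluded and reported, not fatal", {
    summ <- recoveryExperiment(SimConfig(nProbands = 60,
                                         baselineRate = 0.02, seed = 17),
                               nReps = 3)
    expect_equal(summ$n_reps, 3)
    expect_equal(summ$exclusion_rate, summ$n_excluded / 3)
    expect_true(summ$n_excluded >= 1)  # tiny n: zero cells near-certain
})

test_that("simulator configs load from YAML and JSON with a schema", {
    cfg <- readSimConfig(xlinkFixture("sim_config.yaml"))
    expect_s4_class(cfg, "SimConfig")
    expect_equal(cfg@rrX, 1.25)
    expect_equal(attr(cfg, "n_reps"), 200L)

    jf <- withr::local_tempfile(fileext = ".json")
    writeLines('{"n_probands": 500, "rr_x": 1.1, "seed": 3}', jf)
    cfgj <- readSimConfig(jf)
    expect_equal(cfgj@nProbands, 500L)
    expect_equal(cfgj@seed, 3L)

    noseed <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("n_probands: 10", "rr_x: 1.2"), noseed)
    expect_error(readSimConfig(noseed), "seed")

    typo <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("seed: 1", "rr_xx: 1.2"), typo)
    expect_error(readSimConfig(typo), "unknown simulator config field")
})
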