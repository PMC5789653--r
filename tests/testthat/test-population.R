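calcium <- predefinedSystem("calcium_pth")
glucose <- predefinedSystem("glucose_insulin")

test_that("zero variance yields identical copies of the template", {
  spec <- populationSpec(calcium, n = 5, seed = 3, effectorCV = 0)
  pop <- samplePopulation(spec)
  expect_length(pop, 5)
  for (ind in pop) {
    expect_equal(curveParams(sensor(ind)), curveParams(sensor(calcium)))
    expect_equal(curveParams(effector(ind)), curveParams(effector(calcium)))
  }
})

test_that("log-normal draws are median-preserving with the requested CV", {
  # analytic moment: mean of a median-parameterized lognormal is
  # template * exp(sigma^2/2) with sigma = sqrt(log(1 + CV^2)); for CV = 0.2
  # that is within 2% of the template, so the sample mean must sit within 5%
  spec <- populationSpec(calcium, n = 1000, seed = 42, effectorCV = 0.2)
  draws <- parameterDraws(simulateEquilibriumCohort(spec))
  g0 <- curveParams(effector(calcium))[["gain"]]
  expect_lt(abs(mean(draws$gain) - g0) / g0, 0.05)
  expect_equal(median(draws$gain), g0, tolerance = 0.05)
  sdlog <- sd(log(draws$gain))
  expect_equal(sdlog, sqrt(log(1 + 0.2^2)), tolerance = 0.05)
  # sensor parameters untouched in effector-dominant mode
  expect_true(all(draws$alpha == 1) && all(draws$beta == 1))
})

test_that("cohorts are bitwise reproducible from the seed", {
  spec <- populationSpec(calcium, n = 50, seed = 99)
  expect_identical(parameterDraws(simulateEquilibriumCohort(spec)),
                   parameterDraws(simulateEquilibriumCohort(spec)))
  a <- simulateSetpointCohort(populationSpec(calcium, n = 50, seed = 7,
                                             model = "setpoint"))
  b <- simulateSetpointCohort(populationSpec(calcium, n = 50, seed = 7,
                                             model = "setpoint"))
  expect_identical(cohortPairs(a), cohortPairs(b))
  # and samplePopulation sees the same draws as the cohort simulator
  pop <- samplePopulation(spec)
  d <- parameterDraws(simulateEquilibriumCohort(spec))
  expect_equal(curveParams(effector(pop[[17]]))[["gain"]], d$gain[17])
})

test_that("variation modes constrain the CVs as declared", {
  expect_error(populationSpec(calcium, n = 10, seed = 1,
                              variationMode = "effector_dominant",
                              sensorCV = 0.1), "sensor CVs")
  expect_error(populationSpec(calcium, n = 10, seed = 1,
                              variationMode = "sensor_dominant",
                              effectorCV = 0.1), "effector CVs")
  expect_error(populationSpec(calcium, n = 1, seed = 1), "n must be")
  expect_error(populationSpec(calcium, n = 10, seed = 1, effectorCV = 1.2),
               "CVs")
})

test_that("equilibrium cohorts satisfy both curve equations per individual", {
  spec <- populationSpec(calcium, n = 200, seed = 5, variationMode = "mixed",
                         sensorCV = 0.1, effectorCV = 0.25)
  samp <- simulateEquilibriumCohort(spec)
  d <- parameterDraws(samp)
  pr <- cohortPairs(samp)
  for (i in c(1, 57, 200)) {
    ind <- feedbackSystem("i",
      sensorCurve(d$alpha[i], d$beta[i], "suppressive"),
      effectorCurve(d$p0[i], d$gain[i], d$k[i], "stimulatory"))
    expect_equal(evaluateCurve(sensor(ind), pr$P[i]), pr$H[i],
                 tolerance = 1e-9)
    expect_equal(evaluateCurve(effector(ind), pr$H[i]), pr$P[i],
                 tolerance = 1e-7)
  }
})

test_that("effector-dominant equilibrium cohorts give exact Spearman signs", {
  # all individuals share the sensor curve, so every (P, H) lies on one
  # strictly monotone curve: |rho| = 1 with the sensor direction's sign
  s1 <- simulateEquilibriumCohort(populationSpec(calcium, n = 1000, seed = 1))
  expect_identical(cohortCorrelation(s1, "spearman")$r, -1)
  s2 <- simulateEquilibriumCohort(populationSpec(glucose, n = 1000, seed = 1))
  expect_identical(cohortCorrelation(s2, "spearman")$r, 1)
})

test_that("mixed-mode calcium cohorts keep a negative Pearson correlation", {
  spec <- populationSpec(calcium, n = 2000, seed = 12,
                         variationMode = "mixed",
                         sensorCV = 0.05, effectorCV = 0.3)
  expect_lt(cohortCorrelation(simulateEquilibriumCohort(spec))$r, 0)
})

test_that("set-point cohorts attain their targets through effector inversion", {
  spec <- populationSpec(calcium, n = 500, seed = 31, model = "setpoint")
  samp <- simulateSetpointCohort(spec)
  d <- parameterDraws(samp)
  pr <- cohortPairs(samp)
  expect_identical(pr$P, d$target)
  # targets confined to the invertible band
  expect_true(all(pr$P > d$p0 + 0.05 * d$gain))
  expect_true(all(pr$P < d$p0 + 0.95 * d$gain))
  # P = g(H) holds exactly for each individual's effector curve
  for (i in c(2, 250, 500)) {
    e <- effectorCurve(d$p0[i], d$gain[i], d$k[i], "stimulatory")
    expect_equal(evaluateCurve(e, pr$H[i]), pr$P[i], tolerance = 1e-9)
  }
})

test_that("set-point cohorts with a shared effector are exactly monotone", {
  spec <- populationSpec(calcium, n = 1000, seed = 8, model = "setpoint",
                         variationMode = "sensor_dominant", sensorCV = 0)
  samp <- simulateSetpointCohort(spec)
  expect_identical(cohortCorrelation(samp, "spearman")$r, 1)
})

test_that("set-point correlation signs follow the effector direction", {
  # across seeded replicates and a CV grid, the Pearson sign matches the
  # effector direction in at least 95% of replicates
  for (sysName in c("calcium_pth", "glucose_insulin")) {
    sys <- predefinedSystem(sysName)
    want <- impliedSign(sys, "setpoint")
    for (cv in c(0.05, 0.3)) {
      hits <- 0L
      for (rep in 1:40) {
        spec <- populationSpec(sys, n = 1000, seed = 7000 + rep,
                               model = "setpoint", effectorCV = cv,
                               setpointCV = cv)
        r <- cohortCorrelation(simulateSetpointCohort(spec))$r
        if (sign(r) == want) hits <- hits + 1L
      }
      expect_gte(hits / 40, 0.95)
    }
  }
})

test_that("equilibrium correlation approaches the effector-dominant value as sensor CV shrinks", {
  grid <- c(0.3, 0.15, 0.05)
  meanR <- function(scv) {
    mean(vapply(1:50, function(rep) {
      spec <- if (scv == 0)
        populationSpec(calcium, n = 400, seed = 300 + rep,
                       effectorCV = 0.2)
      else
        populationSpec(calcium, n = 400, seed = 300 + rep,
                       variationMode = "mixed", sensorCV = scv,
                       effectorCV = 0.2)
      cohortCorrelation(simulateEquilibriumCohort(spec))$r
    }, numeric(1)))
  }
  r0 <- meanR(0)
  gaps <- abs(vapply(grid, meanR, numeric(1)) - r0)
  expect_true(all(diff(gaps) < 0))  # shrinking sensor CV closes the gap
})

test_that("cohorts export to CSV with provenance columns", {
  spec <- populationSpec(calcium, n = 10, seed = 2, model = "setpoint")
  path <- withr::local_tempfile(fileext = ".csv")
  exportCohort(simulateSetpointCohort(spec), path)
  back <- read.csv(path)
  expect_identical(names(back), c("id", "P", "H", "model", "seed"))
  expect_identical(unique(back$model), "setpoint")
  expect_identical(unique(back$seed), 2L)
})

test_that("population specs round-trip through the config list form", {
  spec <- populationSpec(glucose, n = 77, seed = 5, model = "setpoint",
                         variationMode = "mixed", sensorCV = 0.07,
                         effectorCV = 0.22, setpointCV = 0.12,
                         epsilon = 0.04)
  back <- populationSpecFromList(populationSpecToList(spec))
  expect_identical(cohortPairs(simulateSetpointCohort(back)),
                   cohortPairs(simulateSetpointCohort(spec)))
})
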