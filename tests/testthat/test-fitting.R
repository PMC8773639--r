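## hand-built miniature dataset: constant-count model with known predictions
flatDataset <- function(red, green, times_h = c(0, 24, 48)) {
  df <- rbind(
    data.frame(condition = "flat", ratio = 1, time_h = times_h,
               channel = "red", count = red, replicate = 1),
    data.frame(condition = "flat", ratio = 1, time_h = times_h,
               channel = "green", count = green, replicate = 1)
  )
  new("GrowthDataset", data = df,
      metadata = list(conditions = list(flat = list(total = 200,
                                                    convention = "S:T"))))
}

test_that("the likelihood matches a hand-summed Gaussian log-density", {
  ## all rates zero -> predicted counts stay at the 100/100 seeding
  obs_r <- c(100, 110, 90)
  obs_g <- c(100, 105, 95)
  ds <- flatDataset(obs_r, obs_g)
  par <- c(K = 0, Kb = 0, KGs0 = 0, KGt0 = 0, Kstr = 0, Kstrd = 0,
           a = 0, b = 0, g = 0)
  byHand <- sum(0.5 * log(2 * pi * 1^2) +
                  (log(c(obs_r, obs_g)) - log(100))^2 / 2)
  expect_equal(negLogLikelihood(par, ds, sigma = 1), byHand, tolerance = 1e-8)

  ## profiled sigma equals the analytic minimum n/2 (log(2 pi SSR/n) + 1)
  ssr <- sum((log(c(obs_r, obs_g)) - log(100))^2)
  expect_equal(negLogLikelihood(par, ds),
               6 / 2 * (log(2 * pi * ssr / 6) + 1), tolerance = 1e-8)
})

test_that("truth minimizes the likelihood of noise-free data", {
  ds0 <- generateDataset(studyDesign("heterotypic", ratios = c(1, 4),
                                     sampleEvery = 12),
                         noiseModel("none"), seed = 1)
  tv <- c(K = 0.049, Kb = 3.57, KGs0 = 0.713, KGt0 = 0.687, Kstr = 7.14e-4,
          Kstrd = 5.64e-3, a = 0.046, b = 0.038, g = 0.018)
  nll0 <- negLogLikelihood(tv, ds0)
  set.seed(9)
  for (i in 1:8) {
    pert <- tv
    j <- sample(length(tv), 1)
    pert[j] <- pert[j] * 1.05 + 1e-4
    expect_gte(negLogLikelihood(pert, ds0), nll0)
  }
})

test_that("non-positive predictions incur a large finite penalty", {
  ds <- flatDataset(c(100, 110, 90), c(100, 105, 95))
  ## enormous stress-driven death collapses counts to the integrator floor
  par <- c(K = 0.1, Kb = 5, KGs0 = 0, KGt0 = 0, Kstr = 0.001, Kstrd = 0,
           a = 0.1, b = 0.1, g = 0.1)
  v <- negLogLikelihood(par, ds, atol = 1e-3)
  expect_true(is.finite(v))
})

test_that("the GA solves standard benchmarks and is seed-reproducible", {
  sphere <- function(x) sum(x^2)
  fit <- gaOptimize(sphere, rep(-5, 9), rep(5, 9), gaConfig(seed = 3))
  expect_lt(fit@value, 1e-2)

  quad <- function(x) (x - 1.234)^2
  fit1 <- gaOptimize(quad, -5, 5, gaConfig(popSize = 40, generations = 80,
                                           seed = 7))
  expect_equal(unname(fit1@par), 1.234, tolerance = 0.05)

  ## determinism under a fixed seed, sensitivity to a different one
  a <- gaOptimize(sphere, rep(-5, 3), rep(5, 3),
                  gaConfig(popSize = 30, generations = 40, seed = 11))
  b <- gaOptimize(sphere, rep(-5, 3), rep(5, 3),
                  gaConfig(popSize = 30, generations = 40, seed = 11))
  c_ <- gaOptimize(sphere, rep(-5, 3), rep(5, 3),
                   gaConfig(popSize = 30, generations = 40, seed = 12))
  expect_identical(a@par, b@par)
  expect_identical(a@trace, b@trace)
  expect_false(identical(a@par, c_@par))

  ## elitist best-so-far never worsens
  expect_true(all(diff(a@trace$best) <= 0))
})

test_that("the GA does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(gaOptimize(function(x) sum(x^2), -1, 1,
                       gaConfig(popSize = 10, generations = 5, seed = 99)))
  expect_identical(runif(3), before)
})

test_that("free-parameter counts are 9 drug-free and 16 with the drug block", {
  expect_length(psmsrParameterNames(FALSE), 9)
  expect_length(psmsrParameterNames(TRUE), 16)
  expect_identical(psmsrParameterNames()[1], "K")
})

test_that("drug conditions lock switching and stress removal in every candidate", {
  ds <- makeFixture("drug-panel")
  fit <- fitCondition(ds, "heterotypic-cisplatin-continuous",
                      gaConfig(popSize = 10, generations = 3, seed = 1))
  expect_length(fit@par, 16)
  expect_false(any(c("Kb", "Kstrd", "a") %in% fit@free))
  expect_identical(unname(fit@par[c("Kb", "Kstrd", "a")]), c(0, 0, 0))
  expect_length(fit@free, 13)

  ## drug-free fits expose all 9 phenotype parameters
  ds2 <- makeFixture("tiny-heterotypic")
  fit2 <- fitCondition(ds2, "heterotypic",
                       gaConfig(popSize = 10, generations = 3, seed = 1))
  expect_identical(fit2@free, psmsrParameterNames())
})

test_that("noise-free panel refits recover the identifiable growth rates", {
  ds0 <- generateDataset(studyDesign("heterotypic", ratios = c(1, 4),
                                     sampleEvery = 12),
                         noiseModel("none"), seed = 1)
  fit <- fitCondition(ds0, "heterotypic",
                      gaConfig(popSize = 40, generations = 60, seed = 5))
  expect_lt(abs(fit@par[["KGs0"]] - 0.713) / 0.713, 0.1)
  expect_lt(abs(fit@par[["KGt0"]] - 0.687) / 0.687, 0.1)
  ## (no likelihood comparison against the truth here: with profiled sigma
  ## the noise-free likelihood is unbounded as the residual sum approaches
  ## zero, so only parameter recovery is meaningful)
})

test_that("profile intervals match the analytic Gaussian case", {
  ## independent quadratic: profiling is exact, CI = est +/- 1.96 se
  obj <- function(th) 0.5 * ((th[["x"]] - 1) / 0.2)^2 +
    0.5 * ((th[["y"]] - 2) / 0.5)^2
  par <- c(x = 1, y = 2)
  bounds <- matrix(c(-10, -10, 10, 10), 2, 2,
                   dimnames = list(c("x", "y"), c("lower", "upper")))
  pr <- likelihoodProfile(obj, par, "x", bounds)
  expect_equal(unname(pr$ci), c(1 - 1.96 * 0.2, 1 + 1.96 * 0.2),
               tolerance = 0.02)
  expect_false(pr$flat)
  ## profile minimum does not exceed the endpoints
  expect_lte(min(pr$profile$nll), min(head(pr$profile$nll, 1),
                                      tail(pr$profile$nll, 1)))
})

test_that("a structurally non-identifiable direction yields a flat flagged profile", {
  ## only the product x*y enters: either factor alone is unconstrained
  obj <- function(th) (th[["x"]] * th[["y"]] - 1)^2
  par <- c(x = 1, y = 1)
  bounds <- matrix(c(0.1, 0.1, 10, 10), 2, 2,
                   dimnames = list(c("x", "y"), c("lower", "upper")))
  pr <- likelihoodProfile(obj, par, "x", bounds)
  expect_true(pr$flat)
  expect_true(all(pr$unbounded))
  expect_equal(unname(pr$ci), c(0.1, 10))
})

test_that("profiles on synthetic data bracket the true growth rate", {
  ds <- makeFixture("tiny-heterotypic")
  fit <- fitCondition(ds, "heterotypic",
                      gaConfig(popSize = 40, generations = 60, seed = 5))
  pr <- profileLikelihood(ds, fit, "KGs0")
  expect_false(pr$flat)
  expect_true(pr$ci[1] <= 0.713 && 0.713 <= pr$ci[2])
  expect_true(pr$ci[1] <= fit@par[["KGs0"]] && fit@par[["KGs0"]] <= pr$ci[2])
})
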