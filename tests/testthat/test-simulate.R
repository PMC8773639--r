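test_that("degenerate and closed-form limits integrate exactly", {
  ## all rates zero: constant trajectory
  tr <- simulateTrajectory(deadParams(), init = seedState(1000, 1),
                           times = seq(0, 6, by = 0.5))
  expect_true(all(abs(sweep(tr@states, 2, tr@states[1, ])) < 1e-9))

  ## pure exponential sensitive growth vs closed form
  p <- PhenotypeParams(K = 0, Kb = 0, KGs0 = 0.7, KGt0 = 0, Kstr = 0,
                       Kstrd = 0, a = 0, b = 0, g = 0)
  tr <- simulateTrajectory(p, init = LineageState(Rs = 1000),
                           times = seq(0, 6, by = 0.25))
  expect_equal(tr@states[, "Rs"], 1000 * exp(0.7 * tr@times), tolerance = 1e-7)
})

test_that("lsoda and the compiled RK45 engine agree", {
  p <- het$phenotype
  a <- simulateTrajectory(p, init = seedState(5000, 2), times = seq(0, 6, by = 0.25))
  b <- simulateTrajectory(p, init = seedState(5000, 2), times = seq(0, 6, by = 0.25),
                          engine = "rk45")
  expect_equal(a@states[, 1:4], b@states[, 1:4], tolerance = 1e-6)
})

test_that("sigmoidal coupling integrates and departs from linear only at high stress", {
  p <- het$phenotype
  lin <- simulateTrajectory(p, init = seedState(5000, 1), times = seq(0, 6, by = 0.5))
  sig <- simulateTrajectory(p, init = seedState(5000, 1), times = seq(0, 6, by = 0.5),
                            coupling = "sigmoidal")
  ## near-identical early (low stress), diverging as stress saturates the maps
  expect_equal(sig@states[3, 1:4], lin@states[3, 1:4], tolerance = 1e-3)
  expect_false(isTRUE(all.equal(sig@states[13, 1:4], lin@states[13, 1:4],
                                tolerance = 1e-4)))
})

test_that("heterotypic co-culture shows the published qualitative shape", {
  tr <- simulateTrajectory(het$phenotype, init = seedState(5000, 1))
  cc <- channelCounts(tr)
  n <- nrow(cc)
  expect_gt(cc$red[n], cc$green[n])   # sensitive-seeded channel ends higher
  expect_gt(cc$Cstr[n], 0)            # stress accumulates
  ## red channel keeps rising throughout
  expect_true(all(diff(cc$red) > 0))
})

test_that("seeding panels share a grid and order final label ratios by seeding", {
  des <- seedingDesign(total = 5000, ratios = c(1, 2, 4, 8), duration = 6,
                       sampleEvery = 4)
  panel <- runSeedingPanel(het$phenotype, des)
  expect_length(panel, 4)
  expect_true(all(vapply(panel, function(t) identical(t@times, panel[[1]]@times),
                         TRUE)))
  ## single-ratio design reduces to one trajectory
  expect_length(runSeedingPanel(het$phenotype, seedingDesign(ratios = 2)), 1)
  ## higher sensitive seeding fraction -> lower final green/red ratio
  finals <- vapply(panel, function(t) tsRatio(t, 144), 0)
  expect_true(all(diff(finals) < 0))
  ## before switching equilibrates, the tolerant:sensitive phenotype ratio
  ## still reflects the seeding composition
  tFrac <- vapply(panel, function(t) {
    cc <- channelCounts(t)
    i <- which(cc$time_h == 12)
    cc$T[i] / cc$S[i]
  }, 0)
  expect_true(all(diff(rev(tFrac)) > 0))
})

test_that("switched fractions start at zero, stay in [0,1] and favor the green lineage", {
  tr <- simulateTrajectory(het$phenotype, init = seedState(5000, 1))
  sf <- switchedFractions(tr)
  expect_equal(sf$tolerantToSensitive[1], 0)
  expect_equal(sf$sensitiveToTolerant[1], 0)
  expect_true(all(sf$tolerantToSensitive >= 0 & sf$tolerantToSensitive <= 1))
  expect_true(all(sf$sensitiveToTolerant >= 0 & sf$sensitiveToTolerant <= 1))
  ## tolerant-seeded cells switch to sensitive far more than the reverse
  expect_gt(max(sf$tolerantToSensitive), max(sf$sensitiveToTolerant))

  ## with switching off both fractions are identically zero
  p0 <- PhenotypeParams(K = 0, Kb = 0, KGs0 = 0.7, KGt0 = 0.2, Kstr = 1e-4,
                        Kstrd = 0, a = 0, b = 0, g = 0)
  sf0 <- switchedFractions(simulateTrajectory(p0, init = seedState(5000, 1)))
  expect_true(all(sf0$tolerantToSensitive == 0))
  expect_true(all(sf0$sensitiveToTolerant == 0))
})

test_that("fold change and T:S ratio readouts behave at their anchors", {
  tr <- simulateTrajectory(deadParams(), init = seedState(2000, 1),
                           times = seq(0, 6, by = 0.5))
  expect_equal(foldChange(tr, 144, "red"), 1)
  expect_equal(tsRatio(tr, 144), 1)

  p <- PhenotypeParams(K = 0, Kb = 0, KGs0 = 0.7, KGt0 = 0, Kstr = 0,
                       Kstrd = 0, a = 0, b = 0, g = 0)
  tr2 <- simulateTrajectory(p, init = LineageState(Rs = 1000),
                            times = seq(0, 6, by = 1 / 24))
  expect_equal(foldChange(tr2, 24 * log(2) / 0.7, "red"), 2, tolerance = 1e-3)

  ## red fold change exceeds green at 144 h in the 1:1 heterotypic panel
  trh <- simulateTrajectory(het$phenotype, init = seedState(5000, 1))
  expect_gt(foldChange(trh, 144, "red"), foldChange(trh, 144, "green"))

  ## extinct red channel: degenerate ratio is flagged
  trx <- simulateTrajectory(deadParams(), init = LineageState(Gt = 100),
                            times = seq(0, 1, by = 0.1))
  expect_warning(v <- tsRatio(trx, 24), "degenerate")
  expect_identical(v, Inf)
})

test_that("back-to-back identical episodes equal one merged episode", {
  two <- doseSchedule(c(0, 2), c(2, 4), 5, "two")
  one <- doseSchedule(0, 4, 5, "one")
  t1 <- simulateTrajectory(hetDrug$phenotype, hetDrug$drug, seedState(5000, 1),
                           two, times = seq(0, 6, by = 0.25))
  t2 <- simulateTrajectory(hetDrug$phenotype, hetDrug$drug, seedState(5000, 1),
                           one, times = seq(0, 6, by = 0.25))
  expect_equal(t1@states, t2@states, tolerance = 1e-6)
})

test_that("an untreated schedule with drug parameters reduces to floor-shifted growth", {
  p <- hetDrug$phenotype
  d <- hetDrug$drug
  tr <- simulateTrajectory(p, d, seedState(5000, 1), untreatedSchedule(),
                           times = seq(0, 6, by = 0.25))
  expect_true(all(tr@states[, "AUC"] == 0))
  ## constant kill floor at AUC = 0 is equivalent to reduced growth rates
  floorS <- d@SCALEs * sigmoidKill(0, d@AUCs5, d@AUCs95)
  floorT <- d@SCALEt * sigmoidKill(0, d@AUCt5, d@AUCt95)
  pAdj <- p
  pAdj@KGs0 <- p@KGs0 - floorS
  pAdj@KGt0 <- p@KGt0 - floorT
  trAdj <- simulateTrajectory(pAdj, NULL, seedState(5000, 1),
                              untreatedSchedule(), times = seq(0, 6, by = 0.25))
  expect_equal(tr@states[, 1:4], trAdj@states[, 1:4], tolerance = 1e-7)
})

test_that("reported counts converge under reporting-grid refinement", {
  p <- het$phenotype
  a <- simulateTrajectory(p, init = seedState(5000, 1), times = seq(0, 6, by = 2 / 24))
  b <- simulateTrajectory(p, init = seedState(5000, 1), times = seq(0, 6, by = 1 / 24))
  sub <- match(round(a@times, 10), round(b@times, 10))
  rel <- abs(a@states[, 1:4] - b@states[sub, 1:4]) /
    pmax(abs(b@states[sub, 1:4]), 1)
  expect_lt(max(rel), 1e-6)
})

test_that("exposure memory modes hold, decay or reset the AUC after washout", {
  p <- hetDrug$phenotype
  d <- hetDrug$drug
  pulse <- doseSchedule(0, 1, 5, "pulse")
  times <- seq(0, 3, by = 0.25)
  hold <- simulateTrajectory(p, d, seedState(5000, 1), pulse, times, aucMode = "hold")
  expect_equal(hold@states[nrow(hold@states), "AUC"], 120, tolerance = 1e-8,
               ignore_attr = TRUE)
  dec <- simulateTrajectory(p, d, seedState(5000, 1), pulse, times,
                            aucMode = "decay", aucHalfLife = 1)
  expect_equal(dec@states[nrow(dec@states), "AUC"], 120 / 4, tolerance = 1e-6,
               ignore_attr = TRUE)
  res <- simulateTrajectory(p, d, seedState(5000, 1), pulse, times, aucMode = "reset")
  expect_equal(res@states[nrow(res@states), "AUC"], 0, ignore_attr = TRUE)
  ## AUC at the washout boundary itself is recorded before the reset
  expect_equal(res@states[res@times == 1, "AUC"], 120, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("therapy regimens order the final tolerant:sensitive ratio", {
  scheds <- therapySchedules(conc = 5, horizon = 8)
  expect_named(scheds, c("untreated", "intermittent-1", "intermittent-2",
                         "continuous"))
  finals <- suppressWarnings(vapply(names(scheds), function(nm) {
    tr <- simulateTrajectory(hetDrug$phenotype, hetDrug$drug,
                             seedState(50000, 4), scheds[[nm]],
                             times = seq(0, 8, by = 0.25), condition = nm)
    tsRatio(tr, 8 * 24)
  }, 0))
  expect_gte(finals["continuous"], finals["intermittent-2"])
  expect_gte(finals["intermittent-2"], finals["intermittent-1"])
  expect_gte(finals["intermittent-1"], finals["untreated"])
})

test_that("trajectories export tidily", {
  tr <- simulateTrajectory(het$phenotype, init = seedState(5000, 2),
                           condition = "het", ratio = 2,
                           times = seq(0, 2, by = 0.5))
  df <- as.data.frame(tr)
  expect_named(df, c("condition", "ratio", "time_h", "red", "green", "S", "T",
                     "Cstr", "AUC"))
  expect_equal(df$red + df$green, df$S + df$T, tolerance = 1e-9)
})
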