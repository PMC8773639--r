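test_that("sigmoid kill curve is anchored at its 5% and 95% exposures", {
  expect_equal(sigmoidKill(239, 239, 1153), 0.05, tolerance = 1e-12)
  expect_equal(sigmoidKill(1153, 239, 1153), 0.95, tolerance = 1e-12)
  ## midpoint symmetry and limits
  expect_equal(sigmoidKill((239 + 1153) / 2, 239, 1153), 0.5, tolerance = 1e-12)
  expect_equal(sigmoidKill(1e9, 239, 1153), 1)
  expect_equal(sigmoidKill(-1e9, 239, 1153), 0)
  ## strictly increasing
  auc <- seq(-200, 2000, by = 25)
  expect_true(all(diff(sigmoidKill(auc, 239, 1153)) > 0))
  expect_error(sigmoidKill(100, 500, 500), "AUC5")
})

test_that("stress-coupled rates follow the linear laws and their contracts", {
  p <- het$phenotype
  r0 <- stressCoupledRates(p, 0)
  expect_equal(r0$KGS, 0.713)                      # baseline sensitive growth
  expect_equal(r0$K, 0.049)                        # zero-stress identity
  expect_equal(r0$Ka, 0.049 * 3.57)
  r10 <- stressCoupledRates(p, 10)
  expect_equal(r10$K, 0.229)
  expect_equal(r10$Ka, 0.81753)
  expect_equal(r10$KGS, 0.713 - 0.46)
  ## effective growth may go negative under high stress (net death)
  expect_lt(stressCoupledRates(p, 100)$KGS, 0)
  expect_error(stressCoupledRates(p, -1), "non-negative")
})

test_that("both coupling modes are monotone and agree in value and slope at zero stress", {
  p <- het$phenotype
  cs <- seq(0, 50, by = 0.5)
  for (mode in c("linear", "sigmoidal")) {
    rs <- lapply(cs, function(C) stressCoupledRates(p, C, mode))
    expect_true(all(diff(vapply(rs, function(r) r$KGS, 0)) <= 0))
    expect_true(all(diff(vapply(rs, function(r) r$KGT, 0)) <= 0))
    expect_true(all(diff(vapply(rs, function(r) r$K, 0)) >= 0))
    expect_true(all(diff(vapply(rs, function(r) r$Ka, 0)) >= 0))
  }
  h <- 1e-6
  lin0 <- stressCoupledRates(p, h, "linear")
  sig0 <- stressCoupledRates(p, h, "sigmoidal")
  expect_equal(sig0$KGS, lin0$KGS, tolerance = 1e-8)  # matching slope at 0
  expect_equal(sig0$KGT, lin0$KGT, tolerance = 1e-8)
  expect_equal(sig0$K, lin0$K, tolerance = 1e-8)
  ## sigmoidal growth rates saturate instead of going negative
  expect_gte(stressCoupledRates(p, 1e4, "sigmoidal")$KGS, 0)
})

test_that("kill rates require drug parameters and scale the sigmoid", {
  p <- hetDrug$phenotype
  d <- hetDrug$drug
  r <- stressCoupledRates(p, 0, drug = d, AUC = 239)
  expect_equal(r$deathS, 8.61 * 0.05, tolerance = 1e-12)
  expect_equal(stressCoupledRates(p, 0)$deathS, 0)
  expect_error(DrugParams(100, 500, 400, 8, 233, 1201, 5), "AUCs5")
})

test_that("the switch equilibrium constant ties the forward and backward rates", {
  set.seed(1)
  for (i in 1:20) {
    p <- PhenotypeParams(K = runif(1, 0, 0.1), Kb = runif(1, 0, 5),
                         KGs0 = runif(1, 0, 2), KGt0 = runif(1, 0, 2),
                         Kstr = runif(1, 0, 1e-3), Kstrd = runif(1, 0, 0.02),
                         a = runif(1, 0, 0.1), b = runif(1, 0, 0.1),
                         g = runif(1, 0, 0.1))
    C <- runif(1, 0, 30)
    r <- stressCoupledRates(p, C)
    expect_identical(r$Ka, r$K * p@Kb)
  }
})

test_that("the RHS reproduces the stress balance and single-term fluxes", {
  p <- het$phenotype
  expect_equal(psmsrRHS(LineageState(Rs = 5000), p)[["Cstr"]], 3.57)
  ## a lone tolerant green population feeds Gs at rate Kb
  p0 <- switchOnlyParams()
  d <- psmsrRHS(LineageState(Gt = 1000), p0)
  expect_equal(d[["Gs"]], 3.57 * 1000)
  expect_equal(d[["Rs"]], 0)
})

test_that("switching alone conserves the total population", {
  set.seed(2)
  p0 <- switchOnlyParams()
  for (i in 1:10) {
    d <- psmsrRHS(randomState(), p0)
    expect_equal(sum(d[c("Rs", "Rt", "Gs", "Gt")]), 0, tolerance = 1e-10)
  }
})

test_that("label-summed RHS equals the two-variable phenotype-total equations", {
  set.seed(3)
  p <- het$phenotype
  d <- hetDrug$drug
  for (i in 1:10) {
    st <- randomState()
    conc <- sample(c(0, 5), 1)
    dv <- psmsrRHS(st, p, drug = d, conc = conc)
    S <- st@Rs + st@Gs
    T <- st@Rt + st@Gt
    r <- stressCoupledRates(p, st@Cstr, drug = d, AUC = st@AUC)
    dS <- -r$Ka * S + p@Kb * T + r$KGS * S - r$deathS * S
    dT <- r$Ka * S - p@Kb * T + r$KGT * T - r$deathT * T
    expect_equal(dv[["Rs"]] + dv[["Gs"]], dS, tolerance = 1e-12)
    expect_equal(dv[["Rt"]] + dv[["Gt"]], dT, tolerance = 1e-12)
    ## bookkeeping identity: label totals and phenotype totals agree
    expect_identical(st@Rs + st@Rt + st@Gs + st@Gt, S + T)
  }
})

test_that("the compiled RHS matches the R reference implementation", {
  set.seed(4)
  p <- hetDrug$phenotype
  d <- hetDrug$drug
  for (conc in c(0, 5)) {
    st <- randomState()
    ref <- psmsrRHS(st, p, drug = d, conc = conc)
    pv <- psmsr:::.parvec(p, d, conc = conc, drugOn = conc > 0)
    cmp <- psmsr:::.rhs_compiled(psmsr:::.state_to_vec(st), pv)
    expect_equal(unname(cmp), unname(ref), tolerance = 1e-12)
  }
})

test_that("AUC accumulates at 24 x concentration while drug is on", {
  p <- het$phenotype
  d <- hetDrug$drug
  expect_equal(psmsrRHS(LineageState(Rs = 1), p, drug = d, conc = 5)[["AUC"]],
               120)
  expect_equal(psmsrRHS(LineageState(Rs = 1), p, drug = d, conc = 0)[["AUC"]],
               0)
  ## decay mode removes exposure memory after washout
  expect_lt(psmsrRHS(LineageState(Rs = 1, AUC = 100), p, drug = d, conc = 0,
                     aucDecay = log(2))[["AUC"]], 0)
})

test_that("stress has a reflecting boundary and an optional drug source", {
  p <- het$phenotype
  ## tolerant-majority culture at zero stress: removal cannot push Cstr < 0
  expect_identical(psmsrRHS(LineageState(Gt = 5000), p)[["Cstr"]], 0)
  ## but removal acts as soon as stress is present
  expect_lt(psmsrRHS(LineageState(Gt = 5000, Cstr = 1), p)[["Cstr"]], 0)
  ## optional Sdrug coupling adds a stress source while drug is on
  d <- hetDrug$drug
  base <- psmsrRHS(LineageState(Rs = 100), p, drug = d, conc = 5)[["Cstr"]]
  plus <- psmsrRHS(LineageState(Rs = 100), p, drug = d, conc = 5,
                   sdrugStress = TRUE)[["Cstr"]]
  expect_equal(plus - base, d@Sdrug)
  ## with the drug absent the coupling is inert
  off <- psmsrRHS(LineageState(Rs = 100), p, drug = d, conc = 0,
                  sdrugStress = TRUE)[["Cstr"]]
  expect_equal(off, psmsrRHS(LineageState(Rs = 100), p, drug = d,
                             conc = 0)[["Cstr"]])
})

test_that("state and parameter validity is enforced", {
  expect_error(LineageState(Rs = -1), "non-negative")
  expect_error(PhenotypeParams(K = -0.1, Kb = 1, KGs0 = 1, KGt0 = 1,
                               Kstr = 0, Kstrd = 0, a = 0, b = 0, g = 0),
               "non-negative")
  expect_s4_class(lockDrugCondition(het$phenotype), "PhenotypeParams")
  pl <- lockDrugCondition(het$phenotype)
  expect_identical(pl@Kb, 0)
  expect_identical(pl@Kstrd, 0)
  expect_identical(pl@a, 0)
})
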