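## shared fixtures built in code

het <- presetParams("heterotypic")
hetDrug <- presetParams("heterotypic-cisplatin")

## switching only: growth, stress couplings of growth, and drug off
switchOnlyParams <- function(K = 0.049, Kb = 3.57, Kstr = 7.14e-4,
                             Kstrd = 5.64e-3, g = 0.018) {
  PhenotypeParams(K = K, Kb = Kb, KGs0 = 0, KGt0 = 0, Kstr = Kstr,
                  Kstrd = Kstrd, a = 0, b = 0, g = g)
}

deadParams <- function() {
  PhenotypeParams(K = 0, Kb = 0, KGs0 = 0, KGt0 = 0, Kstr = 0, Kstrd = 0,
                  a = 0, b = 0, g = 0)
}

randomState <- function() {
  LineageState(Rs = runif(1, 0, 1e4), Rt = runif(1, 0, 1e4),
               Gs = runif(1, 0, 1e4), Gt = runif(1, 0, 1e4),
               Cstr = runif(1, 0, 20), AUC = runif(1, 0, 800))
}

## simulate a two-species competitive LV system and wrap it as a Trajectory
## (species 1 -> red, species 2 -> green); independent of the PSMSR code path
lvTrajectory <- function(lv, N0 = c(5000, 3000), duration = 6, by = 0.01) {
  times <- seq(0, duration, by = by)
  sol <- deSolve::ode(
    y = N0, times = times,
    func = function(t, y, parms) list(lvRHS(y[1], y[2], lv)),
    parms = NULL, rtol = 1e-10, atol = 1e-10
  )
  st <- cbind(Rs = sol[, 2], Rt = 0, Gs = 0, Gt = sol[, 3], Cstr = 0, AUC = 0)
  new("Trajectory", times = times, states = st, condition = "lv", ratio = 1,
      metadata = list())
}
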