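#' Construct a dosing schedule
#'
#' @param start,end episode start/end times in days (equal-length vectors).
#' @param conc cisplatin concentration in uM per episode (recycled).
#' @param label regimen label.
#' @return A [DoseSchedule-class] object.
#' @examples
#' doseSchedule(start = c(0, 6), end = c(2, 10), conc = 5, label = "intermittent-2")
#' @export
doseSchedule <- function(start = numeric(), end = numeric(), conc = numeric(),
                         label = "custom") {
  ep <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   conc = rep_len(as.numeric(conc), length(start)))
  ep <- ep[order(ep$start), , drop = FALSE]
  rownames(ep) <- NULL
  new("DoseSchedule", episodes = ep, label = label)
}

#' @rdname doseSchedule
#' @export
untreatedSchedule <- function() doseSchedule(label = "untreated")

#' @rdname doseSchedule
#' @param duration horizon of continuous exposure in days.
#' @export
continuousSchedule <- function(conc = 5, duration = 12) {
  doseSchedule(start = 0, end = duration, conc = conc, label = "continuous")
}

#' Standard therapy regimens
#'
#' The four regimens compared in the therapy simulations: untreated;
#' continuous exposure over the whole horizon; a single two-day pulse
#' (intermittent, 1 cycle); and the two-day pulse followed by one extra
#' four-day episode after a recovery gap (intermittent, 2 cycles). The pulse
#' lengths follow the published protocol; the remaining day-level boundaries
#' are configurable defaults documented as approximations (two-day recovery,
#' eight-day horizon containing all episodes).
#'
#' @param conc cisplatin concentration (uM).
#' @param horizon total simulated duration (days).
#' @param firstCycle start/end (days) of the first two-day pulse.
#' @param secondCycle start/end (days) of the extra four-day episode.
#' @return Named list of [DoseSchedule-class] objects
#'   (untreated, intermittent-1, intermittent-2, continuous).
#' @export
therapySchedules <- function(conc = 5, horizon = 8, firstCycle = c(0, 2),
                             secondCycle = c(4, 8)) {
  list(
    "untreated" = untreatedSchedule(),
    "intermittent-1" = doseSchedule(firstCycle[1], firstCycle[2], conc,
                                    label = "intermittent-1"),
    "intermittent-2" = doseSchedule(c(firstCycle[1], secondCycle[1]),
                                    c(firstCycle[2], secondCycle[2]), conc,
                                    label = "intermittent-2"),
    "continuous" = continuousSchedule(conc, horizon)
  )
}

#' Construct a seeding panel design
#'
#' @param total total seeded cells per culture (default 5000).
#' @param ratios seeding ratios r (r:1), default \code{c(1, 2, 4, 8)}.
#' @param duration duration in days (default 6, i.e. 144 h).
#' @param sampleEvery imaging interval in hours (default 2).
#' @param convention "S:T" (red:green = r:1) or "T:S".
#' @return A [SeedingDesign-class] object.
#' @export
seedingDesign <- function(total = 5000, ratios = c(1, 2, 4, 8), duration = 6,
                          sampleEvery = 2, convention = c("S:T", "T:S")) {
  convention <- match.arg(convention)
  new("SeedingDesign", total = total, ratios = ratios, duration = duration,
      sampleEvery = sampleEvery, convention = convention)
}

## concentration in force at time t (start-inclusive, end-exclusive)
.conc_at <- function(schedule, t) {
  ep <- schedule@episodes
  hit <- which(ep$start <= t & t < ep$end)
  if (length(hit)) ep$conc[hit[1]] else 0
}

#' Simulate a PSMSR trajectory
#'
#' Integrates the lineage-resolved model over a dosing schedule. The drug
#' concentration is piecewise constant; integration restarts at every episode
#' boundary. The default engine is the stiff-safe adaptive lsoda solver
#' (rtol = atol = 1e-8); "rk45" selects the package's compiled Dormand-Prince
#' 5(4) integrator, used internally by the fitting objective.
#'
#' @param p a [PhenotypeParams-class] object.
#' @param drug optional [DrugParams-class]; enables the kill terms.
#' @param init a [LineageState-class] initial state (see [seedState()]).
#' @param schedule a [DoseSchedule-class]; default untreated.
#' @param times reporting times in days (default 2-hourly over 144 h).
#' @param coupling "linear" or "sigmoidal" stress coupling.
#' @param aucMode exposure memory after washout: "hold" (default; AUC is kept,
#'   the literal memory-effect reading), "decay" (exponential with
#'   \code{aucHalfLife}), or "reset" (AUC zeroed at each episode end).
#' @param aucHalfLife half-life in days for \code{aucMode = "decay"}.
#' @param sdrugStress couple Sdrug as a stress source while drug is on?
#' @param engine "lsoda" or "rk45".
#' @param rtol,atol integrator tolerances.
#' @param condition,ratio labels stored on the trajectory.
#' @return A [Trajectory-class] object.
#' @examples
#' p <- presetParams("heterotypic")$phenotype
#' tr <- simulateTrajectory(p, init = seedState(5000, 1))
#' head(channelCounts(tr))
#' @export
simulateTrajectory <- function(p, drug = NULL, init,
                               schedule = untreatedSchedule(),
                               times = seq(0, 6, by = 2 / 24),
                               coupling = c("linear", "sigmoidal"),
                               aucMode = c("hold", "decay", "reset"),
                               aucHalfLife = 1, sdrugStress = FALSE,
                               engine = c("lsoda", "rk45"),
                               rtol = 1e-8, atol = 1e-8,
                               condition = "sim", ratio = NA_real_) {
  coupling <- match.arg(coupling)
  aucMode <- match.arg(aucMode)
  engine <- match.arg(engine)
  stopifnot(is(p, "PhenotypeParams"), is(init, "LineageState"),
            is(schedule, "DoseSchedule"))
  validObject(p)
  validObject(init)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing with at least two points")
  }
  aucDecay <- if (aucMode == "decay") log(2) / aucHalfLife else 0

  t0 <- times[1]
  t1 <- times[length(times)]
  ep <- schedule@episodes
  bnd <- sort(unique(c(t0, t1, ep$start, ep$end)))
  bnd <- bnd[bnd >= t0 & bnd <= t1]

  y <- unname(.state_to_vec(init))
  out <- matrix(NA_real_, nrow = length(times), ncol = 6,
                dimnames = list(NULL, .STATE_NAMES))
  out[1, ] <- y

  for (i in seq_len(length(bnd) - 1)) {
    s0 <- bnd[i]
    s1 <- bnd[i + 1]
    conc <- .conc_at(schedule, s0)
    pv <- .parvec(p, drug, conc = conc, drugOn = conc > 0, coupling = coupling,
                  aucDecay = aucDecay, sdrugCouple = sdrugStress)
    inner <- times[times > s0 & times < s1]
    segt <- unique(c(s0, inner, s1))
    seg <- .integrate_segment(y, segt, pv, engine, rtol, atol)
    if (any(!is.finite(seg))) {
      bad <- which(!apply(is.finite(seg), 1, all))[1]
      stop(sprintf(
        "integration failed near t = %.4g days (condition '%s', KGs0 = %g, KGt0 = %g)",
        segt[bad], condition, p@KGs0, p@KGt0
      ))
    }
    keep <- match(times[times > s0 & times <= s1], segt)
    out[which(times > s0 & times <= s1), ] <- seg[keep, , drop = FALSE]
    y <- seg[nrow(seg), ]
    if (aucMode == "reset" && any(abs(ep$end - s1) < 1e-12)) y[6] <- 0
  }

  ## tiny negative excursions from the integrator are clamped to zero
  out[, 1:4][out[, 1:4] < 0 & out[, 1:4] > -1e-3] <- 0

  new("Trajectory",
    times = times, states = out, condition = condition, ratio = ratio,
    metadata = list(
      phenotype = p, drug = drug, schedule = schedule, coupling = coupling,
      aucMode = aucMode, aucHalfLife = aucHalfLife, sdrugStress = sdrugStress,
      engine = engine, rtol = rtol, atol = atol
    )
  )
}

.integrate_segment <- function(y, segt, pv, engine, rtol, atol) {
  if (length(segt) == 1) return(matrix(y, nrow = 1))
  if (engine == "rk45") {
    .Call(C_psmsr_panel, as.numeric(y), as.numeric(segt), as.numeric(pv),
          rtol, atol)
  } else {
    sol <- deSolve::ode(
      y = y, times = segt, func = "psmsr_derivs", parms = pv,
      dllname = "psmsr", initfunc = "psmsr_initmod",
      method = "lsoda", rtol = rtol, atol = atol
    )
    unname(sol[, -1, drop = FALSE])
  }
}

#' Simulate a seeding panel
#'
#' One trajectory per seeding ratio, identical parameters and schedule across
#' the panel, on a shared time grid.
#'
#' @param p a [PhenotypeParams-class] object.
#' @param design a [SeedingDesign-class].
#' @param schedule a [DoseSchedule-class]; default untreated.
#' @param drug optional [DrugParams-class].
#' @param ... further arguments to [simulateTrajectory()].
#' @return Named list of [Trajectory-class] objects ("r:1" per ratio).
#' @export
runSeedingPanel <- function(p, design = seedingDesign(),
                            schedule = untreatedSchedule(), drug = NULL, ...) {
  stopifnot(is(design, "SeedingDesign"))
  validObject(design)
  times <- seq(0, design@duration, by = design@sampleEvery / 24)
  trajs <- lapply(design@ratios, function(r) {
    simulateTrajectory(
      p, drug = drug, init = seedState(design@total, r, design@convention),
      schedule = schedule, times = times, ratio = r, ...
    )
  })
  names(trajs) <- sprintf("%g:1", design@ratios)
  trajs
}

#' Per-channel counts and derived series of a trajectory
#'
#' @param traj a [Trajectory-class] object.
#' @return data.frame with columns \code{time_h}, \code{red}, \code{green}
#'   (label totals), \code{S}, \code{T} (phenotype totals), \code{Cstr},
#'   \code{AUC}.
#' @export
channelCounts <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  st <- traj@states
  data.frame(
    time_h = traj@times * 24,
    red = st[, "Rs"] + st[, "Rt"],
    green = st[, "Gs"] + st[, "Gt"],
    S = st[, "Rs"] + st[, "Gs"],
    T = st[, "Rt"] + st[, "Gt"],
    Cstr = st[, "Cstr"],
    AUC = st[, "AUC"]
  )
}

#' Switched-phenotype fractions over time
#'
#' Fraction of each labelled lineage found in the opposite phenotype: for the
#' green (tolerant-seeded) lineage the fraction that has switched to the
#' sensitive phenotype, Gs/(Gs+Gt), and for the red (sensitive-seeded) lineage
#' the fraction switched to tolerant, Rt/(Rs+Rt). Times where a lineage is
#' absent give NA.
#'
#' @param traj a [Trajectory-class] object.
#' @return data.frame with columns \code{time_h}, \code{tolerantToSensitive},
#'   \code{sensitiveToTolerant}, values in [0, 1] or NA.
#' @export
switchedFractions <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  st <- traj@states
  R <- st[, "Rs"] + st[, "Rt"]
  G <- st[, "Gs"] + st[, "Gt"]
  data.frame(
    time_h = traj@times * 24,
    tolerantToSensitive = ifelse(G > 0, st[, "Gs"] / G, NA_real_),
    sensitiveToTolerant = ifelse(R > 0, st[, "Rt"] / R, NA_real_)
  )
}

.channel_at <- function(traj, t_h, channel) {
  cc <- channelCounts(traj)
  if (t_h < min(cc$time_h) - 1e-9 || t_h > max(cc$time_h) + 1e-9) {
    stop("time outside trajectory range")
  }
  stats::approx(cc$time_h, cc[[channel]], xout = t_h)$y
}

#' Fold change of a channel relative to seeding
#'
#' @param traj a [Trajectory-class] object.
#' @param t time in hours.
#' @param channel "red", "green", "S" or "T".
#' @return count(t) / count(0); errors if the channel is empty at t = 0.
#' @export
foldChange <- function(traj, t, channel = c("red", "green", "S", "T")) {
  channel <- match.arg(channel)
  c0 <- .channel_at(traj, min(traj@times) * 24, channel)
  if (c0 <= 0) stop(sprintf("channel '%s' empty at t = 0", channel))
  .channel_at(traj, t, channel) / c0
}

#' Tolerant-to-sensitive label-count ratio
#'
#' Ratio of green (tolerant-seeded) to red (sensitive-seeded) label counts at
#' a time point, the experimental T:S readout. If the red channel is extinct
#' the ratio is undefined and NA is returned with a warning.
#'
#' @param traj a [Trajectory-class] object.
#' @param t time in hours.
#' @return green/red label-count ratio; Inf (with a warning) when only the
#'   red channel is extinct, NA when both are.
#' @export
tsRatio <- function(traj, t) {
  red <- .channel_at(traj, t, "red")
  green <- .channel_at(traj, t, "green")
  if (red <= 0) {
    warning("red channel extinct; T:S ratio degenerate")
    return(if (green > 0) Inf else NA_real_)
  }
  green / red
}

#' @describeIn Trajectory-class tidy export (condition, ratio, time_h, red,
#'   green, S, T, Cstr, AUC)
#' @param x a Trajectory.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "Trajectory", function(x, ...) {
  cbind(
    data.frame(condition = x@condition, ratio = x@ratio),
    channelCounts(x)
  )
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory '%s'%s: %d time points over %.3g days\n",
    object@condition,
    if (is.na(object@ratio)) "" else sprintf(" (ratio %g:1)", object@ratio),
    length(object@times), diff(range(object@times))
  ))
  cc <- channelCounts(object)
  cat(sprintf(
    "  final counts: red %.4g, green %.4g; Cstr %.4g, AUC %.4g\n",
    cc$red[nrow(cc)], cc$green[nrow(cc)], cc$Cstr[nrow(cc)], cc$AUC[nrow(cc)]
  ))
})

setMethod("show", "DoseSchedule", function(object) {
  cat(sprintf("DoseSchedule '%s': %d episode(s)\n", object@label,
              nrow(object@episodes)))
  if (nrow(object@episodes)) print(object@episodes)
})

setMethod("show", "SeedingDesign", function(object) {
  cat(sprintf(
    "SeedingDesign: total %g cells, ratios %s (%s), %g days sampled every %g h\n",
    object@total, paste(object@ratios, collapse = ","), object@convention,
    object@duration, object@sampleEvery
  ))
})
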