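## Likelihood machinery: lognormal multiplicative observation error on the
## per-channel counts, i.e. Gaussian residuals on log counts, with the noise
## SD profiled out analytically unless supplied.

## bounded quasi-Newton with per-parameter gradient steps and scaling;
## parameter ranges span five orders of magnitude, so optim's default
## absolute ndeps would be useless for the small-scale rates
.optim_box <- function(par, fn, lower, upper, maxit = 200) {
  rng <- pmax(upper - lower, 1e-12)
  res <- try(stats::optim(
    par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = maxit, parscale = rng,
                   ndeps = pmax(1e-5 * rng, 1e-12))
  ), silent = TRUE)
  if (inherits(res, "try-error")) list(par = par, value = fn(par)) else res
}

## numeric-only parameter vector builder (hot path; see .parvec for the
## S4-typed version)
.parvec_raw <- function(ph, dr = NULL, conc = 0, drugOn = FALSE, sigm = FALSE,
                        aucDecay = 0, sdrug = FALSE) {
  c(ph,
    if (is.null(dr)) rep(0, 7) else dr,
    conc, as.numeric(drugOn), as.numeric(!is.null(dr)), as.numeric(sigm),
    aucDecay, as.numeric(sdrug), ph[3], ph[4], ph[1])
}

## Split a condition's records into simulation groups: series sharing a time
## grid are stacked into one panel integration. Returns a list of groups with
## elements times (days), inits (6 x m matrix), obs (nt x 2m, red/green
## interleaved as red_1, green_1, red_2, ...), mask (which channels observed).
.prep_condition <- function(ds, condition) {
  df <- ds@data[ds@data$condition == condition, , drop = FALSE]
  if (!nrow(df)) stop(sprintf("condition '%s' not present in dataset", condition))
  meta <- ds@metadata$conditions[[condition]]
  schedule <- if (!is.null(meta$schedule)) meta$schedule else untreatedSchedule()

  keys <- unique(df[, c("ratio", "replicate")])
  series <- lapply(seq_len(nrow(keys)), function(i) {
    sd_ <- df[df$ratio %in% keys$ratio[i] & df$replicate == keys$replicate[i], ]
    th <- sort(unique(sd_$time_h))
    red <- sd_$count[sd_$channel == "red"][match(th, sd_$time_h[sd_$channel == "red"])]
    green <- sd_$count[sd_$channel == "green"][match(th, sd_$time_h[sd_$channel == "green"])]
    init <- if (!is.null(meta$mono) && !is.na(meta$mono) && nzchar(meta$mono)) {
      if (meta$mono == "red") LineageState(Rs = meta$total) else LineageState(Gt = meta$total)
    } else if (!is.null(meta$total)) {
      seedState(meta$total, keys$ratio[i],
                if (!is.null(meta$convention)) meta$convention else "S:T")
    } else {
      LineageState(Rs = if (length(red)) red[1] else 0,
                   Gt = if (length(green)) green[1] else 0)
    }
    list(times = th / 24, red = red, green = green,
         init = unname(.state_to_vec(init)))
  })

  sig <- vapply(series, function(s) paste(signif(s$times, 10), collapse = ","), "")
  groups <- lapply(split(series, sig), function(grp) {
    list(
      times = grp[[1]]$times,
      inits = vapply(grp, `[[`, numeric(6), "init"),
      red = vapply(grp, function(s) {
        if (is.null(s$red) || !length(s$red)) rep(NA_real_, length(s$times)) else s$red
      }, numeric(length(grp[[1]]$times))),
      green = vapply(grp, function(s) {
        if (is.null(s$green) || !length(s$green)) rep(NA_real_, length(s$times)) else s$green
      }, numeric(length(grp[[1]]$times)))
    )
  })
  list(groups = unname(groups), schedule = schedule)
}

## Integrate a stacked panel through the schedule with the compiled RK45.
## Returns list(red, green): nt x m matrices, or NULL on integrator failure.
.panel_sim <- function(ph, dr, inits, times, schedule, coupling = "linear",
                       aucMode = "hold", aucHalfLife = 1, rtol = 1e-7,
                       atol = 1e-7) {
  sigm <- coupling == "sigmoidal"
  aucDecay <- if (aucMode == "decay") log(2) / aucHalfLife else 0
  m <- ncol(inits)
  nt <- length(times)
  t0 <- times[1]
  t1 <- times[nt]
  ep <- schedule@episodes
  bnd <- sort(unique(c(t0, t1, ep$start, ep$end)))
  bnd <- bnd[bnd >= t0 & bnd <= t1]

  y <- as.numeric(inits)
  out <- matrix(NA_real_, nt, 6 * m)
  out[1, ] <- y
  for (i in seq_len(length(bnd) - 1)) {
    s0 <- bnd[i]
    s1 <- bnd[i + 1]
    conc <- .conc_at(schedule, s0)
    pv <- .parvec_raw(ph, dr, conc = conc, drugOn = conc > 0, sigm = sigm,
                      aucDecay = aucDecay)
    inner <- times[times > s0 & times < s1]
    segt <- unique(c(s0, inner, s1))
    seg <- .Call(C_psmsr_panel, y, segt, pv, rtol, atol)
    if (any(!is.finite(seg[nrow(seg), ]))) return(NULL)
    keep <- match(times[times > s0 & times <= s1], segt)
    out[which(times > s0 & times <= s1), ] <- seg[keep, , drop = FALSE]
    y <- seg[nrow(seg), ]
    if (aucMode == "reset" && any(abs(ep$end - s1) < 1e-12)) {
      y[seq(6, 6 * m, by = 6)] <- 0
    }
  }
  idx <- (seq_len(m) - 1) * 6
  list(red = out[, idx + 1, drop = FALSE] + out[, idx + 2, drop = FALSE],
       green = out[, idx + 3, drop = FALSE] + out[, idx + 4, drop = FALSE])
}

#' Negative log-likelihood of a parameter set
#'
#' Gaussian likelihood on log-transformed per-channel counts (equivalently a
#' lognormal multiplicative error model). With \code{sigma = NULL} the noise
#' SD is profiled out analytically per dataset: the returned value is the
#' minimum over sigma of the negative log-likelihood,
#' n/2 (log(2 pi SSR/n) + 1). A simulated count that is non-positive (or an
#' integrator failure) at an observation point yields a large finite penalty
#' rather than NaN. Deterministic given parameters and data.
#'
#' @param par named numeric vector of model parameters (the 9 drug-free names,
#'   plus the 7 drug-block names for drug conditions; see
#'   [psmsrParameterNames()]).
#' @param data a [GrowthDataset-class].
#' @param condition condition tag to evaluate (default: the only condition in
#'   the data).
#' @param sigma fixed log-scale noise SD, or NULL to profile it out.
#' @param coupling "linear" or "sigmoidal".
#' @param aucMode,aucHalfLife exposure memory handling (see
#'   [simulateTrajectory()]).
#' @param rtol,atol tolerances of the compiled integrator.
#' @param penalty finite value returned when a predicted count is non-positive
#'   at an observation point (default 1e8).
#' @return Scalar negative log-likelihood (lower is better).
#' @export
negLogLikelihood <- function(par, data, condition = NULL, sigma = NULL,
                             coupling = c("linear", "sigmoidal"),
                             aucMode = "hold", aucHalfLife = 1,
                             rtol = 1e-7, atol = 1e-7, penalty = 1e8) {
  coupling <- match.arg(coupling)
  stopifnot(is(data, "GrowthDataset"))
  if (is.null(condition)) {
    condition <- unique(data@data$condition)
    if (length(condition) != 1) stop("specify 'condition' for multi-condition data")
  }
  prep <- .prep_condition(data, condition)
  obj <- .make_nll(prep, drug = any(psmsrParameterNames(TRUE)[10:16] %in% names(par)),
                   sigma = sigma, coupling = coupling, aucMode = aucMode,
                   aucHalfLife = aucHalfLife, rtol = rtol, atol = atol,
                   penalty = penalty)
  obj(par)
}

## Build the fast closure: par (named, full layout) -> NLL.
.make_nll <- function(prep, drug, sigma = NULL, coupling = "linear",
                      aucMode = "hold", aucHalfLife = 1, rtol = 1e-7,
                      atol = 1e-7, penalty = 1e8) {
  groups <- prep$groups
  schedule <- prep$schedule
  phenoNames <- psmsrParameterNames(FALSE)
  drugNames <- setdiff(psmsrParameterNames(TRUE), phenoNames)
  logobs <- lapply(groups, function(g) {
    lo <- cbind(log(g$red), log(g$green))
    lo[!is.finite(lo)] <- NA
    lo
  })
  nobs <- sum(vapply(logobs, function(x) sum(!is.na(x)), 0L))
  if (!nobs) stop("no positive observations")

  function(par) {
    ph <- unname(par[phenoNames])
    dr <- if (drug) unname(par[drugNames]) else NULL
    if (anyNA(ph) || (drug && anyNA(dr))) stop("parameter vector incomplete")
    if (drug && (dr[2] >= dr[3] || dr[5] >= dr[6])) return(penalty) # AUC5 >= AUC95
    ssr <- 0
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      sim <- .panel_sim(ph, dr, g$inits, g$times, schedule, coupling,
                        aucMode, aucHalfLife, rtol, atol)
      if (is.null(sim)) return(penalty)
      pred <- cbind(sim$red, sim$green)
      lo <- logobs[[i]]
      ok <- !is.na(lo)
      if (any(pred[ok] <= 0)) return(penalty)
      ssr <- ssr + sum((lo[ok] - log(pred[ok]))^2)
    }
    if (!is.finite(ssr)) return(penalty)
    if (is.null(sigma)) {
      nobs / 2 * (log(2 * pi * max(ssr, 1e-300) / nobs) + 1)
    } else {
      nobs / 2 * log(2 * pi * sigma^2) + ssr / (2 * sigma^2)
    }
  }
}

#' Fit one experimental condition
#'
#' Builds the condition's likelihood, applies the condition's parameter
#' locking mask, runs the genetic algorithm over the published search ranges
#' and polishes the best chromosome with bounded quasi-Newton iterations.
#' Conditions whose dosing schedule contains drug episodes are fitted with the
#' 16-parameter drug model and the drug-condition lock (\code{Kb = 0},
#' \code{Kstrd = 0}, \code{a} unused): phenotypic switching and stress removal
#' are turned off under cisplatin.
#'
#' @param data a [GrowthDataset-class].
#' @param condition condition tag present in the data.
#' @param config a [GAConfig-class].
#' @param coupling "linear" or "sigmoidal".
#' @param polish run a bounded L-BFGS-B polish after the GA?
#' @param sigma fixed noise SD or NULL to profile it out.
#' @param bounds optional bounds matrix overriding [searchRanges()].
#' @param ... further arguments to the likelihood (aucMode, rtol, ...).
#' @return A [PSMSRFit-class] tagged with the condition; \code{par} holds all
#'   model parameters (locked ones at their locked value), \code{free} the
#'   optimized subset.
#' @export
fitCondition <- function(data, condition, config = gaConfig(),
                         coupling = c("linear", "sigmoidal"), polish = TRUE,
                         sigma = NULL, bounds = NULL, ...) {
  coupling <- match.arg(coupling)
  stopifnot(is(data, "GrowthDataset"))
  prep <- .prep_condition(data, condition)
  drug <- nrow(prep$schedule@episodes) > 0 &&
    any(prep$schedule@episodes$conc > 0)
  if (is.null(bounds)) bounds <- searchRanges(drug)
  allNames <- psmsrParameterNames(drug)

  lock <- if (drug) c(Kb = 0, Kstrd = 0, a = 0) else numeric()
  free <- setdiff(allNames, names(lock))

  obj <- .make_nll(prep, drug = drug, sigma = sigma, coupling = coupling, ...)
  objFree <- function(theta) {
    names(theta) <- free
    par <- c(theta, lock)[allNames]
    names(par) <- allNames
    obj(par)
  }

  gaFit <- gaOptimize(objFree, bounds[free, "lower"], bounds[free, "upper"],
                      config, names = free)
  theta <- gaFit@par
  value <- gaFit@value

  if (polish) {
    ## two rounds: L-BFGS-B can stop early on this landscape
    for (round in 1:2) {
      pol <- .optim_box(theta, objFree, bounds[free, "lower"],
                        bounds[free, "upper"], maxit = 500)
      if (is.finite(pol$value) && pol$value <= value) {
        theta <- pol$par
        value <- pol$value
      }
    }
  }

  par <- c(theta, lock)[allNames]
  names(par) <- allNames
  tr <- gaFit@trace
  tr$best <- pmin(tr$best, value) # polish may improve the final best
  new("PSMSRFit",
    par = par, free = free, value = value, trace = tr,
    ci = matrix(NA_real_, length(allNames), 2,
                dimnames = list(allNames, c("lower", "upper"))),
    seed = config@seed, condition = condition,
    details = list(config = config, lock = lock, drug = drug,
                   coupling = coupling, bounds = bounds, sigma = sigma,
                   likArgs = list(...))
  )
}

#' Profile likelihood over one objective coordinate
#'
#' Generic profiling engine: for each grid value of one coordinate, all other
#' free coordinates are re-optimized (bounded quasi-Newton, warm-started from
#' the optimum) and the 95% confidence interval is read off where twice the
#' log-likelihood drop crosses the chi-squared(1) 0.95 quantile (3.84), by
#' linear interpolation. A profile that stays essentially flat is flagged
#' non-identifiable and the corresponding interval side is unbounded
#' (reported at the parameter bound).
#'
#' @param objective function of the full free parameter vector.
#' @param par named optimum of \code{objective}.
#' @param param name of the coordinate to profile.
#' @param bounds matrix with rownames = names(par), columns lower/upper.
#' @param grid grid of values for \code{param}; NULL builds an adaptive grid
#'   from the local curvature.
#' @param value objective at \code{par} (recomputed if NULL).
#' @param maxit re-optimization iteration cap per grid point.
#' @param flatTol profile ranges below this are declared flat.
#' @return list with \code{param}, \code{profile} (data.frame value/nll),
#'   \code{ci} (length-2 vector), \code{flat} (logical), \code{threshold}.
#' @export
likelihoodProfile <- function(objective, par, param, bounds, grid = NULL,
                              value = NULL, maxit = 60, flatTol = 0.01) {
  stopifnot(param %in% names(par))
  free <- names(par)
  others <- setdiff(free, param)
  if (is.null(value)) value <- objective(par)

  reopt <- function(pval, start) {
    fixedObj <- function(theta) {
      full <- c(theta, stats::setNames(pval, param))[free]
      names(full) <- free
      objective(full)
    }
    if (!length(others)) return(list(value = fixedObj(numeric(0)), par = numeric(0)))
    ## two starts: the warm-start chain and the global optimum
    best <- .optim_box(start[others], fixedObj, bounds[others, "lower"],
                       bounds[others, "upper"], maxit = maxit)
    if (max(abs(start[others] - par[others])) > 0) {
      alt <- .optim_box(par[others], fixedObj, bounds[others, "lower"],
                        bounds[others, "upper"], maxit = maxit)
      if (alt$value < best$value) best <- alt
    }
    best
  }

  lo <- bounds[param, "lower"]
  hi <- bounds[param, "upper"]
  est <- par[[param]]

  if (is.null(grid)) {
    ## local curvature -> approximate SE -> grid out to ~4 SE each side
    h <- max(1e-4 * (hi - lo), 1e-10)
    fp <- objective(`[<-`(par, param, min(est + h, hi)))
    fm <- objective(`[<-`(par, param, max(est - h, lo)))
    d2 <- (fp - 2 * value + fm) / h^2
    se <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else (hi - lo) / 8
    steps <- c(0.25, 0.5, 1, 1.5, 2, 3, 4) * 1.96 * se
    grid <- sort(unique(pmin(pmax(c(est - steps, est, est + steps), lo), hi)))
  }

  threshold <- value + stats::qchisq(0.95, df = 1) / 2

  ## walk outward from the estimate, warm-starting each grid point from its
  ## neighbor; keep extending with geometrically growing steps until the
  ## profile crosses the threshold or reaches the parameter bound
  walk <- function(dir) {
    bound <- if (dir > 0) hi else lo
    xs <- if (dir > 0) sort(grid[grid > est]) else sort(grid[grid < est],
                                                        decreasing = TRUE)
    start <- par
    outX <- numeric(0)
    outN <- numeric(0)
    for (x in xs) {
      r <- reopt(x, start)
      outX <- c(outX, x)
      outN <- c(outN, r$value)
      if (length(others)) start[others] <- r$par
    }
    step <- if (length(outX)) max(abs(diff(c(est, outX)))) else (hi - lo) / 16
    extra <- 0L
    while ((!length(outN) || max(outN) < threshold) && extra < 40L) {
      lastX <- if (length(outX)) outX[length(outX)] else est
      if (abs(lastX - bound) < 1e-12) break
      step <- step * 1.7
      x <- if (dir > 0) min(lastX + step, hi) else max(lastX - step, lo)
      r <- reopt(x, start)
      outX <- c(outX, x)
      outN <- c(outN, r$value)
      if (length(others)) start[others] <- r$par
      extra <- extra + 1L
    }
    list(x = outX, nll = outN)
  }
  up <- walk(+1)
  dn <- walk(-1)

  gridAll <- c(rev(dn$x), est, up$x)
  nll <- pmax(c(rev(dn$nll), value, up$nll), value)

  flat <- (max(nll) - min(nll)) < flatTol
  ciSide <- function(xs, ys, bound) {
    ys <- pmax(ys, value)
    cross <- which(ys > threshold)
    if (!length(cross)) return(c(bound, TRUE)) # unbounded side
    j <- cross[1]
    if (j == 1) return(c(xs[1], FALSE))
    c(stats::approx(ys[(j - 1):j], xs[(j - 1):j], xout = threshold,
                    ties = "ordered")$y, FALSE)
  }
  upSide <- ciSide(up$x, up$nll, hi)
  dnSide <- ciSide(dn$x, dn$nll, lo)
  ci <- c(lower = dnSide[1], upper = upSide[1])
  list(param = param, profile = data.frame(value = gridAll, nll = nll),
       ci = ci, flat = flat,
       unbounded = c(lower = dnSide[2] > 0, upper = upSide[2] > 0),
       threshold = threshold)
}

#' Profile-likelihood confidence interval for a fitted condition
#'
#' Rebuilds the fitted condition's likelihood and profiles one parameter (see
#' [likelihoodProfile()]). Locked parameters cannot be profiled.
#'
#' @param data the [GrowthDataset-class] used for the fit.
#' @param fit a [PSMSRFit-class] from [fitCondition()].
#' @param param free parameter name to profile.
#' @param grid optional explicit grid.
#' @param maxit re-optimization iteration cap per grid point.
#' @return As [likelihoodProfile()].
#' @export
profileLikelihood <- function(data, fit, param, grid = NULL, maxit = 60) {
  stopifnot(is(fit, "PSMSRFit"), param %in% fit@free)
  det <- fit@details
  prep <- .prep_condition(data, fit@condition)
  obj <- do.call(.make_nll, c(
    list(prep, drug = det$drug, sigma = det$sigma, coupling = det$coupling),
    det$likArgs
  ))
  lock <- det$lock
  allNames <- names(fit@par)
  free <- fit@free
  objFree <- function(theta) {
    names(theta) <- free
    par <- c(theta, lock)[allNames]
    names(par) <- allNames
    obj(par)
  }
  likelihoodProfile(objFree, fit@par[fit@free], param,
                    det$bounds[fit@free, , drop = FALSE],
                    grid = grid, value = fit@value, maxit = maxit)
}
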