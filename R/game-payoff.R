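#' Construct competitive Lotka-Volterra parameters
#'
#' @param r1,r2 intrinsic growth rates (1/day).
#' @param Kc1,Kc2 carrying capacities (cells).
#' @param alpha12 effect of species 2 on species 1 (positive = competition,
#'   negative = cooperation).
#' @param alpha21 effect of species 1 on species 2.
#' @return An [LVParams-class] object.
#' @export
LVParams <- function(r1, r2, Kc1, Kc2, alpha12, alpha21) {
  new("LVParams", r1 = as.numeric(r1), r2 = as.numeric(r2),
      Kc1 = as.numeric(Kc1), Kc2 = as.numeric(Kc2),
      alpha12 = as.numeric(alpha12), alpha21 = as.numeric(alpha21))
}

setMethod("show", "LVParams", function(object) {
  cat(sprintf(
    "LVParams: r1=%.4g r2=%.4g Kc1=%.4g Kc2=%.4g alpha12=%.4g alpha21=%.4g\n",
    object@r1, object@r2, object@Kc1, object@Kc2, object@alpha12,
    object@alpha21
  ))
})

#' Competitive Lotka-Volterra right-hand side
#'
#' @param N1,N2 species abundances (>= 0).
#' @param lv an [LVParams-class] object.
#' @return Numeric vector \code{c(dN1, dN2)}.
#' @examples
#' lv <- LVParams(1, 0.5, 1e5, 1e5, 0.3, -0.2)
#' lvRHS(1e5, 0, lv)[1]  # at carrying capacity alone: 0
#' @export
lvRHS <- function(N1, N2, lv) {
  stopifnot(is(lv, "LVParams"), N1 >= 0, N2 >= 0)
  c(
    lv@r1 * N1 * (1 - (N1 + lv@alpha12 * N2) / lv@Kc1),
    lv@r2 * N2 * (1 - (N2 + lv@alpha21 * N1) / lv@Kc2)
  )
}

## central differences of log counts: per-capita growth rates at interior
## points; returns list(t, N1, N2, g1, g2)
.percapita_rates <- function(t, N1, N2) {
  n <- length(t)
  i <- 2:(n - 1)
  dt2 <- t[i + 1] - t[i - 1]
  list(
    t = t[i], N1 = N1[i], N2 = N2[i],
    g1 = (log(N1[i + 1]) - log(N1[i - 1])) / dt2,
    g2 = (log(N2[i + 1]) - log(N2[i - 1])) / dt2
  )
}

## fit g = b0 + b1*N1 + b2*N2 for one species; map to (r, Kc, alpha);
## bounded refit when the unconstrained optimum leaves the box
.fit_lv_species <- function(g, Nself, Nother, bounds, nStarts, seed) {
  X <- cbind(1, Nself, Nother)
  ls <- stats::lm.fit(X, g)
  b <- ls$coefficients
  r <- b[1]
  Kc <- -b[1] / b[2]
  alpha <- b[3] / b[2]
  sse <- sum(ls$residuals^2)

  ## regression SE of alpha by the delta method (diagnostic only)
  dof <- length(g) - 3
  seAlpha <- NA_real_
  if (dof > 0 && sse > 0) {
    s2 <- sse / dof
    XtXi <- try(chol2inv(chol(crossprod(X))), silent = TRUE)
    if (!inherits(XtXi, "try-error") && is.finite(b[2]) && abs(b[2]) > 0) {
      gr <- c(0, -b[3] / b[2]^2, 1 / b[2])
      seAlpha <- sqrt(max(0, s2 * drop(t(gr) %*% XtXi %*% gr)))
    }
  }

  inBox <- is.finite(r) && is.finite(Kc) && is.finite(alpha) &&
    r >= bounds$r[1] && r <= bounds$r[2] &&
    Kc >= bounds$Kc[1] && Kc <= bounds$Kc[2] &&
    alpha >= bounds$alpha[1] && alpha <= bounds$alpha[2]

  ## identifiability is judged on the exact least-squares solution: a
  ## carrying capacity outside the admissible range (or an undetermined
  ## interaction column, e.g. proportional channels) means the window does
  ## not constrain the density dependence
  lsUnident <- !is.finite(Kc) || Kc <= 0 || Kc >= 0.95 * bounds$Kc[2] ||
    !is.finite(alpha)

  if (!inBox) {
    obj <- function(p) {
      pred <- p[1] * (1 - (Nself + p[3] * Nother) / p[2])
      sum((g - pred)^2)
    }
    lower <- c(bounds$r[1], bounds$Kc[1], bounds$alpha[1])
    upper <- c(bounds$r[2], bounds$Kc[2], bounds$alpha[2])
    best <- NULL
    .with_seed(seed, function() {
      starts <- rbind(
        c(min(max(mean(g), lower[1] + 1e-6), upper[1]), stats::median(Nself) * 10, 0),
        matrix(stats::runif((nStarts - 1) * 3,
                            rep(lower, each = nStarts - 1),
                            rep(upper, each = nStarts - 1)),
               nStarts - 1, 3, byrow = FALSE)
      )
      for (k in seq_len(nrow(starts))) {
        st <- pmin(pmax(starts[k, ], lower), upper)
        res <- .optim_box(st, obj, lower, upper, maxit = 200)
        if (is.finite(res$value) && (is.null(best) || res$value < best$value)) {
          best <<- res
        }
      }
    })
    if (!is.null(best)) {
      r <- best$par[1]
      Kc <- best$par[2]
      alpha <- best$par[3]
      sse <- best$value
    }
  }

  list(r = unname(r), Kc = unname(Kc), alpha = unname(alpha), sse = sse,
       seAlpha = seAlpha,
       unident = lsUnident || !is.finite(Kc) || Kc >= 0.95 * bounds$Kc[2] ||
         Kc <= 0)
}

#' Fit a Lotka-Volterra model to one time window
#'
#' Least-squares fit of the competitive Lotka-Volterra per-capita growth
#' rates to the finite-difference (central, on log counts) growth rates of
#' the two label channels within a window. The rate model is linear in its
#' coefficients, so the unconstrained optimum is found exactly by linear
#' least squares; when it falls outside the admissible box
#' (r in [0,5], Kc in [10,1e7], alpha in [-10,10]) a bounded multi-start
#' refit is used. Deterministic given trajectory, window and seed.
#'
#' @param traj a [Trajectory-class] object.
#' @param window numeric c(t0, t1) in days; needs >= 6 samples inside.
#' @param channels which series to treat as species 1 and 2: "label"
#'   (red, green; the experimentally observable channels, default) or
#'   "phenotype" (S, T).
#' @param nStarts multi-starts for the bounded refit.
#' @param seed RNG seed for the multi-starts.
#' @return list with \code{lv} ([LVParams-class] or NULL), \code{residual}
#'   (RMS of the rate residuals, 1/day), \code{seAlpha12}, \code{seAlpha21}
#'   (regression SEs of the interaction coefficients), \code{flagged}
#'   (TRUE when a channel is degenerate in the window or either species'
#'   density dependence is unidentifiable), per-species \code{flagged1},
#'   \code{flagged2}, and \code{nPoints}. Once the two lineages reach the
#'   same phenotype mix the label channels grow proportionally and the
#'   interaction split becomes a ridge direction: signs remain stable but
#'   magnitudes are ill-determined, which the flags and SEs report.
#' @export
fitLVWindow <- function(traj, window, channels = c("label", "phenotype"),
                        nStarts = 10, seed = 1) {
  channels <- match.arg(channels)
  stopifnot(is(traj, "Trajectory"), length(window) == 2, window[1] < window[2])
  cc <- channelCounts(traj)
  tday <- traj@times
  sel <- which(tday >= window[1] - 1e-9 & tday <= window[2] + 1e-9)
  if (length(sel) < 6) stop("window must contain at least 6 samples")
  t <- tday[sel]
  if (channels == "label") {
    N1 <- cc$red[sel]
    N2 <- cc$green[sel]
  } else {
    N1 <- cc$S[sel]
    N2 <- cc$T[sel]
  }
  degenerate <- min(N1) <= 0 || min(N2) <= 0 ||
    max(N1) < 1e-6 * max(cc$red + cc$green) ||
    max(N2) < 1e-6 * max(cc$red + cc$green)
  if (degenerate) {
    return(list(lv = NULL, residual = NA_real_, seAlpha12 = NA_real_,
                seAlpha21 = NA_real_, flagged = TRUE, flagged1 = TRUE,
                flagged2 = TRUE, nPoints = length(sel)))
  }

  pr <- .percapita_rates(t, N1, N2)
  box <- list(r = c(0, 5), Kc = c(10, 1e7), alpha = c(-10, 10))
  f1 <- .fit_lv_species(pr$g1, pr$N1, pr$N2, box, nStarts, seed)
  f2 <- .fit_lv_species(pr$g2, pr$N2, pr$N1, box, nStarts, seed + 1)

  lv <- LVParams(r1 = f1$r, r2 = f2$r,
                 Kc1 = max(f1$Kc, 10), Kc2 = max(f2$Kc, 10),
                 alpha12 = f1$alpha, alpha21 = f2$alpha)
  list(
    lv = lv,
    residual = sqrt((f1$sse + f2$sse) / (2 * length(pr$g1))),
    seAlpha12 = f1$seAlpha, seAlpha21 = f2$seAlpha,
    flagged = f1$unident || f2$unident,
    flagged1 = f1$unident, flagged2 = f2$unident,
    nPoints = length(sel)
  )
}

#' Time-resolved payoff landscape
#'
#' Simulates a seeding panel, slides a fixed-length window along each
#' trajectory and fits the competitive Lotka-Volterra model in every window
#' (see [fitLVWindow()]), giving the interaction coefficients alpha12 (effect
#' of the tolerant-seeded channel on the sensitive-seeded one) and alpha21 as
#' functions of window start time and seeding ratio, with per-window residual
#' diagnostics for window-length selection.
#'
#' @param p a [PhenotypeParams-class] object.
#' @param ratios seeding ratios (r:1).
#' @param total total seeded cells.
#' @param duration trajectory duration in days.
#' @param windowLen window length in days (default 4).
#' @param strideH stride between window starts in hours (default 12).
#' @param sampleEvery sampling interval in hours.
#' @param convention seeding ratio convention (see [seedingDesign()]).
#' @param channels "label" or "phenotype" series (see [fitLVWindow()]).
#' @param seed RNG seed for bounded refits.
#' @param ... further arguments to [simulateTrajectory()].
#' @return A [PayoffSurface-class] object.
#' @export
payoffLandscape <- function(p, ratios = c(1, 2, 4, 8), total = 5000,
                            duration = 6, windowLen = 4, strideH = 12,
                            sampleEvery = 2, convention = "S:T",
                            channels = "label", seed = 1, ...) {
  stopifnot(windowLen <= duration)
  design <- seedingDesign(total = total, ratios = ratios, duration = duration,
                          sampleEvery = sampleEvery, convention = convention)
  trajs <- runSeedingPanel(p, design, ...)
  starts <- seq(0, duration - windowLen, by = strideH / 24)
  rows <- list()
  k <- 0L
  for (ri in seq_along(ratios)) {
    for (t0 in starts) {
      k <- k + 1L
      fw <- fitLVWindow(trajs[[ri]], c(t0, t0 + windowLen),
                        channels = channels, seed = seed + k)
      rows[[k]] <- data.frame(
        t0 = t0, ratio = ratios[ri],
        alpha12 = if (is.null(fw$lv)) NA_real_ else fw$lv@alpha12,
        alpha21 = if (is.null(fw$lv)) NA_real_ else fw$lv@alpha21,
        residual = fw$residual, flagged = fw$flagged,
        flagged1 = if (is.null(fw$lv)) TRUE else fw$flagged1,
        flagged2 = if (is.null(fw$lv)) TRUE else fw$flagged2,
        seAlpha12 = fw$seAlpha12, seAlpha21 = fw$seAlpha21
      )
    }
  }
  new("PayoffSurface", grid = do.call(rbind, rows), windowLen = windowLen,
      strideH = strideH)
}

#' @describeIn payoffLandscape tidy export of the payoff grid
#' @param x a PayoffSurface.
#' @export
setMethod("as.data.frame", "PayoffSurface", function(x, ...) x@grid)

setMethod("show", "PayoffSurface", function(object) {
  cat(sprintf(
    "PayoffSurface: %d windows (%g-day windows, %g-h stride), %d flagged\n",
    nrow(object@grid), object@windowLen, object@strideH,
    sum(object@grid$flagged, na.rm = TRUE)
  ))
  cat(sprintf(
    "  alpha12 range [%.3g, %.3g]; alpha21 range [%.3g, %.3g]\n",
    min(object@grid$alpha12, na.rm = TRUE), max(object@grid$alpha12, na.rm = TRUE),
    min(object@grid$alpha21, na.rm = TRUE), max(object@grid$alpha21, na.rm = TRUE)
  ))
})

#' Window-length residual diagnostic
#'
#' Mean rate-fit residual of the moving-window Lotka-Volterra fits as a
#' function of window length, used to pick a window that is neither too short
#' (ill-determined coefficients) nor too long (the constant-payoff model stops
#' tracking the switching dynamics).
#'
#' @param p a [PhenotypeParams-class] object.
#' @param windowLens candidate window lengths in days.
#' @param ... further arguments to [payoffLandscape()].
#' @return data.frame with columns \code{windowLen}, \code{meanResidual}
#'   (rate-fit error; grows with window length as the constant-payoff model
#'   stops tracking the stress-driven rate drift), \code{fracFlagged} and
#'   \code{meanSE12} (regression SE of alpha12; blows up in short windows,
#'   whose coefficients are ill-determined).
#' @export
windowLengthDiagnostic <- function(p, windowLens = c(0.5, 1, 2, 4, 5, 6), ...) {
  rows <- lapply(windowLens, function(w) {
    ps <- payoffLandscape(p, windowLen = w, ...)
    data.frame(
      windowLen = w,
      meanResidual = mean(ps@grid$residual, na.rm = TRUE),
      fracFlagged = mean(ps@grid$flagged, na.rm = TRUE),
      meanSE12 = mean(ps@grid$seAlpha12, na.rm = TRUE)
    )
  })
  do.call(rbind, rows)
}
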