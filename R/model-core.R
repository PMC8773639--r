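#' @useDynLib psmsr, .registration = TRUE
NULL

.state_to_vec <- function(state) {
  c(Rs = state@Rs, Rt = state@Rt, Gs = state@Gs, Gt = state@Gt,
    Cstr = state@Cstr, AUC = state@AUC)
}

## Flat parameter vector shared with src/psmsr.c (length 25; see header there).
.parvec <- function(p, d = NULL, conc = 0, drugOn = FALSE,
                    coupling = "linear", aucDecay = 0, sdrugCouple = FALSE,
                    amplitudes = NULL) {
  if (is.null(amplitudes)) {
    amplitudes <- c(ampGS = p@KGs0, ampGT = p@KGt0, ampK = p@K0)
  }
  dv <- if (is.null(d)) rep(0, 7) else unname(.drug_to_vec(d))
  c(
    p@K0, p@Kb, p@KGs0, p@KGt0, p@Kstr, p@Kstrd, p@a, p@b, p@g,
    dv,
    conc, as.numeric(drugOn), as.numeric(!is.null(d)),
    as.numeric(coupling == "sigmoidal"), aucDecay, as.numeric(sdrugCouple),
    unname(amplitudes)
  )
}

#' Sigmoidal kill fraction of accumulated drug exposure
#'
#' Logistic curve in accumulated exposure (AUC, uM*h), anchored so that it
#' equals 0.05 at \code{AUC5} and 0.95 at \code{AUC95}:
#' \deqn{sigmoid(AUC) = \{1 + \exp[\ln 19\,(1 - 2 (AUC - AUC_5)/(AUC_{95} -
#' AUC_5))]\}^{-1}.}
#' Multiplied by the phenotype's SCALE parameter it gives the death rate.
#'
#' @param AUC accumulated exposure (uM*h); vectorized.
#' @param AUC5,AUC95 exposures at 5% and 95% of maximum effect; must satisfy
#'   \code{AUC5 < AUC95}.
#' @return Kill fraction in (0, 1), strictly increasing in \code{AUC}.
#' @examples
#' sigmoidKill(239, 239, 1153)   # 0.05
#' sigmoidKill(1153, 239, 1153)  # 0.95
#' @export
sigmoidKill <- function(AUC, AUC5, AUC95) {
  if (AUC5 >= AUC95) stop("AUC5 must be < AUC95")
  z <- log(19) * (1 - 2 * (AUC - AUC5) / (AUC95 - AUC5))
  1 / (1 + exp(pmin(pmax(z, -700), 700)))
}

#' Stress- and exposure-dependent rates
#'
#' Evaluates the effective rates of the model at stress level \code{Cstr} and
#' accumulated exposure \code{AUC}. In linear coupling mode (the default)
#' \code{KGS = KGs0 - a Cstr}, \code{KGT = KGt0 - b Cstr} (either may go
#' negative: the effective growth rate incorporates both proliferation and
#' death) and \code{K = K0 + g Cstr}; the forward switch rate is
#' \code{Ka = K * Kb}. Sigmoidal mode replaces each linear map by a saturating
#' tanh map with the same value and slope at zero stress (amplitudes default
#' to the baseline values). Kill rates are \code{SCALE * sigmoidKill(AUC)} per
#' phenotype when drug parameters are supplied, zero otherwise.
#'
#' @param p a [PhenotypeParams-class] object.
#' @param Cstr stress level (>= 0).
#' @param coupling "linear" or "sigmoidal".
#' @param drug optional [DrugParams-class].
#' @param AUC accumulated exposure (uM*h) at which to evaluate kill rates.
#' @param amplitudes optional named numeric (ampGS, ampGT, ampK) saturation
#'   amplitudes for sigmoidal mode.
#' @return A [RateSet-class] object.
#' @examples
#' p <- presetParams("heterotypic")$phenotype
#' stressCoupledRates(p, Cstr = 0)$KGS  # 0.713
#' @export
stressCoupledRates <- function(p, Cstr, coupling = c("linear", "sigmoidal"),
                               drug = NULL, AUC = 0, amplitudes = NULL) {
  coupling <- match.arg(coupling)
  stopifnot(is(p, "PhenotypeParams"))
  if (!is.numeric(Cstr) || length(Cstr) != 1L || is.na(Cstr) || Cstr < 0) {
    stop("Cstr must be a non-negative scalar")
  }
  if (is.null(amplitudes)) {
    amplitudes <- c(ampGS = p@KGs0, ampGT = p@KGt0, ampK = p@K0)
  }
  sat <- function(f0, s, amp, sign) {
    if (amp <= 0 || s <= 0) return(f0 + sign * s * Cstr)
    f0 + sign * amp * tanh(s * Cstr / amp)
  }
  if (coupling == "linear") {
    KGS <- p@KGs0 - p@a * Cstr
    KGT <- p@KGt0 - p@b * Cstr
    K <- p@K0 + p@g * Cstr
  } else {
    KGS <- sat(p@KGs0, p@a, amplitudes[["ampGS"]], -1)
    KGT <- sat(p@KGt0, p@b, amplitudes[["ampGT"]], -1)
    K <- sat(p@K0, p@g, amplitudes[["ampK"]], +1)
  }
  deathS <- deathT <- 0
  if (!is.null(drug)) {
    deathS <- drug@SCALEs * sigmoidKill(AUC, drug@AUCs5, drug@AUCs95)
    deathT <- drug@SCALEt * sigmoidKill(AUC, drug@AUCt5, drug@AUCt95)
  }
  new("RateSet", KGS = KGS, KGT = KGT, K = K, Ka = K * p@Kb,
      deathS = deathS, deathT = deathT)
}

#' @export
setMethod("$", "RateSet", function(x, name) slot(x, name))

#' PSMSR right-hand side (reference implementation)
#'
#' Time derivative of the lineage-resolved state. Within each label the
#' sensitive compartment loses cells to switching at rate \code{Ka}, gains
#' them back at rate \code{Kb}, grows at \code{KGS} and dies at the
#' exposure-dependent kill rate; the tolerant compartment mirrors this.
#' Summing the two labels reproduces the published two-variable model for the
#' phenotype totals S and T. Stress evolves as
#' \code{dCstr/dt = Kstr*S - Kstrd*T} and accumulated exposure as
#' \code{dAUC/dt = 24*conc} while drug is present (time in days, conc in uM).
#'
#' This R implementation is the readable reference; simulation goes through
#' the identical compiled version (see [simulateTrajectory()]).
#'
#' @param state a [LineageState-class] object.
#' @param p a [PhenotypeParams-class] object.
#' @param drug optional [DrugParams-class]; NULL disables the kill terms.
#' @param conc current drug concentration (uM); drug is considered present
#'   when \code{conc > 0}.
#' @param coupling "linear" or "sigmoidal" stress coupling.
#' @param aucDecay exponential AUC decay rate (1/day) applied while drug is
#'   absent; 0 means exposure memory is held.
#' @param sdrugStress couple \code{Sdrug} as an additional stress source while
#'   drug is on?
#' @return Named numeric vector of derivatives
#'   (\code{Rs, Rt, Gs, Gt, Cstr, AUC}).
#' @examples
#' p <- presetParams("heterotypic")$phenotype
#' psmsrRHS(LineageState(Rs = 5000), p)[["Cstr"]]  # 7.14e-4 * 5000 = 3.57
#' @export
psmsrRHS <- function(state, p, drug = NULL, conc = 0,
                     coupling = c("linear", "sigmoidal"), aucDecay = 0,
                     sdrugStress = FALSE) {
  coupling <- match.arg(coupling)
  stopifnot(is(state, "LineageState"))
  r <- stressCoupledRates(p, state@Cstr, coupling, drug = drug, AUC = state@AUC)
  drugOn <- conc > 0
  S <- state@Rs + state@Gs
  T <- state@Rt + state@Gt
  dCstr <- p@Kstr * S - p@Kstrd * T +
    (if (sdrugStress && drugOn && !is.null(drug)) drug@Sdrug else 0)
  ## stress cannot be removed below zero (reflecting boundary)
  if (state@Cstr <= 0 && dCstr < 0) dCstr <- 0
  c(
    Rs = -r@Ka * state@Rs + p@Kb * state@Rt + r@KGS * state@Rs - r@deathS * state@Rs,
    Rt = r@Ka * state@Rs - p@Kb * state@Rt + r@KGT * state@Rt - r@deathT * state@Rt,
    Gs = -r@Ka * state@Gs + p@Kb * state@Gt + r@KGS * state@Gs - r@deathS * state@Gs,
    Gt = r@Ka * state@Gs - p@Kb * state@Gt + r@KGT * state@Gt - r@deathT * state@Gt,
    Cstr = dCstr,
    AUC = if (drugOn) 24 * conc else -aucDecay * state@AUC
  )
}

## compiled RHS at a state vector, for cross-checks and tests
.rhs_compiled <- function(statevec, parvec) {
  out <- .Call(C_psmsr_rhs, as.numeric(statevec), as.numeric(parvec))
  names(out) <- rep(.STATE_NAMES, length.out = length(out))
  out
}
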