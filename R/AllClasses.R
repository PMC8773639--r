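#' @import methods
NULL

.PHENO_SLOTS <- c("K0", "Kb", "KGs0", "KGt0", "Kstr", "Kstrd", "a", "b", "g")
.DRUG_SLOTS <- c("Sdrug", "AUCs5", "AUCs95", "SCALEs", "AUCt5", "AUCt95", "SCALEt")
.STATE_NAMES <- c("Rs", "Rt", "Gs", "Gt", "Cstr", "AUC")

.scalar_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Drug-free PSMSR rate constants
#'
#' Holds the nine rate constants of the phenotype switch model with stress
#' response in the absence of drug: the baseline switch equilibrium constant
#' \code{K0} (dimensionless), the tolerant-to-sensitive switch rate \code{Kb}
#' (1/day), the baseline effective growth rates \code{KGs0} and \code{KGt0}
#' (1/day) of the sensitive and tolerant phenotypes, the stress generation and
#' removal rates \code{Kstr} and \code{Kstrd} (stress units per cell per day),
#' and the stress couplings \code{a}, \code{b} (growth, 1/day per stress unit)
#' and \code{g} (switch equilibrium, 1/stress unit).
#'
#' @slot K0,Kb,KGs0,KGt0,Kstr,Kstrd,a,b,g numeric scalars, all non-negative.
#' @seealso [PhenotypeParams()], [presetParams()], [searchRanges()]
#' @export
setClass("PhenotypeParams",
  representation(
    K0 = "numeric", Kb = "numeric", KGs0 = "numeric", KGt0 = "numeric",
    Kstr = "numeric", Kstrd = "numeric", a = "numeric", b = "numeric",
    g = "numeric"
  ),
  validity = function(object) {
    for (s in .PHENO_SLOTS) {
      v <- slot(object, s)
      if (!.scalar_ok(v)) return(sprintf("'%s' must be a finite numeric scalar", s))
      if (v < 0) return(sprintf("'%s' must be non-negative", s))
    }
    TRUE
  }
)

#' Cisplatin response parameters
#'
#' The seven constants of the exposure-dependent kill term: the drug coupling
#' constant \code{Sdrug} (stored for round-trip fidelity; only enters the
#' dynamics when the optional stress-source coupling is enabled), and per
#' phenotype the exposure levels \code{AUC5}/\code{AUC95} (uM*h) at which 5%
#' and 95% of the maximum kill effect are reached plus the maximum death rate
#' \code{SCALE} (1/day).
#'
#' @slot Sdrug,AUCs5,AUCs95,SCALEs,AUCt5,AUCt95,SCALEt numeric scalars;
#'   \code{AUC5 < AUC95} per phenotype, \code{SCALE >= 0}.
#' @seealso [DrugParams()], [sigmoidKill()]
#' @export
setClass("DrugParams",
  representation(
    Sdrug = "numeric", AUCs5 = "numeric", AUCs95 = "numeric",
    SCALEs = "numeric", AUCt5 = "numeric", AUCt95 = "numeric",
    SCALEt = "numeric"
  ),
  validity = function(object) {
    for (s in .DRUG_SLOTS) {
      v <- slot(object, s)
      if (!.scalar_ok(v)) return(sprintf("'%s' must be a finite numeric scalar", s))
    }
    if (object@AUCs5 >= object@AUCs95) return("AUCs5 must be < AUCs95")
    if (object@AUCt5 >= object@AUCt95) return("AUCt5 must be < AUCt95")
    if (object@SCALEs < 0 || object@SCALEt < 0) return("SCALE must be >= 0")
    if (object@Sdrug < 0) return("Sdrug must be >= 0")
    TRUE
  }
)

#' Lineage-resolved population state
#'
#' Cell counts split by fluorescence label (red/green) and phenotype
#' (sensitive/tolerant), plus the hidden stress level and accumulated drug
#' exposure. Phenotype totals are S = Rs + Gs and T = Rt + Gt; label totals
#' are R = Rs + Rt and G = Gs + Gt.
#'
#' @slot Rs,Rt,Gs,Gt cell counts (non-negative).
#' @slot Cstr hidden stress level (stress units, non-negative).
#' @slot AUC accumulated drug exposure (uM*h, non-negative).
#' @seealso [LineageState()], [seedState()]
#' @export
setClass("LineageState",
  representation(
    Rs = "numeric", Rt = "numeric", Gs = "numeric", Gt = "numeric",
    Cstr = "numeric", AUC = "numeric"
  ),
  validity = function(object) {
    for (s in .STATE_NAMES) {
      v <- slot(object, s)
      if (!.scalar_ok(v)) return(sprintf("'%s' must be a finite numeric scalar", s))
      if (v < 0) return(sprintf("'%s' must be non-negative", s))
    }
    TRUE
  }
)

#' Stress- and exposure-dependent instantaneous rates
#'
#' The effective rates of the model evaluated at a given stress level and
#' accumulated exposure: growth rates \code{KGS}, \code{KGT} (1/day, may be
#' negative under high stress in linear coupling mode), the switch equilibrium
#' constant \code{K} with the forward switch rate \code{Ka = K * Kb}, and the
#' phenotype-specific kill rates \code{deathS}, \code{deathT} (1/day).
#'
#' @seealso [stressCoupledRates()]
#' @export
setClass("RateSet",
  representation(
    KGS = "numeric", KGT = "numeric", K = "numeric", Ka = "numeric",
    deathS = "numeric", deathT = "numeric"
  ),
  validity = function(object) {
    if (object@K < 0) return("K must be non-negative")
    if (object@deathS < 0 || object@deathT < 0) return("death rates must be non-negative")
    TRUE
  }
)

#' Cisplatin dosing schedule
#'
#' A set of non-overlapping exposure episodes, each a (start, end, conc)
#' triple in days and uM. Between episodes the drug is absent; accumulated
#' exposure follows the configured AUC memory mode.
#'
#' @slot episodes data.frame with columns \code{start}, \code{end} (days) and
#'   \code{conc} (uM), ordered and non-overlapping.
#' @slot label free-text regimen label, e.g. "continuous" or "intermittent-1".
#' @seealso [doseSchedule()], [therapySchedules()]
#' @export
setClass("DoseSchedule",
  representation(episodes = "data.frame", label = "character"),
  validity = function(object) {
    ep <- object@episodes
    need <- c("start", "end", "conc")
    if (!all(need %in% names(ep))) {
      return("episodes needs columns start, end, conc")
    }
    if (nrow(ep)) {
      if (any(ep$end <= ep$start)) return("episode end must exceed start")
      if (any(ep$conc < 0)) return("concentrations must be non-negative")
      if (is.unsorted(ep$start, strictly = TRUE) && nrow(ep) > 1) {
        return("episodes must be ordered by start time")
      }
      if (nrow(ep) > 1 && any(ep$start[-1] < ep$end[-nrow(ep)])) {
        return("episodes must not overlap")
      }
    }
    TRUE
  }
)

#' Seeding panel design
#'
#' Describes a live-imaging co-culture panel: total seeded cells, the seeding
#' ratios, experiment duration and the imaging interval.
#'
#' @slot total total seeded cells per well.
#' @slot ratios numeric vector of seeding ratios r, interpreted as r:1 in the
#'   order given by \code{convention}.
#' @slot duration experiment duration in days.
#' @slot sampleEvery imaging interval in hours; must tile the duration evenly.
#' @slot convention "S:T" (red:green = r:1) or "T:S" (green:red = r:1).
#' @seealso [seedingDesign()], [runSeedingPanel()]
#' @export
setClass("SeedingDesign",
  representation(
    total = "numeric", ratios = "numeric", duration = "numeric",
    sampleEvery = "numeric", convention = "character"
  ),
  validity = function(object) {
    if (!.scalar_ok(object@total) || object@total <= 0) return("total must be > 0")
    if (!length(object@ratios) || any(object@ratios <= 0)) return("ratios must be positive")
    if (!.scalar_ok(object@duration) || object@duration <= 0) return("duration must be > 0")
    if (!.scalar_ok(object@sampleEvery) || object@sampleEvery <= 0) {
      return("sampleEvery must be > 0")
    }
    nsteps <- object@duration * 24 / object@sampleEvery
    if (abs(nsteps - round(nsteps)) > 1e-8) {
      return("sampleEvery must divide the duration evenly")
    }
    if (!object@convention %in% c("S:T", "T:S")) return("convention must be 'S:T' or 'T:S'")
    TRUE
  }
)

#' Simulated trajectory of a single culture
#'
#' Times (days) and the lineage-resolved state at each time, together with the
#' condition label, seeding ratio and the simulation settings used.
#'
#' @slot times numeric vector of times in days, strictly increasing.
#' @slot states numeric matrix, one row per time, columns
#'   \code{Rs, Rt, Gs, Gt, Cstr, AUC}.
#' @slot condition condition label.
#' @slot ratio seeding ratio (r in r:1).
#' @slot metadata list of simulation settings (parameters, schedule, coupling
#'   and AUC modes, integrator).
#' @seealso [simulateTrajectory()], [channelCounts()], [switchedFractions()]
#' @export
setClass("Trajectory",
  representation(
    times = "numeric", states = "matrix", condition = "character",
    ratio = "numeric", metadata = "list"
  ),
  validity = function(object) {
    if (nrow(object@states) != length(object@times)) {
      return("states must have one row per time point")
    }
    if (!identical(colnames(object@states), .STATE_NAMES)) {
      return(sprintf("state columns must be %s", paste(.STATE_NAMES, collapse = ", ")))
    }
    if (length(object@times) > 1 && any(diff(object@times) <= 0)) {
      return("times must be strictly increasing")
    }
    if (any(object@states[, 1:4] < -1e-3, na.rm = TRUE)) {
      return("negative cell counts")
    }
    TRUE
  }
)

#' Growth-curve dataset
#'
#' Long-format per-channel cell counts over time across experimental
#' conditions, seeding ratios and replicates; the fitting target. The
#' \code{metadata} list carries per-condition information (parameter sets used
#' for synthetic data, dose schedules, seeding totals).
#'
#' @slot data data.frame with columns \code{condition}, \code{ratio},
#'   \code{time_h}, \code{channel} ("red"/"green"), \code{count},
#'   \code{replicate}.
#' @slot metadata list; for synthetic datasets includes \code{conditions} (a
#'   named list of per-condition truth and design) and the noise model.
#' @seealso [generateDataset()], [readGrowthCsv()], [makeFixture()]
#' @export
setClass("GrowthDataset",
  representation(data = "data.frame", metadata = "list"),
  validity = function(object) {
    need <- c("condition", "ratio", "time_h", "channel", "count", "replicate")
    miss <- setdiff(need, names(object@data))
    if (length(miss)) {
      return(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
    }
    if (nrow(object@data)) {
      if (any(object@data$count < 0, na.rm = TRUE)) return("counts must be non-negative")
      if (!all(object@data$channel %in% c("red", "green"))) {
        return("channel must be 'red' or 'green'")
      }
    }
    TRUE
  }
)

#' Genetic-algorithm configuration
#'
#' @slot popSize population size.
#' @slot generations number of generations.
#' @slot pcrossover,pmutation crossover and per-gene mutation probabilities.
#' @slot elitism number of elite chromosomes copied unchanged.
#' @slot seed integer RNG seed; all GA randomness flows from it.
#' @seealso [gaConfig()], [gaOptimize()]
#' @export
setClass("GAConfig",
  representation(
    popSize = "numeric", generations = "numeric", pcrossover = "numeric",
    pmutation = "numeric", elitism = "numeric", seed = "numeric"
  ),
  validity = function(object) {
    if (object@popSize < 4) return("popSize must be >= 4")
    if (object@generations < 1) return("generations must be >= 1")
    if (object@pcrossover < 0 || object@pcrossover > 1) return("pcrossover must be in [0,1]")
    if (object@pmutation < 0 || object@pmutation > 1) return("pmutation must be in [0,1]")
    if (object@elitism < 0 || object@elitism >= object@popSize) {
      return("elitism must be in [0, popSize)")
    }
    TRUE
  }
)

#' Result of a model fit
#'
#' @slot par named numeric vector of all model parameters (free and locked).
#' @slot free names of the parameters that were actually optimized.
#' @slot value best objective value (negative log-likelihood).
#' @slot trace data.frame with columns \code{generation} and \code{best}
#'   (elitist best-so-far; non-increasing).
#' @slot ci matrix of per-parameter 95% profile confidence limits (columns
#'   \code{lower}, \code{upper}; NA until profiled, Inf/bound when flat).
#' @slot seed RNG seed used.
#' @slot condition condition tag the fit belongs to.
#' @slot details list (GA config, locking mask, polish info).
#' @seealso [fitCondition()], [gaOptimize()], [profileLikelihood()]
#' @export
setClass("PSMSRFit",
  representation(
    par = "numeric", free = "character", value = "numeric",
    trace = "data.frame", ci = "matrix", seed = "numeric",
    condition = "character", details = "list"
  ),
  validity = function(object) {
    if (nrow(object@trace) > 1 && any(diff(object@trace$best) > 1e-10)) {
      return("trace best-so-far must be non-increasing")
    }
    TRUE
  }
)

#' Competitive Lotka-Volterra parameters
#'
#' Two-species competitive Lotka-Volterra model
#' dN1/dt = r1 N1 (1 - (N1 + alpha12 N2)/Kc1),
#' dN2/dt = r2 N2 (1 - (N2 + alpha21 N1)/Kc2).
#' Positive interaction coefficients mean competition, negative mean
#' cooperation.
#'
#' @slot r1,r2 intrinsic growth rates (1/day).
#' @slot Kc1,Kc2 carrying capacities (cells, > 0).
#' @slot alpha12 effect of species 2 on species 1 (dimensionless).
#' @slot alpha21 effect of species 1 on species 2 (dimensionless).
#' @seealso [lvRHS()], [fitLVWindow()]
#' @export
setClass("LVParams",
  representation(
    r1 = "numeric", r2 = "numeric", Kc1 = "numeric", Kc2 = "numeric",
    alpha12 = "numeric", alpha21 = "numeric"
  ),
  validity = function(object) {
    if (object@Kc1 <= 0 || object@Kc2 <= 0) return("carrying capacities must be > 0")
    TRUE
  }
)

#' Time-resolved payoff surface
#'
#' Grid of moving-window Lotka-Volterra interaction coefficients over window
#' start time and seeding ratio, with per-window fit residuals and diagnostic
#' flags.
#'
#' @slot grid data.frame with columns \code{t0} (window start, days),
#'   \code{ratio}, \code{alpha12}, \code{alpha21}, \code{residual},
#'   \code{flagged}.
#' @slot windowLen window length in days.
#' @slot strideH stride between window starts in hours.
#' @seealso [payoffLandscape()]
#' @export
setClass("PayoffSurface",
  representation(grid = "data.frame", windowLen = "numeric", strideH = "numeric"),
  validity = function(object) {
    need <- c("t0", "ratio", "alpha12", "alpha21", "residual", "flagged")
    miss <- setdiff(need, names(object@grid))
    if (length(miss)) return(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
    if (any(object@grid$residual < 0, na.rm = TRUE)) return("residuals must be >= 0")
    TRUE
  }
)

#' Noise model for synthetic counts
#'
#' @slot kind "lognormal" (multiplicative, log-scale SD \code{sigma}) or
#'   "none".
#' @slot sigma log-scale standard deviation (>= 0).
#' @seealso [noiseModel()], [generateDataset()]
#' @export
setClass("NoiseModel",
  representation(kind = "character", sigma = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("lognormal", "none")) return("kind must be 'lognormal' or 'none'")
    if (object@sigma < 0) return("sigma must be >= 0")
    TRUE
  }
)
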