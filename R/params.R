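#' Construct a drug-free parameter set
#'
#' Argument names follow the published parameter table: \code{K} is the
#' baseline switch equilibrium constant (stored in slot \code{K0}).
#'
#' @param K baseline phenotype-switch equilibrium constant (dimensionless).
#' @param Kb tolerant-to-sensitive switch rate (1/day).
#' @param KGs0,KGt0 baseline effective growth rates (1/day).
#' @param Kstr,Kstrd stress generation/removal rate per cell (1/day).
#' @param a,b stress coupling of sensitive/tolerant growth (1/day per stress unit).
#' @param g stress coupling of the switch equilibrium (1/stress unit).
#' @return A [PhenotypeParams-class] object.
#' @examples
#' p <- PhenotypeParams(K = 0.049, Kb = 3.57, KGs0 = 0.713, KGt0 = 0.687,
#'                      Kstr = 7.14e-4, Kstrd = 5.64e-3,
#'                      a = 0.046, b = 0.038, g = 0.018)
#' @export
PhenotypeParams <- function(K, Kb, KGs0, KGt0, Kstr, Kstrd, a, b, g) {
  new("PhenotypeParams",
    K0 = as.numeric(K), Kb = as.numeric(Kb), KGs0 = as.numeric(KGs0),
    KGt0 = as.numeric(KGt0), Kstr = as.numeric(Kstr),
    Kstrd = as.numeric(Kstrd), a = as.numeric(a), b = as.numeric(b),
    g = as.numeric(g)
  )
}

#' Construct a cisplatin-response parameter set
#'
#' @param Sdrug drug coupling constant (inert unless the optional stress-source
#'   coupling is enabled in the simulator).
#' @param AUCs5,AUCs95 exposures (uM*h) at 5%/95% of maximum sensitive-cell
#'   kill.
#' @param SCALEs maximum sensitive-cell death rate (1/day).
#' @param AUCt5,AUCt95,SCALEt same for the tolerant phenotype.
#' @return A [DrugParams-class] object.
#' @export
DrugParams <- function(Sdrug, AUCs5, AUCs95, SCALEs, AUCt5, AUCt95, SCALEt) {
  new("DrugParams",
    Sdrug = as.numeric(Sdrug), AUCs5 = as.numeric(AUCs5),
    AUCs95 = as.numeric(AUCs95), SCALEs = as.numeric(SCALEs),
    AUCt5 = as.numeric(AUCt5), AUCt95 = as.numeric(AUCt95),
    SCALEt = as.numeric(SCALEt)
  )
}

#' Construct a lineage-resolved state
#'
#' @param Rs,Rt red-labelled cells in the sensitive/tolerant phenotype.
#' @param Gs,Gt green-labelled cells in the sensitive/tolerant phenotype.
#' @param Cstr hidden stress level (default 0).
#' @param AUC accumulated drug exposure in uM*h (default 0).
#' @return A [LineageState-class] object.
#' @export
LineageState <- function(Rs = 0, Rt = 0, Gs = 0, Gt = 0, Cstr = 0, AUC = 0) {
  new("LineageState",
    Rs = as.numeric(Rs), Rt = as.numeric(Rt), Gs = as.numeric(Gs),
    Gt = as.numeric(Gt), Cstr = as.numeric(Cstr), AUC = as.numeric(AUC)
  )
}

#' Initial state for a seeding ratio
#'
#' Red-labelled cells are seeded entirely in the sensitive phenotype and
#' green-labelled cells entirely in the tolerant phenotype; stress and
#' accumulated exposure start at zero.
#'
#' @param total total seeded cells.
#' @param ratio seeding ratio r (meaning r:1 under \code{convention}).
#' @param convention "S:T" (red:green = r:1, the convention of the heterotypic
#'   prediction panels) or "T:S" (green:red = r:1).
#' @return A [LineageState-class] object.
#' @examples
#' seedState(5000, 4)            # 4000 red (sensitive) : 1000 green (tolerant)
#' seedState(5000, 4, "T:S")     # 1000 red : 4000 green
#' @export
seedState <- function(total, ratio, convention = c("S:T", "T:S")) {
  convention <- match.arg(convention)
  stopifnot(total > 0, ratio > 0)
  major <- total * ratio / (ratio + 1)
  minor <- total - major
  if (convention == "S:T") {
    LineageState(Rs = major, Gt = minor)
  } else {
    LineageState(Rs = minor, Gt = major)
  }
}

## Published parameter table (point estimates) ------------------------------

.TABLE_PARAMS <- list(
  "heterotypic" = list(
    phenotype = c(
      K = 0.049, Kb = 3.57, KGs0 = 0.713, KGt0 = 0.687,
      Kstr = 7.14e-4, Kstrd = 5.64e-3, a = 0.046, b = 0.038, g = 0.018
    ),
    drug = NULL
  ),
  "heterotypic-3wk" = list(
    phenotype = c(
      K = 0.052, Kb = 2.6, KGs0 = 0.708, KGt0 = 0.189,
      Kstr = 6.74e-4, Kstrd = 5.52e-3, a = 0.05, b = 0.038, g = 0.02
    ),
    drug = NULL
  ),
  "heterotypic-cisplatin" = list(
    phenotype = c(
      K = 0.033, Kb = 0, KGs0 = 1.033, KGt0 = 0.976,
      Kstr = 5.9e-4, Kstrd = 0, a = 0, b = 0.04, g = 0.034
    ),
    drug = c(
      Sdrug = 108, AUCs5 = 239, AUCs95 = 1153, SCALEs = 8.61,
      AUCt5 = 233, AUCt95 = 1201, SCALEt = 5.79
    )
  ),
  "heterotypic-3wk-cisplatin" = list(
    phenotype = c(
      K = 0.033, Kb = 0, KGs0 = 0.966, KGt0 = 0.967,
      Kstr = 5.8e-4, Kstrd = 0, a = 0, b = 0.039, g = 0.036
    ),
    drug = c(
      Sdrug = 96.8, AUCs5 = 271, AUCs95 = 1098, SCALEs = 8.91,
      AUCt5 = 250, AUCt95 = 1098, SCALEt = 6.89
    )
  )
)

#' Published parameter sets
#'
#' Point estimates of the fitted parameter table for the four published
#' co-culture conditions. The cisplatin rows come with the switch rate
#' \code{Kb} and the stress-removal rate \code{Kstrd} fixed at zero and the
#' sensitive-growth stress coupling \code{a} unused (stored as 0), reflecting
#' that phenotypic switching and stress removal are turned off under drug.
#'
#' @param condition one of \code{"heterotypic"}, \code{"heterotypic-3wk"},
#'   \code{"heterotypic-cisplatin"}, \code{"heterotypic-3wk-cisplatin"}.
#' @return A list with elements \code{phenotype} ([PhenotypeParams-class]) and
#'   \code{drug} ([DrugParams-class] or NULL).
#' @examples
#' presetParams("heterotypic")$phenotype
#' @export
presetParams <- function(condition = names(.TABLE_PARAMS)) {
  condition <- match.arg(condition)
  row <- .TABLE_PARAMS[[condition]]
  list(
    phenotype = do.call(PhenotypeParams, as.list(row$phenotype)),
    drug = if (!is.null(row$drug)) do.call(DrugParams, as.list(row$drug)) else NULL
  )
}

#' Parameter search ranges
#'
#' Lower/upper bounds used for fitting, matching the published search ranges.
#'
#' @param drug if TRUE, include the seven cisplatin-response parameters.
#' @return A matrix with columns \code{lower} and \code{upper}, one row per
#'   parameter.
#' @export
searchRanges <- function(drug = FALSE) {
  lo <- c(
    K = 0, Kb = 0, KGs0 = 0, KGt0 = 0, Kstr = 0, Kstrd = 0,
    a = 0, b = 0, g = 0
  )
  hi <- c(
    K = 0.1, Kb = 5, KGs0 = 2, KGt0 = 2, Kstr = 0.001, Kstrd = 0.02,
    a = 0.1, b = 0.1, g = 0.1
  )
  if (drug) {
    lo <- c(lo, Sdrug = 1, AUCs5 = 1, AUCs95 = 10, SCALEs = 0.1,
            AUCt5 = 1, AUCt95 = 10, SCALEt = 0.1)
    hi <- c(hi, Sdrug = 500, AUCs5 = 500, AUCs95 = 1500, SCALEs = 20,
            AUCt5 = 500, AUCt95 = 1500, SCALEt = 20)
  }
  cbind(lower = lo, upper = hi)
}

#' Model parameter names
#'
#' The free parameters of the model: nine without the drug block, sixteen with
#' it.
#'
#' @param drug include the cisplatin-response block?
#' @return Character vector of parameter names.
#' @examples
#' length(psmsrParameterNames())       # 9
#' length(psmsrParameterNames(TRUE))   # 16
#' @export
psmsrParameterNames <- function(drug = FALSE) {
  nm <- c("K", "Kb", "KGs0", "KGt0", "Kstr", "Kstrd", "a", "b", "g")
  if (drug) {
    nm <- c(nm, "Sdrug", "AUCs5", "AUCs95", "SCALEs", "AUCt5", "AUCt95", "SCALEt")
  }
  nm
}

#' Apply the drug-condition parameter lock
#'
#' Under cisplatin the best-fitting model has community cooperation turned
#' off: the tolerant-to-sensitive switch rate \code{Kb} (and hence the forward
#' rate \code{Ka = K*Kb}) and the stress removal rate \code{Kstrd} are set to
#' zero, and the sensitive-growth stress coupling \code{a} is unused.
#'
#' @param p a [PhenotypeParams-class] object.
#' @return The locked [PhenotypeParams-class].
#' @export
lockDrugCondition <- function(p) {
  stopifnot(is(p, "PhenotypeParams"))
  p@Kb <- 0
  p@Kstrd <- 0
  p@a <- 0
  validObject(p)
  p
}

## named-vector round trips --------------------------------------------------

.pheno_to_vec <- function(p) {
  c(
    K = p@K0, Kb = p@Kb, KGs0 = p@KGs0, KGt0 = p@KGt0, Kstr = p@Kstr,
    Kstrd = p@Kstrd, a = p@a, b = p@b, g = p@g
  )
}

.drug_to_vec <- function(d) {
  c(
    Sdrug = d@Sdrug, AUCs5 = d@AUCs5, AUCs95 = d@AUCs95, SCALEs = d@SCALEs,
    AUCt5 = d@AUCt5, AUCt95 = d@AUCt95, SCALEt = d@SCALEt
  )
}

.vec_to_pheno <- function(v) do.call(PhenotypeParams, as.list(v[psmsrParameterNames()]))

.vec_to_drug <- function(v) {
  nm <- setdiff(psmsrParameterNames(TRUE), psmsrParameterNames())
  do.call(DrugParams, as.list(v[nm]))
}

setMethod("show", "PhenotypeParams", function(object) {
  cat("PhenotypeParams (drug-free PSMSR rate constants)\n")
  print(signif(.pheno_to_vec(object), 4))
})

setMethod("show", "DrugParams", function(object) {
  cat("DrugParams (cisplatin response)\n")
  print(signif(.drug_to_vec(object), 4))
})

setMethod("show", "LineageState", function(object) {
  v <- c(Rs = object@Rs, Rt = object@Rt, Gs = object@Gs, Gt = object@Gt,
         Cstr = object@Cstr, AUC = object@AUC)
  cat("LineageState:", paste(names(v), signif(v, 5), sep = "=", collapse = " "), "\n")
})

setMethod("show", "RateSet", function(object) {
  v <- c(KGS = object@KGS, KGT = object@KGT, K = object@K, Ka = object@Ka,
         deathS = object@deathS, deathT = object@deathT)
  cat("RateSet:", paste(names(v), signif(v, 5), sep = "=", collapse = " "), "\n")
})
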