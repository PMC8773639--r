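#' Noise model for synthetic counts
#'
#' Lognormal multiplicative noise: each simulated count is multiplied by
#' exp(N(0, sigma^2)). This matches the positivity and scale heterogeneity of
#' live-imaging cell counts. The default sigma is 0.05 on the log scale.
#'
#' @param kind "lognormal" or "none".
#' @param sigma log-scale standard deviation.
#' @return A [NoiseModel-class] object.
#' @export
noiseModel <- function(kind = c("lognormal", "none"), sigma = 0.05) {
  kind <- match.arg(kind)
  new("NoiseModel", kind = kind, sigma = if (kind == "none") 0 else sigma)
}

#' Default synthetic study design
#'
#' Emulates the published live-imaging campaign: monotypic red and green
#' cultures, heterotypic co-cultures counted immediately after mixing and
#' after three weeks of cohabitation, each at seeding ratios 1:1 to 8:1
#' (total 5000 cells, 144 h sampled every 2 h), plus the two cisplatin
#' conditions under continuous 5 uM exposure. Ground-truth parameters are the
#' published point estimates; the monotypic conditions reuse the heterotypic
#' row because no monotypic row is printed. With one replicate this design
#' yields 2482 records, within 20% of the ~2900 points of the original
#' campaign.
#'
#' @param conditions subset of condition names to include.
#' @param replicates number of replicates per condition.
#' @param total total seeded cells.
#' @param duration duration in days.
#' @param sampleEvery sampling interval in hours.
#' @param ratios heterotypic seeding ratios.
#' @param conc cisplatin concentration (uM) for the drug conditions.
#' @return A list of per-condition specifications (name, params, design,
#'   schedule, mono flag) consumed by [generateDataset()].
#' @export
studyDesign <- function(conditions = c(
                          "monotypic-red", "monotypic-green",
                          "heterotypic", "heterotypic-3wk",
                          "heterotypic-cisplatin", "heterotypic-3wk-cisplatin"
                        ),
                        replicates = 1, total = 5000, duration = 6,
                        sampleEvery = 2, ratios = c(1, 2, 4, 8), conc = 5) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  design <- list()
  for (cond in conditions) {
    mono <- if (cond == "monotypic-red") "red"
            else if (cond == "monotypic-green") "green" else ""
    paramRow <- switch(cond,
      "monotypic-red" = ,
      "monotypic-green" = ,
      "heterotypic" = "heterotypic",
      "heterotypic-3wk" = "heterotypic-3wk",
      "heterotypic-cisplatin" = "heterotypic-cisplatin",
      "heterotypic-3wk-cisplatin" = "heterotypic-3wk-cisplatin"
    )
    drugCond <- grepl("cisplatin", cond)
    design[[cond]] <- list(
      name = cond,
      params = presetParams(paramRow),
      design = seedingDesign(
        total = total, ratios = if (nzchar(mono)) 1 else ratios,
        duration = duration, sampleEvery = sampleEvery
      ),
      schedule = if (drugCond) continuousSchedule(conc, duration)
                 else untreatedSchedule(),
      mono = mono,
      replicates = replicates
    )
  }
  design
}

#' Generate a synthetic growth dataset
#'
#' Simulates every condition of a study design with its ground-truth
#' parameter set, samples the label channels on the design's time grid and
#' applies multiplicative noise per record. Monotypic conditions record only
#' their seeded channel. The truth (parameters, schedules, seeding) is stored
#' in the dataset metadata.
#'
#' @param design a study design from [studyDesign()].
#' @param noise a [NoiseModel-class].
#' @param seed integer RNG seed; the dataset is byte-identical under a fixed
#'   seed.
#' @param digits counts are rounded to this many decimals so that CSV
#'   round-trips are exact.
#' @return A [GrowthDataset-class] object.
#' @examples
#' ds <- generateDataset(studyDesign("heterotypic"), noiseModel(sigma = 0.05),
#'                       seed = 1)
#' nrow(growthData(ds))
#' @export
generateDataset <- function(design = studyDesign(), noise = noiseModel(),
                            seed = 1, digits = 3) {
  stopifnot(is(noise, "NoiseModel"))
  rows <- list()
  meta <- list()
  .with_seed(seed, function() {
    for (cond in design) {
      d <- cond$design
      times <- seq(0, d@duration, by = d@sampleEvery / 24)
      for (rep_ in seq_len(cond$replicates)) {
        for (r in d@ratios) {
          init <- if (nzchar(cond$mono)) {
            if (cond$mono == "red") LineageState(Rs = d@total)
            else LineageState(Gt = d@total)
          } else {
            seedState(d@total, r, d@convention)
          }
          traj <- simulateTrajectory(
            cond$params$phenotype, drug = cond$params$drug, init = init,
            schedule = cond$schedule, times = times,
            condition = cond$name, ratio = r
          )
          cc <- channelCounts(traj)
          channels <- if (nzchar(cond$mono)) cond$mono else c("red", "green")
          for (ch in channels) {
            cnt <- cc[[ch]]
            if (noise@kind == "lognormal" && noise@sigma > 0) {
              cnt <- cnt * exp(stats::rnorm(length(cnt), 0, noise@sigma))
            }
            rows[[length(rows) + 1L]] <<- data.frame(
              condition = cond$name,
              ratio = if (nzchar(cond$mono)) NA_real_ else r,
              time_h = cc$time_h, channel = ch,
              count = round(cnt, digits), replicate = rep_
            )
          }
        }
      }
      meta[[cond$name]] <<- list(
        truth = list(
          phenotype = .pheno_to_vec(cond$params$phenotype),
          drug = if (!is.null(cond$params$drug)) .drug_to_vec(cond$params$drug)
        ),
        schedule = cond$schedule, total = cond$design@total,
        convention = cond$design@convention, mono = cond$mono
      )
    }
  })
  new("GrowthDataset",
    data = do.call(rbind, rows),
    metadata = list(conditions = meta, noise = noise, seed = seed)
  )
}

#' @describeIn generateDataset the record table of a dataset
#' @param ds a [GrowthDataset-class].
#' @export
growthData <- function(ds) {
  stopifnot(is(ds, "GrowthDataset"))
  ds@data
}

#' @describeIn generateDataset the metadata list of a dataset
#' @export
datasetMeta <- function(ds) {
  stopifnot(is(ds, "GrowthDataset"))
  ds@metadata
}

#' @export
setMethod("as.data.frame", "GrowthDataset", function(x, ...) x@data)

setMethod("show", "GrowthDataset", function(object) {
  df <- object@data
  cat(sprintf(
    "GrowthDataset: %d records, %d condition(s), %d time point(s)\n",
    nrow(df), length(unique(df$condition)), length(unique(df$time_h))
  ))
  if (nrow(df)) {
    tab <- table(df$condition)
    cat("  records per condition:\n")
    for (nm in names(tab)) cat(sprintf("    %-28s %d\n", nm, tab[[nm]]))
  }
})

## fixture registry: small seeded datasets with committed ground truth
.FIXTURES <- list(
  "tiny-heterotypic" = function() {
    generateDataset(
      studyDesign("heterotypic", ratios = c(1, 4), sampleEvery = 12),
      noiseModel(sigma = 0.05), seed = 42
    )
  },
  "drug-panel" = function() {
    cond <- studyDesign("heterotypic-cisplatin", ratios = 1, sampleEvery = 12)
    inter <- cond[[1]]
    inter$name <- "heterotypic-cisplatin-intermittent"
    inter$schedule <- doseSchedule(0, 2, 5, label = "intermittent-1")
    cond[[1]]$name <- "heterotypic-cisplatin-continuous"
    design <- list(cond[[1]], inter)
    names(design) <- vapply(design, `[[`, "", "name")
    generateDataset(design, noiseModel(sigma = 0.05), seed = 42)
  }
)

#' Small registered fixture datasets
#'
#' Deterministic miniature datasets (<= 200 records) with committed ground
#' truth, used for fast tests: \code{"tiny-heterotypic"} (heterotypic
#' condition, ratios 1:1 and 4:1, 13 time points) and \code{"drug-panel"}
#' (continuous and intermittent cisplatin schedules at 1:1 seeding).
#'
#' @param name fixture name.
#' @return A [GrowthDataset-class] object.
#' @export
makeFixture <- function(name = names(.FIXTURES)) {
  name <- match.arg(name)
  .FIXTURES[[name]]()
}
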