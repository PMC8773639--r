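#' Read a growth-curve CSV
#'
#' Accepts the canonical long format (columns condition, ratio, time_h,
#' channel, count, replicate) or the wide convenience variant (condition,
#' ratio, time_h, red, green and optionally replicate), which is pivoted to
#' long. Rows are validated: negative counts and unsorted times within a
#' series are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return A [GrowthDataset-class] object.
#' @export
readGrowthCsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  )
  if (!nrow(df)) stop(sprintf("'%s' contains an empty dataset", path))

  long <- c("condition", "ratio", "time_h", "channel", "count", "replicate")
  wide <- c("condition", "ratio", "time_h", "red", "green")
  if (all(long %in% names(df))) {
    out <- df[long]
  } else if (all(wide %in% names(df))) {
    if (!"replicate" %in% names(df)) df$replicate <- 1
    out <- rbind(
      data.frame(condition = df$condition, ratio = df$ratio,
                 time_h = df$time_h, channel = "red", count = df$red,
                 replicate = df$replicate),
      data.frame(condition = df$condition, ratio = df$ratio,
                 time_h = df$time_h, channel = "green", count = df$green,
                 replicate = df$replicate)
    )
  } else {
    miss <- setdiff(long, names(df))
    stop(sprintf("missing columns in '%s': %s (long schema) and no wide schema found",
                 path, paste(miss, collapse = ", ")))
  }

  out$condition <- as.character(out$condition)
  out$channel <- as.character(out$channel)
  out$ratio <- as.numeric(out$ratio)
  out$time_h <- as.numeric(out$time_h)
  out$count <- as.numeric(out$count)
  out$replicate <- as.integer(out$replicate)

  bad <- which(!is.na(out$count) & out$count < 0)
  if (length(bad)) {
    stop(sprintf("negative counts at line(s) %s of '%s'",
                 paste(utils::head(bad + 1, 5), collapse = ", "), path))
  }
  key <- interaction(out$condition, out$ratio, out$channel, out$replicate,
                     drop = TRUE)
  for (k in levels(key)) {
    tt <- out$time_h[key == k]
    if (is.unsorted(tt)) {
      stop(sprintf("unsorted times within series '%s' of '%s'", k, path))
    }
  }
  new("GrowthDataset", data = out, metadata = list(source = path))
}

#' Write a growth dataset to CSV (canonical long format)
#'
#' @param ds a [GrowthDataset-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeGrowthCsv <- function(ds, path) {
  stopifnot(is(ds, "GrowthDataset"))
  utils::write.csv(ds@data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write flat parameter configs
#'
#' Parameter sets serialize to flat key-value YAML or JSON (by file
#' extension) with keys matching the published parameter table (K, Kb, KGs0,
#' KGt0, Kstr, Kstrd, a, b, g and, when present, Sdrug, AUCs5, AUCs95,
#' SCALEs, AUCt5, AUCt95, SCALEt) plus \code{coupling} and \code{aucMode}.
#'
#' @param phenotype a [PhenotypeParams-class].
#' @param drug optional [DrugParams-class].
#' @param path file path ending in .yaml, .yml or .json.
#' @param coupling,aucMode simulation modes stored alongside the values.
#' @return \code{writeParams}: the path, invisibly. \code{readParams}: a list
#'   with elements \code{phenotype}, \code{drug} (or NULL), \code{coupling},
#'   \code{aucMode}.
#' @export
writeParams <- function(phenotype, drug = NULL, path, coupling = "linear",
                        aucMode = "hold") {
  stopifnot(is(phenotype, "PhenotypeParams"))
  kv <- c(
    as.list(.pheno_to_vec(phenotype)),
    if (!is.null(drug)) as.list(.drug_to_vec(drug)),
    list(coupling = coupling, aucMode = aucMode)
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(kv, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(kv, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("path must end in .yaml, .yml or .json")
  }
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  kv <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("path must end in .yaml, .yml or .json")
  }
  phenoNames <- psmsrParameterNames()
  drugNames <- setdiff(psmsrParameterNames(TRUE), phenoNames)
  miss <- setdiff(phenoNames, names(kv))
  if (length(miss)) {
    stop(sprintf("missing parameter keys: %s", paste(miss, collapse = ", ")))
  }
  pheno <- do.call(PhenotypeParams, kv[phenoNames])
  drug <- if (all(drugNames %in% names(kv))) do.call(DrugParams, kv[drugNames])
  list(
    phenotype = pheno, drug = drug,
    coupling = if (!is.null(kv$coupling)) kv$coupling else "linear",
    aucMode = if (!is.null(kv$aucMode)) kv$aucMode else "hold"
  )
}
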