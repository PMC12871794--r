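## Tab-separated readers/writers for cohorts, panels, GWAS tables, PRS
## weights and configs. Writers stamp the package version (and seed where
## one exists) into a comment header line; readers skip comment lines.

.stamp <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("scaleGxE"))
  paste0("# scaleGxE ", v, if (!is.null(seed)) paste0(" seed=", seed))
}

.writeTsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.stamp(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a cohort as a tab-separated table
#'
#' Columns: sample_id, y_observed, E, PGS_1..PGS_m, then covariates. The
#' latent phenotype and generative coefficients are not serialised; a
#' read-back cohort is a plain data.frame for modelling, not a
#' [Cohort-class].
#'
#' @param cohort a [Cohort-class].
#' @param path output file.
#' @return \code{path}, invisibly (writer); a data.frame (reader).
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "Cohort"))
  df <- data.frame(sample_id = sprintf("S%d", seq_along(cohort@E)),
                   y_observed = cohort@yObserved, E = cohort@E,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(cohort@G))
  if (ncol(cohort@covariates) > 0) df <- cbind(df, as.data.frame(cohort@covariates))
  seed <- if (is(cohort@config, "SimulationConfig")) cohort@config@seed else NULL
  .writeTsv(df, path, seed)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) .readTsv(path)

#' Write / read a genotype panel (dosage TSV + SNP map TSV)
#'
#' @param panel a [GenotypePanel-class].
#' @param dosagePath,mapPath output files for the dosage matrix (samples x
#'   SNPs, SNP ids as header) and the SNP map (snp, chr, bp, a1, a2, freq).
#' @return the paths, invisibly (writer); a [GenotypePanel-class] (reader).
#' @export
writeGenotypePanel <- function(panel, dosagePath, mapPath) {
  stopifnot(is(panel, "GenotypePanel"))
  .writeTsv(as.data.frame(panel@dosages), dosagePath)
  .writeTsv(panel@snpMap, mapPath)
  invisible(c(dosagePath, mapPath))
}

#' @rdname writeGenotypePanel
#' @export
readGenotypePanel <- function(dosagePath, mapPath) {
  dos <- as.matrix(.readTsv(dosagePath))
  map <- .readTsv(mapPath)
  colnames(dos) <- map$snp
  new("GenotypePanel", dosages = dos, snpMap = map, trueEffects = NULL)
}

#' Write / read GWAS summary statistics
#'
#' Standard columns SNP, CHR, BP, A1, A2, BETA, SE, P, N.
#'
#' @param gwas GWAS summary data.frame (internal lower-case columns).
#' @param path file path.
#' @return \code{path}, invisibly (writer); a GWAS data.frame with the
#'   package's lower-case columns (reader).
#' @export
writeGwasTable <- function(gwas, path) {
  .checkGwasTable(gwas)
  out <- gwas[, c("snp", "chr", "bp", "a1", "a2", "beta", "se", "p", "n")]
  names(out) <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N")
  .writeTsv(out, path)
}

#' @rdname writeGwasTable
#' @export
readGwasTable <- function(path) {
  df <- .readTsv(path)
  names(df) <- tolower(names(df))
  .checkGwasTable(df)
  df
}

#' Write / read PRS weights
#'
#' Columns SNP, A1, WEIGHT, with the training scale and selected p-value
#' threshold stamped as comment lines.
#'
#' @param model a [PrsModel-class].
#' @param path file path.
#' @return \code{path}, invisibly (writer); a [PrsModel-class] (reader).
#' @export
writePrsModel <- function(model, path) {
  stopifnot(is(model, "PrsModel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.stamp(), con)
  writeLines(sprintf("# train_scale=%s p_threshold=%g",
                     model@trainScale, model@pThresholdUsed), con)
  w <- model@weights
  names(w) <- c("SNP", "A1", "WEIGHT")
  utils::write.table(w, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePrsModel
#' @export
readPrsModel <- function(path) {
  hdr <- readLines(path, n = 5L)
  meta <- grep("train_scale=", hdr, value = TRUE)
  trainScale <- sub(".*train_scale=(\\S+).*", "\\1", meta)
  pThr <- as.numeric(sub(".*p_threshold=(\\S+).*", "\\1", meta))
  w <- .readTsv(path)
  names(w) <- c("snp", "a1", "weight")
  new("PrsModel", weights = w, trainScale = trainScale, pThresholdUsed = pThr)
}

#' Write / read a simulation config as YAML
#'
#' @param config a [SimulationConfig-class].
#' @param path file path.
#' @return \code{path}, invisibly (writer); a [SimulationConfig-class]
#'   (reader).
#' @export
writeSimulationConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  x <- list(nSamples = config@nSamples, nPgs = config@nPgs, h2 = config@h2,
            envVar = config@envVar, gamma = config@gamma,
            observationScale = config@observationScale,
            locationShift = config@locationShift,
            envType = config@envType, envFreq = config@envFreq,
            seed = config@seed,
            package_version = as.character(utils::packageVersion("scaleGxE")))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeSimulationConfig
#' @export
readSimulationConfig <- function(path) {
  x <- yaml::read_yaml(path)
  simulationConfig(nSamples = x$nSamples, nPgs = x$nPgs, h2 = x$h2,
                   envVar = x$envVar, gamma = x$gamma,
                   observationScale = x$observationScale,
                   locationShift = if (is.null(x$locationShift)) NA_real_ else x$locationShift,
                   envType = x$envType, envFreq = x$envFreq, seed = x$seed)
}

#' Write a lambda profile as a TSV
#'
#' One row per transformation (grid lambdas, then RINT when present) with
#' the p-value; the threshold and classification ride along as columns.
#'
#' @param profile a [LambdaProfile-class].
#' @param path file path.
#' @param pgsId identifier stamped into the \code{pgs_id} column.
#' @return \code{path}, invisibly.
#' @export
writeLambdaProfile <- function(profile, path, pgsId = "PGS_1") {
  stopifnot(is(profile, "LambdaProfile"))
  df <- data.frame(pgs_id = pgsId,
                   transform = .TRANSFORM_LABELS(profile@lambdas, !is.na(profile@rintP)),
                   lambda = c(profile@lambdas, if (!is.na(profile@rintP)) NA_real_),
                   p_value = c(profile@pValues, if (!is.na(profile@rintP)) profile@rintP),
                   threshold = profile@threshold,
                   classification = profile@classification,
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
}
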