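#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML (or an equivalent R list) with sections
#' `genotypes` (either `source: simulate` plus [genotypeSimConfig()]
#' fields, or `source: file` with `path`/`format`), `qc`
#' ([qcConfig()] fields), `trait` ([architectureConfig()] fields), `cv`
#' (`k`, `replicates`), `methods` (a character vector of method names or
#' a named list of per-method config overrides), plus top-level `seed`,
#' `predictor_set` and `truth_target`. Validation errors name the
#' offending field.
#'
#' @param path YAML file path.
#' @return A validated config list of class `runConfig`.
#' @export
readRunConfig <- function(path) {
  .check(file.exists(path), "config file not found: %s", path)
  validateRunConfig(yaml::read_yaml(path))
}

#' @describeIn readRunConfig validate a configuration list directly.
#' @param config a raw configuration list.
#' @export
validateRunConfig <- function(config) {
  .check(is.list(config), "config must be a list")
  defaults <- list(seed = 1L,
                   predictor_set = "all",
                   truth_target = "genetic_value",
                   genotypes = list(source = "simulate"),
                   qc = list(),
                   trait = list(),
                   cv = list(k = 5L, replicates = 5L),
                   methods = "gblup")
  unknown <- setdiff(names(config), names(defaults))
  .check(length(unknown) == 0, "unknown config field(s): %s",
         paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)

  .check(cfg$genotypes$source %in% c("simulate", "file"),
         "genotypes.source must be 'simulate' or 'file'")
  if (cfg$genotypes$source == "file") {
    .check(!is.null(cfg$genotypes$path), "genotypes.path is required")
    .check(file.exists(cfg$genotypes$path),
           "genotypes.path: file not found: %s", cfg$genotypes$path)
  }
  .check(cfg$predictor_set %in% c("all", "causal", "markers"),
         "predictor_set must be 'all', 'causal' or 'markers'")
  .check(cfg$truth_target %in% c("genetic_value", "phenotype"),
         "truth_target must be 'genetic_value' or 'phenotype'")

  methodNames <- if (is.character(cfg$methods)) cfg$methods else names(cfg$methods)
  bad <- setdiff(methodNames, .benchmarkMethods)
  .check(length(bad) == 0, "methods: unknown method name(s): %s",
         paste(bad, collapse = ", "))
  .check(length(methodNames) > 0, "methods: at least one method required")
  class(cfg) <- "runConfig"
  cfg
}

.writeTSV <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  path
}

#' Run the end-to-end simulation and benchmarking pipeline
#'
#' Executes genotype acquisition (simulation or file), quality control,
#' trait simulation, the cross-validated benchmark and its summary, and
#' writes all artifacts to `outDir`: `genotype_qc.tsv` (per-rule removed
#' SNPs), `qtn_effects.tsv` and `epistatic_pairs.tsv` (simulation truth),
#' `phenotype.tsv` (per-individual components), `metrics.tsv`,
#' `summary.tsv` and `manifest.json` (file list with MD5 content hashes,
#' the config echo and the master seed). Re-running with an identical
#' config reproduces every artifact bit-identically.
#'
#' All stage seeds derive deterministically from the master seed.
#'
#' @param config a `runConfig` (from [readRunConfig()] /
#'   [validateRunConfig()]) or a path to a YAML config.
#' @param outDir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!inherits(config, "runConfig")) config <- validateRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  files <- character(0)

  # --- genotypes ---
  if (config$genotypes$source == "simulate") {
    gsc <- .mergeConfig(
      unclass(genotypeSimConfig(seed = deriveSeed(seed, "genotypes"))),
      config$genotypes[setdiff(names(config$genotypes), c("source", "seed"))],
      "genotypes")
    g <- simulateGenotypes(do.call(genotypeSimConfig, gsc))
  } else {
    g <- readGenotypes(config$genotypes$path,
                       format = config$genotypes$format %||% "tsv")
  }

  # --- QC ---
  qcc <- do.call(qcConfig, config$qc)
  qcRes <- applyQC(g, qcc)
  g <- qcRes$genotypes
  qcDF <- do.call(rbind, lapply(c("chrom", "maf", "missing", "hwe"), function(rule) {
    ids <- qcRes$report[[rule]]
    if (length(ids) == 0) return(NULL)
    data.frame(rule = rule, snp = ids)
  }))
  if (is.null(qcDF)) qcDF <- data.frame(rule = character(0), snp = character(0))
  files <- c(files, .writeTSV(qcDF, file.path(outDir, "genotype_qc.tsv")))

  # --- trait simulation ---
  arch <- do.call(architectureConfig,
                  c(config$trait, list(seed = deriveSeed(seed, "trait"))))
  sim <- simulateTrait(g, arch)
  eff <- sim$effects
  q <- sim$qtn
  qtnDF <- data.frame(snp = snpIDs(g)[qtnIndices(q)],
                      column = qtnIndices(q), core = q@coreFlags,
                      additive = eff@additive, dominance = eff@dominance,
                      substitution = eff@substitution)
  files <- c(files, .writeTSV(qtnDF, file.path(outDir, "qtn_effects.tsv")))
  pairDF <- if (nrow(eff@pairs) > 0)
    data.frame(k = eff@pairs[, 1], kp = eff@pairs[, 2],
               aa = eff@epiAA, ad = eff@epiAD, da = eff@epiDA, dd = eff@epiDD)
  else data.frame(k = integer(0), kp = integer(0), aa = numeric(0),
                  ad = numeric(0), da = numeric(0), dd = numeric(0))
  files <- c(files, .writeTSV(pairDF, file.path(outDir, "epistatic_pairs.tsv")))
  trait <- sim$trait
  phenoDF <- data.frame(sample = sampleIDs(g), phenotype = phenotype(trait),
                        gTotal = geneticValue(trait),
                        gAdditive = trait@gAdditive,
                        gDominance = trait@gDominance,
                        gEpistatic = trait@gEpistatic,
                        residual = trait@residual)
  files <- c(files, .writeTSV(phenoDF, file.path(outDir, "phenotype.tsv")))

  # --- benchmark ---
  cvc <- .mergeConfig(list(k = 5L, replicates = 5L), config$cv, "cv")
  plan <- makeCVFolds(nSamples(g), k = cvc$k, replicates = cvc$replicates,
                      seed = deriveSeed(seed, "cv"))
  methodNames <- if (is.character(config$methods)) config$methods else
    names(config$methods)
  configs <- if (is.list(config$methods)) config$methods else
    setNames(vector("list", length(methodNames)), methodNames)
  metrics <- runBenchmark(g, trait, methods = methodNames, plan = plan,
                          predictorSet = config$predictor_set, qtn = q,
                          truthTarget = config$truth_target,
                          configs = configs, scenario = "pipeline")
  files <- c(files, .writeTSV(metrics, file.path(outDir, "metrics.tsv")))
  files <- c(files, .writeTSV(summarizeMetrics(metrics),
                              file.path(outDir, "summary.tsv")))

  # --- manifest with content hashes ---
  manifest <- list(
    seed = seed,
    config = unclass(config),
    realizedPartition = as.list(realizedPartition(trait)),
    files = lapply(setNames(files, basename(files)),
                   function(f) list(md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
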