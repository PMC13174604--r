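## Orchestration: a validated run configuration and a staged pipeline whose
## stages exchange diff-able TSV artifacts (tab-separated, header row, no
## quoting). Every stage is a pure function of its declared inputs, so a
## rerun with identical config and seed is bit-identical.

.CONFIG_DEFAULTS <- list(
  paths = list(reference_fasta = NULL, sample_sheet = NULL,
               structure_file = NULL, design_manifest = NULL),
  parameters = list(min_input = 10, pseudocount = 1e-6, max_mismatches = 2,
                    min_overlap = 20, max_mismatch_rate = 0.1,
                    threshold_construct = "CrPV",
                    reference_condition = "control"),
  simulate = list(conditions = "control", n_reads = 20000, epsilon = 0.001,
                  te_range = c(-5, 5), duplication_mean = 1.5,
                  spike_ratio = c(0.01, 0.1, 1),
                  stress_gcap_factor = 0.6, stress_global_ip_factor = 1),
  seed = 1
)

.checkNum <- function(x, at, positive = FALSE, len = 1L) {
  if (!is.numeric(x) || (!is.null(len) && length(x) != len) || anyNA(x))
    stop("type error at ", at, ": expected numeric", call. = FALSE)
  if (positive && any(x <= 0))
    stop("validation error at ", at, ": must be positive", call. = FALSE)
  x
}

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or a nested list with blocks `paths`,
#' `parameters`, `simulate` and a top-level `seed`. Unknown keys are
#' rejected; missing keys get defaults (which match the quantification
#' defaults used throughout the package: min_input 10, pseudocount
#' 0.000001, max_mismatches 2, CrPV threshold, control reference).
#'
#' @param config YAML path or list (empty list = all defaults).
#' @return the normalized config list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  for (blk in c("paths", "parameters", "simulate")) {
    unknown <- setdiff(names(config[[blk]]), names(.CONFIG_DEFAULTS[[blk]]))
    if (length(unknown))
      stop("unknown key(s) at ", blk, ": ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(.CONFIG_DEFAULTS, config)
  p <- cfg$parameters
  .checkNum(p$min_input, "parameters.min_input")
  .checkNum(p$pseudocount, "parameters.pseudocount", positive = TRUE)
  .checkNum(p$max_mismatches, "parameters.max_mismatches")
  .checkNum(p$min_overlap, "parameters.min_overlap")
  .checkNum(p$max_mismatch_rate, "parameters.max_mismatch_rate")
  .checkNum(cfg$seed, "seed")
  s <- cfg$simulate
  .checkNum(s$n_reads, "simulate.n_reads", positive = TRUE)
  .checkNum(s$epsilon, "simulate.epsilon")
  .checkNum(s$te_range, "simulate.te_range", len = 2L)
  .checkNum(s$duplication_mean, "simulate.duplication_mean", positive = TRUE)
  .checkNum(s$spike_ratio, "simulate.spike_ratio", positive = TRUE, len = 3L)
  cfg
}

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the pipeline end to end
#'
#' Stages run in fixed order (`simulate`, `process`, `quant`, `stress`,
#' `classify`, `profile`), each reading its predecessor's TSV artifacts
#' from `outdir`: `samples.tsv`, `counts.tsv` + `report.tsv`,
#' `te_<condition>.tsv`, `differential.tsv`, `activity.tsv`,
#' `profile.tsv`. A `manifest.json` records the config and per-stage row
#' counts. Stages needing inputs that are absent fail with the file named.
#'
#' @param config a config list or YAML path, see [validateConfig()].
#' @param stages subset of the stage names (default: all applicable).
#' @param outdir artifact directory (created if needed).
#' @param seed overrides `config$seed`.
#' @return invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config = list(),
                        stages = c("simulate", "process", "quant", "stress",
                                   "classify", "profile"),
                        outdir = ".", seed = NULL) {
  cfg <- validateConfig(config)
  if (!is.null(seed)) cfg$seed <- seed
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  art <- list(samples = file.path(outdir, "samples.tsv"),
              counts = file.path(outdir, "counts.tsv"),
              report = file.path(outdir, "report.tsv"),
              manifest = file.path(outdir, "manifest.json"))
  rowCounts <- list()
  lib <- NULL
  getLib <- function() {
    if (is.null(lib)) {
      fa <- cfg$paths$reference_fasta
      if (is.null(fa) || !file.exists(fa))
        stop("reference FASTA not found: ",
             if (is.null(fa)) "(paths.reference_fasta unset)" else fa)
      lib <<- loadConstructs(fa)
    }
    lib
  }

  if ("simulate" %in% stages) {
    s <- cfg$simulate
    library <- getLib()
    truth <- buildTruth(library, config = list(
      epsilon = s$epsilon, teRange = s$te_range,
      duplicationMean = s$duplication_mean, spikeRatio = s$spike_ratio,
      readsPerSample = as.integer(s$n_reads)), seed = cfg$seed)
    truths <- list(control = truth)
    if ("stress" %in% s$conditions) {
      st <- scaleTrueTE(truth, s$stress_gcap_factor, capClass = "g_cap",
                        includeSpikeIns = FALSE)
      truths$stress <- scaleTrueTE(st, s$stress_global_ip_factor)
    }
    samples <- expand.grid(role = c("input", "IP"), condition = s$conditions,
                           bio_rep = 1L, tech_rep = 1L,
                           stringsAsFactors = FALSE)
    samples$sample_id <- paste(samples$role, samples$condition,
                               samples$bio_rep, samples$tech_rep, sep = "_")
    samples <- simulateExperiment(truths, library, samples, outdir,
                                  seed = cfg$seed)
    cfg$paths$sample_sheet <- art$samples
    rowCounts$simulate <- nrow(samples)
    .stageLog("simulate", nrow(samples), " samples written")
  }

  if ("process" %in% stages) {
    sheet <- cfg$paths$sample_sheet
    if (is.null(sheet)) sheet <- art$samples
    if (!file.exists(sheet)) stop("sample sheet not found: ", sheet)
    cc <- buildCapCounts(sheet, getLib(),
                         minOverlap = cfg$parameters$min_overlap,
                         maxMismatchRate = cfg$parameters$max_mismatch_rate,
                         maxMismatches = cfg$parameters$max_mismatches)
    long <- data.frame(SummarizedExperiment::rowData(cc)[
      rep(seq_len(nrow(cc)), ncol(cc)), c("construct_id", "cap_class")],
      sample_id = rep(colnames(cc), each = nrow(cc)),
      umi_count = as.vector(SummarizedExperiment::assay(cc, "counts")))
    .writeTsv(long, art$counts)
    .writeTsv(S4Vectors::metadata(cc)$reports, art$report)
    rowCounts$process <- nrow(long)
    .stageLog("process", nrow(long), " count rows written")
  }

  teArt <- function(cond) file.path(outdir, paste0("te_", cond, ".tsv"))
  if ("quant" %in% stages) {
    if (!file.exists(art$counts)) stop("counts file not found: ", art$counts)
    sheet <- cfg$paths$sample_sheet
    if (is.null(sheet)) sheet <- art$samples
    samples <- .readTsv(sheet)
    counts <- .readTsv(art$counts)
    cc <- CapCounts(counts, samples, getLib())
    tes <- teFromCounts(cc, minInput = cfg$parameters$min_input,
                        pseudocount = cfg$parameters$pseudocount)
    if (is(tes, "TETable")) tes <- setNames(list(tes),
                                            S4Vectors::metadata(tes)$condition)
    for (cond in names(tes)) writeTETable(tes[[cond]], teArt(cond))
    rowCounts$quant <- sum(vapply(tes, nrow, 0L))
    art <- c(art, setNames(lapply(names(tes), teArt), paste0("te_", names(tes))))
    .stageLog("quant", "TE tables: ", paste(names(tes), collapse = ", "))
  }

  readTE <- function(cond) {
    f <- teArt(cond)
    if (!file.exists(f)) stop("TE table not found: ", f)
    df <- .readTsv(f)
    .TETable(df[setdiff(names(df), "condition")], cond,
             cfg$parameters$pseudocount, cfg$parameters$min_input)
  }

  if ("stress" %in% stages) {
    ref <- cfg$parameters$reference_condition
    teFiles <- list.files(outdir, pattern = "^te_.*\\.tsv$")
    conds <- sub("^te_(.*)\\.tsv$", "\\1", teFiles)
    if (length(conds) < 2L)
      stop("stress stage needs TE tables for two conditions under ", outdir)
    tes <- setNames(lapply(conds, readTE), conds)
    spikes <- spikeInSetFromLibrary(getLib())
    spikes <- fitSpikeInFactors(tes, spikes, reference = ref)
    other <- setdiff(conds, ref)[1]
    diffte <- differentialTE(adjustTE(tes[[ref]], spikes),
                             adjustTE(tes[[other]], spikes))
    art$differential <- file.path(outdir, "differential.tsv")
    .writeTsv(as.data.frame(diffte), art$differential)
    rowCounts$stress <- nrow(diffte)
    .stageLog("stress", sprintf("factor[%s] = %.4g", other,
                                normFactors(spikes)[[other]]))
  }

  if ("classify" %in% stages) {
    calls <- classifyActive(readTE(cfg$parameters$reference_condition),
                            cfg$parameters$threshold_construct)
    art$activity <- file.path(outdir, "activity.tsv")
    .writeTsv(as.data.frame(calls), art$activity)
    rowCounts$classify <- nrow(calls)
    .stageLog("classify", sum(calls$label == "active"), " active constructs")
  }

  if ("profile" %in% stages) {
    man <- cfg$paths$design_manifest
    if (is.null(man) || !file.exists(man))
      stop("design manifest not found: ",
           if (is.null(man)) "(paths.design_manifest unset)" else man)
    prof <- mutagenesisProfile(readTE(cfg$parameters$reference_condition), man)
    art$profile <- file.path(outdir, "profile.tsv")
    .writeTsv(as.data.frame(prof), art$profile)
    rowCounts$profile <- nrow(prof)
    .stageLog("profile", nrow(prof), " windows profiled")
  }

  manifest <- list(package = "iresMPRA",
                   version = as.character(utils::packageVersion("iresMPRA")),
                   seed = cfg$seed, parameters = cfg$parameters,
                   config_hash = digestConfig(cfg), row_counts = rowCounts)
  jsonlite::write_json(manifest, art$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(art)
}

#' @rdname runPipeline
#' @export
digestConfig <- function(cfg) {
  ## stable content hash without extra dependencies
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}
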