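.FEATURE_META_COLS <- c("feature_id", "assay_id", "mz", "rt", "annotation",
                        "lipid_class")
.SAMPLE_META_COLS <- c("sample_id", "subject_id", "family_id", "genotype",
                       "age", "sex", "cohort", "fasting", "is_qc")

# full-precision numeric formatting so write -> read round-trips exactly
.fmtNum <- function(v) {
    out <- formatC(v, digits = 17, format = "g")
    out[is.na(v)] <- ""
    out
}

#' Read a feature table from delimited text
#'
#' Tab-separated file with one row per feature: the reserved metadata
#' columns `feature_id`, `assay_id`, `mz`, `rt`, `annotation`, `lipid_class`
#' first, then one column per sample. Empty cells are missing values.
#'
#' @param path file path.
#' @return A list with `values` (numeric matrix, features x samples) and
#'   `featureData` (data.frame of the metadata columns). Duplicate feature
#'   ids and non-positive peak areas are rejected with the offending row
#'   named.
#' @export
readFeatureTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            na.strings = c("", "NA"),
                            stringsAsFactors = FALSE)
    miss <- setdiff(.FEATURE_META_COLS, colnames(df))
    if (length(miss))
        stop("feature table ", path, " lacks column(s): ",
             paste(miss, collapse = ", "))
    dup <- which(duplicated(df$feature_id))
    if (length(dup))
        stop("duplicate feature id '", df$feature_id[dup[1L]],
             "' at data row ", dup[1L])
    sampleCols <- setdiff(colnames(df), .FEATURE_META_COLS)
    if (!length(sampleCols)) stop("feature table has no sample columns")
    vals <- as.matrix(df[, sampleCols, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- df$feature_id
    bad <- which(rowSums(!is.na(vals) & vals <= 0) > 0L)
    if (length(bad))
        stop("non-positive peak area for feature '", df$feature_id[bad[1L]],
             "' (data row ", bad[1L], ")")
    fd <- df[, setdiff(.FEATURE_META_COLS, "feature_id"), drop = FALSE]
    rownames(fd) <- df$feature_id
    list(values = vals, featureData = fd)
}

#' Read a sample-metadata table from delimited text
#'
#' @param path tab-separated file with columns `sample_id`, `subject_id`,
#'   `family_id`, `genotype` (`carrier`/`non-carrier`, empty for pooled QC),
#'   `age`, `sex`, `cohort`, `fasting`, `is_qc`.
#' @return data.frame with rownames = sample ids; unknown genotype codes are
#'   rejected with the offending row named.
#' @export
readSampleMeta <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            na.strings = c("", "NA"),
                            stringsAsFactors = FALSE)
    miss <- setdiff(.SAMPLE_META_COLS, colnames(df))
    if (length(miss))
        stop("sample metadata ", path, " lacks column(s): ",
             paste(miss, collapse = ", "))
    bad <- which(!is.na(df$genotype) &
                 !df$genotype %in% c("carrier", "non-carrier"))
    if (length(bad))
        stop("unknown genotype code '", df$genotype[bad[1L]],
             "' at data row ", bad[1L])
    df$fasting <- as.logical(df$fasting)
    df$is_qc <- as.logical(df$is_qc)
    rownames(df) <- df$sample_id
    df[, setdiff(.SAMPLE_META_COLS, "sample_id"), drop = FALSE]
}

#' Assemble a MetaboExperiment from feature-table and sample-metadata files
#'
#' @param featurePath,samplePath paths for [readFeatureTable()] and
#'   [readSampleMeta()].
#' @return A [MetaboExperiment-class]; errors if the sample sets disagree.
#' @export
readStudy <- function(featurePath, samplePath) {
    ft <- readFeatureTable(featurePath)
    sm <- readSampleMeta(samplePath)
    missing <- setdiff(colnames(ft$values), rownames(sm))
    if (length(missing))
        stop("sample(s) in the feature table but not the metadata: ",
             paste(missing, collapse = ", "))
    MetaboExperiment(ft$values, ft$featureData,
                     sm[colnames(ft$values), , drop = FALSE])
}

#' Write a MetaboExperiment (and simulation outputs) as delimited text
#'
#' `writeFeatureTable`/`writeSampleMeta` write one [MetaboExperiment-class]
#' in the format [readFeatureTable()] / [readSampleMeta()] read (numeric
#' values at full precision, so a write-read round trip is exact).
#' `writeStudy` writes a [simulateStudy()] result: the feature table, sample
#' metadata, clinical lipids and the ground-truth tables.
#'
#' @param x a [MetaboExperiment-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
    stopifnot(is(x, "MetaboExperiment"))
    m <- assay(x, "peakarea")
    fd <- as.data.frame(featureMeta(x))
    df <- data.frame(feature_id = rownames(m),
                     assay_id = fd$assay_id, mz = .fmtNum(fd$mz),
                     rt = .fmtNum(fd$rt), annotation = fd$annotation,
                     lipid_class = fd$lipid_class,
                     stringsAsFactors = FALSE, check.names = FALSE)
    vals <- apply(m, 2L, .fmtNum)
    df <- cbind(df, vals)
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @export
writeSampleMeta <- function(x, path) {
    stopifnot(is(x, "MetaboExperiment"))
    sd <- as.data.frame(sampleMeta(x))
    df <- data.frame(sample_id = rownames(sd),
                     subject_id = sd$subject_id, family_id = sd$family_id,
                     genotype = sd$genotype, age = .fmtNum(sd$age),
                     sex = sd$sex, cohort = sd$cohort,
                     fasting = sd$fasting, is_qc = sd$is_qc,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @param sim a [simulateStudy()] result list.
#' @param dir output directory (created if absent).
#' @export
writeStudy <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeFeatureTable(sim$experiment, file.path(dir, "feature_table.tsv"))
    writeSampleMeta(sim$experiment, file.path(dir, "sample_meta.tsv"))
    utils::write.table(sim$clinical, file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, na = "", row.names = FALSE)
    tr <- sim$truth
    utils::write.table(
        data.frame(feature_id = names(trueEffects(tr)),
                   effect = .fmtNum(trueEffects(tr)),
                   affected = names(trueEffects(tr)) %in%
                       affectedFeatures(tr)),
        file.path(dir, "truth_features.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(sample_id = names(trueDilutions(tr)),
                   dilution = .fmtNum(trueDilutions(tr))),
        file.path(dir, "truth_samples.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(.fmtNum(tr@lod), file.path(dir, "truth_lod.txt"))
    invisible(dir)
}

#' Pipeline configuration
#'
#' Collects the thresholds and switches of the end-to-end pipeline. The
#' defaults are the analysis constants of the underlying design: QC RSD 30%,
#' QC detection 70%, sample missingness 50%, TPA mean + 3 SD, both-class
#' missingness 30%, FDR 0.05.
#'
#' @param rsdMax,detMin pooled-QC feature thresholds, percent.
#' @param sampleMissMax,tpaSD study-sample thresholds.
#' @param classMissMax both-class missingness threshold, percent.
#' @param fdrAlpha FDR threshold for both association tracks.
#' @param mode analysis mode: `"primary"` (fasting samples only),
#'   `"keep_nonfasting"`, or `"imputed"` (half-minimum imputation before
#'   normalization; fasting samples only).
#' @param imputeMethod imputation used in `"imputed"` mode.
#' @param pqnReference PQN reference mode (see [pqnNormalize()]).
#' @param heatmapExcludeClass lipid class(es) excluded from a second heatmap
#'   rendering (`NULL` to skip).
#' @param seed integer seed recorded in provenance.
#' @return Validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(rsdMax = 30, detMin = 70, sampleMissMax = 50,
                           tpaSD = 3, classMissMax = 30, fdrAlpha = 0.05,
                           mode = c("primary", "keep_nonfasting", "imputed"),
                           imputeMethod = c("half_min", "min", "none"),
                           pqnReference = c("study_median", "qc_median"),
                           heatmapExcludeClass = "TAG",
                           seed = 1L) {
    mode <- match.arg(mode)
    imputeMethod <- match.arg(imputeMethod)
    pqnReference <- match.arg(pqnReference)
    for (v in c(rsdMax, detMin, sampleMissMax, tpaSD, classMissMax))
        if (!is.numeric(v) || v < 0) stop("thresholds must be non-negative")
    if (fdrAlpha <= 0 || fdrAlpha >= 1) stop("fdrAlpha must lie in (0, 1)")
    cfg <- list(rsdMax = rsdMax, detMin = detMin,
                sampleMissMax = sampleMissMax, tpaSD = tpaSD,
                classMissMax = classMissMax, fdrAlpha = fdrAlpha,
                mode = mode, imputeMethod = imputeMethod,
                pqnReference = pqnReference,
                heatmapExcludeClass = heatmapExcludeClass,
                seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; absent keys take the
#' defaults.
#'
#' @param path YAML file.
#' @return A `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
    lst <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(names(lst), known)
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    do.call(pipelineConfig, lst)
}
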