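#' Run the full recall-by-genotype metabolomics pipeline
#'
#' Executes the whole analysis in order: pooled-QC feature filtering ->
#' sample filtering -> both-class missingness filtering -> (optional
#' left-censored imputation, `"imputed"` mode) -> probabilistic quotient
#' normalization -> rank inverse-normal transformation -> three-dataset
#' abundance association with BH-FDR -> presence/absence Fisher scan on the
#' pre-imputation table -> annotation deduplication per dataset ->
#' lipid-class summary -> variance-explained survey -> cohort table ->
#' figures. Per-stage feature/sample counts are kept in the filter log and
#' written, with versions, seed and thresholds, to a provenance file. All
#' steps are deterministic given the input and configuration.
#'
#' @param x a raw [MetaboExperiment-class] (e.g. from [simulateStudy()] or
#'   [readStudy()]).
#' @param clinical optional clinical-lipids data.frame (`sample_id` plus
#'   numeric traits) for the cohort table.
#' @param config a [pipelineConfig()].
#' @param outDir optional directory; when given, all result tables (TSV),
#'   the provenance file and figures (PNG) are written there.
#' @return A result bundle (list): `experiment` (preprocessed object with
#'   all assays and the filter log), `qcReport`, `filterLog`, `association`
#'   (see [runPrimaryAnalyses()]), `missingness` (see
#'   [runMissingnessScan()]), `overlap`, `metabolites` (deduplicated
#'   associated metabolites per dataset), `nUniqueMetabolites`,
#'   `classSummary`, `varianceExplained` (per-feature data.frame),
#'   `cohortTable`, `config`, `provenance`.
#' @export
runPipeline <- function(x, clinical = NULL, config = pipelineConfig(),
                        outDir = NULL) {
    stopifnot(is(x, "MetaboExperiment"), inherits(config, "PipelineConfig"))
    set.seed(config$seed)
    stage <- function(name, expr) {
        res <- tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        res
    }
    qcReport <- stage("feature_qc_stats",
                      featureQCStats(x, config$rsdMax, config$detMin))
    x <- stage("feature_qc_filter",
               applyFeatureQCFilter(x, qcReport, config$rsdMax,
                                    config$detMin))
    x <- stage("sample_filters",
               applySampleFilters(x, config$sampleMissMax, config$tpaSD))
    x <- stage("class_missingness",
               applyClassMissingnessFilter(x, config$classMissMax))
    preImputation <- x
    if (config$mode == "imputed")
        x <- stage("imputation", imputeLeftCensored(x, config$imputeMethod))
    x <- stage("pqn", pqnNormalize(x, config$pqnReference))
    x <- stage("rank_normal", rankNormalize(x))

    assocMode <- if (config$mode == "keep_nonfasting") "keep_nonfasting"
                 else "primary"
    assoc <- stage("association",
                   runPrimaryAnalyses(x, mode = assocMode,
                                      fdrAlpha = config$fdrAlpha))

    ## missingness track: real (pre-imputation) missingness, combined dataset
    sdPre <- colData(preImputation)
    combinedIds <- colnames(preImputation)[!sdPre$is_qc &
        (if (assocMode == "primary") sdPre$fasting %in% TRUE else TRUE)]
    missScan <- stage("missingness",
                      runMissingnessScan(preImputation, combinedIds,
                                         config$fdrAlpha))
    overlap <- overlapSummary(assoc$associated, attr(missScan, "discovered"))

    ## deduplicate associated features to metabolites, per dataset
    fd <- featureMeta(x)
    metabolites <- list()
    for (ds in assoc$datasets) {
        res <- assoc$results[assoc$results$dataset == ds &
                             assoc$results$feature %in% assoc$associated, ,
                             drop = FALSE]
        if (nrow(res)) metabolites[[ds]] <- dedupAnnotations(res, fd)
    }
    annotatedLabels <- unique(unlist(lapply(metabolites, function(m)
        m$metabolite[!is.na(m$metabolite)])))
    clsSummary <- if (!is.null(metabolites$combined))
        classSummary(metabolites$combined) else NULL

    ## variance-explained survey: simple OLS over all features, all samples
    rnt <- assay(x, "rnt")
    sdAll <- as.data.frame(colData(x))
    study <- !sdAll$is_qc
    ve <- t(vapply(seq_len(nrow(rnt)), function(i) {
        v <- varianceExplained(rnt[i, study], sdAll[study, , drop = FALSE])
        c(genotype = v$genotype, age = v$age, sex = v$sex, full = v$full)
    }, numeric(4)))
    varExpl <- data.frame(feature = rownames(rnt), ve,
                          stringsAsFactors = FALSE)

    cohort <- stage("cohort_table",
                    cohortTable(as.data.frame(colData(x))[study, ,
                                                          drop = FALSE],
                                clinical))

    provenance <- list(
        package = as.character(utils::packageVersion("metaboRBG")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = config$seed,
        mode = config$mode,
        thresholds = config[c("rsdMax", "detMin", "sampleMissMax", "tpaSD",
                              "classMissMax", "fdrAlpha")],
        stage_counts = filterLog(x))

    bundle <- list(experiment = x, qcReport = qcReport,
                   filterLog = filterLog(x), association = assoc,
                   missingness = missScan, overlap = overlap,
                   metabolites = metabolites,
                   nUniqueMetabolites = length(annotatedLabels),
                   classSummary = clsSummary,
                   varianceExplained = varExpl, cohortTable = cohort,
                   config = config, provenance = provenance)
    if (!is.null(outDir)) .writeBundle(bundle, outDir)
    bundle
}

# write all result tables, the provenance file and figures to outDir
.writeBundle <- function(bundle, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) {
        num <- vapply(df, is.numeric, logical(1))
        df[num] <- lapply(df[num], .fmtNum)
        utils::write.table(df, file.path(outDir, name), sep = "\t",
                           quote = FALSE, na = "", row.names = FALSE)
    }
    wt(bundle$association$results, "association_results.tsv")
    wt(bundle$missingness, "missingness_results.tsv")
    wt(bundle$filterLog, "filter_log.tsv")
    wt(bundle$varianceExplained, "variance_explained.tsv")
    if (!is.null(bundle$cohortTable)) wt(bundle$cohortTable,
                                         "cohort_table.tsv")
    if (!is.null(bundle$classSummary)) wt(bundle$classSummary,
                                          "class_summary.tsv")
    for (ds in names(bundle$metabolites))
        wt(bundle$metabolites[[ds]], sprintf("metabolites_%s.tsv", ds))
    writeLines(yaml::as.yaml(list(
        provenance = bundle$provenance[setdiff(names(bundle$provenance),
                                               "stage_counts")],
        overlap = bundle$overlap,
        n_unique_metabolites = bundle$nUniqueMetabolites)),
        file.path(outDir, "provenance.yaml"))

    combMet <- bundle$metabolites$combined
    x <- bundle$experiment
    if (!is.null(combMet) && nrow(combMet) >= 2L) {
        try({
            plotAssociationHeatmap(x, combMet,
                                   file = file.path(outDir, "heatmap.png"))
            excl <- bundle$config$heatmapExcludeClass
            if (!is.null(excl) &&
                sum(!(combMet$lipid_class %in% excl)) >= 2L)
                plotAssociationHeatmap(x, combMet, excludeClass = excl,
                                       file = file.path(outDir,
                                           "heatmap_no_target_class.png"))
            plotEffectByMz(combMet, featureMeta(x),
                           file = file.path(outDir, "effect_by_mz.png"))
        }, silent = TRUE)
    }
    invisible(outDir)
}
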