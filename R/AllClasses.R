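#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames rowData rowData<- colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.REQUIRED_FEATURE_COLS <- c("assay_id", "mz", "rt", "annotation", "lipid_class")
.REQUIRED_SAMPLE_COLS <- c("subject_id", "family_id", "genotype", "age", "sex",
                           "cohort", "fasting", "is_qc")
.ASSAY_LEVELS <- c("HILIC-POS", "HILIC-NEG", "LIPIDS-POS", "LIPIDS-NEG")

#' MetaboExperiment: an untargeted LC-MS feature table with study metadata
#'
#' `MetaboExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] to hold a positive
#' peak-area matrix (features x samples, `NA` marking a non-detected value) in
#' the `"peakarea"` assay, per-feature metadata (acquisition dataset, m/z,
#' retention time, optional annotation and lipid class) in `rowData`, and
#' per-sample design information (subject, family, genotype group, age, sex,
#' cohort, fasting and pooled-QC flags) in `colData`. Downstream steps add the
#' `"normalized"` (probabilistic quotient normalized) and `"rnt"` (rank
#' inverse-normal transformed) assays and keep provenance in `metadata()`.
#'
#' Validity requires: all present peak areas strictly positive; unique feature
#' and sample identifiers; genotype constant within subject; pooled-QC samples
#' carrying no genotype; mothers recorded as female.
#'
#' @slot .placeholder inherited SummarizedExperiment slots only.
#' @seealso [MetaboExperiment()] for the constructor, [peakAreas()],
#'   [featureMeta()], [sampleMeta()], [isQC()].
#' @export
setClass("MetaboExperiment", contains = "SummarizedExperiment")

setValidity("MetaboExperiment", function(object) {
    msg <- character()
    if (!"peakarea" %in% assayNames(object))
        msg <- c(msg, "assay 'peakarea' is required")
    fd <- rowData(object)
    sd <- colData(object)
    miss <- setdiff(.REQUIRED_FEATURE_COLS, colnames(fd))
    if (length(miss))
        msg <- c(msg, paste0("missing feature metadata column(s): ",
                             paste(miss, collapse = ", ")))
    miss <- setdiff(.REQUIRED_SAMPLE_COLS, colnames(sd))
    if (length(miss))
        msg <- c(msg, paste0("missing sample metadata column(s): ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) return(msg)
    m <- assay(object, "peakarea")
    if (any(m[!is.na(m)] <= 0))
        msg <- c(msg, "present peak areas must be strictly positive")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (any(!is.na(sd$genotype) &
            !sd$genotype %in% c("carrier", "non-carrier")))
        msg <- c(msg, "genotype must be 'carrier', 'non-carrier' or NA")
    if (any(sd$is_qc & !is.na(sd$genotype)))
        msg <- c(msg, "pooled-QC samples must carry no genotype")
    study <- !sd$is_qc
    if (any(study)) {
        gt <- split(as.character(sd$genotype[study]), sd$subject_id[study])
        bad <- vapply(gt, function(g) length(unique(g)) > 1L, logical(1))
        if (any(bad))
            msg <- c(msg, paste0("genotype differs within subject(s): ",
                                 paste(names(gt)[bad], collapse = ", ")))
        mum <- study & sd$cohort == "mother"
        if (any(mum & sd$sex != "F", na.rm = TRUE))
            msg <- c(msg, "mother-cohort samples must be female")
    }
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated recall-by-genotype study
#'
#' Returned alongside a simulated [MetaboExperiment] by [simulateStudy()];
#' carries what the generator knows and the analysis must recover: the true
#' standardized genotype effect per feature, the true per-sample dilution
#' factor, the limit-of-detection threshold applied (NA when no censoring),
#' the set of truly affected features, and the grouping of redundant features
#' under one metabolite label.
#'
#' @slot effect named numeric, true standardized effect per feature.
#' @slot dilution named numeric, true multiplicative dilution per sample.
#' @slot lod numeric(1), censoring threshold on the raw abundance scale.
#' @slot affected character, feature ids with nonzero true effect.
#' @slot annotationGroups named list, metabolite label -> member feature ids.
#' @export
setClass("SimTruth", representation(
    effect = "numeric",
    dilution = "numeric",
    lod = "numeric",
    affected = "character",
    annotationGroups = "list"
))

setValidity("SimTruth", function(object) {
    msg <- character()
    if (!setequal(object@affected,
                  names(object@effect)[object@effect != 0]))
        msg <- c(msg, "affected must equal the nonzero-effect feature set")
    if (any(object@dilution <= 0))
        msg <- c(msg, "dilution factors must be positive")
    if (length(msg)) msg else TRUE
})

#' Quality-control statistics for features and samples
#'
#' Produced by [featureQCStats()]. `featureStats` holds, per feature, the
#' pooled-QC relative standard deviation (percent), the pooled-QC detection
#' rate (percent) and the pass flag with reason codes. `sampleStats` holds,
#' per study sample and acquisition dataset, the missing-data percentage and
#' total peak area. `thresholds` records the cut-offs the flags used.
#'
#' @slot featureStats data.frame of per-feature QC metrics.
#' @slot sampleStats data.frame of per-sample, per-assay metrics.
#' @slot thresholds named list of numeric thresholds.
#' @export
setClass("QCReport", representation(
    featureStats = "data.frame",
    sampleStats = "data.frame",
    thresholds = "list"
))

setValidity("QCReport", function(object) {
    fs <- object@featureStats
    msg <- character()
    if (nrow(fs)) {
        if (any(fs$rsd_qc < 0, na.rm = TRUE))
            msg <- c(msg, "rsd_qc must be non-negative")
        if (any(fs$detection_qc < 0 | fs$detection_qc > 100, na.rm = TRUE))
            msg <- c(msg, "detection_qc must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
})
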