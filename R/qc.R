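#' Feature- and sample-level quality-control statistics
#'
#' Computes, per feature, the relative standard deviation (RSD,
#' `100 * sd / mean`, sample SD with denominator n-1) and the percentage
#' detection rate over pooled-QC injections, and, per study sample and
#' acquisition dataset, the missing-data percentage and total peak area (TPA).
#' A feature fails when its QC RSD exceeds `rsdMax` or its QC detection rate
#' falls below `detMin`; features never detected in QC get detection 0 and an
#' undefined RSD and fail. RSD is computed on the raw (not log) peak areas,
#' the convention of pooled-QC assessment in untargeted metabolomics.
#'
#' @param x a [MetaboExperiment-class] with at least two pooled-QC samples.
#' @param rsdMax maximum acceptable QC RSD, percent (default 30).
#' @param detMin minimum acceptable QC detection rate, percent (default 70).
#' @return A [QCReport-class].
#' @examples
#' sim <- simulateStudy(simConfig(nCarriers = 6L, seed = 11L))
#' rep <- featureQCStats(sim$experiment)
#' rep
#' @export
featureQCStats <- function(x, rsdMax = 30, detMin = 70) {
    stopifnot(is(x, "MetaboExperiment"))
    qc <- isQC(x)
    if (sum(qc) < 2L)
        stop("at least 2 pooled-QC samples are required to compute ",
             "QC RSD and detection rate (found ", sum(qc), ")")
    m <- assay(x, "peakarea")
    qm <- m[, qc, drop = FALSE]
    nQC <- ncol(qm)
    nPresent <- rowSums(!is.na(qm))
    mu <- rowMeans(qm, na.rm = TRUE)
    sdv <- apply(qm, 1L, stats::sd, na.rm = TRUE)
    rsd <- ifelse(nPresent >= 2L, 100 * sdv / mu, NA_real_)
    det <- 100 * nPresent / nQC
    ## an undefined RSD (<2 present QC values) is caught by the detection
    ## rule; the RSD rule applies only where the RSD is defined
    failRSD <- !is.na(rsd) & rsd > rsdMax
    failDet <- det < detMin
    reason <- character(nrow(m))
    reason[failRSD] <- "rsd_qc"
    reason[failDet] <- ifelse(nzchar(reason[failDet]),
                              paste0(reason[failDet], ";detection_qc"),
                              "detection_qc")
    featureStats <- data.frame(
        feature_id = rownames(m),
        rsd_qc = rsd,
        detection_qc = det,
        pass = !(failRSD | failDet),
        reason = reason,
        stringsAsFactors = FALSE)

    study <- which(!qc)
    assayId <- as.character(rowData(x)$assay_id)
    sampleStats <- do.call(rbind, lapply(unique(assayId), function(a) {
        sub <- m[assayId == a, study, drop = FALSE]
        data.frame(sample_id = colnames(sub),
                   assay_id = a,
                   missing_pct = 100 * colMeans(is.na(sub)),
                   tpa = colSums(sub, na.rm = TRUE),
                   stringsAsFactors = FALSE)
    }))
    rownames(sampleStats) <- NULL
    new("QCReport", featureStats = featureStats, sampleStats = sampleStats,
        thresholds = list(rsd_max = rsdMax, det_min = detMin))
}

#' Remove features failing pooled-QC quality control
#'
#' Drops features whose pooled-QC RSD exceeds `rsdMax` or whose QC detection
#' rate is below `detMin`, and appends the removal (ids and reason codes) to
#' the object's filter log.
#'
#' @param x a [MetaboExperiment-class].
#' @param report a [QCReport-class] computed on `x` by [featureQCStats()];
#'   recomputed when omitted.
#' @param rsdMax,detMin thresholds, percent.
#' @return The filtered [MetaboExperiment-class]; see [filterLog()].
#' @export
applyFeatureQCFilter <- function(x, report = NULL, rsdMax = 30, detMin = 70) {
    stopifnot(is(x, "MetaboExperiment"))
    if (is.null(report))
        report <- featureQCStats(x, rsdMax, detMin)
    fs <- report@featureStats
    if (!setequal(fs$feature_id, rownames(x)))
        stop("QC report feature ids do not match the table")
    fs <- fs[match(rownames(x), fs$feature_id), , drop = FALSE]
    failRSD <- !is.na(fs$rsd_qc) & fs$rsd_qc > rsdMax
    failDet <- fs$detection_qc < detMin
    drop <- failRSD | failDet
    reason <- character(nrow(fs))
    reason[failRSD] <- "rsd_qc"
    reason[failDet] <- ifelse(nzchar(reason[failDet]),
                              paste0(reason[failDet], ";detection_qc"),
                              "detection_qc")
    out <- x[!drop, ]
    .logFilter(out, "feature_qc", "feature",
               fs$feature_id[drop], reason[drop])
}

#' Remove outlying study samples
#'
#' Within each acquisition dataset, flags study samples with more than
#' `missMax` percent missing features or a total peak area (TPA) above
#' `mean(TPA) + tpaSD * sd(TPA)` (mean and SD over the study samples of that
#' dataset). Both rules are evaluated on the unfiltered input (not
#' sequentially re-estimated). A sample failing either rule in any dataset is
#' removed entirely. Pooled-QC samples are exempt: the filters address study
#' samples only.
#'
#' @param x a [MetaboExperiment-class].
#' @param missMax maximum percent missing per sample (default 50).
#' @param tpaSD number of SDs above the mean TPA tolerated (default 3).
#' @return The filtered [MetaboExperiment-class]; see [filterLog()].
#' @export
applySampleFilters <- function(x, missMax = 50, tpaSD = 3) {
    stopifnot(is(x, "MetaboExperiment"))
    m <- assay(x, "peakarea")
    qc <- isQC(x)
    study <- which(!qc)
    if (!length(study)) stop("no study samples present")
    assayId <- as.character(rowData(x)$assay_id)
    reasons <- stats::setNames(rep("", length(study)), colnames(x)[study])
    for (a in unique(assayId)) {
        sub <- m[assayId == a, study, drop = FALSE]
        if (!nrow(sub)) next
        missPct <- 100 * colMeans(is.na(sub))
        tpa <- colSums(sub, na.rm = TRUE)
        cut <- mean(tpa) + tpaSD * stats::sd(tpa)
        if (is.na(cut)) cut <- Inf          # single sample: sd undefined
        badMiss <- missPct > missMax
        badTPA <- tpa > cut
        tag <- character(length(study))
        tag[badMiss] <- sprintf("missing_pct[%s]", a)
        tag[badTPA] <- ifelse(nzchar(tag[badTPA]),
                              paste0(tag[badTPA], ";", sprintf("tpa[%s]", a)),
                              sprintf("tpa[%s]", a))
        has <- nzchar(tag)
        reasons[has] <- ifelse(nzchar(reasons[has]),
                               paste0(reasons[has], ";", tag[has]), tag[has])
    }
    dropIds <- names(reasons)[nzchar(reasons)]
    if (length(dropIds) == length(study))
        stop("sample filters would remove every study sample")
    keep <- !(colnames(x) %in% dropIds)
    out <- x[, keep]
    .logFilter(out, "sample_filters", "sample", dropIds,
               unname(reasons[dropIds]))
}

#' Remove features heavily missing in both genotype classes
#'
#' Computes, per feature, the percent missing separately among carrier and
#' non-carrier study samples and removes the feature only when both exceed
#' `missMax`. Features missing predominantly in one class are deliberately
#' retained: class-differential missingness is the signal the
#' presence/absence track tests.
#'
#' @param x a [MetaboExperiment-class], after sample filtering.
#' @param missMax maximum percent missing tolerated per class (default 30).
#' @return The filtered [MetaboExperiment-class]; see [filterLog()].
#' @export
applyClassMissingnessFilter <- function(x, missMax = 30) {
    stopifnot(is(x, "MetaboExperiment"))
    sd <- colData(x)
    carr <- which(!sd$is_qc & sd$genotype %in% "carrier")
    ctrl <- which(!sd$is_qc & sd$genotype %in% "non-carrier")
    if (!length(carr) || !length(ctrl))
        stop("both genotype classes must be non-empty")
    m <- assay(x, "peakarea")
    missCarr <- 100 * rowMeans(is.na(m[, carr, drop = FALSE]))
    missCtrl <- 100 * rowMeans(is.na(m[, ctrl, drop = FALSE]))
    drop <- missCarr > missMax & missCtrl > missMax
    out <- x[!drop, ]
    .logFilter(out, "class_missingness", "feature", rownames(x)[drop],
               rep("missing_both_classes", sum(drop)))
}
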