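#' Construct a MetaboExperiment
#'
#' Assembles a feature-by-sample peak-area matrix and its metadata into a
#' validated [MetaboExperiment-class] object.
#'
#' @param peakAreas numeric matrix, features x samples; `NA` marks a
#'   non-detected (missing) value; present values must be positive. Row names
#'   are feature ids, column names sample ids.
#' @param featureData data.frame (or DataFrame) with one row per feature and
#'   columns `assay_id` (one of `"HILIC-POS"`, `"HILIC-NEG"`, `"LIPIDS-POS"`,
#'   `"LIPIDS-NEG"`), `mz`, `rt`, `annotation` (NA when unannotated) and
#'   `lipid_class` (NA when unknown).
#' @param sampleData data.frame (or DataFrame) with one row per sample and
#'   columns `subject_id`, `family_id`, `genotype` (`"carrier"`,
#'   `"non-carrier"` or NA for pooled QC), `age`, `sex` (`"F"`/`"M"`),
#'   `cohort` (`"young"`/`"mother"`), `fasting` (logical), `is_qc` (logical).
#' @return A [MetaboExperiment-class].
#' @examples
#' m <- matrix(c(10, 20, 30, 40), 2, 2,
#'             dimnames = list(c("F1", "F2"), c("S1", "S2")))
#' fd <- data.frame(assay_id = "LIPIDS-NEG", mz = c(700.1, 800.2),
#'                  rt = c(120, 240), annotation = NA, lipid_class = NA)
#' sd <- data.frame(subject_id = c("A", "B"), family_id = c("fA", "fB"),
#'                  genotype = c("carrier", "non-carrier"), age = c(16, 17),
#'                  sex = "F", cohort = "young", fasting = TRUE,
#'                  is_qc = FALSE)
#' MetaboExperiment(m, fd, sd)
#' @export
MetaboExperiment <- function(peakAreas, featureData, sampleData) {
    peakAreas <- as.matrix(peakAreas)
    storage.mode(peakAreas) <- "double"
    if (is.null(rownames(peakAreas)))
        stop("peakAreas must have feature ids as row names")
    if (is.null(colnames(peakAreas)))
        stop("peakAreas must have sample ids as column names")
    fd <- DataFrame(featureData, row.names = rownames(peakAreas))
    sd <- DataFrame(sampleData, row.names = colnames(peakAreas))
    se <- SummarizedExperiment(assays = list(peakarea = peakAreas),
                               rowData = fd, colData = sd)
    new("MetaboExperiment", se)
}

#' Raw peak areas
#'
#' @param x a [MetaboExperiment-class].
#' @return Numeric matrix of raw peak areas (`NA` = missing).
#' @export
setMethod("peakAreas", "MetaboExperiment",
          function(x) assay(x, "peakarea"))

#' Feature metadata
#'
#' @param x a [MetaboExperiment-class].
#' @return `DataFrame` of per-feature metadata.
#' @export
setMethod("featureMeta", "MetaboExperiment", function(x) rowData(x))

#' Sample metadata
#'
#' @param x a [MetaboExperiment-class].
#' @return `DataFrame` of per-sample design information.
#' @export
setMethod("sampleMeta", "MetaboExperiment", function(x) colData(x))

#' Pooled-QC flag
#'
#' @param x a [MetaboExperiment-class].
#' @return Logical vector, `TRUE` for pooled-QC injections.
#' @export
setMethod("isQC", "MetaboExperiment", function(x) colData(x)$is_qc)

#' Estimated dilution quotients
#'
#' Per-sample median quotients estimated by [pqnNormalize()]; proportional to
#' the sample dilution under the multiplicative dilution model.
#'
#' @param x a [MetaboExperiment-class] that has been PQN-normalized.
#' @return Named numeric vector of per-sample quotients.
#' @export
setMethod("dilutionQuotients", "MetaboExperiment", function(x) {
    q <- metadata(x)$pqn$quotient
    if (is.null(q)) stop("no PQN normalization recorded; run pqnNormalize()")
    q
})

#' PQN reference spectrum
#'
#' @param x a [MetaboExperiment-class] that has been PQN-normalized.
#' @return Named numeric vector: reference abundance per feature.
#' @export
setMethod("pqnReference", "MetaboExperiment", function(x) {
    r <- metadata(x)$pqn$reference
    if (is.null(r)) stop("no PQN normalization recorded; run pqnNormalize()")
    r
})

#' Per-stage filter log
#'
#' @param x a [MetaboExperiment-class].
#' @return data.frame with one row per filtering stage applied so far:
#'   stage name, axis (`feature`/`sample`), counts in/removed/out, and a
#'   comma-separated list of removed ids with reason codes in
#'   `metadata(x)$removed`.
#' @export
setMethod("filterLog", "MetaboExperiment", function(x) {
    lg <- metadata(x)$filter_log
    if (is.null(lg))
        lg <- data.frame(stage = character(), axis = character(),
                         n_in = integer(), n_removed = integer(),
                         n_out = integer(), stringsAsFactors = FALSE)
    lg
})

setMethod("show", "MetaboExperiment", function(object) {
    m <- assay(object, "peakarea")
    sd <- colData(object)
    cat("class: MetaboExperiment\n")
    cat(sprintf("features: %d  samples: %d (%d study, %d pooled QC)\n",
                nrow(object), ncol(object), sum(!sd$is_qc), sum(sd$is_qc)))
    cat(sprintf("assays: %s\n", paste(assayNames(object), collapse = ", ")))
    cat(sprintf("acquisition datasets: %s\n",
                paste(sort(unique(rowData(object)$assay_id)), collapse = ", ")))
    gt <- table(factor(sd$genotype[!sd$is_qc],
                       levels = c("carrier", "non-carrier")))
    cat(sprintf("genotype: %d carrier / %d non-carrier samples\n",
                gt[["carrier"]], gt[["non-carrier"]]))
    cat(sprintf("missing: %.1f%% of study-sample cells\n",
                100 * mean(is.na(m[, !sd$is_qc, drop = FALSE]))))
    lg <- filterLog(object)
    if (nrow(lg))
        cat(sprintf("filters applied: %s\n", paste(lg$stage, collapse = " -> ")))
    invisible(NULL)
})

#' @describeIn SimTruth-class true standardized effect per feature.
#' @param x a `SimTruth`.
#' @export
setMethod("trueEffects", "SimTruth", function(x) x@effect)

#' @describeIn SimTruth-class true per-sample dilution factors.
#' @export
setMethod("trueDilutions", "SimTruth", function(x) x@dilution)

#' @describeIn SimTruth-class ids of features with nonzero true effect.
#' @export
setMethod("affectedFeatures", "SimTruth", function(x) x@affected)

#' @describeIn SimTruth-class metabolite label -> member feature ids.
#' @export
setMethod("annotationGroups", "SimTruth", function(x) x@annotationGroups)

setMethod("show", "SimTruth", function(object) {
    cat("class: SimTruth\n")
    cat(sprintf("features: %d (%d affected)  samples: %d\n",
                length(object@effect), length(object@affected),
                length(object@dilution)))
    cat(sprintf("lod: %s\n",
                if (is.na(object@lod)) "none" else format(object@lod)))
    cat(sprintf("annotated metabolite groups: %d\n",
                length(object@annotationGroups)))
    invisible(NULL)
})

setMethod("show", "QCReport", function(object) {
    fs <- object@featureStats
    cat("class: QCReport\n")
    cat(sprintf("features assessed: %d (%d fail)\n", nrow(fs), sum(!fs$pass)))
    cat(sprintf("sample/assay rows: %d\n", nrow(object@sampleStats)))
    cat(sprintf("thresholds: %s\n",
                paste(names(object@thresholds), unlist(object@thresholds),
                      sep = "=", collapse = ", ")))
    invisible(NULL)
})

# internal: append one stage to the filter log and the removal record
.logFilter <- function(x, stage, axis, removedIds, reasons) {
    lg <- filterLog(x)
    nIn <- if (axis == "feature") nrow(x) + length(removedIds)
           else ncol(x) + length(removedIds)
    lg <- rbind(lg, data.frame(stage = stage, axis = axis, n_in = nIn,
                               n_removed = length(removedIds),
                               n_out = nIn - length(removedIds),
                               stringsAsFactors = FALSE))
    metadata(x)$filter_log <- lg
    rem <- metadata(x)$removed
    if (is.null(rem)) rem <- list()
    rem[[stage]] <- data.frame(id = removedIds, reason = reasons,
                               stringsAsFactors = FALSE)
    metadata(x)$removed <- rem
    x
}
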