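#' Probabilistic quotient normalization (PQN)
#'
#' Corrects per-sample multiplicative dilution. The reference spectrum is the
#' feature-wise median over study samples (present values only; set
#' `reference = "qc_median"` for the pooled-QC median instead). For each
#' sample the quotients value/reference are formed over the features present
#' in both, the sample's dilution estimate is the median quotient, and every
#' present value is divided by it. Missing values stay missing. Under the
#' multiplicative model \eqn{v_{fi} = d_i \, p_f}, the estimated quotients
#' are proportional to the true dilutions \eqn{d_i} and normalization
#' recovers the common profile up to one global scalar.
#'
#' @param x a [MetaboExperiment-class], QC-filtered, with at least two
#'   features present per sample.
#' @param reference `"study_median"` (default) or `"qc_median"`.
#' @return `x` with a `"normalized"` assay added; the quotients and reference
#'   spectrum are retrievable with [dilutionQuotients()] and
#'   [pqnReference()].
#' @export
pqnNormalize <- function(x, reference = c("study_median", "qc_median")) {
    stopifnot(is(x, "MetaboExperiment"))
    reference <- match.arg(reference)
    m <- assay(x, "peakarea")
    refCols <- if (reference == "study_median") !isQC(x) else isQC(x)
    if (!any(refCols)) stop("no samples available for the PQN reference")
    ref <- apply(m[, refCols, drop = FALSE], 1L, stats::median, na.rm = TRUE)
    usable <- !is.na(ref) & ref > 0
    q <- vapply(seq_len(ncol(m)), function(j) {
        ok <- usable & !is.na(m[, j])
        if (sum(ok) < 1L)
            stop("sample '", colnames(m)[j],
                 "' shares no present features with the PQN reference")
        stats::median(m[ok, j] / ref[ok])
    }, numeric(1))
    names(q) <- colnames(m)
    norm <- sweep(m, 2L, q, "/")
    assay(x, "normalized") <- norm
    metadata(x)$pqn <- list(reference_mode = reference,
                            reference = stats::setNames(ref, rownames(m)),
                            quotient = q)
    x
}

#' Rank-based inverse-normal transform of one feature
#'
#' Maps the present values of a vector to standard-normal quantiles of their
#' ranks: value with rank \eqn{r} among \eqn{n} present values becomes
#' \eqn{\Phi^{-1}((r - 0.5)/n)}, ties receiving the average rank. Missing
#' values are preserved in place. The transform is strictly monotone where
#' ranks are untied and forces an approximately standard-normal marginal
#' regardless of the input distribution.
#'
#' @param v numeric vector, possibly with `NA`; at least 3 present values.
#' @param zeroIfConstant when all present values are identical the transform
#'   is undefined (one tie block); `TRUE` returns zeros there instead of
#'   erroring.
#' @return Numeric vector of the same length, `NA` preserved.
#' @examples
#' rankNormalTransform(c(10, 20, 30))   # -0.967, 0, 0.967
#' @export
rankNormalTransform <- function(v, zeroIfConstant = FALSE) {
    present <- !is.na(v)
    n <- sum(present)
    if (n < 3L) stop("rank-normal transform needs at least 3 present values")
    vv <- v[present]
    if (length(unique(vv)) == 1L) {
        if (!zeroIfConstant)
            stop("all present values identical; transform undefined ",
                 "(set zeroIfConstant = TRUE to map them to 0)")
        v[present] <- 0
        return(v)
    }
    r <- rank(vv, ties.method = "average")
    v[present] <- stats::qnorm((r - 0.5) / n)
    v
}

#' Rank-normalize every feature of a table
#'
#' Applies [rankNormalTransform()] row-wise to the `"normalized"` assay
#' (falling back to `"peakarea"` if PQN has not been run) and stores the
#' result as the `"rnt"` assay. Ranks are computed over study samples only:
#' pooled-QC injections play no part in the statistical analysis, and
#' letting their near-centre values occupy ranks would distort the study
#' samples' quantiles; their `"rnt"` entries are set to `NA`. Features with
#' fewer than 3 present study values or constant values are transformed to
#' all-zero (flagged in `metadata(x)$rnt_degenerate`).
#'
#' @param x a [MetaboExperiment-class].
#' @return `x` with the `"rnt"` assay added.
#' @export
rankNormalize <- function(x) {
    stopifnot(is(x, "MetaboExperiment"))
    src <- if ("normalized" %in% assayNames(x)) "normalized" else "peakarea"
    m <- assay(x, src)
    out <- m
    qc <- isQC(x)
    out[, qc] <- NA_real_
    study <- which(!qc)
    degenerate <- character()
    for (i in seq_len(nrow(m))) {
        vi <- m[i, study]
        pres <- !is.na(vi)
        if (sum(pres) < 3L || length(unique(vi[pres])) == 1L) {
            vi[pres] <- 0
            degenerate <- c(degenerate, rownames(m)[i])
        } else {
            vi <- rankNormalTransform(vi)
        }
        out[i, study] <- vi
    }
    assay(x, "rnt") <- out
    metadata(x)$rnt_degenerate <- degenerate
    x
}

#' Impute left-censored missing values
#'
#' Replaces each missing value by a feature-wise constant below the detection
#' range: half the feature's minimum present value (`"half_min"`, default),
#' the minimum itself (`"min"`), or nothing (`"none"`). Used by the
#' sensitivity analysis that re-runs the association scan on a fully observed
#' table; the primary analysis leaves missingness to the presence/absence
#' track instead.
#'
#' @param x a [MetaboExperiment-class], after the class-missingness filter.
#' @param method `"half_min"`, `"min"` or `"none"`.
#' @return `x` with missing peak areas filled in (except `"none"`); imputed
#'   cell positions are recorded in `metadata(x)$imputation`.
#' @export
imputeLeftCensored <- function(x, method = c("half_min", "min", "none")) {
    stopifnot(is(x, "MetaboExperiment"))
    method <- match.arg(method)
    if (method == "none") {
        metadata(x)$imputation <- list(method = "none", n_imputed = 0L)
        return(x)
    }
    m <- assay(x, "peakarea")
    allMissing <- rowSums(!is.na(m)) == 0L
    if (any(allMissing))
        stop("feature(s) entirely missing (should have been filtered): ",
             paste(rownames(m)[allMissing], collapse = ", "))
    fill <- apply(m, 1L, min, na.rm = TRUE)
    if (method == "half_min") fill <- fill / 2
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- fill[idx[, 1L]]
    assay(x, "peakarea") <- m
    metadata(x)$imputation <- list(method = method, n_imputed = nrow(idx),
                                   cells = idx)
    x
}
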