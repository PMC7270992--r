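#' Presence/absence contingency table for one feature
#'
#' Counts missing and present values by genotype class over the study
#' samples supplied. Must be computed on pre-imputation data: the
#' missingness being tested is real non-detection.
#'
#' @param feature a feature id present in `x`.
#' @param x a [MetaboExperiment-class] (post-filter, pre-imputation).
#' @param sampleIds sample ids defining the analysis dataset (default: all
#'   study samples).
#' @return 2x2 integer matrix, rows `missing`/`present`, columns
#'   `carrier`/`non-carrier`.
#' @export
missingnessTable <- function(feature, x, sampleIds = NULL) {
    stopifnot(is(x, "MetaboExperiment"))
    if (!feature %in% rownames(x))
        stop("feature '", feature, "' not in the table")
    sd <- colData(x)
    if (is.null(sampleIds))
        sampleIds <- colnames(x)[!sd$is_qc]
    v <- assay(x, "peakarea")[feature, sampleIds]
    gt <- sd[sampleIds, "genotype"]
    keep <- gt %in% c("carrier", "non-carrier")
    v <- v[keep]; gt <- factor(gt[keep], c("carrier", "non-carrier"))
    tab <- table(factor(is.na(v), c(TRUE, FALSE),
                        labels = c("missing", "present")), gt)
    m <- matrix(as.integer(tab), 2L, 2L,
                dimnames = list(c("missing", "present"),
                                c("carrier", "non-carrier")))
    m
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test with all margins fixed. The two-sided p-value is
#' the point-probability construction: the sum of hypergeometric
#' probabilities of all tables with the same margins whose probability does
#' not exceed that of the observed table (within a relative tolerance of
#' 1e-7, matching the conventional implementation).
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return p-value in `(0, 1]`; when a margin is zero the test is
#'   uninformative and `p = 1` is returned with attribute
#'   `degenerate = TRUE`.
#' @examples
#' fisherExact2x2(matrix(c(5, 0, 0, 5), 2))   # 2/choose(10, 5)
#' @export
fisherExact2x2 <- function(counts) {
    counts <- as.matrix(counts)
    if (!all(dim(counts) == 2L) || any(counts < 0) ||
        any(counts != round(counts)))
        stop("counts must be a 2x2 matrix of non-negative integers")
    r1 <- sum(counts[1L, ]); c1 <- sum(counts[, 1L]); c2 <- sum(counts[, 2L])
    if (r1 == 0L || sum(counts[2L, ]) == 0L || c1 == 0L || c2 == 0L) {
        p <- 1
        attr(p, "degenerate") <- TRUE
        return(p)
    }
    support <- max(0L, r1 - c2):min(r1, c1)
    dens <- stats::dhyper(support, c1, c2, r1)
    dObs <- stats::dhyper(counts[1L, 1L], c1, c2, r1)
    p <- sum(dens[dens <= dObs * (1 + 1e-7)])
    min(p, 1)
}

#' Scan every feature for genotype-differential missingness
#'
#' The presence/absence association track: for each retained feature of the
#' combined dataset, a two-sided Fisher's exact test compares the proportion
#' of missing values between carriers and non-carriers; BH adjustment is
#' applied across all tested features. This track catches features whose
#' concentration falls below the detection limit in one genotype class —
#' missing-not-at-random signal the abundance models cannot see.
#'
#' @param x a [MetaboExperiment-class], post-filter and pre-imputation.
#' @param sampleIds analysis samples (default: all fasting study samples,
#'   the combined dataset of the primary analysis).
#' @param fdrAlpha FDR threshold for declaring differential missingness.
#' @return data.frame with one row per feature: the four cell counts
#'   (`n_miss_carrier`, `n_miss_control`, `n_pres_carrier`,
#'   `n_pres_control`), `p`, `q`, and `direction` (sign of carrier minus
#'   non-carrier missingness proportion). The ids declared differentially
#'   missing are in `attr(, "discovered")`.
#' @export
runMissingnessScan <- function(x, sampleIds = NULL, fdrAlpha = 0.05) {
    stopifnot(is(x, "MetaboExperiment"))
    sd <- colData(x)
    if (is.null(sampleIds))
        sampleIds <- colnames(x)[!sd$is_qc & sd$fasting %in% TRUE]
    m <- assay(x, "peakarea")[, sampleIds, drop = FALSE]
    gt <- sd[sampleIds, "genotype"]
    carr <- gt %in% "carrier"; ctrl <- gt %in% "non-carrier"
    nC <- sum(carr); nN <- sum(ctrl)
    if (nC == 0L || nN == 0L)
        stop("both genotype classes must be present")
    missC <- rowSums(is.na(m[, carr, drop = FALSE]))
    missN <- rowSums(is.na(m[, ctrl, drop = FALSE]))
    p <- vapply(seq_len(nrow(m)), function(i) {
        as.numeric(fisherExact2x2(matrix(c(missC[i], nC - missC[i],
                                           missN[i], nN - missN[i]), 2L)))
    }, numeric(1))
    out <- data.frame(feature = rownames(m),
                      n_miss_carrier = missC, n_miss_control = missN,
                      n_pres_carrier = nC - missC, n_pres_control = nN - missN,
                      p = p, q = bhAdjust(p),
                      direction = sign(missC / nC - missN / nN),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "discovered") <- out$feature[out$q < fdrAlpha]
    attr(out, "fdrAlpha") <- fdrAlpha
    out
}

#' Overlap between the abundance and missingness discovery sets
#'
#' Inclusion-exclusion bookkeeping of the two association tracks: how many
#' features each track declared, their intersection, and the union of
#' features influenced by genotype on either track.
#'
#' @param associated feature ids from the abundance track
#'   ([runPrimaryAnalyses()]).
#' @param differentiallyMissing feature ids from the missingness track
#'   ([runMissingnessScan()]).
#' @return A list of counts: `n_abundance`, `n_missingness`,
#'   `n_intersection`, `n_missingness_only`, `n_union`.
#' @export
overlapSummary <- function(associated, differentiallyMissing) {
    inter <- intersect(associated, differentiallyMissing)
    list(n_abundance = length(associated),
         n_missingness = length(differentiallyMissing),
         n_intersection = length(inter),
         n_missingness_only = length(setdiff(differentiallyMissing,
                                             associated)),
         n_union = length(union(associated, differentiallyMissing)))
}
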