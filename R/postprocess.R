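#' Collapse redundant annotations to one feature per metabolite
#'
#' Several LC-MS features (adducts, isotopes, cross-assay detections) can
#' represent one metabolite. Within each analysis dataset, features sharing
#' an annotation label are collapsed to the member with the strongest
#' association (smallest p-value; exact ties broken by the smaller feature
#' id, keeping the output run-to-run stable). Unannotated features pass
#' through ungrouped and are reported as features, not metabolites.
#'
#' @param results per-feature association results for one dataset: a
#'   data.frame with at least `feature` and `p` (e.g. one dataset's rows of
#'   [runPrimaryAnalyses()]`$results`).
#' @param featureData feature metadata with `annotation` and `lipid_class`
#'   columns, rownames = feature ids (e.g. [featureMeta()]).
#' @return data.frame with one row per metabolite label (plus one per
#'   unannotated feature): `metabolite`, `feature` (the representative),
#'   `lipid_class`, `n_members`, `members` (comma-separated ids) and the
#'   representative's result columns.
#' @export
dedupAnnotations <- function(results, featureData) {
    stopifnot(all(c("feature", "p") %in% colnames(results)))
    fd <- as.data.frame(featureData)
    ann <- fd[results$feature, "annotation"]
    cls <- fd[results$feature, "lipid_class"]
    res <- cbind(results,
                 metabolite = ifelse(is.na(ann), NA_character_,
                                     as.character(ann)),
                 lipid_class = as.character(cls),
                 stringsAsFactors = FALSE)
    key <- ifelse(is.na(res$metabolite),
                  paste0(".feature:", res$feature), res$metabolite)
    ## order by p then feature id: first row of each group is the winner
    ord <- order(key, res$p, res$feature, na.last = TRUE)
    res <- res[ord, , drop = FALSE]
    key <- key[ord]
    first <- !duplicated(key)
    members <- vapply(split(res$feature, key), paste, character(1),
                      collapse = ",")
    nMembers <- lengths(split(res$feature, key))
    out <- res[first, , drop = FALSE]
    out$n_members <- as.integer(nMembers[key[first]])
    out$members <- members[key[first]]
    rownames(out) <- NULL
    out[order(out$p, out$feature), , drop = FALSE]
}

#' Metabolite counts per lipid class
#'
#' Tabulates deduplicated metabolite results by lipid class: counts, column
#' percentages, and direction-of-effect tallies (how many class members
#' increase versus decrease in carriers).
#'
#' @param metabolites output of [dedupAnnotations()] (optionally already
#'   restricted to associated metabolites); must contain `lipid_class` and
#'   `beta`.
#' @return data.frame per class: `lipid_class`, `n`, `pct` (column
#'   percentage), `n_up`, `n_down` (sign of `beta`). Records with an unknown
#'   or missing class are bucketed as `"other"`.
#' @export
classSummary <- function(metabolites) {
    cls <- metabolites$lipid_class
    cls[is.na(cls) | !nzchar(cls)] <- "other"
    beta <- metabolites$beta
    agg <- lapply(split(seq_along(cls), cls), function(i) {
        data.frame(n = length(i),
                   n_up = sum(beta[i] > 0, na.rm = TRUE),
                   n_down = sum(beta[i] < 0, na.rm = TRUE))
    })
    out <- do.call(rbind, agg)
    out <- data.frame(lipid_class = rownames(out), out,
                      stringsAsFactors = FALSE)
    out$pct <- 100 * out$n / sum(out$n)
    rownames(out) <- NULL
    out[order(-out$n, out$lipid_class),
        c("lipid_class", "n", "pct", "n_up", "n_down")]
}

#' Residualize a response on age and sex
#'
#' OLS residuals of a (transformed) feature on age and sex — genotype
#' deliberately excluded, so genotype-driven structure survives into the
#' clustering view. Missing responses are preserved in place.
#'
#' @param y numeric vector with `NA` allowed.
#' @param meta data.frame aligned with `y`: columns `age`, `sex`.
#' @return Numeric vector of residuals, `NA` where `y` was missing.
#' @export
residualize <- function(y, meta) {
    meta <- as.data.frame(meta)
    stopifnot(length(y) == nrow(meta))
    out <- rep(NA_real_, length(y))
    use <- !is.na(y) & !is.na(meta$age) & !is.na(meta$sex)
    if (sum(use) < 3L) return(out)
    df <- data.frame(y = y[use], age = meta$age[use],
                     sex = as.numeric(meta$sex[use] == "M"))
    keep <- vapply(c("age", "sex"), function(p)
        length(unique(df[[p]])) > 1L, logical(1))
    form <- if (any(keep))
        stats::as.formula(paste("y ~", paste(c("age", "sex")[keep],
                                             collapse = " + ")))
    else y ~ 1
    out[use] <- stats::residuals(stats::lm(form, data = df))
    out
}

#' Residualized metabolite-by-sample matrix for clustering
#'
#' Builds the matrix behind the clustered heatmap: for each representative
#' feature of the deduplicated metabolite set, the rank-transformed values of
#' the analysis samples residualized on age and sex. Rows with any remaining
#' missing value are dropped (complete-case default) or filled from the
#' half-minimum-imputed view upstream.
#'
#' @param x a preprocessed [MetaboExperiment-class] with an `"rnt"` assay.
#' @param metabolites output of [dedupAnnotations()].
#' @param sampleIds analysis samples (default: fasting study samples).
#' @return Numeric matrix, metabolites x samples, rownames = metabolite
#'   labels (feature id when unannotated).
#' @export
residualMatrix <- function(x, metabolites, sampleIds = NULL) {
    stopifnot(is(x, "MetaboExperiment"))
    sd <- colData(x)
    if (is.null(sampleIds))
        sampleIds <- colnames(x)[!sd$is_qc & sd$fasting %in% TRUE]
    Y <- assay(x, "rnt")[metabolites$feature, sampleIds, drop = FALSE]
    meta <- as.data.frame(sd[sampleIds, , drop = FALSE])
    R <- t(apply(Y, 1L, residualize, meta = meta))
    dimnames(R) <- list(ifelse(is.na(metabolites$metabolite),
                               metabolites$feature, metabolites$metabolite),
                        sampleIds)
    R[stats::complete.cases(R), , drop = FALSE]
}

#' Ward hierarchical clustering of both axes
#'
#' Agglomerative clustering by Ward's minimum-variance criterion (each merge
#' chosen to minimize the increase in total within-cluster sum of squares)
#' on Euclidean distances, applied to rows and columns of a dense matrix.
#'
#' @param m numeric matrix without missing entries, at least 2 rows and 2
#'   columns.
#' @return A list: `rowHclust`, `colHclust` (objects of class
#'   [stats::hclust], method `"ward.D2"`), `rowOrder`, `colOrder` (dendrogram
#'   leaf orders).
#' @export
wardCluster <- function(m) {
    m <- as.matrix(m)
    if (anyNA(m)) stop("clustering input must have no missing entries")
    if (nrow(m) < 2L || ncol(m) < 2L)
        stop("at least 2 items are required on each axis")
    rh <- stats::hclust(stats::dist(m), method = "ward.D2")
    ch <- stats::hclust(stats::dist(t(m)), method = "ward.D2")
    list(rowHclust = rh, colHclust = ch,
         rowOrder = rh$order, colOrder = ch$order)
}

#' Cohort characteristics table with Wilcoxon tests
#'
#' Per cohort, group means and SDs of quantitative traits (age plus any
#' numeric columns of `clinical`, e.g. BMI and the clinical lipids HDL, LDL,
#' TAG in mmol/l) in carriers and non-carriers, with a two-sided two-sample
#' Wilcoxon rank-sum test per trait. The exact null distribution is used
#' when both groups have at most 20 observations and no ties, the normal
#' approximation with continuity correction otherwise. Stars encode the
#' p-value: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `n` otherwise.
#'
#' @param meta sample metadata (a data.frame or [sampleMeta()] output) for
#'   study samples: `sample_id` as rownames (or column), `genotype`, `age`,
#'   `cohort`.
#' @param clinical optional data.frame with `sample_id` and numeric trait
#'   columns.
#' @return data.frame: `cohort`, `trait`, `carrier_mean`, `carrier_sd`,
#'   `ncarrier_mean`, `ncarrier_sd`, `n_carrier`, `n_ncarrier`, `p`,
#'   `stars`.
#' @export
cohortTable <- function(meta, clinical = NULL) {
    meta <- as.data.frame(meta)
    if (!"sample_id" %in% colnames(meta))
        meta$sample_id <- rownames(meta)
    meta <- meta[!meta$is_qc %in% TRUE, , drop = FALSE]
    traits <- data.frame(sample_id = meta$sample_id, age = meta$age,
                         stringsAsFactors = FALSE)
    if (!is.null(clinical)) {
        num <- vapply(clinical, is.numeric, logical(1))
        traits <- merge(traits,
                        clinical[, c("sample_id", names(num)[num]),
                                 drop = FALSE],
                        by = "sample_id", all.x = TRUE)
    }
    meta <- meta[match(traits$sample_id, meta$sample_id), , drop = FALSE]
    traitNames <- setdiff(colnames(traits), "sample_id")
    rows <- list()
    for (co in unique(meta$cohort[!is.na(meta$cohort)])) {
        inCo <- meta$cohort %in% co
        for (tr in traitNames) {
            v <- traits[[tr]][inCo]
            g <- meta$genotype[inCo]
            vc <- v[g %in% "carrier" & !is.na(v)]
            vn <- v[g %in% "non-carrier" & !is.na(v)]
            if (!length(vc) || !length(vn)) next
            exact <- length(vc) <= 20L && length(vn) <= 20L &&
                !anyDuplicated(c(vc, vn))
            p <- stats::wilcox.test(vc, vn, exact = exact,
                                    correct = TRUE)$p.value
            rows[[length(rows) + 1L]] <- data.frame(
                cohort = co, trait = tr,
                carrier_mean = mean(vc), carrier_sd = stats::sd(vc),
                ncarrier_mean = mean(vn), ncarrier_sd = stats::sd(vn),
                n_carrier = length(vc), n_ncarrier = length(vn),
                p = p, stars = starCode(p), stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Significance star coding
#'
#' @param p numeric vector of p-values.
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `"n"` otherwise.
#' @export
starCode <- function(p) {
    ifelse(p < 0.001, "***",
           ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n")))
}
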