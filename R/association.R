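#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sorted p-values are scaled by
#' m/rank, a cumulative minimum enforces monotonicity, and values are capped
#' at 1. Thin wrapper around [stats::p.adjust()] with `method = "BH"`,
#' tolerating `NA`s (adjusted within the non-missing set).
#'
#' @param p numeric vector of p-values in `[0, 1]` (may be empty).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric(0))
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

# design matrix for the fixed effects; drops constant covariates
.assocDesign <- function(meta) {
    g <- as.numeric(meta$genotype == "carrier")
    X <- cbind(`(Intercept)` = 1, genotype = g)
    if (length(unique(meta$age[!is.na(meta$age)])) > 1L)
        X <- cbind(X, age = meta$age)
    if (length(unique(meta$sex[!is.na(meta$sex)])) > 1L)
        X <- cbind(X, sexM = as.numeric(meta$sex == "M"))
    X
}

.naResult <- function(kind = "ols") {
    data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
               n_samples = 0L, n_subjects = 0L, model_kind = kind,
               converged = FALSE, stringsAsFactors = FALSE)
}

#' Test one feature for association with genotype
#'
#' Fits transformed abundance on carrier status (coded 0/1) with age and sex
#' as fixed covariates. When any subject contributes more than one sample
#' among the rows used, a linear mixed model with a per-subject random
#' intercept (optionally plus a per-family intercept for pedigree structure)
#' is fitted by maximum likelihood via [lme4::lmer()]; otherwise ordinary
#' least squares. Covariates constant in the analysis dataset (e.g. sex in a
#' mothers-only analysis) are dropped automatically. Missing responses are
#' dropped listwise. The reported p-value is the two-sided Wald test on the
#' genotype coefficient (t-based for OLS, normal for the ML mixed fit).
#' Non-convergence is reported through `converged = FALSE`, never by
#' dropping the feature.
#'
#' @param y numeric response vector (transformed abundances), `NA` allowed.
#' @param meta data.frame aligned with `y`: columns `subject_id`,
#'   `family_id`, `genotype`, `age`, `sex`.
#' @param useFamily add a family-level random intercept (pedigree term).
#' @return One-row data.frame: `beta`, `se`, `p`, `n_samples`, `n_subjects`,
#'   `model_kind` (`"ols"`/`"mixed"`), `converged`.
#' @export
fitFeatureAssociation <- function(y, meta, useFamily = FALSE) {
    meta <- as.data.frame(meta)
    stopifnot(length(y) == nrow(meta))
    use <- !is.na(y) & !is.na(meta$genotype)
    y <- y[use]; meta <- meta[use, , drop = FALSE]
    if (length(y) < 3L)
        stop("fewer than 3 informative observations")
    mixed <- anyDuplicated(meta$subject_id) > 0L
    X <- .assocDesign(meta)
    if (!"genotype" %in% colnames(X) ||
        length(unique(X[, "genotype"])) < 2L)
        return(.naResult(if (mixed) "mixed" else "ols"))
    if (!mixed) {
        fit <- .olsGenotype(X, matrix(y, ncol = 1L))
        return(data.frame(beta = fit$beta, se = fit$se, p = fit$p,
                          n_samples = length(y),
                          n_subjects = length(unique(meta$subject_id)),
                          model_kind = "ols", converged = !is.na(fit$beta),
                          stringsAsFactors = FALSE))
    }
    df <- data.frame(y = y, X[, -1L, drop = FALSE],
                     subject = meta$subject_id, family = meta$family_id)
    terms <- paste(setdiff(colnames(X), "(Intercept)"), collapse = " + ")
    form <- paste("y ~", terms, "+ (1 | subject)")
    if (useFamily) form <- paste(form, "+ (1 | family)")
    res <- tryCatch({
        conv <- TRUE
        fit <- withCallingHandlers(
            lme4::lmer(stats::as.formula(form), data = df, REML = FALSE,
                       control = lme4::lmerControl(calc.derivs = FALSE,
                                                   check.conv.singular =
                                                       "ignore")),
            warning = function(w) {
                conv <<- FALSE
                invokeRestart("muffleWarning")
            })
        co <- suppressWarnings(summary(fit)$coefficients)
        z <- co["genotype", "t value"]
        conv <- conv && length(fit@optinfo$conv$lme4$messages) == 0L
        data.frame(beta = co["genotype", "Estimate"],
                   se = co["genotype", "Std. Error"],
                   p = 2 * stats::pnorm(-abs(z)),
                   n_samples = length(y),
                   n_subjects = length(unique(meta$subject_id)),
                   model_kind = "mixed", converged = conv,
                   stringsAsFactors = FALSE)
    }, error = function(e) .naResult("mixed"))
    res
}

# multi-response OLS on the genotype coefficient; Y is n x k
.olsGenotype <- function(X, Y) {
    n <- nrow(X); pdim <- ncol(X)
    qrX <- qr(X)
    if (qrX$rank < pdim || n <= pdim)
        return(list(beta = rep(NA_real_, ncol(Y)),
                                     se = rep(NA_real_, ncol(Y)),
                                     p = rep(NA_real_, ncol(Y))))
    B <- qr.coef(qrX, Y)
    res <- Y - X %*% B
    sigma2 <- pmax(colSums(res^2), 0) / (n - pdim)
    xtxinv <- chol2inv(chol(crossprod(X)))
    gi <- match("genotype", colnames(X))
    se <- sqrt(sigma2 * xtxinv[gi, gi])
    tt <- B[gi, ] / se
    list(beta = unname(B[gi, ]), se = unname(se),
         p = unname(2 * stats::pt(-abs(tt), df = n - pdim)))
}

# association scan over all features of a transformed matrix
# Y: features x samples ("rnt" assay, subset to the analysis samples)
.assocScan <- function(Y, meta, useFamily = FALSE) {
    meta <- as.data.frame(meta)
    mixed <- anyDuplicated(meta$subject_id) > 0L
    nFeat <- nrow(Y)
    out <- data.frame(feature = rownames(Y), beta = NA_real_, se = NA_real_,
                      p = NA_real_, n_samples = NA_integer_,
                      n_subjects = NA_integer_,
                      model_kind = if (mixed) "mixed" else "ols",
                      converged = FALSE, stringsAsFactors = FALSE)
    if (!mixed) {
        ## group features by missingness pattern; one matrix OLS per pattern
        pat <- apply(is.na(Y), 1L, function(z) paste(which(z), collapse = ","))
        for (key in unique(pat)) {
            rows <- which(pat == key)
            drop <- if (nzchar(key))
                as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
            else integer(0)
            cols <- setdiff(seq_len(ncol(Y)), drop)
            sub <- meta[cols, , drop = FALSE]
            if (length(cols) < 3L || length(unique(sub$genotype)) < 2L) next
            X <- .assocDesign(sub)
            if (length(cols) <= ncol(X)) next
            fit <- .olsGenotype(X, t(Y[rows, cols, drop = FALSE]))
            out$beta[rows] <- fit$beta
            out$se[rows] <- fit$se
            out$p[rows] <- fit$p
            out$n_samples[rows] <- length(cols)
            out$n_subjects[rows] <- length(unique(sub$subject_id))
            out$converged[rows] <- !is.na(fit$beta)
        }
        return(out)
    }
    for (i in seq_len(nFeat)) {
        r <- tryCatch(fitFeatureAssociation(Y[i, ], meta,
                                            useFamily = useFamily),
                      error = function(e) .naResult("mixed"))
        out$beta[i] <- r$beta; out$se[i] <- r$se; out$p[i] <- r$p
        out$n_samples[i] <- r$n_samples; out$n_subjects[i] <- r$n_subjects
        out$model_kind[i] <- r$model_kind; out$converged[i] <- r$converged
    }
    out
}

#' Carrier/non-carrier fold change per feature
#'
#' Ratio of group means, carrier mean over non-carrier mean, computed on the
#' PQN-normalized (pre-rank-transform) data over present values only.
#'
#' @param x a [MetaboExperiment-class] with a `"normalized"` assay.
#' @param sampleIds sample ids defining the analysis dataset (default: all
#'   study samples).
#' @return Named numeric vector, one ratio per feature; `NA` (flagged
#'   undefined) when a class has no present values.
#' @export
foldChange <- function(x, sampleIds = NULL) {
    stopifnot(is(x, "MetaboExperiment"))
    if (!"normalized" %in% assayNames(x))
        stop("run pqnNormalize() first: fold change uses normalized data")
    sd <- colData(x)
    if (is.null(sampleIds))
        sampleIds <- colnames(x)[!sd$is_qc]
    m <- assay(x, "normalized")[, sampleIds, drop = FALSE]
    gt <- sd[sampleIds, "genotype"]
    carr <- rowMeans(m[, gt %in% "carrier", drop = FALSE], na.rm = TRUE)
    ctrl <- rowMeans(m[, gt %in% "non-carrier", drop = FALSE], na.rm = TRUE)
    fc <- carr / ctrl
    fc[!is.finite(fc)] <- NA_real_
    fc
}

#' Variance in a transformed feature explained by the fixed effects
#'
#' Fits a simple linear model of the response on age, sex and genotype over
#' all supplied samples (repeated measures treated as independent, no random
#' effects) and reports, per predictor, the incremental R-squared when that
#' predictor is added last to the model containing the other two, as a
#' percentage, together with the full-model R-squared.
#'
#' @param y numeric response vector (`NA` dropped listwise).
#' @param meta data.frame aligned with `y`: `genotype`, `age`, `sex`.
#' @return A list: `genotype`, `age`, `sex` (percentages; a constant
#'   predictor yields 0 and is named in `constant`), and `full` (full-model
#'   R-squared, percent).
#' @export
varianceExplained <- function(y, meta) {
    meta <- as.data.frame(meta)
    stopifnot(length(y) == nrow(meta))
    use <- !is.na(y) & !is.na(meta$genotype)
    y <- y[use]; meta <- meta[use, , drop = FALSE]
    df <- data.frame(y = y,
                     genotype = as.numeric(meta$genotype == "carrier"),
                     age = meta$age,
                     sex = as.numeric(meta$sex == "M"))
    preds <- c("genotype", "age", "sex")
    isConst <- vapply(preds, function(p)
        length(unique(df[[p]][!is.na(df[[p]])])) < 2L, logical(1))
    active <- preds[!isConst]
    r2 <- function(vars) {
        if (!length(vars)) return(0)
        f <- stats::as.formula(paste("y ~", paste(vars, collapse = " + ")))
        suppressWarnings(summary(stats::lm(f, data = df))$r.squared)
    }
    full <- r2(active)
    out <- stats::setNames(as.list(rep(0, 3L)), preds)
    for (p in active)
        out[[p]] <- 100 * (full - r2(setdiff(active, p)))
    out$full <- 100 * full
    out$constant <- preds[isConst]
    out
}

#' Run the three-dataset primary association analysis
#'
#' Scans every feature for association with carrier status in the combined,
#' mothers-only and young-participants-only datasets. In the primary mode
#' only fasting samples are analysed; `"keep_nonfasting"` retains them (first
#' sensitivity analysis). Within each dataset, a mixed model (subject random
#' intercept; plus a family intercept in the combined dataset when
#' `pedigreeCombined`) is used whenever any subject contributes repeated
#' samples, otherwise OLS; BH adjustment is applied across all tested
#' features of the dataset (the four acquisition datasets pooled); fold
#' changes come from the normalized, untransformed data. A feature is
#' declared associated when `q < fdrAlpha` in at least one of the three
#' analyses.
#'
#' @param x a preprocessed [MetaboExperiment-class] carrying `"normalized"`
#'   and `"rnt"` assays.
#' @param mode `"primary"` (fasting samples only) or `"keep_nonfasting"`.
#' @param fdrAlpha FDR threshold for declaring association (default 0.05).
#' @param pedigreeCombined include the family random intercept in the
#'   combined-dataset mixed model (default `TRUE`).
#' @return A list: `results` (data.frame over dataset x feature with `beta`,
#'   `se`, `p`, `q`, `fold_change`, sizes, model kind, convergence),
#'   `associated` (feature ids with `q < fdrAlpha` in >= 1 analysis),
#'   `datasets` (those actually analysed), `mode`, `fdrAlpha`.
#' @export
runPrimaryAnalyses <- function(x, mode = c("primary", "keep_nonfasting"),
                               fdrAlpha = 0.05, pedigreeCombined = TRUE) {
    stopifnot(is(x, "MetaboExperiment"))
    mode <- match.arg(mode)
    if (!all(c("normalized", "rnt") %in% assayNames(x)))
        stop("run pqnNormalize() and rankNormalize() before the analysis")
    sd <- colData(x)
    study <- !sd$is_qc
    if (mode == "primary") study <- study & sd$fasting %in% TRUE
    sets <- list(combined = colnames(x)[study],
                 mothers = colnames(x)[study & sd$cohort %in% "mother"],
                 young = colnames(x)[study & sd$cohort %in% "young"])
    Y <- assay(x, "rnt")
    allRes <- list()
    for (ds in names(sets)) {
        ids <- sets[[ds]]
        sub <- as.data.frame(sd[ids, , drop = FALSE])
        nCarr <- length(unique(sub$subject_id[sub$genotype %in% "carrier"]))
        if (nCarr < 2L) {
            warning("dataset '", ds, "' has fewer than 2 carrier subjects; ",
                    "skipped")
            next
        }
        res <- .assocScan(Y[, ids, drop = FALSE], sub,
                          useFamily = pedigreeCombined && ds == "combined")
        res$q <- bhAdjust(res$p)
        res$fold_change <- unname(foldChange(x, ids)[res$feature])
        res$dataset <- ds
        allRes[[ds]] <- res
    }
    if (!length(allRes)) stop("no dataset could be analysed")
    results <- do.call(rbind, allRes)
    rownames(results) <- NULL
    results <- results[, c("dataset", "feature", "beta", "se", "p", "q",
                           "fold_change", "n_samples", "n_subjects",
                           "model_kind", "converged")]
    assoc <- unique(results$feature[!is.na(results$q) &
                                    results$q < fdrAlpha])
    list(results = results, associated = assoc, datasets = names(allRes),
         mode = mode, fdrAlpha = fdrAlpha)
}
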