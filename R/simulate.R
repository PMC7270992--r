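#' Configuration of a synthetic recall-by-genotype UHPLC-MS study
#'
#' Bundles and validates the parameters of the study generator. The defaults
#' describe the study design the package's analysis assumes: a matched 1:2
#' carrier:control design spanning an adolescent ("young") and an adult
#' ("mother") cohort, repeated measures for a subset of carriers, four
#' acquisition datasets, lipid-class-structured genotype effects on
#' log-abundance, per-sample multiplicative dilution, pooled-QC technical
#' replicates, and optional limit-of-detection left-censoring.
#'
#' @param nCarriers number of carrier subjects (default 26: 15 adolescents and
#'   11 mothers, via `mothersFraction`).
#' @param controlsPerCarrier matched controls per carrier (default 2).
#' @param mothersFraction proportion of carriers drawn from the mother cohort.
#' @param repeatMeasureProb probability a carrier subject contributes a second
#'   sample.
#' @param nFeaturesPerClass named integer vector, lipid class -> number of
#'   parent features simulated.
#' @param effectByClass named numeric vector, lipid class -> true standardized
#'   carrier effect on log-abundance (in units of the biological SD; signed).
#'   Every name must appear in `nFeaturesPerClass`.
#' @param dilutionSD SD of the log-normal per-sample dilution factor (log
#'   scale).
#' @param techRSD technical coefficient of variation, percent, of pooled-QC
#'   replicate injections (and of redundant-feature replication noise).
#' @param biolSD biological SD of log-abundance (subject intercept plus
#'   within-subject residual).
#' @param lodQuantile proportion of the pooled study-sample abundance
#'   distribution left-censored to missing (default 0.1, the
#'   limit-of-detection non-detection that makes genotype-lowered features
#'   missing not at random; 0 disables censoring).
#' @param nQC number of pooled-QC injections.
#' @param duplicateRate probability an annotated metabolite yields 2-3
#'   redundant features sharing its annotation label.
#' @param annotationRate probability a parent feature carries a metabolite
#'   annotation (and hence a lipid-class label).
#' @param familyLinkProb probability a young-cohort carrier shares a family id
#'   with a carrier mother (exercises the pedigree random effect).
#' @param nonfastingProb probability a mother-cohort carrier sample is flagged
#'   non-fasting.
#' @param seed integer seed; identical configurations with identical seeds
#'   yield byte-identical studies.
#' @return A validated list of class `"SimConfig"`.
#' @export
simConfig <- function(nCarriers = 26L,
                      controlsPerCarrier = 2L,
                      mothersFraction = 11 / 26,
                      repeatMeasureProb = 0.4,
                      nFeaturesPerClass = c("TAG" = 40L, "DAG" = 15L,
                                            "acyl-acyl GPL" = 40L,
                                            "acyl-alkyl GPL" = 12L,
                                            "Ceramide" = 25L,
                                            "Sphingolipid" = 8L,
                                            "Other" = 60L),
                      effectByClass = c("TAG" = -1, "DAG" = -0.8,
                                        "acyl-acyl GPL" = -1,
                                        "acyl-alkyl GPL" = 0.8,
                                        "Ceramide" = 0.8,
                                        "Sphingolipid" = -0.5,
                                        "Other" = 0),
                      dilutionSD = 0.2,
                      techRSD = 10,
                      biolSD = 0.5,
                      lodQuantile = 0.1,
                      nQC = 8L,
                      duplicateRate = 0.2,
                      annotationRate = 0.7,
                      familyLinkProb = 0.3,
                      nonfastingProb = 0.1,
                      seed = 1L) {
    cfg <- list(nCarriers = as.integer(nCarriers),
                controlsPerCarrier = as.integer(controlsPerCarrier),
                mothersFraction = mothersFraction,
                repeatMeasureProb = repeatMeasureProb,
                nFeaturesPerClass = nFeaturesPerClass,
                effectByClass = effectByClass,
                dilutionSD = dilutionSD, techRSD = techRSD, biolSD = biolSD,
                lodQuantile = lodQuantile, nQC = as.integer(nQC),
                duplicateRate = duplicateRate,
                annotationRate = annotationRate,
                familyLinkProb = familyLinkProb,
                nonfastingProb = nonfastingProb,
                seed = as.integer(seed))
    if (missing(effectByClass)) {
        ## default effects follow the classes actually simulated
        eff <- cfg$effectByClass[names(cfg$nFeaturesPerClass)]
        eff[is.na(eff)] <- 0
        names(eff) <- names(cfg$nFeaturesPerClass)
        cfg$effectByClass <- eff
    }
    probs <- c("mothersFraction", "repeatMeasureProb", "lodQuantile",
               "duplicateRate", "annotationRate", "familyLinkProb",
               "nonfastingProb")
    for (p in probs)
        if (cfg[[p]] < 0 || cfg[[p]] > 1)
            stop(sprintf("%s must lie in [0, 1]", p))
    for (p in c("nCarriers", "controlsPerCarrier", "nQC"))
        if (cfg[[p]] < 0) stop(sprintf("%s must be non-negative", p))
    for (p in c("dilutionSD", "techRSD", "biolSD"))
        if (cfg[[p]] < 0) stop(sprintf("%s must be non-negative", p))
    if (any(cfg$nFeaturesPerClass < 0))
        stop("feature counts must be non-negative")
    unknown <- setdiff(names(cfg$effectByClass), names(cfg$nFeaturesPerClass))
    if (length(unknown))
        stop("effectByClass names unknown class(es): ",
             paste(unknown, collapse = ", "))
    class(cfg) <- "SimConfig"
    cfg
}

# log-scale SD of a log-normal multiplier with coefficient of variation cv
.cvToSDlog <- function(cv) sqrt(log(1 + cv^2))

#' Simulate a recall-by-genotype UHPLC-MS study
#'
#' Generates a complete synthetic study under the multiplicative abundance
#' model
#' \deqn{\log v_{fi} = b_f + \delta_f \,\sigma_b\, g_i + u_{f,s(i)} +
#'   \epsilon_{fi} + \log d_i}
#' where \eqn{b_f} is a feature baseline, \eqn{\delta_f} the standardized
#' class effect, \eqn{g_i} carrier status (0/1), \eqn{u} a subject random
#' intercept, \eqn{\epsilon} residual biological noise (the intercept and
#' residual together have SD `biolSD`), and \eqn{d_i} a log-normal per-sample
#' dilution. Each carrier is matched to `controlsPerCarrier` controls of the
#' same cohort and sex with age within one year. Pooled-QC injections are the
#' pooled mean profile of all study samples with multiplicative technical
#' noise of CV `techRSD` percent. A subset of annotated metabolites yields
#' 2-3 redundant features (replicates of the parent with independent
#' technical noise, sharing the annotation label). When `lodQuantile > 0`
#' the assembled table is left-censored with [applyCensoring()], which turns
#' genotype-lowered features into missing-not-at-random patterns.
#'
#' @param config a `"SimConfig"` from [simConfig()].
#' @return A list with elements
#'   \describe{
#'     \item{experiment}{a [MetaboExperiment-class] with the `"peakarea"`
#'       assay, feature and sample metadata;}
#'     \item{truth}{a [SimTruth-class] with true effects, dilutions, the
#'       censoring threshold and annotation groups;}
#'     \item{clinical}{a data.frame of synthetic clinical lipids (HDL, LDL,
#'       TAG, mmol/l) and BMI per study sample, with genotype effects in the
#'       directions expected for an APOC3 loss-of-function carrier.}
#'   }
#' @export
simulateStudy <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimConfig"))
    if (config$nCarriers == 0L)
        stop("at least one carrier subject is required")
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(config$seed)

    ## -- subjects -----------------------------------------------------------
    nC <- config$nCarriers
    nMother <- round(config$mothersFraction * nC)
    cohorts <- rep(c("mother", "young"), c(nMother, nC - nMother))
    carrier <- data.frame(
        subject_id = sprintf("C%03d", seq_len(nC)),
        cohort = cohorts,
        sex = ifelse(cohorts == "mother", "F",
                     sample(c("F", "M"), nC, replace = TRUE)),
        age = ifelse(cohorts == "mother", rnorm(nC, 48.5, 5.5),
                     rnorm(nC, 16.2, 1.2)),
        genotype = "carrier", stringsAsFactors = FALSE)
    carrier$family_id <- paste0("fam_", carrier$subject_id)
    momIdx <- which(carrier$cohort == "mother")
    for (i in which(carrier$cohort == "young")) {
        if (length(momIdx) && runif(1) < config$familyLinkProb)
            carrier$family_id[i] <- carrier$family_id[sample(momIdx, 1L)]
    }
    k <- config$controlsPerCarrier
    control <- carrier[rep(seq_len(nC), each = k), , drop = FALSE]
    control$subject_id <- sprintf("N%03d", seq_len(nC * k))
    control$family_id <- paste0("fam_", control$subject_id)
    control$age <- control$age + runif(nC * k, -1, 1)
    control$genotype <- "non-carrier"
    subjects <- rbind(carrier, control)
    rownames(subjects) <- NULL

    ## -- samples (repeats for a subset of carriers) -------------------------
    rep2 <- subjects$genotype == "carrier" &
        runif(nrow(subjects)) < config$repeatMeasureProb
    samp <- subjects[c(seq_len(nrow(subjects)), which(rep2)), , drop = FALSE]
    samp$visit <- c(rep(1L, nrow(subjects)), rep(2L, sum(rep2)))
    samp$age <- samp$age + (samp$visit - 1L)
    samp <- samp[order(samp$subject_id, samp$visit), , drop = FALSE]
    samp$sample_id <- sprintf("S%03d", seq_len(nrow(samp)))
    samp$fasting <- TRUE
    nf <- samp$cohort == "mother" & samp$genotype == "carrier" &
        runif(nrow(samp)) < config$nonfastingProb
    samp$fasting[nf] <- FALSE
    samp$is_qc <- FALSE

    ## -- features -----------------------------------------------------------
    cls <- rep(names(config$nFeaturesPerClass), config$nFeaturesPerClass)
    nF <- length(cls)
    if (nF == 0L) stop("at least one feature is required")
    lipid <- cls != "Other"
    feat <- data.frame(
        feature_id = sprintf("M%04d", seq_len(nF)),
        class_true = cls,
        assay_id = ifelse(lipid,
                          sample(c("LIPIDS-NEG", "LIPIDS-POS"), nF, TRUE,
                                 prob = c(0.7, 0.3)),
                          sample(c("HILIC-POS", "HILIC-NEG"), nF, TRUE)),
        mz = ifelse(lipid, runif(nF, 600, 1000), runif(nF, 100, 600)),
        rt = runif(nF, 30, 600),
        stringsAsFactors = FALSE)
    feat$baseline <- rnorm(nF, log(1e5), 1)
    eff <- config$effectByClass[feat$class_true]
    eff[is.na(eff)] <- 0
    feat$effect <- unname(eff)
    annotated <- runif(nF) < config$annotationRate
    feat$annotation <- ifelse(annotated,
                              sprintf("%s(%d)", feat$class_true, seq_len(nF)),
                              NA_character_)
    feat$lipid_class <- ifelse(annotated, feat$class_true, NA_character_)

    ## -- abundance matrix ---------------------------------------------------
    nS <- nrow(samp)
    subjSD <- 0.5 * config$biolSD
    residSD <- sqrt(config$biolSD^2 - subjSD^2)
    sig <- config$biolSD
    g <- as.numeric(samp$genotype == "carrier")
    subjFac <- factor(samp$subject_id)
    U <- matrix(rnorm(nF * nlevels(subjFac), 0, subjSD), nF)
    dil <- exp(rnorm(nS, 0, config$dilutionSD))
    names(dil) <- samp$sample_id
    logv <- feat$baseline +
        outer(feat$effect * sig, g) +
        U[, as.integer(subjFac), drop = FALSE] +
        matrix(rnorm(nF * nS, 0, residSD), nF) +
        rep(log(dil), each = nF)
    vals <- exp(logv)
    dimnames(vals) <- list(feat$feature_id, samp$sample_id)

    ## -- redundant features (adducts / cross-assay detections) --------------
    techSDlog <- .cvToSDlog(config$techRSD / 100)
    dupParents <- which(annotated & runif(nF) < config$duplicateRate)
    dupRows <- list(); dupMeta <- list()
    for (p in dupParents) {
        nDup <- sample(1:2, 1L)            # parent yields 2-3 features total
        for (j in seq_len(nDup)) {
            child <- feat[p, , drop = FALSE]
            child$feature_id <- sprintf("%s.d%d", feat$feature_id[p], j)
            child$mz <- child$mz + runif(1, -0.5, 0.5)
            child$rt <- runif(1, 30, 600)
            child$assay_id <- sample(.ASSAY_LEVELS[if (lipid[p]) 3:4 else 1:2],
                                     1L)
            dupMeta[[length(dupMeta) + 1L]] <- child
            dupRows[[length(dupRows) + 1L]] <-
                vals[p, ] * exp(rnorm(nS, 0, techSDlog))
        }
    }
    if (length(dupRows)) {
        dm <- do.call(rbind, dupMeta)
        vals <- rbind(vals, do.call(rbind, dupRows))
        rownames(vals) <- c(feat$feature_id, dm$feature_id)
        feat <- rbind(feat, dm)
    }

    ## -- pooled-QC injections ------------------------------------------------
    pooled <- rowMeans(vals)
    nQ <- config$nQC
    if (nQ > 0L) {
        qcNoise <- matrix(exp(rnorm(nrow(vals) * nQ, 0, techSDlog)
                              - techSDlog^2 / 2), nrow(vals))
        if (config$techRSD == 0) qcNoise[] <- 1
        qcVals <- pooled * qcNoise
        colnames(qcVals) <- sprintf("QC%02d", seq_len(nQ))
        vals <- cbind(vals, qcVals)
    }
    sampleData <- data.frame(
        subject_id = c(samp$subject_id, sprintf("pooledQC%02d", seq_len(nQ))),
        family_id = c(samp$family_id, rep(NA_character_, nQ)),
        genotype = c(samp$genotype, rep(NA_character_, nQ)),
        age = c(samp$age, rep(NA_real_, nQ)),
        sex = c(samp$sex, rep(NA_character_, nQ)),
        cohort = c(samp$cohort, rep(NA_character_, nQ)),
        fasting = c(samp$fasting, rep(NA, nQ)),
        is_qc = c(rep(FALSE, nS), rep(TRUE, nQ)),
        row.names = colnames(vals), stringsAsFactors = FALSE)

    mexp <- MetaboExperiment(vals,
        featureData = feat[, c("assay_id", "mz", "rt", "annotation",
                               "lipid_class")],
        sampleData = sampleData)

    lod <- NA_real_
    if (config$lodQuantile > 0) {
        cen <- applyCensoring(mexp, config$lodQuantile)
        mexp <- cen$experiment
        lod <- cen$lod
    }
    metadata(mexp)$simConfig <- config

    effects <- stats::setNames(feat$effect * sig, feat$feature_id)
    groups <- split(feat$feature_id, feat$annotation)
    truth <- new("SimTruth",
                 effect = effects,
                 dilution = dil,
                 lod = lod,
                 affected = feat$feature_id[feat$effect != 0],
                 annotationGroups = groups)

    clinical <- data.frame(
        sample_id = samp$sample_id,
        bmi = rnorm(nS, ifelse(samp$cohort == "mother", 25, 22), 3.5),
        hdl = pmax(0.2, rnorm(nS, ifelse(g == 1, 1.75, 1.30), 0.3)),
        ldl = pmax(0.3, rnorm(nS, ifelse(g == 1, 2.30, 2.45), 0.6)),
        tag = pmax(0.05, rnorm(nS, ifelse(g == 1, 0.50, 0.90), 0.25)),
        stringsAsFactors = FALSE)

    list(experiment = mexp, truth = truth, clinical = clinical)
}

#' Left-censor a feature table at a limit of detection
#'
#' Computes the `lodQuantile` quantile of all present study-sample values
#' (pooled over features; pooled-QC samples excluded from the threshold
#' estimate) and sets every value below it — in study and QC samples alike —
#' to missing. Emulates limit-of-detection non-detection, the mechanism that
#' makes low-abundance features missing not at random.
#'
#' @param x a [MetaboExperiment-class].
#' @param lodQuantile proportion in `[0, 1)` of the pooled abundance
#'   distribution to censor; 0 returns the table unchanged.
#' @return A list with `experiment` (the censored [MetaboExperiment-class])
#'   and `lod` (the threshold used, on the raw abundance scale; `-Inf` when
#'   `lodQuantile = 0`).
#' @export
applyCensoring <- function(x, lodQuantile) {
    stopifnot(is(x, "MetaboExperiment"))
    if (!is.numeric(lodQuantile) || length(lodQuantile) != 1L ||
        lodQuantile < 0 || lodQuantile >= 1)
        stop("lodQuantile must be a single value in [0, 1)")
    m <- assay(x, "peakarea")
    if (lodQuantile == 0)
        return(list(experiment = x, lod = -Inf))
    study <- m[, !isQC(x), drop = FALSE]
    lod <- stats::quantile(study[!is.na(study)], lodQuantile, names = FALSE)
    m[!is.na(m) & m < lod] <- NA_real_
    assay(x, "peakarea") <- m
    metadata(x)$lod <- lod
    list(experiment = x, lod = lod)
}
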