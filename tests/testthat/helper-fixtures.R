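# Compact builders for hand-sized MetaboExperiment fixtures.

# values: features x samples matrix; genotype: per study sample; nQC pooled
# QC columns appended unless qcCols names columns of `values` directly.
toyExperiment <- function(values, genotype, nQC = 0,
                          cohort = "young", sex = NULL, age = NULL,
                          assay_id = "LIPIDS-NEG", annotation = NA,
                          lipid_class = NA, fasting = TRUE,
                          subject = NULL, family = NULL) {
    nF <- nrow(values); nS <- ncol(values)
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("F%02d", seq_len(nF))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("S%02d", seq_len(nS))
    nStudy <- length(genotype)
    stopifnot(nStudy + nQC == nS)
    if (is.null(sex)) sex <- rep(c("F", "M"), length.out = nStudy)
    if (is.null(age)) age <- 15 + seq_len(nStudy) / 7
    if (is.null(subject)) subject <- paste0("subj", seq_len(nStudy))
    if (is.null(family)) family <- paste0("fam", subject)
    cohort <- rep(cohort, length.out = nStudy)
    sd <- data.frame(
        subject_id = c(subject, sprintf("pqc%d", seq_len(nQC))),
        family_id = c(family, rep(NA, nQC)),
        genotype = c(genotype, rep(NA, nQC)),
        age = c(age, rep(NA, nQC)),
        sex = c(ifelse(cohort == "mother", "F", sex), rep(NA, nQC)),
        cohort = c(cohort, rep(NA, nQC)),
        fasting = c(rep(fasting, length.out = nStudy), rep(NA, nQC)),
        is_qc = c(rep(FALSE, nStudy), rep(TRUE, nQC)),
        row.names = colnames(values))
    fd <- data.frame(assay_id = rep(assay_id, length.out = nF),
                     mz = 500 + seq_len(nF),
                     rt = 60 * seq_len(nF),
                     annotation = rep(annotation, length.out = nF),
                     lipid_class = rep(lipid_class, length.out = nF),
                     row.names = rownames(values))
    MetaboExperiment(values, fd, sd)
}

# the 12-feature / 25-sample filter-bookkeeping fixture: one known violation
# of each filter rule, everything else clean
filterFixture <- function() {
    feats <- sprintf("F%02d", 1:12)
    samps <- c(sprintf("P%d", 1:7),      # carriers
               sprintf("Q%d", 1:14),     # controls
               sprintf("QC%d", 1:4))
    m <- matrix(100, 12, 25, dimnames = list(feats, samps))
    qc <- 22:25
    m[, qc] <- 100
    m["F01", qc] <- c(5, 10, 15, 10)     # RSD 40.8% > 30 -> fail
    m["F02", qc] <- c(100, 100, NA, NA)  # detection 50% < 70 -> fail
    m["F03", qc] <- c(5, 15, NA, NA)     # RSD 70.7% and detection 50% -> fail
    m[c("F04", "F05", "F06", "F07", "F08"), "Q14"] <- NA  # Q14: 5/9 missing
    m[sprintf("F%02d", 4:12), "Q13"] <- 1000              # Q13: TPA outlier
    m["F11", c("P1", "P2", "P3", "Q1")] <- NA  # 43% / 8% -> retained
    m["F12", c("P1", "P2", "P3", "Q1", "Q2", "Q3", "Q4")] <- NA # both > 30%
    toyExperiment(m, genotype = rep(c("carrier", "non-carrier"), c(7, 14)),
                  nQC = 4)
}

# small fully-crossed study for association unit tests: no repeats
assocFixture <- function(nPerGroup = 12, seed = 101) {
    set.seed(seed)
    n <- 3 * nPerGroup
    g <- rep(c("carrier", "non-carrier"), c(nPerGroup, 2 * nPerGroup))
    data.frame(subject_id = paste0("s", seq_len(n)),
               family_id = paste0("f", seq_len(n)),
               genotype = g,
               age = rnorm(n, 16, 1.2),
               sex = sample(c("F", "M"), n, TRUE))
}
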