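test_that("noise-free degenerate study reproduces the baseline profile", {
    cfg <- simConfig(nCarriers = 4L, techRSD = 0, dilutionSD = 0,
                     biolSD = 0, lodQuantile = 0,
                     nFeaturesPerClass = c("TAG" = 5L, "Other" = 5L),
                     effectByClass = c("TAG" = 0, "Other" = 0),
                     duplicateRate = 0, seed = 3L)
    sim <- simulateStudy(cfg)
    m <- peakAreas(sim$experiment)
    ref <- m[, 1L]
    for (j in seq_len(ncol(m)))
        expect_equal(unname(m[, j]), unname(ref))
})

test_that("identical seeds give byte-identical studies", {
    cfg <- simConfig(nCarriers = 6L, seed = 7L)
    a <- simulateStudy(cfg)
    b <- simulateStudy(cfg)
    expect_identical(peakAreas(a$experiment), peakAreas(b$experiment))
    expect_identical(as.data.frame(sampleMeta(a$experiment)),
                     as.data.frame(sampleMeta(b$experiment)))
    expect_identical(trueEffects(a$truth), trueEffects(b$truth))
    expect_identical(trueDilutions(a$truth), trueDilutions(b$truth))
    expect_identical(a$clinical, b$clinical)
    d <- simulateStudy(simConfig(nCarriers = 6L, seed = 8L))
    expect_false(identical(peakAreas(a$experiment),
                           peakAreas(d$experiment)))
})

test_that("censoring at a quantile produces the matching missing fraction", {
    cfg <- simConfig(nCarriers = 10L, lodQuantile = 0.2,
                     duplicateRate = 0, seed = 5L)
    sim <- simulateStudy(cfg)
    m <- peakAreas(sim$experiment)[, !isQC(sim$experiment)]
    frac <- mean(is.na(m))
    n <- length(m)
    expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n) + 1 / n)
    expect_true(all(m[!is.na(m)] >= sim$truth@lod))
})

test_that("applyCensoring follows the quantile definition", {
    vals <- matrix(as.numeric(1:100), 1, 100,
                   dimnames = list("F1", sprintf("S%03d", 1:100)))
    x <- toyExperiment(vals, genotype = rep(c("carrier", "non-carrier"), 50))
    expect_identical(peakAreas(applyCensoring(x, 0)$experiment),
                     peakAreas(x))
    cen <- applyCensoring(x, 0.10)
    expect_identical(which(is.na(peakAreas(cen$experiment)[1, ])),
                     setNames(1:10, sprintf("S%03d", 1:10)))
    ## quantile nesting: a higher quantile censors a superset
    c1 <- is.na(peakAreas(applyCensoring(x, 0.1)$experiment))
    c3 <- is.na(peakAreas(applyCensoring(x, 0.3)$experiment))
    expect_true(all(c3[c1]))
    expect_gt(sum(c3), sum(c1))
    expect_error(applyCensoring(x, 1), "lodQuantile")
    expect_error(applyCensoring(x, -0.1), "lodQuantile")
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(nCarriers = -1), "non-negative")
    expect_error(simConfig(lodQuantile = 1.2), "\\[0, 1\\]")
    expect_error(simConfig(effectByClass = c(Nope = 1)), "unknown class")
    expect_error(simulateStudy(simConfig(nCarriers = 0L)), "carrier")
})

test_that("carriers are matched 1:k on cohort and sex with age within 1y", {
    cfg <- simConfig(nCarriers = 12L, controlsPerCarrier = 2L, seed = 21L)
    sim <- simulateStudy(cfg)
    sd <- as.data.frame(sampleMeta(sim$experiment))
    sd <- sd[!sd$is_qc & !duplicated(sd$subject_id), ]
    tab <- table(sd$cohort, sd$genotype)
    expect_identical(unname(tab[, "non-carrier"]),
                     unname(2L * tab[, "carrier"]))
    ## controls are cloned per carrier in order: check the matching block
    carriers <- sd[sd$genotype == "carrier", ]
    controls <- sd[sd$genotype == "non-carrier", ]
    controls <- controls[order(controls$subject_id), ]
    idx <- rep(seq_len(nrow(carriers)), each = 2L)
    expect_identical(controls$cohort, carriers$cohort[idx])
    expect_identical(controls$sex, carriers$sex[idx])
    expect_true(all(abs(controls$age - carriers$age[idx]) <= 1))
})

test_that("strong negative effects plus censoring make carriers go missing", {
    diffs <- vapply(1:20, function(s) {
        cfg <- simConfig(nCarriers = 8L, lodQuantile = 0.25,
                         nFeaturesPerClass = c("TAG" = 20L, "Other" = 20L),
                         effectByClass = c("TAG" = -2, "Other" = 0),
                         duplicateRate = 0, annotationRate = 1,
                         biolSD = 0.5, seed = 100L + s)
        sim <- simulateStudy(cfg)
        x <- sim$experiment
        m <- peakAreas(x)[, !isQC(x)]
        gt <- sampleMeta(x)$genotype[!isQC(x)]
        aff <- affectedFeatures(sim$truth)
        missCarr <- mean(is.na(m[aff, gt %in% "carrier"]))
        missCtrl <- mean(is.na(m[aff, gt %in% "non-carrier"]))
        missCarr - missCtrl
    }, numeric(1))
    expect_true(all(diffs >= 0))
    expect_gt(mean(diffs), 0.05)
})

test_that("dilution inflates raw between-sample variance over the truth", {
    cfg <- simConfig(nCarriers = 8L, dilutionSD = 0.4, lodQuantile = 0,
                     effectByClass = c("TAG" = 0, "DAG" = 0,
                                       "acyl-acyl GPL" = 0,
                                       "acyl-alkyl GPL" = 0, "Ceramide" = 0,
                                       "Sphingolipid" = 0, "Other" = 0),
                     duplicateRate = 0, seed = 9L)
    sim <- simulateStudy(cfg)
    x <- sim$experiment
    m <- log(peakAreas(x)[, !isQC(x)])
    corrected <- sweep(m, 2L, log(trueDilutions(sim$truth)), "-")
    vRaw <- mean(apply(m, 1L, var))
    vCor <- mean(apply(corrected, 1L, var))
    expect_gt(vRaw, vCor)
})

test_that("redundant features replicate their parent and share its label", {
    cfg <- simConfig(nCarriers = 6L, duplicateRate = 1, annotationRate = 1,
                     techRSD = 0, lodQuantile = 0, seed = 13L,
                     nFeaturesPerClass = c("TAG" = 6L),
                     effectByClass = c("TAG" = -1))
    sim <- simulateStudy(cfg)
    x <- sim$experiment
    fd <- as.data.frame(featureMeta(x))
    dups <- grep("\\.d", rownames(fd), value = TRUE)
    expect_gt(length(dups), 0)
    m <- peakAreas(x)
    for (d in dups) {
        parent <- sub("\\.d[0-9]+$", "", d)
        ## techRSD = 0: replicate equals its parent exactly
        expect_equal(m[d, ], m[parent, ])
        expect_identical(fd[d, "annotation"], fd[parent, "annotation"])
    }
    groups <- annotationGroups(sim$truth)
    expect_true(all(lengths(groups)[vapply(groups, function(g)
        any(grepl("\\.d", g)), logical(1))] >= 2L))
})

test_that("QC injections are the pooled mean profile under zero tech noise", {
    cfg <- simConfig(nCarriers = 5L, techRSD = 0, lodQuantile = 0,
                     duplicateRate = 0, seed = 17L)
    sim <- simulateStudy(cfg)
    m <- peakAreas(sim$experiment)
    qc <- isQC(sim$experiment)
    pooled <- rowMeans(m[, !qc])
    for (j in which(qc))
        expect_equal(unname(m[, j]), unname(pooled))
})
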