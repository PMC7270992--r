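test_that("BH adjustment matches the hand-computed step-up", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_identical(bhAdjust(numeric(0)), numeric(0))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the from-definition oracle", {
    set.seed(11)
    for (i in 1:25) {
        p <- runif(sample(1:40, 1))^sample(1:3, 1)
        q <- bhAdjust(p)
        expect_equal(q, bhOracle(p), tolerance = 1e-12)
        expect_true(all(q >= p))
        ## order-preserving: sorting by p sorts q non-decreasingly
        expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
})

test_that("a perfectly separating genotype gives beta 1 with p near 0", {
    meta <- assocFixture(10)
    y <- as.numeric(meta$genotype == "carrier")
    r <- fitFeatureAssociation(y, meta)
    expect_equal(r$beta, 1)
    expect_equal(r$p, 0)
    expect_identical(r$model_kind, "ols")
    expect_true(r$converged)
})

test_that("OLS path equals the normal-equations oracle", {
    set.seed(12)
    meta <- assocFixture(15)
    X <- cbind(`(Intercept)` = 1,
               genotype = as.numeric(meta$genotype == "carrier"),
               age = meta$age, sexM = as.numeric(meta$sex == "M"))
    for (i in 1:20) {
        y <- rnorm(nrow(meta), sd = runif(1, 0.5, 2))
        r <- fitFeatureAssociation(y, meta)
        o <- olsOracle(X, y)
        expect_equal(r$beta, o$beta, tolerance = 1e-8)
        expect_equal(r$se, o$se, tolerance = 1e-8)
        expect_equal(r$p, o$p, tolerance = 1e-8)
    }
})

test_that("mixed path reduces to OLS when subject variance is absent", {
    set.seed(13)
    meta <- assocFixture(12)
    metaRep <- rbind(meta, meta[1:8, ])   # repeats, no subject effect in y
    y <- 0.4 * as.numeric(metaRep$genotype == "carrier") +
        rnorm(nrow(metaRep))
    r <- fitFeatureAssociation(y, metaRep)
    expect_identical(r$model_kind, "mixed")
    X <- cbind(`(Intercept)` = 1,
               genotype = as.numeric(metaRep$genotype == "carrier"),
               age = metaRep$age, sexM = as.numeric(metaRep$sex == "M"))
    o <- olsOracle(X, y)
    expect_equal(r$beta, o$beta, tolerance = 1e-3)
})

test_that("constant covariates are dropped, not fatal", {
    meta <- assocFixture(8)
    meta$sex <- "F"                        # mothers-only style dataset
    y <- rnorm(nrow(meta)) + as.numeric(meta$genotype == "carrier")
    r <- fitFeatureAssociation(y, meta)
    expect_true(is.finite(r$beta))
    expect_error(fitFeatureAssociation(c(1, 2, NA), meta[1:3, ]),
                 "informative")
})

test_that("fold change is the ratio of class means on normalized data", {
    m <- rbind(F1 = c(1, 3, 2, 2), F2 = c(1, 1, 2, 2), F3 = c(2, 2, 2, 2))
    colnames(m) <- sprintf("S%d", 1:4)
    x <- toyExperiment(m, genotype = rep(c("carrier", "non-carrier"),
                                         each = 2))
    assay(x, "normalized") <- m            # bypass PQN: test the ratio alone
    fc <- foldChange(x)
    expect_equal(unname(fc["F1"]), 1)      # means 2 and 2
    expect_equal(unname(fc["F2"]), 0.5)
    expect_equal(unname(fc["F3"]), 1)
    ## class with no present values is flagged undefined
    m2 <- rbind(F1 = c(NA, NA, 2, 2))
    colnames(m2) <- sprintf("S%d", 1:4)
    x2 <- toyExperiment(m2, genotype = rep(c("carrier", "non-carrier"),
                                           each = 2))
    assay(x2, "normalized") <- m2
    expect_true(is.na(foldChange(x2)["F1"]))
})

test_that("variance explained attributes a pure genotype signal fully", {
    meta <- data.frame(genotype = rep(c("carrier", "non-carrier"), 10),
                       age = rep(c(15, 16), each = 10),
                       sex = rep(c("F", "F", "M", "M"), 5),
                       subject_id = paste0("s", 1:20),
                       family_id = paste0("f", 1:20))
    y <- as.numeric(meta$genotype == "carrier")
    v <- varianceExplained(y, meta)
    expect_equal(v$genotype, 100, tolerance = 1e-8)
    expect_lt(v$age, 1e-8)
    expect_lt(v$sex, 1e-8)
})

test_that("orthogonal incremental R2 adds up to the full model", {
    ## orthogonal balanced design over 8 cells
    des <- expand.grid(g = c(0, 1), a = c(-1, 1), s = c(0, 1))
    des <- des[rep(1:8, 6), ]
    meta <- data.frame(genotype = ifelse(des$g == 1, "carrier",
                                         "non-carrier"),
                       age = des$a, sex = ifelse(des$s == 1, "M", "F"))
    set.seed(14)
    y <- 0.8 * des$g + 0.5 * des$a - 0.3 * des$s + rnorm(nrow(des), 0, 0.7)
    v <- varianceExplained(y, meta)
    expect_equal(v$genotype + v$age + v$sex, v$full, tolerance = 1e-10)
})

test_that("variance explained is near zero under the null", {
    hits <- vapply(1:100, function(s) {
        set.seed(400 + s)
        meta <- data.frame(genotype = sample(rep(c("carrier", "non-carrier"),
                                                 500)),
                           age = rnorm(1000, 30, 5),
                           sex = sample(c("F", "M"), 1000, TRUE))
        y <- rnorm(1000)
        v <- varianceExplained(y, meta)
        all(c(v$genotype, v$age, v$sex) < 1)
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("constant predictors report zero with a flag", {
    meta <- data.frame(genotype = rep(c("carrier", "non-carrier"), 10),
                       age = 16, sex = rep(c("F", "M"), 10))
    v <- varianceExplained(rnorm(20), meta)
    expect_equal(v$age, 0)
    expect_identical(v$constant, "age")
})

test_that("the vectorized scan equals per-feature fits with missingness", {
    set.seed(15)
    sim <- simulateStudy(simConfig(nCarriers = 8L, repeatMeasureProb = 0,
                                   lodQuantile = 0.15, duplicateRate = 0,
                                   nFeaturesPerClass = c("TAG" = 10L,
                                                         "Other" = 10L),
                                   seed = 55L))
    x <- rankNormalize(pqnNormalize(sim$experiment))
    study <- colnames(x)[!isQC(x)]
    res <- runPrimaryAnalyses(x, mode = "keep_nonfasting")$results
    comb <- res[res$dataset == "combined", ]
    Y <- assay(x, "rnt")[, study]
    meta <- as.data.frame(sampleMeta(x))[study, ]
    for (i in sample(nrow(Y), 8)) {
        f <- rownames(Y)[i]
        if (!comb$converged[comb$feature == f]) next
        r <- fitFeatureAssociation(Y[i, ], meta)
        expect_equal(comb$beta[comb$feature == f], r$beta,
                     tolerance = 1e-10)
        expect_equal(comb$se[comb$feature == f], r$se, tolerance = 1e-10)
    }
})

test_that("the three-dataset analysis applies the union rule", {
    sim <- simulateStudy(simConfig(nCarriers = 12L, seed = 77L,
                                   biolSD = 0.4))
    x <- rankNormalize(pqnNormalize(sim$experiment))
    pa <- runPrimaryAnalyses(x)
    res <- pa$results
    expect_setequal(pa$associated,
                    unique(res$feature[!is.na(res$q) & res$q < 0.05]))
    expect_setequal(pa$datasets, c("combined", "mothers", "young"))
    ## q is BH within dataset across all features
    for (ds in pa$datasets) {
        sub <- res[res$dataset == ds, ]
        ok <- !is.na(sub$p)
        expect_equal(sub$q[ok], bhOracle(sub$p[ok]), tolerance = 1e-12)
    }
    ## determinism of the full analysis
    pa2 <- runPrimaryAnalyses(x)
    expect_identical(pa$results, pa2$results)
})

test_that("fasting filter distinguishes primary from sensitivity mode", {
    sim <- simulateStudy(simConfig(nCarriers = 14L, nonfastingProb = 0.5,
                                   seed = 91L))
    sd <- sampleMeta(sim$experiment)
    expect_gt(sum(!sd$fasting, na.rm = TRUE), 0)
    x <- rankNormalize(pqnNormalize(sim$experiment))
    prim <- runPrimaryAnalyses(x, mode = "primary")$results
    sens <- runPrimaryAnalyses(x, mode = "keep_nonfasting")$results
    nPrim <- prim$n_samples[prim$dataset == "mothers"][1]
    nSens <- sens$n_samples[sens$dataset == "mothers"][1]
    expect_gt(nSens, nPrim)
})
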