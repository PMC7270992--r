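makeResults <- function(features, p, beta = NULL) {
    data.frame(feature = features, p = p,
               beta = if (is.null(beta)) -seq_along(features) else beta,
               q = p, stringsAsFactors = FALSE)
}

makeFeatureData <- function(ids, annotation, lipid_class = NA) {
    data.frame(annotation = annotation,
               lipid_class = rep(lipid_class, length.out = length(ids)),
               row.names = ids)
}

test_that("deduplication keeps the smallest p per metabolite", {
    fd <- makeFeatureData(c("f1", "f2", "f3"), c("A", "A", "B"))
    res <- makeResults(c("f1", "f2", "f3"), c(0.01, 0.001, 0.2))
    out <- dedupAnnotations(res, fd)
    expect_equal(nrow(out), 2)
    expect_equal(out$p[out$metabolite == "A"], 0.001)
    expect_equal(out$feature[out$metabolite == "A"], "f2")
    expect_equal(out$p[out$metabolite == "B"], 0.2)
    expect_equal(out$n_members[out$metabolite == "A"], 2L)
})

test_that("unique labels pass through and ties break on feature id", {
    fd <- makeFeatureData(c("f1", "f2", "f3"), c("A", "B", "C"))
    res <- makeResults(c("f1", "f2", "f3"), c(0.1, 0.2, 0.3))
    expect_equal(nrow(dedupAnnotations(res, fd)), 3)
    fd2 <- makeFeatureData(c("f9", "f2"), c("A", "A"))
    res2 <- makeResults(c("f9", "f2"), c(0.05, 0.05))
    out <- dedupAnnotations(res2, fd2)
    expect_equal(out$feature, "f2")
    ## representative p-values are a subset of the inputs
    fd3 <- makeFeatureData(sprintf("f%d", 1:6),
                           c("A", "A", "B", NA, NA, "B"))
    res3 <- makeResults(sprintf("f%d", 1:6), runif(6))
    out3 <- dedupAnnotations(res3, fd3)
    expect_true(all(out3$p %in% res3$p))
    ## unannotated features are reported as features
    expect_equal(sum(is.na(out3$metabolite)), 2)
})

test_that("class summary computes counts, percentages and directions", {
    met <- data.frame(metabolite = c("a", "b", "c", "d"),
                      lipid_class = c("TAG", "TAG", "acyl-acyl GPL",
                                      "acyl-acyl GPL"),
                      beta = c(-1, -2, 0.5, 1))
    cs <- classSummary(met)
    expect_equal(cs$n, c(2, 2))
    expect_equal(cs$pct, c(50, 50))
    expect_equal(sum(cs$pct), 100)
    expect_equal(cs$n_down[cs$lipid_class == "TAG"], 2)
    expect_equal(cs$n_up[cs$lipid_class == "acyl-acyl GPL"], 2)
    ## missing class goes to "other"
    met2 <- rbind(met, data.frame(metabolite = "e", lipid_class = NA,
                                  beta = 1))
    expect_true("other" %in% classSummary(met2)$lipid_class)
})

test_that("affected classes dominate the class summary over seeds", {
    top <- vapply(1:20, function(s) {
        sim <- simulateStudy(simConfig(
            nCarriers = 10L, seed = 700L + s, duplicateRate = 0,
            annotationRate = 1, lodQuantile = 0,
            nFeaturesPerClass = c("TAG" = 25L, "Ceramide" = 25L,
                                  "Other" = 50L),
            effectByClass = c("TAG" = -1.5, "Ceramide" = 0, "Other" = 0)))
        x <- rankNormalize(pqnNormalize(sim$experiment))
        pa <- runPrimaryAnalyses(x)
        res <- pa$results[pa$results$dataset == "combined" &
                          pa$results$feature %in% pa$associated, ]
        if (!nrow(res)) return(NA_character_)
        cs <- classSummary(dedupAnnotations(res,
                                            featureMeta(sim$experiment)))
        cs$lipid_class[which.max(cs$n)]
    }, character(1))
    expect_gte(mean(top == "TAG", na.rm = TRUE), 0.9)
})

test_that("residualization removes exactly the age/sex fit", {
    meta <- data.frame(age = c(10, 12, 14, 16, 18, 20),
                       sex = rep(c("F", "M"), 3))
    y <- 2 * meta$age
    r <- residualize(y, meta)
    expect_true(all(abs(r) < 1e-10))
    set.seed(31)
    y2 <- rnorm(6)
    y2[3] <- NA
    r2 <- residualize(y2, meta)
    expect_true(is.na(r2[3]))
    use <- !is.na(y2)
    X <- cbind(meta$age[use], as.numeric(meta$sex[use] == "M"))
    expect_true(all(abs(crossprod(X, r2[use])) < 1e-10))
    expect_lt(abs(sum(r2[use])), 1e-10)
})

test_that("Ward clustering recovers well-separated groups", {
    set.seed(32)
    X <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
               matrix(rnorm(20, 50, 0.1), 10, 2))
    rownames(X) <- sprintf("r%02d", 1:20)
    cl <- wardCluster(cbind(X, X))  # >= 2 columns each axis
    k2 <- cutree(cl$rowHclust, 2)
    expect_equal(length(unique(k2[1:10])), 1)
    expect_equal(length(unique(k2[11:20])), 1)
    expect_false(k2[1] == k2[11])
})

test_that("Ward linkage matches the from-definition agglomerator", {
    set.seed(33)
    for (i in 1:10) {
        n <- sample(5:12, 1)
        X <- matrix(rnorm(n * 3), n, 3)
        h <- hclust(dist(X), method = "ward.D2")
        o <- wardOracle(X)
        expect_equal(sort(h$height), sort(o$heights), tolerance = 1e-8)
        for (k in 2:(n - 1))
            expect_identical(canonicalPartition(cutree(h, k)),
                             canonicalPartition(o$partitions[[n - k]]))
    }
})

test_that("Ward partitions are invariant to input permutation", {
    set.seed(34)
    X <- matrix(rnorm(30), 10, 3)
    rownames(X) <- sprintf("r%02d", 1:10)
    h1 <- wardCluster(X)$rowHclust
    perm <- sample(10)
    h2 <- wardCluster(X[perm, ])$rowHclust
    for (k in 2:9) {
        p1 <- cutree(h1, k)
        p2 <- cutree(h2, k)[rownames(X)]
        ## same partition up to label names
        expect_identical(canonicalPartition(p1[order(names(p1))]),
                         canonicalPartition(p2[order(names(p2))]))
    }
    expect_error(wardCluster(X[1, , drop = FALSE]), "at least 2")
    Xna <- X; Xna[1, 1] <- NA
    expect_error(wardCluster(Xna), "missing")
})

test_that("cohort table reproduces exact Wilcoxon enumeration", {
    meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                       subject_id = sprintf("s%d", 1:6),
                       genotype = rep(c("carrier", "non-carrier"), each = 3),
                       age = c(1, 2, 3, 4, 5, 6),
                       cohort = "young", is_qc = FALSE)
    ct <- cohortTable(meta)
    expect_equal(ct$p[ct$trait == "age"], 2 / choose(6, 3), tolerance = 1e-12)
    expect_equal(ct$p[ct$trait == "age"], 0.1, tolerance = 1e-12)
    ## perfectly interleaved groups: exact p = 1
    meta2 <- meta
    meta2$age <- c(1, 4, 5, 2, 3, 6)
    expect_equal(cohortTable(meta2)$p, 1)
    ## clinical traits merge in by sample id
    clin <- data.frame(sample_id = meta$sample_id, hdl = c(2, 2, 2, 1, 1, 1))
    ct3 <- cohortTable(meta, clin)
    expect_true("hdl" %in% ct3$trait)
    expect_equal(ct3$carrier_mean[ct3$trait == "hdl"], 2)
})

test_that("star coding follows the significance legend", {
    expect_identical(starCode(c(0.0005, 0.004, 0.04, 0.4)),
                     c("***", "**", "*", "n"))
})

test_that("the residual heatmap matrix has dedup x sample dimensions", {
    sim <- simulateStudy(simConfig(nCarriers = 8L, seed = 41L,
                                   lodQuantile = 0))
    x <- rankNormalize(pqnNormalize(sim$experiment))
    pa <- runPrimaryAnalyses(x)
    res <- pa$results[pa$results$dataset == "combined" &
                      pa$results$feature %in% pa$associated, ]
    skip_if(nrow(res) < 2)
    met <- dedupAnnotations(res, featureMeta(x))
    sdx <- sampleMeta(x)
    ids <- colnames(x)[!sdx$is_qc & sdx$fasting %in% TRUE]
    R <- residualMatrix(x, met, ids)
    expect_equal(ncol(R), length(ids))
    expect_lte(nrow(R), nrow(met))
    expect_false(anyNA(R))
    f <- file.path(tempdir(), "hm.png")
    plotAssociationHeatmap(x, met, ids, file = f)
    expect_true(file.exists(f))
    f2 <- file.path(tempdir(), "mz.png")
    plotEffectByMz(met, featureMeta(x), file = f2)
    expect_true(file.exists(f2))
})
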