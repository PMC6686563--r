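test_that("missing-gene filter applies the strict less-than rule", {
    study <- tiny_study(n_genes = 4, n_samples = 10, seed = 2)
    v <- exprValues(study)
    v["g02", 1] <- NA                 # exactly 10% missing
    v["g03", 1:2] <- NA               # 20%
    md <- data.frame(sample_id = sampleIds(study),
                     condition = unname(studyConditions(study)),
                     sample_type = unname(sampleTypes(study)),
                     batch = "b1")
    study <- ExpressionStudy(v, md)
    flt <- filterMissingGenes(study, 0.10)
    expect_equal(geneIds(flt$study), c("g01", "g04"))
    expect_setequal(flt$removed, c("g02", "g03"))
    expect_error(filterMissingGenes(study, 0), "every gene")
})

test_that("knn imputation honors identity neighbors and constants", {
    # gene B identical to A everywhere except the missing cell: with k = 1
    # the imputed value is B's value at that sample
    v <- matrix(c(1, 2, 3, 4, 5,
                  1, 2, 3, 4, 5,
                  9, 7, 5, 3, 1), 3, 5, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), paste0("s", 1:5)))
    v["A", 3] <- NA
    md <- data.frame(sample_id = paste0("s", 1:5),
                     condition = c("stroke", "stroke", "control", "control",
                                   "stroke"),
                     sample_type = "whole_blood", batch = "b")
    imp <- knnImpute(ExpressionStudy(v, md), k = 1L)
    expect_equal(exprValues(imp$study)["A", 3], 3)
    expect_equal(imp$imputed_cells, 1L)
    # constant matrix: the only possible value is the constant
    vc <- matrix(5, 3, 8, dimnames = list(c("A", "B", "C"), paste0("s", 1:8)))
    vc["B", 4] <- NA
    mdc <- data.frame(sample_id = paste0("s", 1:8),
                      condition = rep(c("stroke", "control"), 4),
                      sample_type = "whole_blood", batch = "b")
    impc <- knnImpute(ExpressionStudy(vc, mdc), k = 2L)
    expect_equal(exprValues(impc$study)["B", 4], 5)
})

test_that("knn imputation matches the brute-force oracle on random fixtures", {
    for (seed in 1:3) {
        set.seed(seed)
        v <- matrix(rnorm(50 * 20), 50, 20,
                    dimnames = list(sprintf("g%02d", 1:50),
                                    sprintf("s%02d", 1:20)))
        v[sample(length(v), 10)] <- NA
        md <- data.frame(sample_id = colnames(v),
                         condition = rep(c("stroke", "control"), 10),
                         sample_type = "whole_blood", batch = "b")
        study <- ExpressionStudy(v, md)
        imp <- knnImpute(study, k = 5L)
        expect_equal(exprValues(imp$study), oracle_knn_impute(v, 5L),
                     tolerance = 1e-10)
        # observed cells are never altered
        obs <- !is.na(v)
        expect_identical(exprValues(imp$study)[obs], v[obs])
    }
})

test_that("normalizer choice follows housekeeping stability", {
    set.seed(30)
    n <- 40
    cond <- rep(c("stroke", "control"), each = n / 2)
    v <- matrix(rnorm(4 * n, mean = 6, sd = 0.05), 4, n,
                dimnames = list(c("hk_up", "hk_down", "hk_flat", "other"),
                                sprintf("s%02d", seq_len(n))))
    v["hk_up", cond == "stroke"] <- v["hk_up", cond == "stroke"] + 0.5
    v["hk_down", cond == "stroke"] <- v["hk_down", cond == "stroke"] - 0.5
    md <- data.frame(sample_id = colnames(v), condition = cond,
                     sample_type = "whole_blood", batch = "b")
    study <- ExpressionStudy(v, md)
    # every candidate unstable (|log2 FC| ~ 0.5): fall back to medians
    pick <- chooseNormalizer(study, c("hk_up", "hk_down"), fc_threshold = 0.3)
    expect_equal(pick$strategy, "median_per_sample")
    # one stable candidate flips the choice to housekeeping rescaling
    pick2 <- chooseNormalizer(study, c("hk_up", "hk_flat"),
                              fc_threshold = 0.3)
    expect_equal(pick2$strategy, "housekeeping")
    expect_equal(pick2$stable_genes, "hk_flat")
    normed <- housekeepingNormalize(study, pick2$stable_genes)
    anchor <- exprValues(normed)["hk_flat", ]
    expect_lt(max(anchor) - min(anchor), 1e-12)
    expect_warning(chooseNormalizer(study, c("ACTB", "B2M")), "median")
})

test_that("median normalization equalizes per-sample medians exactly", {
    study <- tiny_study(n_genes = 20, n_samples = 8, seed = 3)
    normed <- medianNormalize(study)
    med <- apply(exprValues(normed), 2, median)
    expect_lt(max(med) - min(med), 1e-12)
    # a pre-equalized matrix is unchanged
    again <- medianNormalize(normed)
    expect_equal(exprValues(again), exprValues(normed))
    # a constant per-sample shift is removed entirely: shifting one sample
    # up by 2 and renormalizing reproduces the unshifted normalization
    v <- exprValues(study)
    v2 <- v
    v2[, 3] <- v2[, 3] + 2
    md <- data.frame(sample_id = sampleIds(study),
                     condition = unname(studyConditions(study)),
                     sample_type = unname(sampleTypes(study)), batch = "b")
    n_ref <- medianNormalize(ExpressionStudy(v, md))
    n_shift <- medianNormalize(ExpressionStudy(v2, md))
    # identical up to the (data-dependent) global anchor
    delta <- exprValues(n_shift) - exprValues(n_ref)
    expect_lt(max(delta) - min(delta), 1e-12)
})

test_that("local outlier factor matches the brute-force oracle", {
    set.seed(9)
    x <- rbind(matrix(rnorm(60), 30, 2), c(8, 8))
    lof <- localOutlierFactor(x, k = 5L)
    expect_equal(lof, oracle_lof(x, 5L), tolerance = 1e-10)
    expect_gt(lof[31], 1.5)          # the planted far point
    expect_lt(median(lof[1:30]), 1.2)
})

test_that("PCA+LOF flags a shifted sample and applies the validity gate", {
    set.seed(10)
    v <- matrix(rnorm(60 * 41, mean = 6, sd = 0.5), 60, 41,
                dimnames = list(sprintf("g%02d", 1:60),
                                sprintf("s%02d", 1:41)))
    v[, 41] <- v[, 41] + rnorm(60, sd = 5)  # 10 noise-sd global shift
    md <- data.frame(sample_id = colnames(v),
                     condition = rep(c("stroke", "control"), length.out = 41),
                     sample_type = "whole_blood", batch = "b")
    det <- detectOutliers(ExpressionStudy(v, md), lof_neighbors = 10L)
    expect_equal(det$outliers, "s41")
    expect_true(det$dataset_valid)
    # i.i.d. samples: few flags, dataset valid
    v2 <- v[, 1:40]
    det2 <- detectOutliers(ExpressionStudy(v2, md[1:40, ]),
                           lof_neighbors = 10L)
    expect_lte(length(det2$outliers) / 40, 0.05)
    expect_true(det2$dataset_valid)
})

test_that("planted outliers are recovered and heavy contamination invalidates", {
    # recovery across seeds at default contamination
    found <- 0L; planted <- 0L; fp <- 0L; clean_n <- 0L
    for (seed in 1:10) {
        out <- generateStudy(mid_config(seed = 500 + seed))
        pre <- suppressWarnings(preprocessStudy(out$study,
                                                pipelineConfig(seed = seed)))
        truth <- out$truth@outlier_samples
        found <- found + length(intersect(pre$qc@outlier_samples, truth))
        planted <- planted + length(truth)
        fp <- fp + length(setdiff(pre$qc@outlier_samples, truth))
        clean_n <- clean_n + 137 - length(truth)
    }
    expect_gte(found / planted, 0.9)
    expect_lte(fp / clean_n, 0.05)
    # 15% planted outliers: the validity gate trips
    out2 <- generateStudy(mid_config(n_outliers = 21L, seed = 77))
    pre2 <- suppressWarnings(preprocessStudy(out2$study, pipelineConfig(seed = 77)))
    expect_false(pre2$qc@dataset_valid)
})

test_that("the pipeline refuses to continue on an invalid dataset", {
    out <- generateStudy(mid_config(n_genes = 120L, n_outliers = 21L,
                                    seed = 78))
    expect_error(suppressWarnings(
        runPipeline(out$study, pipelineConfig(seed = 78))), "validity gate")
})
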