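test_that("gene-wise OLS matches an explicit normal-equations solver", {
    study <- tiny_study(n_genes = 5, n_samples = 12, seed = 4)
    fit <- fitGeneModels(study)
    X <- cbind(1, as.numeric(studyConditions(study) == "stroke"),
               as.numeric(sampleTypes(study) == "pbmc"))
    xtx_inv <- solve(t(X) %*% X)
    v <- exprValues(study)
    for (g in seq_len(5)) {
        beta <- xtx_inv %*% t(X) %*% v[g, ]
        res <- v[g, ] - X %*% beta
        s2 <- sum(res^2) / (12 - 3)
        expect_equal(unname(fit$beta[g]), beta[2, 1], tolerance = 1e-10)
        expect_equal(unname(fit$s_sq[g]), s2, tolerance = 1e-10)
    }
    expect_equal(fit$df, 9)
    expect_equal(fit$unscaled_sd, sqrt(xtx_inv[2, 2]), tolerance = 1e-12)
})

test_that("collinear covariate is dropped and the effect becomes a mean difference", {
    set.seed(5)
    v <- matrix(rnorm(4 * 10, 6), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
    md <- data.frame(sample_id = colnames(v),
                     condition = rep(c("stroke", "control"), each = 5),
                     sample_type = "whole_blood", batch = "b")
    study <- ExpressionStudy(v, md)
    expect_warning(fit <- fitGeneModels(study), "collinear")
    means <- rowMeans(v[, 1:5]) - rowMeans(v[, 6:10])
    expect_equal(unname(fit$beta), unname(means), tolerance = 1e-12)
})

test_that("an orthogonal covariate leaves the condition effect unchanged", {
    set.seed(6)
    v <- matrix(rnorm(3 * 12, 6), 3, 12,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:12)))
    md <- data.frame(sample_id = colnames(v),
                     condition = rep(c("stroke", "control"), each = 6),
                     sample_type = rep(c("whole_blood", "pbmc"),
                                       times = 6),  # balanced within condition
                     batch = "b")
    study <- ExpressionStudy(v, md)
    fit_with <- fitGeneModels(study)
    md2 <- md
    md2$sample_type <- "whole_blood"
    expect_warning(fit_without <- fitGeneModels(ExpressionStudy(v, md2)))
    expect_equal(fit_with$beta, fit_without$beta, tolerance = 1e-10)
})

test_that("variance-prior estimation recovers known parameters", {
    # draws from a scaled inverse chi-square prior with d0 = 4, s0^2 = 1:
    # s^2_g | sg2 ~ sg2 * chisq(d)/d with sg2 ~ d0 s0^2 / chisq(d0)
    d <- 6
    rel_err_d0 <- c()
    rel_err_s0 <- c()
    for (seed in 1:10) {
        set.seed(seed)
        sg2 <- 4 * 1 / rchisq(5000, df = 4)
        s2 <- sg2 * rchisq(5000, df = d) / d
        eb <- estimateEbayes(s2, d)
        rel_err_d0 <- c(rel_err_d0, abs(eb$d0 - 4) / 4)
        rel_err_s0 <- c(rel_err_s0, abs(eb$s0_sq - 1))
    }
    expect_lt(mean(rel_err_d0), 0.15)
    expect_lt(mean(rel_err_s0), 0.15)
})

test_that("variance prior edge cases follow the contract", {
    expect_error(estimateEbayes(rep(1, 5), 4), "at least 10")
    expect_error(estimateEbayes(c(rep(1, 20), -1), 4), "positive")
    # identical variances: no dispersion beyond sampling floor -> d0 = Inf
    eb <- estimateEbayes(rep(2, 100), 10)
    expect_true(is.infinite(eb$d0))
})

test_that("moderated variance arithmetic and limits are exact", {
    # stated shrinkage identity: (4*1 + 6*2) / (4 + 6) = 1.6
    mt <- moderatedT(beta = 1, s_sq = 2, df = 6,
                     eb = list(d0 = 4, s0_sq = 1), unscaled_sd = 1)
    expect_equal(mt$s_sq_post, 1.6)
    # d0 = 0: ordinary t
    mt0 <- moderatedT(beta = 2, s_sq = 2, df = 6,
                      eb = list(d0 = 0, s0_sq = 1), unscaled_sd = 0.5)
    expect_equal(mt0$t, 2 / (sqrt(2) * 0.5))
    expect_equal(mt0$p_value, 2 * pt(-abs(mt0$t), df = 6))
    # d0 = Inf: fully shrunk to the prior for every gene
    mtI <- moderatedT(beta = c(1, 2), s_sq = c(5, 9), df = 6,
                      eb = list(d0 = Inf, s0_sq = 2), unscaled_sd = 1)
    expect_equal(mtI$s_sq_post, c(2, 2))
})

test_that("moderated t agrees with limma on a shared fixture", {
    skip_if_not_installed("limma")
    out <- small_synth(seed = 41)
    study <- out$study
    v <- exprValues(study)
    X <- cbind(1, as.numeric(studyConditions(study) == "stroke"),
               as.numeric(sampleTypes(study) == "pbmc"))
    lfit <- limma::eBayes(limma::lmFit(v, X))
    fit <- fitGeneModels(study)
    eb <- estimateEbayes(fit$s_sq, fit$df)
    mt <- moderatedT(fit$beta, fit$s_sq, fit$df, eb, fit$unscaled_sd)
    expect_equal(unname(fit$beta), unname(lfit$coefficients[, 2]),
                 tolerance = 1e-8)
    expect_equal(eb$d0, lfit$df.prior, tolerance = 0.05)
    expect_equal(eb$s0_sq, lfit$s2.prior, tolerance = 0.02)
    expect_equal(unname(mt$t), unname(lfit$t[, 2]), tolerance = 1e-6)
    expect_equal(unname(mt$p_value), unname(lfit$p.value[, 2]),
                 tolerance = 1e-6)
})

test_that("BH adjustment matches the reference step-up on random inputs", {
    expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
                 rep(0.04, 4))
    expect_equal(benjaminiHochberg(0.3), 0.3)
    expect_error(benjaminiHochberg(c(0.1, 1.2)), "\\[0, 1\\]")
    set.seed(8)
    for (i in 1:1000) {
        p <- runif(sample(1:50, 1))
        expect_equal(benjaminiHochberg(p), oracle_bh(p),
                     tolerance = 1e-12)
    }
})

test_that("differential expression table satisfies its invariants", {
    out <- small_synth(seed = 42)
    cfg <- pipelineConfig(seed = 42)
    de <- runDiffexp(out$study, cfg)
    expect_true(all(de$p_adjusted >= de$p_value - 1e-15))
    expect_identical(de$significant, de$p_adjusted < cfg@fdr_alpha)
    nz <- de$log_fc != 0 & de$t_moderated != 0
    expect_true(all(sign(de$log_fc[nz]) == sign(de$t_moderated[nz])))
    expect_equal(de$ave_expr, unname(rowMeans(exprValues(out$study))))
})

test_that("DE detection is calibrated under the null and powered under effects", {
    # global null: no gene family-wise significant in most seeds
    fracs <- c()
    for (seed in 1:5) {
        out <- generateStudy(mid_config(
            n_genes = 200L, de_effect = 0, n_hub_genes = 0L,
            n_outliers = 0L, missing_rate = 0, seed = 600 + seed))
        de <- runDiffexp(out$study, pipelineConfig(seed = seed))
        fracs <- c(fracs, mean(de$significant))
    }
    expect_lt(mean(fracs), 0.05)
    # default effects: most planted DE genes recovered
    out <- generateStudy(syntheticConfig(seed = 43))
    pre <- suppressWarnings(preprocessStudy(out$study, pipelineConfig(seed = 43)))
    de <- runDiffexp(pre$study, pipelineConfig(seed = 43))
    rec <- mean(out$truth@de_genes %in% de$gene_id[de$significant])
    expect_gte(rec, 0.8)
})
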