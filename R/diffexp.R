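#' @include AllClasses.R
NULL

#' Gene-wise linear models with a sample-type covariate
#'
#' Fits, per gene, ordinary least squares on the design
#' `~ condition + sample_type` (intercept, stroke indicator, PBMC
#' indicator). The condition coefficient is the covariate-adjusted log2 fold
#' change stroke vs control. A covariate collinear with the rest of the
#' design (e.g. a single sample type) is dropped with a warning.
#'
#' @param study An [ExpressionStudy-class] without missing values, both
#'   conditions present with at least 2 samples each.
#' @return List with per-gene vectors `beta` (condition effect), `s_sq`
#'   (residual variance), `ave_expr`, scalar `df` (residual degrees of
#'   freedom) and `unscaled_sd` (sqrt of the condition coefficient's
#'   unscaled variance, shared across genes).
#' @export
fitGeneModels <- function(study) {
    v <- exprValues(study)
    if (anyNA(v)) stop("impute missing values before model fitting")
    cond <- studyConditions(study)
    if (sum(cond == "stroke") < 2L || sum(cond == "control") < 2L)
        stop("each condition needs at least 2 samples")
    x_cond <- as.numeric(cond == "stroke")
    x_type <- as.numeric(sampleTypes(study) == "pbmc")
    X <- cbind(intercept = 1, condition = x_cond, sample_type = x_type)
    if (qr(X)$rank < ncol(X)) {
        warning("sample-type covariate collinear with design; dropped")
        X <- X[, c("intercept", "condition"), drop = FALSE]
    }
    n <- nrow(X)
    qrX <- qr(X)
    # coefficients for all genes at once: solve X B = Y
    B <- qr.coef(qrX, t(v))
    fitted <- X %*% B
    res <- t(v) - fitted
    df <- n - qrX$rank
    s_sq <- colSums(res^2) / df
    xtx_inv <- chol2inv(qr.R(qrX))
    j <- which(colnames(X) == "condition")
    list(beta = B[j, ], s_sq = unname(s_sq), df = df,
         ave_expr = rowMeans(v), unscaled_sd = sqrt(xtx_inv[j, j]))
}

# Newton inversion of the trigamma function (decreasing on (0, Inf)).
.trigamma_inverse <- function(y) {
    vapply(y, function(yy) {
        if (yy <= 0) return(Inf)
        if (yy > 1e7) return(1 / sqrt(yy))
        x <- 0.5 + 1 / yy
        for (i in 1:60) {
            tri <- trigamma(x)
            dif <- tri * (1 - tri / yy) / psigamma(x, 2L)
            x <- x + dif
            if (abs(dif) < 1e-10 * x) break
        }
        x
    }, numeric(1))
}

#' Empirical-Bayes prior for gene variances
#'
#' Fits a scaled inverse chi-square prior to the observed residual variances
#' by matching the mean and variance of `log(s^2)` (method of moments on the
#' log scale). When the empirical dispersion of `log(s^2)` does not exceed
#' the sampling floor `trigamma(df/2)`, the prior degrees of freedom are
#' infinite (all variances shrunk fully to `s0_sq`).
#'
#' @param s_sq Per-gene residual variances (at least 10 genes, all > 0).
#' @param df Residual degrees of freedom of the gene-wise fits (scalar).
#' @return List with `d0` (prior df; may be `Inf`) and `s0_sq` (prior
#'   variance).
#' @export
estimateEbayes <- function(s_sq, df) {
    if (length(s_sq) < 10L)
        stop("need at least 10 genes to estimate the variance prior")
    if (any(s_sq <= 0)) stop("residual variances must be positive")
    stopifnot(df >= 1)
    z <- log(s_sq)
    evar <- stats::var(z) - trigamma(df / 2)
    if (evar <= 0) {
        d0 <- Inf
        s0 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
    } else {
        d0 <- 2 * .trigamma_inverse(evar)
        s0 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
    }
    list(d0 = d0, s0_sq = s0)
}

#' Moderated t-statistics
#'
#' Shrinks each gene's variance toward the prior,
#' `s2_tilde = (d0 * s0_sq + df * s_sq) / (d0 + df)`, and tests the
#' condition effect with `t = beta / (sqrt(s2_tilde) * unscaled_sd)` on
#' `d0 + df` degrees of freedom (normal in the `d0 = Inf` limit). `d0 = 0`
#' reproduces the ordinary t-statistic.
#'
#' @param beta Per-gene condition effects.
#' @param s_sq Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @param eb Prior from [estimateEbayes()].
#' @param unscaled_sd Unscaled standard deviation of the condition
#'   coefficient (from [fitGeneModels()]).
#' @return List with `t` (moderated t), `p_value` (two-sided) and
#'   `s_sq_post` (posterior variances).
#' @export
moderatedT <- function(beta, s_sq, df, eb, unscaled_sd) {
    stopifnot(eb$s0_sq > 0, eb$d0 >= 0)
    s2p <- if (is.infinite(eb$d0)) rep(eb$s0_sq, length(s_sq))
           else (eb$d0 * eb$s0_sq + df * s_sq) / (eb$d0 + df)
    tt <- beta / (sqrt(s2p) * unscaled_sd)
    p <- 2 * stats::pt(-abs(tt), df = eb$d0 + df)
    list(t = tt, p_value = p, s_sq_post = s2p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1, input
#' order preserved); delegates to [stats::p.adjust()] after validating the
#' input.
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
benjaminiHochberg <- function(p_values) {
    if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p_values, method = "BH")
}

#' Differential expression analysis
#'
#' Gene-wise linear models with the sample-type covariate, empirical-Bayes
#' moderated t-statistics, and BH-adjusted two-sided p-values.
#'
#' @param study A preprocessed [ExpressionStudy-class].
#' @param cfg A [PipelineConfig-class] (uses `fdr_alpha`).
#' @return Data frame with one row per gene: `gene_id`, `log_fc`,
#'   `ave_expr`, `t_moderated`, `p_value`, `p_adjusted`, `significant`.
#' @export
runDiffexp <- function(study, cfg = pipelineConfig()) {
    fit <- fitGeneModels(study)
    eb <- estimateEbayes(fit$s_sq, fit$df)
    mt <- moderatedT(fit$beta, fit$s_sq, fit$df, eb, fit$unscaled_sd)
    padj <- benjaminiHochberg(mt$p_value)
    data.frame(gene_id = geneIds(study), log_fc = unname(fit$beta),
               ave_expr = unname(fit$ave_expr), t_moderated = unname(mt$t),
               p_value = unname(mt$p_value), p_adjusted = padj,
               significant = padj < cfg@fdr_alpha,
               stringsAsFactors = FALSE)
}
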