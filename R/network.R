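#' @include AllClasses.R core_io.R
NULL

#' Default number of quantile bins at sample size n
#'
#' `ceil(sqrt(n/5))` clamped to `[2, 24]`: roughly five observations per
#' marginal bin, enough cells to resolve dependence without starving the
#' joint table. The upper clamp keeps the estimator within 0.1 nat of the
#' bivariate-Gaussian closed form at `n = 5000`.
#'
#' @param n Sample count.
#' @return Integer bin count.
#' @export
defaultBins <- function(n) {
    as.integer(max(2L, min(24L, ceiling(sqrt(n / 5)))))
}

.rank_bins <- function(x, n_bins) {
    r <- rank(x, ties.method = "min")
    as.integer(floor((r - 1) * n_bins / length(x)) + 1L)
}

#' Discretize a pair of expression vectors
#'
#' Equal-frequency (quantile) binning per variable; tied values share the
#' lower bin. Returns the joint contingency table and its marginals. A
#' constant vector lands in a single bin (marginal entropy zero, so MI
#' against anything is 0).
#'
#' @param x,y Numeric vectors of equal length (>= 8).
#' @param n_bins Bins per variable (default [defaultBins()] of the length).
#' @return List with `bin_counts` (joint counts), `p_ij` (joint
#'   frequencies), `p_i`, `p_j` (marginals), `n`, `n_bins`, and the
#'   per-sample bin indices `bins_x`, `bins_y`.
#' @export
discretizePair <- function(x, y, n_bins = defaultBins(length(x))) {
    stopifnot(length(x) == length(y), length(x) >= 8L, n_bins >= 2L)
    bx <- .rank_bins(x, n_bins)
    by <- .rank_bins(y, n_bins)
    counts <- matrix(tabulate((bx - 1L) * n_bins + by, n_bins * n_bins),
                     n_bins, n_bins, byrow = TRUE)
    p <- counts / length(x)
    list(bin_counts = counts, p_ij = p, p_i = rowSums(p), p_j = colSums(p),
         n = length(x), n_bins = n_bins, bins_x = bx, bins_y = by)
}

#' Mutual information of a discretized pair
#'
#' `I = sum_ij p_ij log(p_ij / (p_i p_j))` in nats over nonzero cells,
#' normalized by the smaller marginal entropy so the value lives in
#' `[0, 1]` (with `0/0` defined as 0; a non-constant profile against itself
#' scores exactly 1).
#'
#' @param pair Output of [discretizePair()].
#' @return List with `i` (nats), `i_norm`, `h_x`, `h_y`.
#' @export
mutualInformation <- function(pair) {
    p <- pair$p_ij
    px <- pair$p_i
    py <- pair$p_j
    nz <- p > 0
    ratio <- p / outer(px, py)
    i <- sum(p[nz] * log(ratio[nz]))
    if (i < 0) i <- 0
    hx <- -sum(px[px > 0] * log(px[px > 0]))
    hy <- -sum(py[py > 0] * log(py[py > 0]))
    hmin <- min(hx, hy)
    list(i = i, i_norm = if (hmin > 0) min(i / hmin, 1) else 0,
         h_x = hx, h_y = hy)
}

#' Null-calibrated edge threshold for normalized MI
#'
#' Monte-Carlo quantile of the normalized-MI estimator under independence at
#' the given sample size and bin count (both margins are random orderings of
#' the balanced bin labels the quantile rule produces). The published edge
#' rule places its cut at the upper tail of the null; because the finite-n
#' estimator is biased upward, the resulting threshold depends on `n` and
#' the bin count and is not portable as a fixed number across estimators.
#'
#' @param n Sample count.
#' @param n_bins Bins per variable (default [defaultBins()]).
#' @param quantile Null quantile (default 0.9999: with on the order of 1e5
#'   gene pairs per network, a looser cut admits enough false edges to
#'   distort centrality through spurious two-node components).
#' @param n_null Null draws (default 50000).
#' @return The threshold (numeric scalar). Uses the current RNG state.
#' @export
calibrateEdgeThreshold <- function(n, n_bins = defaultBins(n),
                                   quantile = 0.9999, n_null = 50000L) {
    null <- cpp_null_nmi(as.integer(n), as.integer(n_bins),
                         as.integer(n_null))
    unname(stats::quantile(null, quantile))
}

.resolve_edge_threshold <- function(cfg, n, n_bins) {
    if (cfg@mi_edge_rule == "fixed") return(cfg@mi_edge_threshold)
    max(.resolve_prefilter(cfg, n, n_bins),
        calibrateEdgeThreshold(n, n_bins, cfg@mi_null_quantile))
}

# Operative weak-dependence screen. The configured prefilter value is a
# published constant on an estimator scale where the independence null sits
# far lower; under the statistical edge rules the screen is tightened to
# the null's 95th percentile when that is smaller, so genuinely dependent
# mid-strength pairs are not discarded at large n while clearly
# uncorrelated pairs still are.
.resolve_prefilter <- function(cfg, n, n_bins) {
    if (cfg@mi_edge_rule == "fixed") return(cfg@mi_prefilter)
    min(cfg@mi_prefilter, calibrateEdgeThreshold(n, n_bins, 0.95, 4000L))
}

#' Critical correlation of the bivariate-normal edge rule
#'
#' Smallest absolute Pearson correlation declared significant at sample
#' size `n` under a two-sided Fisher-z test at per-pair level `alpha`
#' (`z = atanh(r) * sqrt(n - 3)`). With `alpha = 1 - mi_null_quantile` the
#' expected number of false edges in a network of `P` pairs is `P * alpha`.
#'
#' @param n Sample count (> 3).
#' @param alpha Per-pair two-sided level.
#' @return The critical |r|.
#' @export
fisherEdgeCritical <- function(n, alpha) {
    stopifnot(n > 3, alpha > 0, alpha < 1)
    tanh(stats::qnorm(1 - alpha / 2) / sqrt(n - 3))
}

#' Significance of one candidate edge
#'
#' Two-stage rule: pairs with normalized MI below `mi_prefilter` are
#' discarded as uncorrelated (no p-value). Surviving pairs are tested
#' according to `cfg@mi_edge_rule`:
#'
#' * `"fisher"` (default): bivariate-normal confidence-interval rule; the
#'   pair is significant iff `|cor(x, y)|` reaches
#'   [fisherEdgeCritical()]`(n, 1 - mi_null_quantile)`; the reported
#'   p-value is the two-sided Fisher-z p.
#' * `"calibrated"`: seeded permutation test of the MI (permuting one
#'   margin, which preserves both marginal entropies); significant iff the
#'   permutation p is below 0.05 *and* the normalized MI reaches the
#'   Monte-Carlo null quantile threshold of [calibrateEdgeThreshold()].
#' * `"fixed"`: as `"calibrated"`, but against the fixed
#'   `cfg@mi_edge_threshold`.
#'
#' @param x,y Expression vectors over one condition's samples.
#' @param cfg A [PipelineConfig-class].
#' @param n_perm Permutations for the permutation-based rules (default
#'   `cfg@n_perm`; must be >= 20).
#' @return List with `i_norm`, `p_edge` (`NA` below the prefilter),
#'   `significant`, and `threshold` (the resolved MI edge threshold, or the
#'   MI prefilter under the fisher rule).
#' @export
edgeSignificance <- function(x, y, cfg = pipelineConfig(),
                             n_perm = cfg@n_perm) {
    if (n_perm < 20L) stop("n_perm must be at least 20")
    n_bins <- if (is.na(cfg@mi_bins)) defaultBins(length(x)) else cfg@mi_bins
    pair <- discretizePair(x, y, n_bins)
    mi <- mutualInformation(pair)
    if (cfg@mi_edge_rule == "fisher") {
        thr <- .resolve_prefilter(cfg, length(x), n_bins)
        if (mi$i_norm < thr)
            return(list(i_norm = mi$i_norm, p_edge = NA_real_,
                        significant = FALSE, threshold = thr))
        r <- stats::cor(x, y)
        z <- atanh(min(abs(r), 1 - 1e-12)) * sqrt(length(x) - 3)
        rc <- fisherEdgeCritical(length(x), 1 - cfg@mi_null_quantile)
        return(list(i_norm = mi$i_norm, p_edge = 2 * stats::pnorm(-z),
                    significant = abs(r) >= rc, threshold = thr))
    }
    thr <- .resolve_edge_threshold(cfg, length(x), n_bins)
    if (mi$i_norm < cfg@mi_prefilter)
        return(list(i_norm = mi$i_norm, p_edge = NA_real_,
                    significant = FALSE, threshold = thr))
    bins <- rbind(pair$bins_x, pair$bins_y)
    p <- cpp_perm_pvals(bins, as.integer(n_bins),
                        matrix(c(1L, 2L), 1L), as.integer(n_perm))[1L]
    list(i_norm = mi$i_norm, p_edge = p,
         significant = p < 0.05 && mi$i_norm >= thr, threshold = thr)
}

#' Build a per-condition co-expression network
#'
#' Evaluates normalized mutual information for every unordered gene pair on
#' the condition's samples and keeps edges that pass the two-stage
#' significance rule of [edgeSignificance()] under `cfg@mi_edge_rule`.
#' Edge weights are normalized MI. Under the permutation-based rules,
#' p-values are computed only for pairs that reach the MI edge threshold
#' (pairs below it can never be significant, so skipping their
#' permutations changes nothing). Genes without edges remain as isolated
#' nodes.
#'
#' @param study A preprocessed [ExpressionStudy-class].
#' @param condition `"stroke"` or `"control"`.
#' @param cfg A [PipelineConfig-class].
#' @param n_bins Bin-count override (default: `cfg@mi_bins`, else
#'   [defaultBins()] at the condition's sample count).
#' @param samples Optional sample-id subset (used by resampling schemes).
#' @return A [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(study, condition, cfg = pipelineConfig(),
                         n_bins = NULL, samples = NULL) {
    if (is.null(samples)) {
        if (!condition %in% studyConditions(study))
            stop("condition '", condition, "' absent from study")
        keep <- sampleIds(study)[studyConditions(study) == condition]
    } else {
        keep <- samples
    }
    v <- exprValues(study)[, keep, drop = FALSE]
    if (anyNA(v)) stop("impute missing values before network construction")
    n <- ncol(v)
    if (is.null(n_bins))
        n_bins <- if (is.na(cfg@mi_bins)) defaultBins(n) else cfg@mi_bins
    bins <- t(apply(v, 1L, .rank_bins, n_bins = n_bins))
    storage.mode(bins) <- "integer"
    nmi <- cpp_nmi_matrix(bins, as.integer(n_bins))
    genes <- rownames(v)
    empty <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), p_edge = numeric(),
                        stringsAsFactors = FALSE)
    if (cfg@mi_edge_rule == "fisher") {
        rc <- fisherEdgeCritical(n, 1 - cfg@mi_null_quantile)
        pref <- .resolve_prefilter(cfg, n, n_bins)
        rmat <- stats::cor(t(v))
        sel <- which(upper.tri(nmi) & nmi >= pref &
                     abs(rmat) >= rc, arr.ind = TRUE)
        edges <- if (nrow(sel)) {
            z <- atanh(pmin(abs(rmat[sel]), 1 - 1e-12)) * sqrt(n - 3)
            data.frame(gene_a = genes[sel[, 1L]], gene_b = genes[sel[, 2L]],
                       weight = nmi[sel], p_edge = 2 * stats::pnorm(-z),
                       stringsAsFactors = FALSE)
        } else empty
        return(new("CoexpressionNetwork", condition = condition,
                   nodes = genes, edges = edges,
                   params = list(n_bins = n_bins, threshold = pref,
                                 rule = "fisher", r_critical = rc,
                                 prefilter = pref, n_samples = n)))
    }
    thr <- .resolve_edge_threshold(cfg, n, n_bins)
    eff <- max(thr, cfg@mi_prefilter)
    cand <- which(upper.tri(nmi) & nmi >= eff, arr.ind = TRUE)
    if (nrow(cand)) {
        pv <- cpp_perm_pvals(bins, as.integer(n_bins),
                             matrix(as.integer(cand), ncol = 2L),
                             as.integer(cfg@n_perm))
        sig <- pv < 0.05
        edges <- data.frame(gene_a = genes[cand[sig, 1L]],
                            gene_b = genes[cand[sig, 2L]],
                            weight = nmi[cand[sig, , drop = FALSE]],
                            p_edge = pv[sig], stringsAsFactors = FALSE)
    } else {
        edges <- empty
    }
    new("CoexpressionNetwork", condition = condition, nodes = genes,
        edges = edges,
        params = list(n_bins = n_bins, threshold = eff, rule = cfg@mi_edge_rule,
                      prefilter = cfg@mi_prefilter, n_samples = n))
}
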