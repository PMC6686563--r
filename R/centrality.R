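#' @include AllClasses.R network.R
NULL

#' Weighted PageRank centrality
#'
#' Power iteration on the weighted undirected graph: the transition
#' probability from a node to a neighbor is proportional to the edge weight;
#' nodes without edges are dangling and redistribute their mass uniformly
#' (teleport-only treatment). Scores sum to 1.
#'
#' @param net A [CoexpressionNetwork-class].
#' @param damping Damping factor in (0, 1) (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 500); non-convergence is an error
#'   carrying the last residual.
#' @return Named numeric vector of centrality scores over the network nodes.
#' @export
pageRank <- function(net, damping = 0.85, tol = 1e-10, max_iter = 500L) {
    stopifnot(damping > 0, damping < 1)
    nodes <- networkNodes(net)
    n <- length(nodes)
    e <- networkEdges(net)
    W <- matrix(0, n, n, dimnames = list(nodes, nodes))
    if (nrow(e)) {
        ia <- match(e$gene_a, nodes)
        ib <- match(e$gene_b, nodes)
        W[cbind(ia, ib)] <- e$weight
        W[cbind(ib, ia)] <- e$weight
    }
    strength <- rowSums(W)
    linked <- strength > 0
    # column-stochastic transition matrix over linked nodes
    P <- matrix(0, n, n)
    if (any(linked))
        P[, linked] <- t(W[linked, , drop = FALSE] / strength[linked])
    p <- rep(1 / n, n)
    for (it in seq_len(max_iter)) {
        dangling <- sum(p[!linked])
        pn <- (1 - damping) / n + damping * (as.vector(P %*% p) + dangling / n)
        delta <- sum(abs(pn - p))
        p <- pn
        if (delta < tol) {
            names(p) <- nodes
            return(p / sum(p))
        }
    }
    stop(sprintf("PageRank did not converge in %d iterations (residual %.3g)",
                 max_iter, delta))
}

#' Remove small components from a co-expression network
#'
#' Drops every edge belonging to a connected component with fewer than
#' `min_size` nodes; the affected genes remain as isolated nodes. Spurious
#' edges between otherwise unconnected genes form tiny components in which
#' a damped random walk gets trapped, inflating those genes' PageRank far
#' above the teleport floor; pruning removes this artifact while leaving
#' genuine co-expression modules intact.
#'
#' @param net A [CoexpressionNetwork-class].
#' @param min_size Minimum component size to keep (default 3).
#' @return The pruned [CoexpressionNetwork-class].
#' @export
pruneComponents <- function(net, min_size = 3L) {
    e <- networkEdges(net)
    if (!nrow(e) || min_size <= 1L) return(net)
    nodes <- unique(c(e$gene_a, e$gene_b))
    parent <- seq_along(nodes)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    ia <- match(e$gene_a, nodes)
    ib <- match(e$gene_b, nodes)
    for (k in seq_len(nrow(e))) {
        ra <- find(ia[k])
        rb <- find(ib[k])
        if (ra != rb) parent[ra] <- rb
    }
    root <- vapply(seq_along(nodes), find, integer(1))
    size <- table(root)
    keep_nodes <- nodes[size[as.character(root)] >= min_size]
    net@edges <- e[e$gene_a %in% keep_nodes, , drop = FALSE]
    net
}

#' Differential PageRank centrality between conditions
#'
#' Per-condition centralities come from the full-cohort networks, each
#' condition at its own sample size with a null-calibrated edge threshold
#' (so both networks carry the same expected spurious-edge count) and
#' small components pruned via [pruneComponents()]. Scores are floored at
#' `1 / (10 * G * G)` and
#' `log_fc_centrality = log2(pr_stroke / pr_control)`.
#'
#' Significance uses an empirical-null studentization in the spirit of
#' large-scale simultaneous testing: among genes connected in at least one
#' condition, the gap distribution is centered at its median (absorbing
#' any systematic offset that differing per-condition edge-recovery rates
#' produce) and scaled by its MAD, giving per-gene z-scores that are
#' referred to the normal distribution and BH-adjusted. Genes isolated in
#' both networks carry no centrality evidence and receive p = 1. With at
#' most a small fraction of truly rewired genes the robust center/scale
#' estimates track the null component; when the data carry no connected
#' genes at all (or a degenerate spread), no gene is called significant.
#'
#' @param study A preprocessed [ExpressionStudy-class] with both conditions.
#' @param cfg A [PipelineConfig-class].
#' @return Data frame with one row per gene: `gene_id`, `pr_control`,
#'   `pr_stroke`, `log_fc_centrality`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
differentialCentrality <- function(study, cfg = pipelineConfig()) {
    cond <- studyConditions(study)
    if (!all(c("stroke", "control") %in% cond))
        stop("both conditions are required")
    withr::with_seed(cfg@seed, {
        genes <- geneIds(study)
        g <- length(genes)
        floor_val <- 1 / (10 * g * g)

        one_condition <- function(condition) {
            net <- pruneComponents(buildNetwork(study, condition, cfg))
            list(pr = pmax(pageRank(net)[genes], floor_val),
                 degree = nodeDegrees(net)[genes])
        }
        st <- one_condition("stroke")
        ct <- one_condition("control")
        pr_s <- st$pr / sum(st$pr)
        pr_c <- ct$pr / sum(ct$pr)

        gap <- log2(pr_s / pr_c)
        connected <- st$degree > 0 | ct$degree > 0
        pv <- rep(1, g)
        if (sum(connected) >= 10L) {
            center <- stats::median(gap[connected])
            scale <- stats::mad(gap[connected])
            if (scale > 1e-8) {
                z <- (gap[connected] - center) / scale
                pv[connected] <- 2 * stats::pnorm(-abs(z))
            }
        }
        padj <- benjaminiHochberg(pv)
        data.frame(gene_id = genes, pr_control = unname(pr_c),
                   pr_stroke = unname(pr_s),
                   log_fc_centrality = unname(gap),
                   p_value = pv, p_adjusted = padj,
                   significant = padj < cfg@fdr_alpha,
                   stringsAsFactors = FALSE)
    })
}

#' Power-law fit of the degree distribution
#'
#' Fits `p(k) ~ k^(-alpha)` by least squares of log frequency on log degree
#' over the observed nonzero-count degrees, then reports the Spearman rank
#' correlation (and p-value) between observed and fitted frequencies as a
#' concordance diagnostic.
#'
#' @param net A [CoexpressionNetwork-class] whose nodes span at least 5
#'   distinct positive degrees.
#' @return List with `condition`, `alpha`, `rho_spearman`, `p_value`, and
#'   the underlying `degree`/`observed`/`predicted` vectors.
#' @export
degreePowerlawFit <- function(net) {
    deg <- nodeDegrees(net)
    deg <- deg[deg > 0]
    tab <- table(deg)
    k <- as.numeric(names(tab))
    if (length(k) < 5L)
        stop("need at least 5 distinct positive degrees for a power-law fit")
    obs <- as.numeric(tab) / sum(tab)
    fit <- stats::lm(log(obs) ~ log(k))
    alpha <- -unname(stats::coef(fit)[2L])
    pred <- exp(stats::fitted(fit))
    ct <- suppressWarnings(stats::cor.test(obs, pred, method = "spearman",
                                           exact = FALSE))
    list(condition = net@condition, alpha = alpha,
         rho_spearman = unname(ct$estimate), p_value = ct$p.value,
         degree = k, observed = obs, predicted = unname(pred))
}
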