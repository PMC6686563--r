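# Independent reference implementations used as oracles. These deliberately
# use naive algorithms (explicit loops, full matrices) so that agreement
# with the package's optimized paths is informative.

# Brute-force KNN imputation: full distance matrix, explicit sort, same
# contract as knnImpute (neighbors observed at the target sample, distances
# over co-observed samples, 1/d weights, zero-distance neighbors averaged).
oracle_knn_impute <- function(v, k) {
    out <- v
    mask <- is.na(v)
    for (g in seq_len(nrow(v))) {
        for (s in seq_len(ncol(v))) {
            if (!mask[g, s]) next
            d <- rep(NA_real_, nrow(v))
            for (h in seq_len(nrow(v))) {
                if (h == g || mask[h, s]) next
                co <- !mask[g, ] & !mask[h, ]
                if (!any(co)) next
                d[h] <- sqrt(sum((v[g, co] - v[h, co])^2))
            }
            elig <- which(!is.na(d))
            if (!length(elig)) {
                out[g, s] <- mean(v[g, ], na.rm = TRUE)
                next
            }
            nb <- elig[order(d[elig])][seq_len(min(k, length(elig)))]
            dn <- d[nb]
            out[g, s] <- if (any(dn == 0)) mean(v[nb[dn == 0], s])
                         else sum(v[nb, s] / dn) / sum(1 / dn)
        }
    }
    out
}

# Reference BH step-up, written from the definition.
oracle_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    out
}

# Dense PageRank by direct linear solve of the stationarity equations:
# p = (1-d)/n * 1 + d * (M p + dangling/n), with M the column-stochastic
# weighted transition matrix. Solved exactly, no power iteration.
oracle_pagerank <- function(nodes, edges, damping = 0.85) {
    n <- length(nodes)
    W <- matrix(0, n, n, dimnames = list(nodes, nodes))
    if (nrow(edges)) {
        for (e in seq_len(nrow(edges))) {
            i <- match(edges$gene_a[e], nodes)
            j <- match(edges$gene_b[e], nodes)
            W[i, j] <- W[i, j] + edges$weight[e]
            W[j, i] <- W[j, i] + edges$weight[e]
        }
    }
    strength <- rowSums(W)
    M <- matrix(0, n, n)
    for (j in seq_len(n))
        if (strength[j] > 0) M[, j] <- W[j, ] / strength[j]
        else M[, j] <- 1 / n  # dangling: uniform
    A <- diag(n) - damping * M
    p <- solve(A, rep((1 - damping) / n, n))
    p <- p / sum(p)
    names(p) <- nodes
    p
}

# Exhaustive MI of a 2x2 joint table in nats.
oracle_mi_2x2 <- function(tab) {
    p <- tab / sum(tab)
    px <- rowSums(p)
    py <- colSums(p)
    s <- 0
    for (i in 1:2) for (j in 1:2)
        if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    s
}

# Brute-force LOF from the definition.
oracle_lof <- function(x, k) {
    n <- nrow(x)
    d <- as.matrix(dist(x))
    diag(d) <- Inf
    kdist <- numeric(n)
    nbrs <- vector("list", n)
    for (i in seq_len(n)) {
        srt <- sort(d[i, ])
        kdist[i] <- srt[k]
        nbrs[[i]] <- which(d[i, ] <= kdist[i] + 1e-12)
    }
    lrd <- vapply(seq_len(n), function(i) {
        1 / mean(pmax(kdist[nbrs[[i]]], d[i, nbrs[[i]]]))
    }, numeric(1))
    vapply(seq_len(n), function(i) {
        r <- lrd[nbrs[[i]]] / lrd[i]
        r[is.nan(r)] <- 1
        mean(r)
    }, numeric(1))
}

# BFS hop distances from a seed over a thresholded edge list.
oracle_hops <- function(nodes, edges, seed_gene, min_weight) {
    e <- edges[edges$weight >= min_weight, , drop = FALSE]
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[seed_gene] <- 0
    repeat {
        changed <- FALSE
        for (r in seq_len(nrow(e))) {
            a <- e$gene_a[r]; b <- e$gene_b[r]
            if (dist[a] + 1 < dist[b]) { dist[b] <- dist[a] + 1; changed <- TRUE }
            if (dist[b] + 1 < dist[a]) { dist[a] <- dist[b] + 1; changed <- TRUE }
        }
        if (!changed) break
    }
    dist
}

# Small, fast study fixtures -----------------------------------------------

tiny_study <- function(n_genes = 6, n_samples = 10, seed = 1,
                       missing = 0) {
    set.seed(seed)
    v <- matrix(rnorm(n_genes * n_samples, mean = 6), n_genes, n_samples,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    if (missing > 0) v[sample(length(v), missing)] <- NA
    md <- data.frame(sample_id = colnames(v),
                     condition = rep(c("stroke", "control"),
                                     length.out = n_samples),
                     sample_type = rep(c("whole_blood", "whole_blood",
                                         "pbmc"), length.out = n_samples),
                     batch = "b1", stringsAsFactors = FALSE)
    ExpressionStudy(v, md)
}

# mid-size study config: module layout scaled to fit smaller gene counts
mid_config <- function(n_genes = 150L, ...) {
    args <- list(n_genes = n_genes, n_modules = 3L, module_size = 25L,
                 n_de_genes = 20L, n_hub_genes = 3L)
    over <- list(...)
    args[names(over)] <- over
    do.call(syntheticConfig, args)
}

small_synth <- function(seed = 1, ...) {
    generateStudy(syntheticConfig(n_genes = 80L, n_stroke = 24L,
                                  n_control = 20L, n_modules = 2L,
                                  module_size = 15L, n_de_genes = 10L,
                                  n_hub_genes = 2L, n_outliers = 0L,
                                  missing_rate = 0, seed = seed, ...))
}
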