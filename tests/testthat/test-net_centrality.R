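make_net <- function(nodes, edges, condition = "stroke") {
    new("CoexpressionNetwork", condition = condition, nodes = nodes,
        edges = edges, params = list(threshold = 0))
}

edge_df <- function(a, b, w) {
    data.frame(gene_a = a, gene_b = b, weight = w,
               p_edge = rep(NA_real_, length(a)), stringsAsFactors = FALSE)
}

test_that("pagerank symmetry, teleport-only, and conservation", {
    # complete 3-node graph with equal weights: exact thirds
    net <- make_net(c("a", "b", "c"),
                    edge_df(c("a", "a", "b"), c("b", "c", "c"), rep(0.5, 3)))
    pr <- pageRank(net)
    expect_equal(unname(pr), rep(1 / 3, 3), tolerance = 1e-10)
    # empty network: uniform teleport scores
    pr0 <- pageRank(make_net(c("a", "b", "c", "d"),
                             edge_df(character(), character(), numeric())))
    expect_equal(unname(pr0), rep(0.25, 4), tolerance = 1e-12)
    expect_equal(sum(pr), 1, tolerance = 1e-8)
})

test_that("pagerank matches the dense linear-solve oracle on random graphs", {
    set.seed(20)
    for (i in 1:12) {
        n <- sample(5:50, 1)
        nodes <- sprintf("n%02d", seq_len(n))
        ne <- sample(0:(n * 2), 1)
        pairs <- unique(t(replicate(max(ne, 1), sort(sample(n, 2)))))
        edges <- edge_df(nodes[pairs[, 1]], nodes[pairs[, 2]],
                         runif(nrow(pairs), 0.3, 1))
        if (ne == 0) edges <- edges[0, ]
        net <- make_net(nodes, edges)
        pr <- pageRank(net)
        expect_equal(pr, oracle_pagerank(nodes, edges), tolerance = 1e-8)
        expect_equal(sum(pr), 1, tolerance = 1e-8)
    }
})

test_that("pagerank agrees with igraph's implementation", {
    skip_if_not_installed("igraph")
    set.seed(21)
    nodes <- sprintf("n%02d", 1:30)
    pairs <- unique(t(replicate(60, sort(sample(30, 2)))))
    edges <- edge_df(nodes[pairs[, 1]], nodes[pairs[, 2]],
                     runif(nrow(pairs), 0.3, 1))
    net <- make_net(nodes, edges)
    gr <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                        vertices = nodes)
    ig <- igraph::page_rank(gr, weights = edges$weight, damping = 0.85)
    expect_equal(unname(pageRank(net)[nodes]), unname(ig$vector[nodes]),
                 tolerance = 1e-6)
})

test_that("a 5-node star concentrates centrality in the hub", {
    nodes <- c("hub", paste0("leaf", 1:4))
    edges <- edge_df(rep("hub", 4), paste0("leaf", 1:4), rep(0.8, 4))
    pr <- pageRank(make_net(nodes, edges), damping = 0.85)
    expect_equal(pr, oracle_pagerank(nodes, edges), tolerance = 1e-10)
    expect_gt(pr["hub"], max(pr[paste0("leaf", 1:4)]))
})

test_that("small components are pruned and genuine modules kept", {
    nodes <- sprintf("n%02d", 1:8)
    edges <- rbind(
        edge_df(c("n01", "n01", "n02"), c("n02", "n03", "n03"), rep(0.9, 3)),
        edge_df("n04", "n05", 0.9))  # an isolated dyad
    pruned <- pruneComponents(make_net(nodes, edges), min_size = 3L)
    e <- networkEdges(pruned)
    expect_equal(nrow(e), 3L)
    expect_false("n04" %in% c(e$gene_a, e$gene_b))
    expect_setequal(networkNodes(pruned), nodes)
})

test_that("label swap negates every centrality log fold change", {
    out <- small_synth(seed = 51)
    study <- out$study
    cfg <- pipelineConfig(seed = 51)
    cent <- differentialCentrality(study, cfg)
    md_sw <- data.frame(sample_id = sampleIds(study),
                        condition = ifelse(studyConditions(study) == "stroke",
                                           "control", "stroke"),
                        sample_type = unname(sampleTypes(study)),
                        batch = unname(sampleBatches(study)))
    swapped <- ExpressionStudy(exprValues(study), md_sw)
    cent_sw <- differentialCentrality(swapped, cfg)
    expect_equal(cent$log_fc_centrality, -cent_sw$log_fc_centrality,
                 tolerance = 1e-10)
})

test_that("duplicated-cohort null gives zero log fold changes and no calls", {
    # identical stroke/control submatrices: the two networks coincide
    set.seed(22)
    base <- matrix(rnorm(40 * 20, 6), 40, 20)
    v <- cbind(base, base)
    dimnames(v) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:40))
    md <- data.frame(sample_id = colnames(v),
                     condition = rep(c("stroke", "control"), each = 20),
                     sample_type = "whole_blood", batch = "b")
    cent <- differentialCentrality(ExpressionStudy(v, md),
                                   pipelineConfig(seed = 1))
    expect_true(all(abs(cent$log_fc_centrality) < 1e-10))
    expect_false(any(cent$significant))
    expect_equal(sum(cent$pr_stroke), 1, tolerance = 1e-8)
    expect_equal(sum(cent$pr_control), 1, tolerance = 1e-8)
    expect_equal(cent$log_fc_centrality,
                 log2(cent$pr_stroke / cent$pr_control), tolerance = 1e-12)
})

test_that("planted hubs dominate the significant centrality shifts", {
    passes <- 0L
    for (seed in 1:10) {
        out <- generateStudy(syntheticConfig(seed = seed))
        cfg <- pipelineConfig(seed = seed)
        pre <- suppressWarnings(preprocessStudy(out$study, cfg))
        cent <- differentialCentrality(pre$study, cfg)
        sig <- cent[cent$significant, ]
        sig <- sig[order(-abs(sig$log_fc_centrality)), ]
        top20 <- head(sig$gene_id, 20)
        gap <- plantedCentralityGap(out$truth)
        obs <- sign(cent$log_fc_centrality[match(out$truth@hub_genes,
                                                 cent$gene_id)])
        nhub <- sum(out$truth@hub_genes %in% top20 & obs == gap, na.rm = TRUE)
        passes <- passes + (nhub >= 5)
    }
    expect_gte(passes, 8L)
})

test_that("power-law diagnostics behave on star unions and scale-free graphs", {
    # a union of stars of distinct sizes: many degree-1 leaves plus one hub
    # per size; the fit returns finite diagnostics without judgment
    sizes <- c(3, 5, 9, 17, 33)
    nodes <- character(); ea <- character(); eb <- character()
    for (s in sizes) {
        hub <- sprintf("h%02d", s)
        leaves <- sprintf("l%02d_%02d", s, seq_len(s - 1))
        nodes <- c(nodes, hub, leaves)
        ea <- c(ea, rep(hub, s - 1)); eb <- c(eb, leaves)
    }
    fit0 <- degreePowerlawFit(make_net(nodes, edge_df(ea, eb, 0.9)))
    expect_true(is.finite(fit0$alpha))
    expect_true(is.finite(fit0$rho_spearman))
    # scale-free graph from preferential attachment
    set.seed(23)
    n <- 500
    targets <- c(1, 2)
    from <- c(2)
    to <- c(1)
    deg <- c(1, 1)
    for (v in 3:n) {
        pick <- sample(v - 1, 1, prob = deg[1:(v - 1)])
        from <- c(from, v); to <- c(to, pick)
        deg[pick] <- deg[pick] + 1
        deg <- c(deg, 1)
    }
    nodes <- sprintf("n%03d", 1:n)
    edges <- edge_df(nodes[from], nodes[to], 0.9)
    fit <- degreePowerlawFit(make_net(nodes, edges))
    expect_gt(fit$alpha, 0)
    expect_gt(fit$rho_spearman, 0.5)
    expect_lt(fit$p_value, 0.001)
    # degenerate degree sequence: error
    reg <- make_net(c("a", "b"), edge_df("a", "b", 0.5))
    expect_error(degreePowerlawFit(reg), "distinct positive degrees")
})
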