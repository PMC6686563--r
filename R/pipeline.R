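#' @include AllClasses.R preprocess.R diffexp.R network.R centrality.R gasvm.R
NULL

#' The six-gene network-central stroke signature
#'
#' Published network-central predictor genes used as the reference signature
#' for the packaged miRNA:target table.
#'
#' @return Character vector of six gene symbols.
#' @export
strokeSignatureGenes <- function() {
    c("ID3", "MBTPS1", "NOG", "SFXN2", "BMX", "SLC22A1")
}

#' Neighborhood of a gene in a co-expression network
#'
#' Breadth-first expansion over edges with weight at or above `min_weight`,
#' up to `max_distance` hops; the seed gene itself is excluded from the
#' returned set.
#'
#' @param net A [CoexpressionNetwork-class].
#' @param gene Seed gene id (must be a node).
#' @param max_distance Maximum hop count (Hamming distance), >= 1.
#' @param min_weight Minimum edge weight considered (default 0: all edges).
#' @return Character vector of neighbor gene ids (possibly empty).
#' @export
neighborhood <- function(net, gene, max_distance = 1L, min_weight = 0) {
    nodes <- networkNodes(net)
    if (!gene %in% nodes) stop("unknown gene: ", gene)
    stopifnot(max_distance >= 1L)
    e <- networkEdges(net)
    e <- e[e$weight >= min_weight, , drop = FALSE]
    adj <- split(c(e$gene_b, e$gene_a), c(e$gene_a, e$gene_b))
    seen <- gene
    frontier <- gene
    for (d in seq_len(max_distance)) {
        nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
        if (!length(nxt)) break
        seen <- c(seen, nxt)
        frontier <- nxt
    }
    setdiff(seen, gene)
}

#' Filter a miRNA:target table against a gene signature
#'
#' Keeps (miRNA, gene) records whose target gene belongs to the signature
#' and whose confidence score is at least `min_confidence`, then returns the
#' miRNAs with at least `min_targets` qualifying targets, sorted by
#' decreasing target count and then by id.
#'
#' @param records Data frame from [readMirnaTargets()].
#' @param signature Gene ids of the signature.
#' @param min_confidence Confidence threshold (default 0.3, the target
#'   predictor's default cutoff).
#' @param min_targets Minimum qualifying targets per miRNA (default 2).
#' @return Data frame with `mirna_id`, `n_targets` and `targets`
#'   (comma-separated, decreasing confidence). Zero rows when nothing
#'   qualifies.
#' @export
filterMirnaTargets <- function(records, signature, min_confidence = 0.3,
                               min_targets = 2L) {
    stopifnot(min_targets >= 1L)
    keep <- records$target_gene %in% signature &
        records$confidence >= min_confidence
    rec <- records[keep, , drop = FALSE]
    if (!nrow(rec))
        return(data.frame(mirna_id = character(), n_targets = integer(),
                          targets = character(), stringsAsFactors = FALSE))
    rec <- rec[order(rec$mirna_id, -rec$confidence), , drop = FALSE]
    by_mirna <- split(rec$target_gene, rec$mirna_id)
    by_mirna <- by_mirna[lengths(by_mirna) >= min_targets]
    out <- data.frame(mirna_id = names(by_mirna),
                      n_targets = unname(lengths(by_mirna)),
                      targets = vapply(by_mirna, paste, character(1),
                                       collapse = ","),
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(-out$n_targets, out$mirna_id), , drop = FALSE]
}

#' Run the full biomarker-discovery pipeline
#'
#' Preprocess (QC gate) -> differential expression -> per-condition
#' co-expression networks -> differential PageRank centrality -> GA-SVM
#' signature selection over the centrality-significant genes -> report.
#' Aborts after QC when the dataset fails the validity gate. When `out_dir`
#' is given, every intermediate table is written there as TSV.
#'
#' @param study An [ExpressionStudy-class].
#' @param cfg A [PipelineConfig-class]; `cfg@seed` drives every randomized
#'   stage, so equal config and inputs give identical reports.
#' @param out_dir Optional output directory for artifacts.
#' @param pop_size,n_generations GA size (defaults 50 and 100).
#' @param housekeeping_genes Normalizer candidates for preprocessing.
#' @return A [RunReport-class].
#' @export
runPipeline <- function(study, cfg = pipelineConfig(), out_dir = NULL,
                        pop_size = 50L, n_generations = 100L,
                        housekeeping_genes = .HOUSEKEEPING_PANEL) {
    artifacts <- character()
    emit <- function(x, name, allow_empty = FALSE) {
        if (is.null(out_dir)) return()
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        p <- file.path(out_dir, name)
        writeTable(x, p, allow_empty = allow_empty)
        artifacts[[name]] <<- p
    }
    pre <- preprocessStudy(study, cfg, housekeeping_genes)
    qc <- pre$qc
    if (!qc@dataset_valid) {
        emit(data.frame(outlier_sample = qc@outlier_samples), "qc_outliers.tsv",
             allow_empty = TRUE)
        stop("preprocess: dataset failed the QC validity gate (",
             sprintf("%.1f%%", 100 * qc@outlier_fraction),
             " samples flagged as outliers)")
    }
    clean <- pre$study
    emit(clean, "expression_clean.tsv")

    de <- runDiffexp(clean, cfg)
    emit(de, "differential_expression.tsv")

    cent <- differentialCentrality(clean, cfg)
    emit(cent, "differential_centrality.tsv")

    net_s <- withr::with_seed(cfg@seed, buildNetwork(clean, "stroke", cfg))
    net_c <- withr::with_seed(cfg@seed, buildNetwork(clean, "control", cfg))
    emit(networkEdges(net_s), "network_stroke_edges.tsv", allow_empty = TRUE)
    emit(networkEdges(net_c), "network_control_edges.tsv", allow_empty = TRUE)
    fits <- list(stroke = tryCatch(degreePowerlawFit(net_s),
                                   error = function(e) NULL),
                 control = tryCatch(degreePowerlawFit(net_c),
                                    error = function(e) NULL))

    candidates <- cent$gene_id[cent$significant]
    if (length(candidates) < 2L) {
        # degenerate significant set: fall back to the strongest centrality
        # shifts so selection still has material to work with
        ord <- order(-abs(cent$log_fc_centrality))
        candidates <- cent$gene_id[ord][seq_len(min(10L, nrow(cent)))]
    }
    sel <- gaSearch(clean[candidates, ], cfg, pop_size = pop_size,
                    n_generations = n_generations)
    emit(data.frame(gene_id = sel$genes), "signature.tsv", allow_empty = TRUE)
    emit(sel$history, "ga_history.tsv")

    new("RunReport", qc = qc, de_table = de, centrality_table = cent,
        degree_fits = fits, signature = sel$genes,
        signature_eval = c(sel$eval, list(fitness = sel$fitness)),
        fitness = sel$fitness, config = cfg,
        artifacts = if (length(artifacts)) unlist(artifacts) else character())
}
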