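#' @include AllGenerics.R
#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
NULL

.CONDITIONS <- c("stroke", "control")
.SAMPLE_TYPES <- c("whole_blood", "pbmc")

#' ExpressionStudy: a case/control expression study
#'
#' A genes-by-samples matrix of log2-scale expression values together with
#' per-sample annotation, stored as a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with one assay (`"exprs"`). Missing measurements are `NA` in the assay.
#' Column data carries `condition` (`"stroke"`/`"control"`), `sample_type`
#' (`"whole_blood"`/`"pbmc"`) and `batch`.
#'
#' @slot .. see [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class].
#' @seealso [ExpressionStudy()], [readExpressionStudy()], [generateStudy()]
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    gid <- rownames(object); sid <- colnames(object)
    if (is.null(gid) || anyDuplicated(gid))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(sid) || anyDuplicated(sid))
        msg <- c(msg, "sample ids must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    need <- c("condition", "sample_type", "batch")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("missing sample metadata column(s):",
                            paste(miss, collapse = ", ")))
    if ("condition" %in% colnames(cd) &&
        !all(cd$condition %in% .CONDITIONS))
        msg <- c(msg, "condition must be 'stroke' or 'control'")
    if ("sample_type" %in% colnames(cd) &&
        !all(cd$sample_type %in% .SAMPLE_TYPES))
        msg <- c(msg, "sample_type must be 'whole_blood' or 'pbmc'")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   dimnames. `NA` marks missing measurements.
#' @param metadata Data frame with columns `sample_id`, `condition`,
#'   `sample_type`, `batch`; must cover every column of `values`.
#' @return A validated [ExpressionStudy-class] object (samples ordered as in
#'   `values`).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1", "s2"),
#'                  condition = c("stroke", "control"),
#'                  sample_type = "whole_blood", batch = "b1")
#' ExpressionStudy(m, md)
#' @export
ExpressionStudy <- function(values, metadata) {
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have gene and sample dimnames")
    if (anyDuplicated(rownames(values)))
        stop("duplicate gene ids in expression matrix")
    if (anyDuplicated(colnames(values)))
        stop("duplicate sample ids in expression matrix")
    metadata <- as.data.frame(metadata)
    if (anyDuplicated(metadata$sample_id))
        stop("duplicate sample ids in metadata")
    absent <- setdiff(colnames(values), metadata$sample_id)
    if (length(absent))
        stop("samples present in the matrix but absent from metadata: ",
             paste(absent, collapse = ", "))
    metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
    if (any(is.na(metadata$condition)) || any(!nzchar(metadata$condition)))
        stop("every sample needs a non-empty condition")
    if (any(is.na(metadata$sample_type)) || any(!nzchar(metadata$sample_type)))
        stop("every sample needs a non-empty sample_type")
    if (is.null(metadata$batch)) metadata$batch <- "b1"
    cd <- S4Vectors::DataFrame(condition = as.character(metadata$condition),
                               sample_type = as.character(metadata$sample_type),
                               batch = as.character(metadata$batch),
                               row.names = colnames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd)
    new("ExpressionStudy", se)
}

#' @rdname study-accessors
setMethod("exprValues", "ExpressionStudy", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname study-accessors
setMethod("missingMask", "ExpressionStudy", function(x)
    is.na(SummarizedExperiment::assay(x, "exprs")))

#' @rdname study-accessors
setMethod("geneIds", "ExpressionStudy", function(x) rownames(x))

#' @rdname study-accessors
setMethod("sampleIds", "ExpressionStudy", function(x) colnames(x))

.colfield <- function(x, f) {
    v <- SummarizedExperiment::colData(x)[[f]]
    names(v) <- colnames(x)
    v
}

#' @rdname study-accessors
setMethod("studyConditions", "ExpressionStudy", function(x) .colfield(x, "condition"))

#' @rdname study-accessors
setMethod("sampleTypes", "ExpressionStudy", function(x) .colfield(x, "sample_type"))

#' @rdname study-accessors
setMethod("sampleBatches", "ExpressionStudy", function(x) .colfield(x, "batch"))

setMethod("show", "ExpressionStudy", function(object) {
    cond <- table(studyConditions(object))
    cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  conditions:", paste(names(cond), cond, sep = "=", collapse = ", "), "\n")
    cat("  missing cells:", sum(missingMask(object)), "\n")
})

#' CoexpressionNetwork: a per-condition weighted co-expression graph
#'
#' Undirected weighted graph over genes for one condition. Edge weights are
#' normalized mutual information values of the two genes' expression profiles;
#' only edges that passed the configured significance rule are present.
#' Isolated genes remain as nodes.
#'
#' @slot condition Condition the network was built from.
#' @slot nodes Character vector of gene ids (all genes, including isolated).
#' @slot edges Data frame `gene_a`, `gene_b`, `weight`, `p_edge` (edge-rule
#'   p-value: Fisher-z or permutation, `NA` where not computed).
#' @slot params List of build parameters (`n_bins`, `threshold`, `rule`,
#'   `prefilter`, `n_samples`).
#' @seealso [buildNetwork()], [neighborhood()], [pageRank()]
#' @export
setClass("CoexpressionNetwork",
         representation(condition = "character", nodes = "character",
                        edges = "data.frame", params = "list"))

setValidity("CoexpressionNetwork", function(object) {
    msg <- character()
    e <- object@edges
    need <- c("gene_a", "gene_b", "weight")
    if (!all(need %in% colnames(e)))
        return("edges must have columns gene_a, gene_b, weight")
    if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
    if (nrow(e)) {
        if (any(e$gene_a == e$gene_b)) msg <- c(msg, "self-loops are not allowed")
        key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
        if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edges")
        if (!all(c(e$gene_a, e$gene_b) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be nodes")
        if (any(e$weight < 0 | e$weight > 1))
            msg <- c(msg, "edge weights must lie in [0, 1]")
        thr <- object@params$threshold
        if (!is.null(thr) && any(e$weight < thr - 1e-12))
            msg <- c(msg, "edge weights below the build threshold")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname network-accessors
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)

#' @rdname network-accessors
setMethod("networkNodes", "CoexpressionNetwork", function(x) x@nodes)

#' @rdname network-accessors
setMethod("nodeDegrees", "CoexpressionNetwork", function(x) {
    d <- integer(length(x@nodes))
    names(d) <- x@nodes
    if (nrow(x@edges)) {
        tab <- table(c(x@edges$gene_a, x@edges$gene_b))
        d[names(tab)] <- as.integer(tab)
    }
    d
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork (", object@condition, "): ",
        length(object@nodes), " nodes, ", nrow(object@edges), " edges\n",
        sep = "")
    if (!is.null(object@params$threshold))
        cat("  edge rule:", object@params$rule, " threshold:",
            format(object@params$threshold, digits = 3), "\n")
})

#' QCReport: quality-control summary for one study
#'
#' @slot removed_genes Genes dropped by the missingness filter.
#' @slot imputed_cells Number of cells filled by KNN imputation.
#' @slot normalization_strategy `"median_per_sample"` or `"housekeeping"`.
#' @slot outlier_samples Samples flagged by the PCA+LOF screen.
#' @slot outlier_fraction Fraction of samples flagged.
#' @slot dataset_valid `TRUE` iff the flagged fraction is below the validity
#'   threshold.
#' @seealso [preprocessStudy()], [detectOutliers()]
#' @export
setClass("QCReport",
         representation(removed_genes = "character", imputed_cells = "integer",
                        normalization_strategy = "character",
                        outlier_samples = "character",
                        outlier_fraction = "numeric", dataset_valid = "logical"))

setValidity("QCReport", function(object) {
    if (!object@normalization_strategy %in% c("median_per_sample", "housekeeping"))
        return("unknown normalization strategy")
    TRUE
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport: removed", length(object@removed_genes), "genes;",
        object@imputed_cells, "cells imputed;",
        "normalization:", object@normalization_strategy, "\n")
    cat("  outliers:", length(object@outlier_samples),
        sprintf("(%.1f%%);", 100 * object@outlier_fraction),
        "dataset", if (object@dataset_valid) "VALID" else "INVALID", "\n")
})

#' PipelineConfig: tunable parameters of the analysis pipeline
#'
#' Created by [pipelineConfig()]; see that constructor for the meaning and
#' defaults of every field.
#'
#' @seealso [pipelineConfig()], [readPipelineConfig()]
#' @export
setClass("PipelineConfig",
         representation(missing_gene_fraction = "numeric", knn_k = "integer",
                        pca_variance = "numeric",
                        outlier_validity_fraction = "numeric",
                        housekeeping_fc_threshold = "numeric",
                        mi_prefilter = "numeric", mi_edge_threshold = "numeric",
                        mi_edge_rule = "character", mi_null_quantile = "numeric",
                        mi_bins = "integer", n_perm = "integer",
                        fdr_alpha = "numeric", ga_weights = "numeric",
                        cv_folds = "integer", lof_neighbors = "integer",
                        lof_threshold = "numeric", seed = "integer"))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    frac <- c(missing_gene_fraction = object@missing_gene_fraction,
              pca_variance = object@pca_variance,
              outlier_validity_fraction = object@outlier_validity_fraction,
              mi_null_quantile = object@mi_null_quantile,
              fdr_alpha = object@fdr_alpha)
    bad <- names(frac)[frac < 0 | frac > 1]
    if (length(bad))
        msg <- c(msg, paste("fraction fields outside [0,1]:",
                            paste(bad, collapse = ", ")))
    if (object@mi_prefilter >= object@mi_edge_threshold)
        msg <- c(msg, "mi_prefilter must be < mi_edge_threshold")
    if (object@cv_folds < 2L) msg <- c(msg, "cv_folds must be >= 2")
    if (!object@mi_edge_rule %in% c("fisher", "fixed", "calibrated"))
        msg <- c(msg, "mi_edge_rule must be 'fisher', 'fixed' or 'calibrated'")
    if (length(object@ga_weights) != 4L)
        msg <- c(msg, "ga_weights must have length 4")
    if (object@knn_k < 1L) msg <- c(msg, "knn_k must be >= 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig: seed", object@seed, "\n")
    cat("  QC: missing<", object@missing_gene_fraction, ", K=", object@knn_k,
        ", PCA ", object@pca_variance, ", validity<",
        object@outlier_validity_fraction, "\n", sep = "")
    cat("  MI: prefilter", object@mi_prefilter, "edge",
        object@mi_edge_threshold, paste0("(", object@mi_edge_rule, ")"), "\n")
    cat("  FDR alpha", object@fdr_alpha, "; GA weights",
        paste(object@ga_weights, collapse = "/"), "; folds",
        object@cv_folds, "\n")
})

#' SyntheticConfig: parameters of the synthetic study generator
#'
#' Created by [syntheticConfig()]; see that constructor for field meanings
#' and defaults.
#'
#' @seealso [syntheticConfig()], [generateStudy()]
#' @export
setClass("SyntheticConfig",
         representation(n_genes = "integer", n_stroke = "integer",
                        n_control = "integer", n_modules = "integer",
                        module_size = "integer", n_de_genes = "integer",
                        de_effect = "numeric", de_shared_loading = "numeric",
                        hub_effect = "numeric", n_hub_genes = "integer",
                        hub_loading_high = "numeric", hub_loading_low = "numeric",
                        member_loading = "numeric", noise_sd = "numeric",
                        missing_rate = "numeric", n_outliers = "integer",
                        outlier_shift_sd = "numeric",
                        sample_type_fraction = "numeric",
                        covariate_effect = "numeric",
                        covariate_gene_fraction = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@n_modules * object@module_size > object@n_genes)
        msg <- c(msg, "n_modules * module_size must be <= n_genes")
    if (object@n_de_genes + object@n_hub_genes > object@n_genes)
        msg <- c(msg, "n_de_genes + n_hub_genes must be <= n_genes")
    if (object@n_hub_genes > object@n_modules * object@module_size)
        msg <- c(msg, "hub genes must fit inside modules")
    if (object@n_de_genes > object@n_genes - object@n_modules * object@module_size)
        msg <- c(msg, "DE genes are drawn outside modules; not enough genes")
    if (object@missing_rate < 0 || object@missing_rate >= 0.5)
        msg <- c(msg, "missing_rate must be in [0, 0.5)")
    if (object@n_outliers > object@n_stroke + object@n_control)
        msg <- c(msg, "more outliers than samples")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@n_genes, "genes;",
        object@n_stroke, "stroke +", object@n_control, "control samples\n")
    cat("  planted:", object@n_de_genes, "DE (effect",
        object@de_effect, "log2),", object@n_hub_genes, "rewired hubs,",
        object@n_outliers, "outliers; missing rate", object@missing_rate, "\n")
})

#' SyntheticTruth: ground truth of a generated study
#'
#' @slot de_genes Gene ids with a planted condition mean shift.
#' @slot de_sign Named vector, +1/-1: direction of the planted shift
#'   (stroke minus control) per DE gene.
#' @slot hub_genes Gene ids with planted condition-specific module-loading
#'   rewiring.
#' @slot outlier_samples Sample ids perturbed into outliers.
#' @slot module_assignment Data frame `gene_id`, `module`, `loading_stroke`,
#'   `loading_control` for all module member genes.
#' @seealso [generateStudy()], [plantedCentralityGap()]
#' @export
setClass("SyntheticTruth",
         representation(de_genes = "character", de_sign = "numeric",
                        hub_genes = "character", outlier_samples = "character",
                        module_assignment = "data.frame"))

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@de_genes), "DE genes,",
        length(object@hub_genes), "hub genes,",
        length(object@outlier_samples), "outlier samples\n")
})

#' RunReport: artifacts of one end-to-end pipeline run
#'
#' @slot qc The [QCReport-class] of the preprocessing stage.
#' @slot de_table Differential-expression table (one row per gene).
#' @slot centrality_table Differential-centrality table (one row per gene).
#' @slot degree_fits Per-condition power-law degree diagnostics.
#' @slot signature Selected gene signature.
#' @slot signature_eval Cross-validated evaluation of the signature (list).
#' @slot fitness Fitness components of the selected solution (list).
#' @slot config The [PipelineConfig-class] snapshot used for the run.
#' @slot artifacts Named character vector of written file paths.
#' @seealso [runPipeline()]
#' @export
setClass("RunReport",
         representation(qc = "QCReport", de_table = "data.frame",
                        centrality_table = "data.frame", degree_fits = "list",
                        signature = "character", signature_eval = "list",
                        fitness = "list", config = "PipelineConfig",
                        artifacts = "character"))

setMethod("show", "RunReport", function(object) {
    cat("RunReport\n")
    show(object@qc)
    cat("  DE-significant genes:", sum(object@de_table$significant), "\n")
    cat("  centrality-significant genes:",
        sum(object@centrality_table$significant), "\n")
    cat("  signature (", length(object@signature), " genes): ",
        paste(object@signature, collapse = ", "), "\n", sep = "")
    if (length(object@signature_eval))
        cat(sprintf("  signature CV accuracy: %.3f\n",
                    object@signature_eval$accuracy))
})
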