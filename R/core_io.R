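#' @include AllClasses.R
NULL

# Markers treated as missing in expression matrices (case-insensitive),
# besides the empty string: GEO series-matrix dialects vary.
.MISSING_MARKERS <- c("", "na", "nan", "null")

#' Read an expression study from TSV files
#'
#' The matrix file is tab-separated with a `gene_id` first column and sample
#' ids in the header; the metadata file has columns `sample_id`, `condition`,
#' `sample_type`, `batch`. Cells equal to the empty string, `NA`, `NaN` or
#' `NULL` (any case) are recorded as missing; any other non-numeric cell is a
#' parse error reported with its row/column coordinates.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @param transpose If `TRUE`, the matrix file is samples-in-rows and is
#'   transposed after reading.
#' @return A validated [ExpressionStudy-class].
#' @export
readExpressionStudy <- function(matrix_path, metadata_path, transpose = FALSE) {
    raw <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                             check.names = FALSE, colClasses = "character",
                             quote = "", comment.char = "")
    if (ncol(raw) < 2L)
        stop("expression matrix needs a gene_id column plus >=1 sample column")
    ids <- raw[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate gene ids in ", matrix_path)
    cells <- as.matrix(raw[, -1L, drop = FALSE])
    # read.table already converts the literal string NA; treat it, and the
    # other missing markers, as masked cells
    is_missing <- matrix(is.na(cells) |
                             tolower(trimws(cells)) %in% .MISSING_MARKERS,
                         nrow = nrow(cells))
    vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    bad <- which(is.na(vals) & !is_missing, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric cell at row %d (gene %s), column %d (%s)",
                     bad[1, 1], ids[bad[1, 1]], bad[1, 2],
                     colnames(cells)[bad[1, 2]]))
    vals[is_missing] <- NA_real_
    dimnames(vals) <- list(ids, colnames(cells))
    if (transpose) vals <- t(vals)
    md <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            quote = "", comment.char = "")
    need <- c("sample_id", "condition", "sample_type")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    ExpressionStudy(vals, md)
}

#' Write a result table as TSV
#'
#' Deterministic column order (as given) and fixed precision (6 significant
#' digits for floating-point columns) so repeated runs diff cleanly.
#'
#' @param records Data frame (or matrix with dimnames) to write. An
#'   [ExpressionStudy-class] is written as a `gene_id`-keyed matrix TSV that
#'   [readExpressionStudy()] can read back.
#' @param path Output file path.
#' @param allow_empty Permit zero-row tables (header-only output).
#' @return `path`, invisibly.
#' @export
writeTable <- function(records, path, allow_empty = FALSE) {
    if (is(records, "ExpressionStudy")) {
        v <- exprValues(records)
        df <- data.frame(gene_id = rownames(v),
                         signif(v, 6L),
                         check.names = FALSE, stringsAsFactors = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA")
        return(invisible(path))
    }
    df <- as.data.frame(records)
    if (!nrow(df) && !allow_empty)
        stop("refusing to write an empty table (use allow_empty = TRUE)")
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6L)
    ok <- tryCatch({
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA")
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
    invisible(path)
}

#' Write study metadata as TSV
#'
#' Companion to [writeTable()] for the sample annotation of a study, in the
#' format [readExpressionStudy()] expects.
#'
#' @param study An [ExpressionStudy-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMetadata <- function(study, path) {
    md <- data.frame(sample_id = sampleIds(study),
                     condition = unname(studyConditions(study)),
                     sample_type = unname(sampleTypes(study)),
                     batch = unname(sampleBatches(study)),
                     stringsAsFactors = FALSE)
    writeTable(md, path)
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the analysis. Defaults follow the
#' published workflow where it states a value and common practice elsewhere.
#'
#' @param missing_gene_fraction Genes with a missing fraction at or above
#'   this are dropped (strict "less than" retention rule). Default 0.10.
#' @param knn_k Neighbors for KNN imputation. Default 20.
#' @param pca_variance Cumulative explained-variance level retained before
#'   outlier scoring. Default 0.90.
#' @param outlier_validity_fraction Dataset is valid iff the flagged-sample
#'   fraction is strictly below this. Default 0.10.
#' @param housekeeping_fc_threshold Absolute log2 fold-change above which a
#'   housekeeping gene is considered unstable. Default 0.3.
#' @param mi_prefilter Normalized-MI level below which a pair is discarded as
#'   uncorrelated before significance testing. Default 0.2.
#' @param mi_edge_threshold Global normalized-MI edge threshold used when
#'   `mi_edge_rule = "fixed"`. Default 0.7.
#' @param mi_edge_rule Edge significance rule: `"fisher"` (default) is the
#'   bivariate-normal confidence-interval rule (MI prefilter, then
#'   Fisher-z on the Pearson correlation at per-pair level
#'   `1 - mi_null_quantile`); `"calibrated"` thresholds normalized MI at
#'   its Monte-Carlo null quantile plus a permutation test; `"fixed"` uses
#'   `mi_edge_threshold` as-is with a permutation test. See the package
#'   vignette for why a fixed normalized-MI cut is not portable across
#'   sample sizes and estimators.
#' @param mi_null_quantile Family-calibration level of the edge rules:
#'   per-pair level is `1 - mi_null_quantile`. Default 0.9999 (about 20
#'   expected false pairs among the ~2e5 pairs of a 600-gene network).
#' @param mi_bins Number of quantile bins per gene; `NA` (default) applies
#'   `ceil(sqrt(n/5))` clamped to `[2, 24]` at sample size `n`.
#' @param n_perm Permutations for per-edge significance. Default 200.
#' @param fdr_alpha Benjamini-Hochberg significance level. Default 0.05.
#' @param ga_weights Weights of the four fitness components (parsimony,
#'   accuracy, geometric mean, support-vector parsimony). Default
#'   `c(1, 5, 5, 5)`.
#' @param cv_folds Stratified cross-validation folds. Default 5.
#' @param lof_neighbors,lof_threshold Local-outlier-factor neighborhood size
#'   and flagging threshold. Defaults 20 and 1.5.
#' @param seed Integer seed controlling every randomized stage.
#' @return A validated [PipelineConfig-class].
#' @examples
#' cfg <- pipelineConfig(seed = 7)
#' @export
pipelineConfig <- function(missing_gene_fraction = 0.10, knn_k = 20L,
                           pca_variance = 0.90,
                           outlier_validity_fraction = 0.10,
                           housekeeping_fc_threshold = 0.3,
                           mi_prefilter = 0.2, mi_edge_threshold = 0.7,
                           mi_edge_rule = "fisher",
                           mi_null_quantile = 0.9999, mi_bins = NA_integer_,
                           n_perm = 200L, fdr_alpha = 0.05,
                           ga_weights = c(1, 5, 5, 5), cv_folds = 5L,
                           lof_neighbors = 20L, lof_threshold = 1.5,
                           seed = 1L) {
    new("PipelineConfig",
        missing_gene_fraction = missing_gene_fraction,
        knn_k = as.integer(knn_k), pca_variance = pca_variance,
        outlier_validity_fraction = outlier_validity_fraction,
        housekeeping_fc_threshold = housekeeping_fc_threshold,
        mi_prefilter = mi_prefilter, mi_edge_threshold = mi_edge_threshold,
        mi_edge_rule = mi_edge_rule, mi_null_quantile = mi_null_quantile,
        mi_bins = as.integer(mi_bins), n_perm = as.integer(n_perm),
        fdr_alpha = fdr_alpha, ga_weights = as.numeric(ga_weights),
        cv_folds = as.integer(cv_folds),
        lof_neighbors = as.integer(lof_neighbors),
        lof_threshold = lof_threshold, seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of [pipelineConfig()]; arguments passed via
#' `...` override their YAML counterparts.
#'
#' @param path YAML file path.
#' @param ... Overrides, e.g. `seed = 42`.
#' @return A validated [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path, ...) {
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    over <- list(...)
    vals[names(over)] <- over
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    do.call(pipelineConfig, vals)
}

#' Read a miRNA:target confidence table
#'
#' TSV with columns `mirna_id`, `target_gene`, `confidence` and optional
#' `direction` (`up`/`down`/`unknown`). The package ships the published
#' stroke miRNA:target table as
#' `system.file("extdata", "mirna_targets.tsv", package = "netmark")`.
#'
#' @param path TSV file path.
#' @return Data frame of target records, one row per (miRNA, gene) pair.
#' @export
readMirnaTargets <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "")
    need <- c("mirna_id", "target_gene", "confidence")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("miRNA table lacks column(s): ", paste(miss, collapse = ", "))
    if (is.null(df$direction)) df$direction <- "unknown"
    if (!all(df$direction %in% c("up", "down", "unknown")))
        stop("direction must be 'up', 'down' or 'unknown'")
    if (any(df$confidence < 0)) stop("confidence scores must be >= 0")
    if (anyDuplicated(df[c("mirna_id", "target_gene")]))
        stop("duplicate (miRNA, target) pairs")
    df
}
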