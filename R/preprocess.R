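#' @include AllClasses.R core_io.R
NULL

#' Filter genes by missing-value fraction
#'
#' Retains genes whose missing fraction is strictly below `max_fraction`
#' (a gene missing in exactly 10% of samples is removed at the default
#' threshold). Survivor order is preserved.
#'
#' @param study An [ExpressionStudy-class].
#' @param max_fraction Maximum tolerated missing fraction, in `[0, 1]`.
#' @return List with `study` (filtered) and `removed` (gene ids dropped).
#' @export
filterMissingGenes <- function(study, max_fraction = 0.10) {
    stopifnot(max_fraction >= 0, max_fraction <= 1)
    frac <- rowMeans(missingMask(study))
    keep <- frac < max_fraction
    if (!any(keep)) stop("missing-value filter removed every gene")
    list(study = study[keep, ], removed = geneIds(study)[!keep])
}

#' KNN imputation of missing expression values
#'
#' For each missing cell `(g, s)`, the `k` genes nearest to `g` (Euclidean
#' distance over samples where both genes are observed, restricted to genes
#' observed at `s`) vote with weights `1/d`. A zero-distance neighbor returns
#' its value directly (ties averaged). Cells are processed against the
#' original mask, so no value is imputed from an imputation, and no observed
#' value is altered. A missing cell with no eligible neighbor falls back to
#' the gene mean with a warning.
#'
#' @param study An [ExpressionStudy-class].
#' @param k Number of neighbors (default 20).
#' @return A list with `study` (complete) and `imputed_cells` (count).
#' @export
knnImpute <- function(study, k = 20L) {
    stopifnot(k >= 1L)
    v <- exprValues(study)
    mask <- is.na(v)
    if (!any(mask))
        return(list(study = study, imputed_cells = 0L))
    out <- v
    gene_means <- rowMeans(v, na.rm = TRUE)
    todo <- which(rowSums(mask) > 0)
    fallback <- 0L
    for (g in todo) {
        # squared diffs to every gene over co-observed samples
        sq <- sweep(v, 2L, v[g, ], "-")^2
        nco <- rowSums(!is.na(sq))
        d <- sqrt(rowSums(sq, na.rm = TRUE))
        d[g] <- Inf
        d[nco == 0L] <- Inf
        for (s in which(mask[g, ])) {
            elig <- which(!mask[, s] & is.finite(d))
            if (!length(elig)) {
                out[g, s] <- gene_means[g]
                fallback <- fallback + 1L
                next
            }
            nb <- elig[order(d[elig])][seq_len(min(k, length(elig)))]
            dn <- d[nb]
            if (any(dn == 0)) {
                out[g, s] <- mean(v[nb[dn == 0], s])
            } else {
                w <- 1 / dn
                out[g, s] <- sum(w * v[nb, s]) / sum(w)
            }
        }
    }
    if (fallback > 0L)
        warning(fallback, " missing cell(s) had no eligible neighbor; ",
                "gene-mean fallback used")
    md <- data.frame(sample_id = sampleIds(study),
                     condition = unname(studyConditions(study)),
                     sample_type = unname(sampleTypes(study)),
                     batch = unname(sampleBatches(study)),
                     stringsAsFactors = FALSE)
    list(study = ExpressionStudy(out, md), imputed_cells = sum(mask))
}

# Housekeeping panel commonly used for qPCR-style renormalization.
.HOUSEKEEPING_PANEL <- c("ACTB", "B2M", "HMBS", "HPRT1", "RPL13A", "SDHA",
                         "TBA", "YWHAZ")

#' Choose the normalization strategy from housekeeping-gene stability
#'
#' Computes each housekeeping gene's absolute log2 fold change between the
#' condition means on the linear scale implied by the log2 data. If every
#' candidate exceeds `fc_threshold` the panel is unusable and per-sample
#' median normalization is chosen; otherwise the stable candidates anchor a
#' housekeeping rescaling. Candidates absent from the matrix are skipped with
#' a message; an empty intersection falls back to median normalization with
#' a warning.
#'
#' @param study An [ExpressionStudy-class] (no missing values).
#' @param housekeeping_genes Candidate gene ids. Defaults to the standard
#'   8-gene panel.
#' @param fc_threshold Stability threshold in log2 units (default 0.3).
#' @return List with `strategy` (`"median_per_sample"` or `"housekeeping"`)
#'   and `stable_genes` (candidates passing the threshold).
#' @export
chooseNormalizer <- function(study,
                             housekeeping_genes = .HOUSEKEEPING_PANEL,
                             fc_threshold = 0.3) {
    if (!length(housekeeping_genes)) stop("housekeeping_genes must be nonempty")
    present <- intersect(housekeeping_genes, geneIds(study))
    absent <- setdiff(housekeeping_genes, present)
    if (length(absent))
        message("housekeeping candidate(s) not in matrix, skipped: ",
                paste(absent, collapse = ", "))
    if (!length(present)) {
        warning("no housekeeping candidate found; using median normalization")
        return(list(strategy = "median_per_sample", stable_genes = character()))
    }
    v <- exprValues(study)[present, , drop = FALSE]
    stroke <- studyConditions(study) == "stroke"
    lin <- 2^v
    fc <- abs(log2(rowMeans(lin[, stroke, drop = FALSE]) /
                   rowMeans(lin[, !stroke, drop = FALSE])))
    stable <- present[fc <= fc_threshold]
    if (!length(stable))
        list(strategy = "median_per_sample", stable_genes = character())
    else
        list(strategy = "housekeeping", stable_genes = stable)
}

#' Median per-sample normalization
#'
#' Shifts each sample (log scale) so that its median equals the global
#' median of the pre-normalization sample medians.
#'
#' @param study An [ExpressionStudy-class] without missing values.
#' @return The normalized [ExpressionStudy-class].
#' @export
medianNormalize <- function(study) {
    v <- exprValues(study)
    if (anyNA(v)) stop("impute missing values before normalization")
    med <- apply(v, 2L, stats::median)
    target <- stats::median(med)
    v <- sweep(v, 2L, med - target, "-")
    md <- data.frame(sample_id = sampleIds(study),
                     condition = unname(studyConditions(study)),
                     sample_type = unname(sampleTypes(study)),
                     batch = unname(sampleBatches(study)),
                     stringsAsFactors = FALSE)
    ExpressionStudy(v, md)
}

#' Housekeeping rescaling
#'
#' Shifts each sample so that the mean of the stable housekeeping genes is
#' constant across samples (anchored at the global mean).
#'
#' @param study An [ExpressionStudy-class] without missing values.
#' @param stable_genes Stable housekeeping gene ids (from
#'   [chooseNormalizer()]).
#' @return The normalized [ExpressionStudy-class].
#' @export
housekeepingNormalize <- function(study, stable_genes) {
    stopifnot(length(stable_genes) > 0, all(stable_genes %in% geneIds(study)))
    v <- exprValues(study)
    if (anyNA(v)) stop("impute missing values before normalization")
    anchor <- colMeans(v[stable_genes, , drop = FALSE])
    v <- sweep(v, 2L, anchor - mean(anchor), "-")
    md <- data.frame(sample_id = sampleIds(study),
                     condition = unname(studyConditions(study)),
                     sample_type = unname(sampleTypes(study)),
                     batch = unname(sampleBatches(study)),
                     stringsAsFactors = FALSE)
    ExpressionStudy(v, md)
}

#' Local outlier factor
#'
#' Classic density-ratio LOF: reachability distances against the
#' `k`-neighborhood, local reachability density, and the mean density ratio
#' to the neighbors. Values near 1 indicate inliers.
#'
#' @param x Numeric matrix, observations in rows.
#' @param k Neighborhood size.
#' @return Numeric LOF score per observation.
#' @export
localOutlierFactor <- function(x, k) {
    n <- nrow(x)
    stopifnot(k >= 1L, n > k)
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    # k-distance and (tie-inclusive) k-neighborhood per point
    kdist <- numeric(n)
    nbrs <- vector("list", n)
    for (i in seq_len(n)) {
        srt <- sort(d[i, ])
        kdist[i] <- srt[k]
        nbrs[[i]] <- which(d[i, ] <= kdist[i] + 1e-12)
    }
    lrd <- numeric(n)
    for (i in seq_len(n)) {
        reach <- pmax(kdist[nbrs[[i]]], d[i, nbrs[[i]]])
        m <- mean(reach)
        lrd[i] <- if (m > 0) 1 / m else Inf
    }
    lof <- numeric(n)
    for (i in seq_len(n)) {
        r <- lrd[nbrs[[i]]] / lrd[i]
        r[is.nan(r)] <- 1  # duplicate points: both densities infinite
        lof[i] <- mean(r)
    }
    lof
}

#' PCA + LOF sample outlier screening with a validity gate
#'
#' Samples are projected onto the smallest set of principal components whose
#' cumulative explained variance reaches `pca_variance`; the local outlier
#' factor is computed in that space and samples with `LOF > lof_threshold`
#' are flagged. The dataset is valid iff the flagged fraction is strictly
#' below `validity_fraction`.
#'
#' @param study An [ExpressionStudy-class] without missing values.
#' @param pca_variance Cumulative variance level (default 0.90).
#' @param lof_neighbors LOF neighborhood size (default 20; reduced with a
#'   warning when there are too few samples).
#' @param lof_threshold LOF flagging threshold (default 1.5).
#' @param validity_fraction Validity gate (default 0.10).
#' @return List with `outliers` (sample ids), `lof` (scores),
#'   `dataset_valid`, and `outlier_fraction`.
#' @export
detectOutliers <- function(study, pca_variance = 0.90, lof_neighbors = 20L,
                           lof_threshold = 1.5, validity_fraction = 0.10) {
    v <- exprValues(study)
    if (anyNA(v)) stop("impute missing values before outlier detection")
    n <- ncol(v)
    if (n <= lof_neighbors) {
        lof_neighbors <- max(1L, n - 2L)
        warning("fewer samples than LOF neighbors; using k = ", lof_neighbors)
    }
    pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- which(cum >= pca_variance)[1L]
    if (is.na(ncomp)) ncomp <- length(pc$sdev)
    scores <- pc$x[, seq_len(ncomp), drop = FALSE]
    lof <- localOutlierFactor(scores, lof_neighbors)
    names(lof) <- sampleIds(study)
    flagged <- sampleIds(study)[lof > lof_threshold]
    frac <- length(flagged) / n
    list(outliers = flagged, lof = lof,
         dataset_valid = frac < validity_fraction, outlier_fraction = frac)
}

#' Full preprocessing stage
#'
#' Filter genes by missingness, KNN-impute the rest, choose and apply the
#' normalization strategy, then screen samples with PCA+LOF. Flagged samples
#' are removed when the dataset passes the validity gate; when it does not,
#' the study is returned unreduced with `dataset_valid = FALSE` and
#' downstream stages must refuse to run.
#'
#' @param study An [ExpressionStudy-class].
#' @param cfg A [PipelineConfig-class].
#' @param housekeeping_genes Candidate normalizer genes (default: standard
#'   8-gene panel; ignored if none are present).
#' @return List with `study` (preprocessed) and `qc` ([QCReport-class]).
#' @export
preprocessStudy <- function(study, cfg = pipelineConfig(),
                            housekeeping_genes = .HOUSEKEEPING_PANEL) {
    flt <- filterMissingGenes(study, cfg@missing_gene_fraction)
    imp <- knnImpute(flt$study, cfg@knn_k)
    norm <- suppressMessages(
        chooseNormalizer(imp$study, housekeeping_genes,
                         cfg@housekeeping_fc_threshold))
    normed <- if (norm$strategy == "housekeeping")
        housekeepingNormalize(imp$study, norm$stable_genes)
    else
        medianNormalize(imp$study)
    det <- detectOutliers(normed, cfg@pca_variance, cfg@lof_neighbors,
                          cfg@lof_threshold, cfg@outlier_validity_fraction)
    qc <- new("QCReport", removed_genes = flt$removed,
              imputed_cells = as.integer(imp$imputed_cells),
              normalization_strategy = norm$strategy,
              outlier_samples = det$outliers,
              outlier_fraction = det$outlier_fraction,
              dataset_valid = det$dataset_valid)
    out <- normed
    if (det$dataset_valid && length(det$outliers))
        out <- normed[, setdiff(sampleIds(normed), det$outliers)]
    list(study = out, qc = qc)
}
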