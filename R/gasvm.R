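#' @include AllClasses.R core_io.R
NULL

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds, separately shuffled within each
#' class so every fold holds (close to) the class proportions of the whole
#' data. Uses the current RNG state.
#'
#' @param labels Class labels (character or factor).
#' @param k Fold count.
#' @return Integer fold id per sample.
#' @export
stratifiedFolds <- function(labels, k) {
    if (min(table(labels)) < k)
        stop("each class needs at least ", k, " samples for ", k, "-fold CV")
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

#' Confusion-count classification metrics
#'
#' @param tp,tn,fp,fn Pooled confusion counts (stroke is the positive
#'   class).
#' @return List with the counts plus `accuracy`, `sensitivity`,
#'   `specificity` and `gmean` (geometric mean of sensitivity and
#'   specificity). Undefined ratios (zero denominators) are reported as 0.
#' @export
classifierMetrics <- function(tp, tn, fp, fn) {
    div <- function(a, b) if (b > 0) a / b else 0
    sens <- div(tp, tp + fn)
    spec <- div(tn, tn + fp)
    list(tp = tp, tn = tn, fp = fp, fn = fn,
         accuracy = div(tp + tn, tp + tn + fp + fn),
         sensitivity = sens, specificity = spec,
         gmean = sqrt(sens * spec))
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.GA_BOUNDS <- list(log10_c = c(-2, 4), log10_gamma = c(-4, 1))

#' Evaluate one candidate signature solution
#'
#' A solution is a float vector of gene-inclusion scores (gene selected iff
#' score > 0.5) plus RBF-SVM hyperparameter exponents `log10_c` and
#' `log10_gamma`. The selected genes are scored by seeded stratified k-fold
#' cross-validation of an RBF SVM (each fold trains on (k-1)/k of the data),
#' confusion counts pooled over folds. Fitness components: `f1 = 1/(1+k)`
#' with `k` the selected-gene count, `f2` = accuracy, `f3` = geometric mean
#' of sensitivity and specificity, `f4` = mean over folds of
#' `n_train / n_support_vectors`; the overall fitness is the weighted sum
#' with `cfg@ga_weights`. Selecting zero genes scores 0 on every component.
#'
#' @param sol List with `inclusion` (numeric in `[0,1]`, one per candidate
#'   gene), `log10_c`, `log10_gamma`.
#' @param features An [ExpressionStudy-class] restricted to the candidate
#'   genes.
#' @param cfg A [PipelineConfig-class] (folds, weights, seed).
#' @param labels Per-sample condition labels (default: from `features`).
#' @return List with `fitness` (components `f1`..`f4`, `overall`) and
#'   `eval` (confusion counts and metrics, plus mean `n_support_vectors`
#'   and `n_train`).
#' @export
evaluateSolution <- function(sol, features, cfg = pipelineConfig(),
                             labels = unname(studyConditions(features))) {
    genes <- geneIds(features)
    stopifnot(length(sol$inclusion) == length(genes))
    sel <- sol$inclusion > 0.5
    w <- cfg@ga_weights
    if (!any(sel)) {
        fit <- list(f1 = 0, f2 = 0, f3 = 0, f4 = 0, overall = 0)
        return(list(fitness = fit, eval = NULL))
    }
    x <- t(exprValues(features)[sel, , drop = FALSE])
    if (all(apply(x, 2L, stats::var) < 1e-12)) {
        fit <- list(f1 = 0, f2 = 0, f3 = 0, f4 = 0, overall = 0)
        return(list(fitness = fit, eval = NULL))
    }
    y <- factor(labels, levels = c("control", "stroke"))
    fold <- withr::with_seed(cfg@seed,
                             stratifiedFolds(labels, cfg@cv_folds))
    tp <- tn <- fp <- fn <- 0L
    nsv <- ntr <- numeric(cfg@cv_folds)
    for (f in seq_len(cfg@cv_folds)) {
        tr <- fold != f
        model <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                            type = "C-classification", kernel = "radial",
                            cost = 10^sol$log10_c, gamma = 10^sol$log10_gamma,
                            scale = apply(x[tr, , drop = FALSE], 2L,
                                          stats::var) > 1e-12)
        pred <- stats::predict(model, x[!tr, , drop = FALSE])
        truth <- y[!tr]
        tp <- tp + sum(pred == "stroke" & truth == "stroke")
        tn <- tn + sum(pred == "control" & truth == "control")
        fp <- fp + sum(pred == "stroke" & truth == "control")
        fn <- fn + sum(pred == "control" & truth == "stroke")
        nsv[f] <- model$tot.nSV
        ntr[f] <- sum(tr)
    }
    ev <- classifierMetrics(tp, tn, fp, fn)
    ev$n_support_vectors <- mean(nsv)
    ev$n_train <- mean(ntr)
    f1 <- 1 / (1 + sum(sel))
    f4 <- mean(ntr / pmax(nsv, 1))
    fit <- list(f1 = f1, f2 = ev$accuracy, f3 = ev$gmean, f4 = f4,
                overall = w[1] * f1 + w[2] * ev$accuracy + w[3] * ev$gmean +
                    w[4] * f4)
    list(fitness = fit, eval = ev)
}

#' Genetic-algorithm search for a compact SVM gene signature
#'
#' Seeded evolutionary loop over float-vector solutions: initialization
#' biased toward small signatures (expected selected count about
#' `min(10, G/4)`), fitness-proportional (roulette) selection, uniform
#' crossover (rate 0.9), per-locus Gaussian mutation (sd 0.15, rate `1/G`)
#' with clipping to bounds, elitism of one. Hyperparameter loci evolve
#' within `log10_c` in `[-2, 4]` and `log10_gamma` in `[-4, 1]`.
#'
#' @param features An [ExpressionStudy-class] restricted to the candidate
#'   genes (at least 2).
#' @param cfg A [PipelineConfig-class].
#' @param pop_size Population size (default 50; must be >= 4).
#' @param n_generations Generations (default 100; must be >= 1).
#' @return List with `solution` (the best-ever float vector), `genes`
#'   (selected gene ids), `fitness`, `eval`, and `history` (data frame of
#'   per-generation best-ever overall fitness, non-decreasing).
#' @export
gaSearch <- function(features, cfg = pipelineConfig(), pop_size = 50L,
                     n_generations = 100L) {
    if (pop_size < 4L) stop("pop_size must be at least 4")
    if (n_generations < 1L) stop("n_generations must be at least 1")
    genes <- geneIds(features)
    g <- length(genes)
    if (g < 2L) stop("need at least 2 candidate genes")
    withr::with_seed(cfg@seed + 1L, {
        p0 <- min(10, g / 4) / g
        new_sol <- function() {
            v <- stats::runif(g) * 0.5
            hit <- stats::runif(g) < p0
            v[hit] <- v[hit] + 0.5
            list(inclusion = v,
                 log10_c = stats::runif(1, .GA_BOUNDS$log10_c[1],
                                        .GA_BOUNDS$log10_c[2]),
                 log10_gamma = stats::runif(1, .GA_BOUNDS$log10_gamma[1],
                                            .GA_BOUNDS$log10_gamma[2]))
        }
        pop <- replicate(pop_size, new_sol(), simplify = FALSE)
        evals <- lapply(pop, evaluateSolution, features = features, cfg = cfg)
        fit <- vapply(evals, function(e) e$fitness$overall, numeric(1))
        best_i <- which.max(fit)
        best <- list(sol = pop[[best_i]], eval = evals[[best_i]],
                     fitness = fit[best_i])
        history <- numeric(n_generations)
        mut_rate <- 1 / g
        vec_of <- function(s) c(s$inclusion, s$log10_c, s$log10_gamma)
        sol_of <- function(v) list(inclusion = v[seq_len(g)],
                                   log10_c = v[g + 1L],
                                   log10_gamma = v[g + 2L])
        for (gen in seq_len(n_generations)) {
            probs <- if (sum(fit) > 0) fit / sum(fit)
                     else rep(1 / pop_size, pop_size)
            children <- vector("list", pop_size)
            for (i in seq(1L, pop_size, by = 2L)) {
                pa <- vec_of(pop[[sample.int(pop_size, 1, prob = probs)]])
                pb <- vec_of(pop[[sample.int(pop_size, 1, prob = probs)]])
                if (stats::runif(1) < 0.9) {
                    mask <- stats::runif(g + 2L) < 0.5
                    tmp <- pa[mask]
                    pa[mask] <- pb[mask]
                    pb[mask] <- tmp
                }
                mutate <- function(v) {
                    # inclusion loci flip rarely; hyperparameter loci are
                    # explored continuously so cost/width tuning keeps pace
                    # with subset changes
                    hit <- stats::runif(g + 2L) <
                        c(rep(mut_rate, g), 0.25, 0.25)
                    sds <- c(rep(0.15, g), 0.3, 0.3)
                    v[hit] <- v[hit] + stats::rnorm(sum(hit), sd = sds[hit])
                    v[seq_len(g)] <- .clip(v[seq_len(g)], 0, 1)
                    v[g + 1L] <- .clip(v[g + 1L], .GA_BOUNDS$log10_c[1],
                                       .GA_BOUNDS$log10_c[2])
                    v[g + 2L] <- .clip(v[g + 2L], .GA_BOUNDS$log10_gamma[1],
                                       .GA_BOUNDS$log10_gamma[2])
                    v
                }
                children[[i]] <- sol_of(mutate(pa))
                if (i + 1L <= pop_size) children[[i + 1L]] <- sol_of(mutate(pb))
            }
            # elitism: the best-ever solution replaces the first child
            children[[1L]] <- best$sol
            pop <- children
            evals <- lapply(pop, evaluateSolution, features = features,
                            cfg = cfg)
            fit <- vapply(evals, function(e) e$fitness$overall, numeric(1))
            gi <- which.max(fit)
            if (fit[gi] > best$fitness)
                best <- list(sol = pop[[gi]], eval = evals[[gi]],
                             fitness = fit[gi])
            # memetic step every 10 generations and at the end: refine the
            # best solution's hyperparameters on a coarse grid under the
            # same weighted-fitness objective, and reinject it. Gaussian
            # mutation alone explores the cost/width plane too slowly to
            # reach its corners within desk-scale generation counts, and a
            # gene subset judged under poor hyperparameters misleads the
            # subset search itself.
            if (gen %% 10L == 0L || gen == n_generations) {
                for (lc in unique(c(seq(-2, 4, by = 0.5),
                                    best$sol$log10_c))) {
                    for (lg in unique(c(seq(-4, 1, by = 0.5),
                                        best$sol$log10_gamma))) {
                        refined <- best$sol
                        refined$log10_c <- lc
                        refined$log10_gamma <- lg
                        ev <- evaluateSolution(refined, features, cfg)
                        if (ev$fitness$overall > best$fitness)
                            best <- list(sol = refined, eval = ev,
                                         fitness = ev$fitness$overall)
                    }
                }
                pop[[1L]] <- best$sol
                evals[[1L]] <- best$eval
                fit[1L] <- best$fitness
            }
            history[gen] <- best$fitness
        }
        list(solution = best$sol,
             genes = genes[best$sol$inclusion > 0.5],
             fitness = best$eval$fitness, eval = best$eval$eval,
             history = data.frame(generation = seq_len(n_generations),
                                  best_overall = history))
    })
}

#' Head-to-head evaluation of fixed gene sets
#'
#' Evaluates each named gene set with the same seeded cross-validation
#' protocol and default SVM hyperparameters (`C = 1`, `gamma = 1/k` with `k`
#' the set size), enabling comparisons between, e.g., a network-derived
#' signature and a top-fold-change panel.
#'
#' @param features An [ExpressionStudy-class] containing every queried gene.
#' @param gene_sets Named list of gene-id vectors (all nonempty).
#' @param cfg A [PipelineConfig-class].
#' @return Named list of evaluations as returned by [evaluateSolution()].
#' @export
compareGeneSets <- function(features, gene_sets, cfg = pipelineConfig()) {
    stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
    genes <- geneIds(features)
    missing <- unique(unlist(lapply(gene_sets, setdiff, y = genes)))
    if (length(missing))
        stop("unknown gene(s): ", paste(missing, collapse = ", "))
    if (any(!lengths(gene_sets)))
        stop("every gene set must be nonempty")
    lapply(gene_sets, function(set) {
        sub <- features[set, ]
        sol <- list(inclusion = rep(1, length(set)), log10_c = 0,
                    log10_gamma = log10(1 / length(set)))
        evaluateSolution(sol, sub, cfg)
    })
}
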