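#' Log-normalized expression for co-expression analysis
#'
#' `log1p` of counts divided by library-size factors; the scale feeding
#' the correlation matrix of [buildCoexpressionModel()].
#'
#' @param counts genes x nuclei count matrix.
#' @return Dense numeric matrix, same dimensions.
#' @export
normalizeExpression <- function(counts) {
    sf <- sizeFactors(counts)
    log1p(sweep(as.matrix(counts), 2, sf, "/"))
}

#' Scale-free fit index of a signed adjacency
#'
#' Connectivity `k_i = sum_j a_ij` (diagonal excluded) is binned into
#' `nbins` equal-width bins; the index is the R-squared of the regression
#' of `log10 p(k)` on `log10 k` over non-empty bins, signed by the slope
#' (negative slope gives a positive index, the scale-free direction).
#'
#' @param adjacency Symmetric matrix in `[0, 1]`.
#' @param nbins Number of connectivity bins (default 10).
#' @return List `index`, `slope`, `r_squared`.
#' @export
scaleFreeFitIndex <- function(adjacency, nbins = 10L) {
    k <- Matrix::colSums(adjacency) - diag(adjacency)
    brk <- seq(min(k), max(k), length.out = nbins + 1L)
    brk[1L] <- brk[1L] - 1e-9
    bin <- cut(k, brk)
    pk <- tapply(k, bin, length) / length(k)
    km <- tapply(k, bin, mean)
    ok <- !is.na(pk) & pk > 0 & km > 0
    if (sum(ok) < 3) return(list(index = 0, slope = 0, r_squared = 0))
    fit <- stats::lm(log10(pk[ok]) ~ log10(km[ok]))
    r2 <- summary(fit)$r.squared
    sl <- unname(stats::coef(fit)[2L])
    list(index = -sign(sl) * r2, slope = sl, r_squared = r2)
}

#' Choose the soft-thresholding power
#'
#' Signed adjacency `a_ij = ((1 + cor_ij)/2)^power` is computed for every
#' candidate power; returns the lowest power whose scale-free fit index
#' reaches `r2_target`, or (with a warning) the power with maximal index
#' when none does. Genes with constant expression are dropped with a
#' warning.
#'
#' @param expr genes x nuclei normalized expression (see
#'   [normalizeExpression()]).
#' @param candidate_powers Integer vector (default 1:10).
#' @param r2_target Target fit index (default 0.90).
#' @return List `power`, `fit` (`data.frame` power, index, slope),
#'   `correlation` (the Pearson matrix over retained genes).
#' @export
pickSoftPower <- function(expr, candidate_powers = 1:10,
                          r2_target = 0.90) {
    if (nrow(expr) < 10) stop("need at least 10 genes")
    sds <- apply(expr, 1, stats::sd)
    if (any(sds == 0)) {
        warning(sum(sds == 0), " constant gene(s) dropped")
        expr <- expr[sds > 0, , drop = FALSE]
    }
    cm <- stats::cor(Matrix::t(expr))
    fit <- do.call(rbind, lapply(candidate_powers, function(b) {
        adj <- ((1 + cm) / 2)^b
        sf <- scaleFreeFitIndex(adj)
        data.frame(power = b, index = sf$index, slope = sf$slope)
    }))
    reach <- fit$power[fit$index >= r2_target]
    power <- if (length(reach)) min(reach) else {
        warning("no candidate power reaches the fit target; ",
                "returning the power with maximal index")
        fit$power[which.max(fit$index)]
    }
    list(power = power, fit = fit, correlation = cm)
}

#' PAM partition with silhouette-selected k
#'
#' Partitioning around medoids on a dissimilarity matrix for every k in
#' `k_range`; the partition with maximal mean silhouette width
#' `s(i) = (b_i - a_i)/max(a_i, b_i)` is returned, ties broken to the
#' smallest k. k = 1 has no silhouette and is excluded with a warning.
#'
#' For instances small enough to enumerate (at most `exact_limit` medoid
#' subsets) the globally optimal medoid set is found by exhaustive search
#' — the deterministic BUILD + swap heuristic can land in local optima
#' even at a handful of points; beyond that bound the standard
#' deterministic PAM (no random restarts) is used.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param k_range Integer vector of candidate module counts.
#' @param exact_limit Enumeration budget for the exact search
#'   (default 5000 medoid subsets).
#' @return List `partition` (named integer vector), `medoids`, `k`,
#'   `silhouette` (per-gene widths, input order), `mean_silhouette`,
#'   `searched` (`data.frame` k, mean width).
#' @export
pamWithSilhouette <- function(D, k_range = 2:6, exact_limit = 5000) {
    stopifnot(is.matrix(D), nrow(D) == ncol(D))
    if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
    if (max(abs(diag(D))) > 1e-8) stop("D must have zero diagonal")
    n <- nrow(D)
    if (any(k_range == 1L)) {
        warning("k = 1 has no silhouette; excluded from the search")
        k_range <- k_range[k_range != 1L]
    }
    k_range <- sort(unique(k_range[k_range > 1L & k_range < n]))
    if (!length(k_range)) stop("no searchable k in k_range")
    ids <- rownames(D)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    dimnames(D) <- list(ids, ids)
    best <- NULL
    searched <- data.frame(k = k_range, mean_silhouette = NA_real_)
    for (i in seq_along(k_range)) {
        k <- k_range[i]
        if (choose(n, k) <= exact_limit) {
            best_cost <- Inf
            med <- NULL
            for (cand in utils::combn(n, k, simplify = FALSE)) {
                cost <- sum(apply(D[, cand, drop = FALSE], 1, min))
                if (cost < best_cost - 1e-12) {
                    best_cost <- cost
                    med <- cand
                }
            }
            clustering <- apply(D[, med, drop = FALSE], 1, which.min)
            # relabel so every medoid heads its own cluster
            clustering[med] <- seq_len(k)
            pr <- list(clustering = clustering, medoids = ids[med])
        } else {
            fit <- cluster::pam(D, k, diss = TRUE)
            pr <- list(clustering = fit$clustering, medoids = fit$medoids)
        }
        sil <- cluster::silhouette(pr$clustering, dmatrix = D)
        widths <- stats::setNames(sil[, "sil_width"], ids)
        msw <- mean(widths)
        searched$mean_silhouette[i] <- msw
        if (is.null(best) || msw > best$mean_silhouette + 1e-12) {
            best <- list(partition = stats::setNames(pr$clustering, ids),
                         medoids = pr$medoids, k = as.integer(k),
                         silhouette = widths, mean_silhouette = msw)
        }
    }
    c(best, list(searched = searched))
}

#' Build a co-expression model over candidate genes
#'
#' Full chain: normalized expression, soft power selection, signed
#' adjacency `((1 + cor)/2)^power`, dissimilarity `1 - adjacency` (the
#' adjacency itself serves as the topological overlap matrix), and PAM
#' partition with silhouette-selected k.
#'
#' @param x A [BowerExperiment-class] or count matrix.
#' @param candidates Character vector of candidate gene identifiers;
#'   candidates never observed in any nucleus are dropped.
#' @param candidate_powers,r2_target Passed to [pickSoftPower()].
#' @param k_range Candidate module counts (default `2:min(10, n - 1)`).
#' @return A [CoexpressionModel-class].
#' @export
buildCoexpressionModel <- function(x, candidates,
                                   candidate_powers = 1:10,
                                   r2_target = 0.90, k_range = NULL) {
    counts <- if (methods::is(x, "BowerExperiment")) assay(x, "counts")
              else x
    miss <- setdiff(candidates, rownames(counts))
    if (length(miss))
        stop("candidate gene(s) absent: ",
             paste(utils::head(miss, 5), collapse = ", "))
    sub <- counts[candidates, , drop = FALSE]
    observed <- Matrix::rowSums(sub) > 0
    if (any(!observed)) {
        warning(sum(!observed), " candidate(s) observed in no nucleus; ",
                "dropped")
        sub <- sub[observed, , drop = FALSE]
    }
    expr <- normalizeExpression(sub)
    ps <- pickSoftPower(expr, candidate_powers, r2_target)
    genes <- rownames(ps$correlation)
    adj <- ((1 + ps$correlation) / 2)^ps$power
    D <- 1 - adj
    diag(D) <- 0
    if (is.null(k_range)) k_range <- 2:min(10L, length(genes) - 1L)
    pw <- pamWithSilhouette(D, k_range)
    methods::new("CoexpressionModel", genes = genes,
                 correlation = ps$correlation, power = ps$power,
                 scaleFreeFit = ps$fit, adjacency = adj, dissimilarity = D,
                 partition = as.integer(pw$partition),
                 medoids = pw$medoids, silhouette = unname(pw$silhouette),
                 k = pw$k)
}

#' Strength of a focal module
#'
#' Two Welch t-tests comparing the focal module against the remaining
#' candidate genes: (i) silhouette widths and (ii) within-module pairwise
#' correlations versus module-to-outside pairwise correlations.
#'
#' @param model A [CoexpressionModel-class].
#' @param focal_module Module id (defaults to the module with the highest
#'   mean silhouette width).
#' @return `data.frame` with rows `silhouette` and `correlation`:
#'   `t`, `df`, `p`, `mean_in`, `mean_out`.
#' @export
moduleStrength <- function(model, focal_module = NULL) {
    part <- model@partition
    if (is.null(focal_module)) {
        msw <- tapply(model@silhouette, part, mean)
        focal_module <- as.integer(names(msw)[which.max(msw)])
    }
    inMod <- part == focal_module
    if (sum(inMod) < 2 || sum(!inMod) < 2)
        stop("focal module and complement each need at least 2 genes")
    silT <- stats::t.test(model@silhouette[inMod],
                          model@silhouette[!inMod])
    cm <- model@correlation
    within <- cm[inMod, inMod][upper.tri(cm[inMod, inMod])]
    cross <- as.vector(cm[inMod, !inMod])
    corT <- stats::t.test(within, cross)
    data.frame(
        row.names = c("silhouette", "correlation"),
        t = c(unname(silT$statistic), unname(corT$statistic)),
        df = c(unname(silT$parameter), unname(corT$parameter)),
        p = c(silT$p.value, corT$p.value),
        mean_in = c(mean(model@silhouette[inMod]), mean(within)),
        mean_out = c(mean(model@silhouette[!inMod]), mean(cross)))
}

#' Permutation test of module score against a reference score
#'
#' The module score (number of module genes detected per nucleus) is
#' correlated with a reference per-nucleus score; the null distribution is
#' generated by independently permuting each module gene's expression
#' vector across nuclei `n_perm` times and recomputing the correlation.
#' p is the add-one-corrected fraction of null |R| at least as large as
#' the observed |R|.
#'
#' @param x A [BowerExperiment-class] or count matrix.
#' @param module_genes Character vector of module gene identifiers.
#' @param reference_score Numeric per-nucleus reference (e.g. a quiescence
#'   [panelScore()]).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List `r`, `p`, `null_r` (numeric vector).
#' @export
moduleScoreAssociation <- function(x, module_genes, reference_score,
                                   n_perm = 10000L, seed = 1L) {
    counts <- if (methods::is(x, "BowerExperiment")) assay(x, "counts")
              else x
    score <- panelScore(counts, module_genes)
    if (stats::sd(score) == 0 || stats::sd(reference_score) == 0)
        stop("zero-variance score vector")
    robs <- stats::cor(score, reference_score)
    pres <- as.matrix(counts[module_genes, , drop = FALSE] > 0)
    N <- ncol(pres)
    nullR <- .withSeed(seed, {
        vapply(seq_len(n_perm), function(i) {
            s <- integer(N)
            for (g in seq_len(nrow(pres)))
                s <- s + pres[g, sample.int(N)]
            stats::cor(s, reference_score)
        }, numeric(1))
    })
    p <- (1 + sum(abs(nullR) >= abs(robs))) / (n_perm + 1)
    list(r = robs, p = p, null_r = nullR)
}

#' Transcription-factor co-expression with a module score
#'
#' Pearson correlation of each TF's normalized expression with the module
#' score across nuclei, BH-adjusted and ranked. TFs expressed in no
#' nucleus are excluded with a warning.
#'
#' @param x A [BowerExperiment-class] or count matrix.
#' @param module_genes Module gene identifiers.
#' @param tf_list TF gene identifiers (present in the matrix).
#' @return `data.frame` ranked by decreasing R: `tf`, `r`, `p`, `q`.
#' @export
tfCoexpressionScreen <- function(x, module_genes, tf_list) {
    counts <- if (methods::is(x, "BowerExperiment")) assay(x, "counts")
              else x
    miss <- setdiff(tf_list, rownames(counts))
    if (length(miss))
        stop("TF(s) absent from the gene list: ",
             paste(utils::head(miss, 5), collapse = ", "))
    score <- panelScore(counts, module_genes)
    silent <- Matrix::rowSums(counts[tf_list, , drop = FALSE]) == 0
    if (any(silent)) {
        warning(sum(silent), " TF(s) with zero counts everywhere excluded")
        tf_list <- tf_list[!silent]
    }
    # normalize against library sizes of the full matrix, not the subset;
    # empty nuclei keep unit factors (their expression is zero anyway)
    ls <- Matrix::colSums(counts)
    sf <- ifelse(ls > 0, ls / mean(ls[ls > 0]), 1)
    expr <- log1p(sweep(as.matrix(counts[tf_list, , drop = FALSE]), 2,
                        sf, "/"))
    res <- lapply(tf_list, function(tf) {
        ct <- stats::cor.test(expr[tf, ], score)
        data.frame(tf = tf, r = unname(ct$estimate), p = ct$p.value,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$q <- fdrAdjust(pmax(out$p, .Machine$double.xmin))
    out <- out[order(-out$r), , drop = FALSE]
    rownames(out) <- NULL
    out
}
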