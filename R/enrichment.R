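#' Two-sample Z-test of normalized set scores for one cluster
#'
#' Compares the normalized gene-set scores of nuclei inside a cluster
#' against all other nuclei: `Z = (mean_in - mean_out) /
#' sqrt(s_in^2/n_in + s_out^2/n_out)` with sample standard deviations
#' standing in for population ones, two-sided normal p, and Cohen's d with
#' the pooled SD as effect size.
#'
#' @param scores Numeric per-nucleus scores (`NA` excluded).
#' @param inCluster Logical vector: cluster membership.
#' @return List `z`, `p`, `d`, `mean_in`, `mean_out` (or `NULL` with a
#'   warning for singleton groups).
#' @export
clusterZTest <- function(scores, inCluster) {
    ok <- !is.na(scores)
    s <- scores[ok]; g <- inCluster[ok]
    n1 <- sum(g); n2 <- sum(!g)
    if (n1 < 2 || n2 < 2) {
        warning("cluster or complement has fewer than 2 nuclei; skipped")
        return(NULL)
    }
    m1 <- mean(s[g]); m2 <- mean(s[!g])
    v1 <- stats::var(s[g]); v2 <- stats::var(s[!g])
    z <- if (v1 / n1 + v2 / n2 > 0)
        (m1 - m2) / sqrt(v1 / n1 + v2 / n2) else 0
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    d <- if (sp > 0) (m1 - m2) / sp else 0
    list(z = z, p = 2 * stats::pnorm(-abs(z)), d = d,
         mean_in = m1, mean_out = m2)
}

#' Expression-matched random gene lists
#'
#' Genes are ranked by total expression (summed counts, descending; ties
#' broken by gene identifier). For every set gene, a pool of the
#' `pool_size` nearest-ranked non-set genes is formed; each random list
#' draws one gene uniformly from each pool, so random lists match the set
#' gene-for-gene in overall expression and never contain a set gene.
#'
#' @param gene_set Character vector of set genes.
#' @param totals Named numeric vector of per-gene summed counts (all
#'   genes).
#' @param pool_size Pool size per set gene (default 100).
#' @param n_lists Number of random lists (default 10000).
#' @param seed Integer seed; fixed seed gives identical lists.
#' @return Character matrix `n_lists x length(gene_set)`; attribute
#'   `pools` holds the per-set-gene candidate pools.
#' @export
matchedRandomSets <- function(gene_set, totals, pool_size = 100L,
                              n_lists = 10000L, seed = 1L) {
    if (!all(gene_set %in% names(totals)))
        stop("set gene(s) missing from totals")
    ord <- order(-totals, names(totals))
    ranked <- names(totals)[ord]
    rnk <- stats::setNames(seq_along(ranked), ranked)
    eligible <- setdiff(ranked, gene_set)
    if (length(eligible) < pool_size)
        stop("fewer than pool_size eligible genes")
    pools <- lapply(gene_set, function(g) {
        dd <- abs(rnk[eligible] - rnk[[g]])
        eligible[order(dd, rnk[eligible])][seq_len(pool_size)]
    })
    names(pools) <- gene_set
    .withSeed(seed, {
        lists <- vapply(pools, function(pool)
            pool[sample.int(pool_size, n_lists, replace = TRUE)],
            character(n_lists))
        if (n_lists == 1L) lists <- matrix(lists, nrow = 1L)
    })
    dimnames(lists) <- list(NULL, gene_set)
    attr(lists, "pools") <- pools
    lists
}

# per-cluster Cohen's d of a score vector, vectorized over clusters
.clusterD <- function(s, clFactor) {
    ok <- !is.na(s)
    s <- s[ok]; cl <- clFactor[ok]
    n <- as.vector(table(cl))
    sums <- as.vector(rowsum(s, cl))
    sq <- as.vector(rowsum(s^2, cl))
    N <- length(s); S <- sum(s); SQ <- sum(s^2)
    m1 <- sums / n
    v1 <- (sq - n * m1^2) / (n - 1)
    n2 <- N - n
    m2 <- (S - sums) / n2
    v2 <- ((SQ - sq) - n2 * m2^2) / (n2 - 1)
    sp <- sqrt(((n - 1) * v1 + (n2 - 1) * v2) / (n + n2 - 2))
    d <- ifelse(sp > 0, (m1 - m2) / sp, 0)
    stats::setNames(d, levels(cl))
}

#' Expression-matched permutation enrichment across clusters
#'
#' Per-cluster enrichment of a gene set by two gates: (1) a BH-adjusted
#' two-sample Z-test of normalized set scores (cluster vs all other
#' nuclei) and (2) an expression-matched permutation null — the observed
#' Cohen's d must exceed the d of at least `perm_level` of random gene
#' lists drawn from per-gene expression-matched pools. A cluster is
#' significant only when both gates pass.
#'
#' @param x A [BowerExperiment-class] or count matrix.
#' @param gene_set Character vector of set genes.
#' @param meta Per-nucleus metadata (unneeded for a `BowerExperiment`).
#' @param cluster_col Metadata column holding the cluster labels
#'   (default `"cluster_secondary"`).
#' @param n_lists,pool_size,seed Passed to [matchedRandomSets()].
#' @param alpha FDR level for the Z gate (default 0.05).
#' @param perm_level Required permutation quantile (default 0.95).
#' @return `data.frame` per cluster: `cluster`, `mean_in`, `mean_out`,
#'   `z`, `p_z`, `q_z`, `d`, `perm_quantile`, `significant`.
#' @export
permutationEnrichment <- function(x, gene_set, meta = NULL,
                                  cluster_col = "cluster_secondary",
                                  n_lists = 10000L, pool_size = 100L,
                                  seed = 1L, alpha = 0.05,
                                  perm_level = 0.95) {
    if (methods::is(x, "BowerExperiment")) {
        meta <- as.data.frame(colData(x))
        counts <- assay(x, "counts")
    } else counts <- x
    cl <- factor(meta[[cluster_col]])
    scores <- normalizedSetScore(counts, gene_set)
    res <- lapply(levels(cl), function(cc) {
        zt <- clusterZTest(scores, cl == cc)
        if (is.null(zt)) return(NULL)
        data.frame(cluster = cc, mean_in = zt$mean_in,
                   mean_out = zt$mean_out, z = zt$z, p_z = zt$p, d = zt$d,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$q_z <- fdrAdjust(pmax(out$p_z, .Machine$double.xmin))
    totals <- stats::setNames(as.numeric(Matrix::rowSums(counts)),
                              rownames(counts))
    lists <- matchedRandomSets(gene_set, totals, pool_size = pool_size,
                               n_lists = n_lists, seed = seed)
    pres <- as.matrix(counts > 0)
    nExpr <- Matrix::colSums(counts > 0)
    nullD <- matrix(NA_real_, n_lists, nrow(out))
    colnames(nullD) <- out$cluster
    clF <- factor(cl, levels = out$cluster)
    for (i in seq_len(n_lists)) {
        s <- colSums(pres[lists[i, ], , drop = FALSE]) /
            ifelse(nExpr > 0, nExpr, NA)
        nullD[i, ] <- .clusterD(s, clF)
    }
    out$perm_quantile <- vapply(seq_len(nrow(out)), function(j)
        mean(out$d[j] > nullD[, j]), numeric(1))
    out$significant <- out$q_z < alpha & out$perm_quantile >= perm_level
    rownames(out) <- NULL
    out
}

#' 2x2 category enrichment: sample odds ratio and Fisher's exact test
#'
#' Builds the table `a = hits_in_category`, `b = hits_total - a`,
#' `c = category_total - a`, `d = universe_total - a - b - c`, reports the
#' sample odds ratio `ad/bc` and the two-sided Fisher p obtained by
#' summing hypergeometric probabilities no larger than the observed
#' table's.
#'
#' @param hits_in_category,hits_total,category_total,universe_total
#'   Non-negative integers; `hits_in_category` cannot exceed
#'   `min(hits_total, category_total)`.
#' @return List `odds_ratio`, `p`, `table`, `zero_cell` (flag; the odds
#'   ratio is `Inf` or 0 when a cell is empty — no continuity correction).
#' @examples
#' categoryEnrichment2x2(8, 94, 64, 4096)$odds_ratio  # 6.55
#' @export
categoryEnrichment2x2 <- function(hits_in_category, hits_total,
                                  category_total, universe_total) {
    a <- hits_in_category
    if (a > min(hits_total, category_total))
        stop("hits_in_category exceeds a margin")
    b <- hits_total - a
    cc <- category_total - a
    d <- universe_total - a - b - cc
    if (d < 0) stop("universe smaller than the table it must contain")
    tab <- matrix(c(a, b, cc, d), 2L, byrow = TRUE)
    zero <- any(tab == 0)
    orr <- if (b * cc == 0) {
        if (a * d == 0) NaN else Inf
    } else (a * d) / (b * cc)
    p <- stats::fisher.test(tab)$p.value
    list(odds_ratio = orr, p = p, table = tab, zero_cell = zero)
}
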