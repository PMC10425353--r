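#' @rdname panelScore
#' @export
setMethod("panelScore", "ANY", function(x, panel) {
    if (length(panel) == 0) stop("empty panel")
    miss <- setdiff(panel, rownames(x))
    if (length(miss))
        stop("panel gene(s) absent from the matrix: ",
             paste(utils::head(miss, 5), collapse = ", "))
    as.integer(Matrix::colSums(x[panel, , drop = FALSE] > 0))
})

#' @rdname panelScore
#' @export
setMethod("panelScore", "BowerExperiment", function(x, panel) {
    panelScore(assay(x, "counts"), panel)
})

#' @rdname normalizedSetScore
#' @export
setMethod("normalizedSetScore", "ANY", function(x, geneSet) {
    if (length(geneSet) == 0) stop("empty gene set")
    nExpr <- Matrix::colSums(x > 0)
    nSet <- panelScore(x, geneSet)
    out <- ifelse(nExpr > 0, nSet / nExpr, NA_real_)
    if (anyNA(out))
        warning(sum(is.na(out)),
                " nuclei express no gene at all; scores set to NA")
    unname(out)
})

#' @rdname normalizedSetScore
#' @export
setMethod("normalizedSetScore", "BowerExperiment", function(x, geneSet) {
    normalizedSetScore(assay(x, "counts"), geneSet)
})

#' IEG screen parameters
#'
#' @param anchors Established immediate early genes anchoring the screen
#'   (default c-fos, egr1, npas4, spelled as in the count matrix).
#' @param min_positive_nuclei Minimum anchor-positive (and anchor-negative)
#'   nuclei for a cluster to be eligible (default 3).
#' @param min_pct Detection rule: a gene must be expressed in at least this
#'   fraction of nuclei in one of the two splits (default 1/57, the
#'   reciprocal of the smallest cluster size the default taxonomy assumes).
#' @param logfc_threshold Minimum |log fold change| between splits for a
#'   gene to be tested (default 0: no filter).
#' @param alpha Significance level for the per-cluster rank-sum test.
#' @param majority_denominator `"eligible"` (default) or `"all"`: whether
#'   the strict-majority rules count only clusters eligible for the anchor
#'   or every secondary cluster.
#' @return Named list of class `IegScreenParams`.
#' @export
iegScreenParams <- function(anchors = c("cfos", "egr1", "npas4"),
                            min_positive_nuclei = 3L,
                            min_pct = 1 / 57,
                            logfc_threshold = 0,
                            alpha = 0.05,
                            majority_denominator = c("eligible", "all")) {
    stopifnot(length(anchors) >= 1, alpha > 0, alpha < 1,
              min_pct >= 0, min_pct <= 1, min_positive_nuclei >= 1)
    structure(list(anchors = anchors,
                   min_positive_nuclei = as.integer(min_positive_nuclei),
                   min_pct = min_pct, logfc_threshold = logfc_threshold,
                   alpha = alpha,
                   majority_denominator = match.arg(majority_denominator)),
              class = "IegScreenParams")
}

# vectorized two-sided rank-sum test for every row of X between the nuclei
# in pos and the rest; normal approximation with tie correction and
# continuity correction. Returns p-values and the sign of the location
# shift (positive = upregulated in pos).
.rankSumRows <- function(X, pos) {
    n <- ncol(X)
    n1 <- sum(pos)
    n2 <- n - n1
    p <- numeric(nrow(X))
    sgn <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
        r <- rank(X[i, ])
        U <- sum(r[pos]) - n1 * (n1 + 1) / 2
        ties <- table(X[i, ])
        tieAdj <- sum(ties^3 - ties) / (n * (n - 1))
        v <- n1 * n2 / 12 * ((n + 1) - tieAdj)
        mu <- n1 * n2 / 2
        sgn[i] <- sign(U - mu)
        if (v <= 0) { p[i] <- 1; next }
        z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)
        p[i] <- 2 * stats::pnorm(-abs(z))
    }
    # exact test for small groups without ties
    if (n1 < 20 && n2 < 20) {
        for (i in seq_len(nrow(X))) {
            xi <- X[i, pos]; yi <- X[i, !pos]
            if (!anyDuplicated(c(xi, yi))) {
                wt <- stats::wilcox.test(xi, yi, exact = TRUE)
                p[i] <- wt$p.value
            }
        }
    }
    list(p = pmin(1, p), sign = sgn)
}

#' Anchor-based co-expression screen for IEG-like genes
#'
#' For each anchor gene and each secondary cluster with at least
#' `min_positive_nuclei` anchor-positive and anchor-negative nuclei, nuclei
#' are split by anchor detection (count > 0) and every candidate gene
#' passing the detection rule (expressed in at least `min_pct` of nuclei in
#' one of the splits) is compared between splits with a two-sided rank-sum
#' test; genes failing detection in a cluster receive p = 1 there. A gene
#' passes for an anchor when it is detected in a strict majority of the
#' anchor's eligible clusters AND upregulated (positive shift, p < alpha)
#' in a strict majority of those detected clusters. The returned panel is
#' the intersection over all anchors. Output is invariant to gene and
#' nucleus order.
#'
#' @param x A [BowerExperiment-class] (or a count matrix if `meta` given).
#' @param params An [iegScreenParams()].
#' @param meta Optional per-nucleus metadata with `cluster_secondary`
#'   (unneeded for a `BowerExperiment`).
#' @return List with `panel` (character vector), `per_anchor` (named list
#'   of per-anchor passing genes) and `eligible_clusters` (named list).
#' @export
anchorCoexpressionScreen <- function(x, params = iegScreenParams(),
                                     meta = NULL) {
    if (methods::is(x, "BowerExperiment")) {
        meta <- as.data.frame(colData(x))
        counts <- assay(x, "counts")
    } else counts <- x
    miss <- setdiff(params$anchors, rownames(counts))
    if (length(miss))
        stop("anchor(s) absent from the gene list: ",
             paste(miss, collapse = ", "))
    cl <- as.character(meta$cluster_secondary)
    clusters <- sort(unique(cl))
    cand <- setdiff(rownames(counts), params$anchors)
    perAnchor <- list()
    elig <- list()
    for (anchor in params$anchors) {
        aPos <- as.vector(counts[anchor, ] > 0)
        eligible <- clusters[vapply(clusters, function(cc) {
            idx <- cl == cc
            sum(aPos[idx]) >= params$min_positive_nuclei &&
                sum(!aPos[idx]) >= params$min_positive_nuclei
        }, logical(1))]
        elig[[anchor]] <- eligible
        if (!length(eligible)) {
            warning("no eligible clusters for anchor ", anchor)
            perAnchor[[anchor]] <- character()
            next
        }
        detected <- matrix(FALSE, length(cand), length(eligible),
                           dimnames = list(cand, eligible))
        upsig <- detected
        for (cc in eligible) {
            idx <- which(cl == cc)
            Xc <- as.matrix(counts[cand, idx, drop = FALSE])
            pos <- aPos[idx]
            pctPos <- rowMeans(Xc[, pos, drop = FALSE] > 0)
            pctNeg <- rowMeans(Xc[, !pos, drop = FALSE] > 0)
            det <- pmax(pctPos, pctNeg) >= params$min_pct
            if (params$logfc_threshold > 0) {
                lfc <- log(rowMeans(Xc[, pos, drop = FALSE]) + 1e-9) -
                    log(rowMeans(Xc[, !pos, drop = FALSE]) + 1e-9)
                det <- det & abs(lfc) >= params$logfc_threshold
            }
            detected[, cc] <- det
            if (any(det)) {
                rs <- .rankSumRows(Xc[det, , drop = FALSE], pos)
                upsig[det, cc] <- rs$p < params$alpha & rs$sign > 0
            }
        }
        denom <- if (params$majority_denominator == "eligible")
            length(eligible) else length(clusters)
        nDet <- rowSums(detected)
        passDet <- nDet > denom / 2
        passUp <- rowSums(upsig) > nDet / 2
        perAnchor[[anchor]] <- sort(cand[passDet & passUp])
    }
    panel <- Reduce(intersect, perAnchor)
    list(panel = sort(panel), per_anchor = perAnchor,
         eligible_clusters = elig)
}
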