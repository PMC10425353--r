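#' @include AllGenerics.R
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' BowerExperiment: nuclei-by-gene counts with behavioral metadata
#'
#' A thin extension of [SingleCellExperiment::SingleCellExperiment] holding a
#' genes x nuclei integer count matrix (assay `"counts"`), per-nucleus
#' metadata in `colData` (`subject_id`, `cluster_primary`,
#' `cluster_secondary`, optional `subcluster`) and the per-subject behavior
#' table in `metadata(x)$subjects`.
#'
#' Validity enforces the container invariants: unique gene and nucleus
#' identifiers, non-negative integer counts, every nucleus mapped to exactly
#' one subject and one primary/secondary cluster, and (when a subject table
#' is attached) every `subject_id` present there.
#'
#' @seealso [BowerExperiment()] for construction, [subjects()],
#'   [panelScore()], [normalizedSetScore()].
#' @export
setClass("BowerExperiment", contains = "SingleCellExperiment")

.validBowerExperiment <- function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- assay(object, "counts")
        v <- if (methods::is(cnt, "sparseMatrix")) cnt@x else as.vector(cnt)
        if (length(v) && (anyNA(v) || any(v < 0) || any(v != round(v))))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate nucleus identifiers")
    need <- c("subject_id", "cluster_primary", "cluster_secondary")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste("missing colData column(s):",
                            paste(miss, collapse = ", ")))
    else if (anyNA(colData(object)$subject_id))
        msg <- c(msg, "every nucleus must map to a subject")
    sub <- metadata(object)$subjects
    if (!is.null(sub) &&
        "subject_id" %in% colnames(colData(object))) {
        unknown <- setdiff(unique(colData(object)$subject_id),
                           sub$subject_id)
        if (length(unknown))
            msg <- c(msg, paste("nuclei assigned to unknown subject(s):",
                                paste(utils::head(unknown, 3),
                                      collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
}
setValidity("BowerExperiment", .validBowerExperiment)

#' Construct a BowerExperiment
#'
#' @param counts genes x nuclei matrix of non-negative integers (dense or
#'   sparse). Row and column names are the gene and nucleus identifiers.
#' @param meta `data.frame` of per-nucleus metadata with columns
#'   `nucleus_id`, `subject_id`, `cluster_primary`, `cluster_secondary`
#'   (and optionally `subcluster`). Rows are matched to `colnames(counts)`
#'   by `nucleus_id`.
#' @param subjects Optional validated subject table (see
#'   [validateSubjects()]).
#' @return A [BowerExperiment-class] object.
#' @examples
#' cm <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3),
#'                                             paste0("n", 1:2)))
#' meta <- data.frame(nucleus_id = c("n1", "n2"), subject_id = "s1",
#'                    cluster_primary = "1", cluster_secondary = "1.1")
#' be <- BowerExperiment(cm, meta)
#' @export
BowerExperiment <- function(counts, meta, subjects = NULL) {
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must carry gene and nucleus identifiers as dimnames")
    if (!is.data.frame(meta) || !"nucleus_id" %in% colnames(meta))
        stop("meta must be a data.frame with a nucleus_id column")
    idx <- match(colnames(counts), meta$nucleus_id)
    if (anyNA(idx))
        stop("metadata missing for ",
             sum(is.na(idx)), " nuclei (e.g. ",
             colnames(counts)[which(is.na(idx))[1L]], ")")
    cd <- DataFrame(meta[idx, setdiff(colnames(meta), "nucleus_id"),
                         drop = FALSE])
    rownames(cd) <- colnames(counts)
    sce <- SingleCellExperiment(assays = list(counts = counts), colData = cd)
    be <- methods::new("BowerExperiment", sce)
    if (!is.null(subjects)) subjects(be) <- subjects
    methods::validObject(be)
    be
}

#' @rdname subjects
#' @export
setMethod("subjects", "BowerExperiment",
          function(x) metadata(x)$subjects)

#' @rdname subjects
#' @export
setMethod("subjects<-", "BowerExperiment", function(x, value) {
    validateSubjects(value)
    metadata(x)$subjects <- value
    methods::validObject(x)
    x
})

#' @export
setMethod("show", "BowerExperiment", function(object) {
    methods::callNextMethod()
    sub <- metadata(object)$subjects
    if (is.null(sub)) {
        cat("subjects: none attached\n")
    } else {
        cat(sprintf("subjects: %d (%d building, %d control)\n",
                    nrow(sub), sum(sub$condition == "building"),
                    sum(sub$condition == "control")))
    }
})

#' Per-model mixed-model fit
#'
#' One fitted model of the competition suite: identifier, family, a
#' coefficient table (term, estimate, se, p) and a convergence flag.
#'
#' @export
setClass("ModelFit", representation(
    modelId = "character",
    family = "character",
    coefficients = "data.frame",
    converged = "logical"))

#' @export
setMethod("show", "ModelFit", function(object) {
    cat(sprintf("ModelFit '%s' (%s)%s\n", object@modelId, object@family,
                if (object@converged) "" else " [NOT CONVERGED]"))
    print(object@coefficients, digits = 3)
})

#' Result of the multi-model significance competition
#'
#' Holds, for one outcome and one focal covariate (building, quivering or
#' gsi), the per-model raw p-values of the focal term, the harmonic-mean
#' combined p, its FDR-adjusted value, and the dual-rule significance flag:
#' significant iff every per-model raw p < alpha AND the adjusted
#' harmonic-mean p < alpha.
#'
#' @export
setClass("CompetitionResult", representation(
    focal = "character",
    fits = "list",
    perModelP = "numeric",
    hmp = "numeric",
    hmpAdj = "numeric",
    alpha = "numeric",
    significant = "logical",
    converged = "logical"))

setValidity("CompetitionResult", function(object) {
    p <- object@perModelP
    if (length(p) && (any(p <= 0 | p > 1)))
        return("per-model p-values must lie in (0, 1]")
    ok <- isTRUE(object@significant) ==
        (length(p) > 0 && all(p < object@alpha) &&
         isTRUE(object@hmpAdj < object@alpha) && object@converged)
    if (!ok) return("significant flag inconsistent with the dual rule")
    TRUE
})

#' @export
setMethod("show", "CompetitionResult", function(object) {
    cat(sprintf("CompetitionResult focal = %s (%d models)\n",
                object@focal, length(object@perModelP)))
    cat(sprintf("  per-model p: %s\n",
                paste(signif(object@perModelP, 3), collapse = ", ")))
    cat(sprintf("  hmp = %.4g, hmp_adj = %.4g, significant = %s\n",
                object@hmp, object@hmpAdj, object@significant))
})

#' Signed co-expression model over a candidate gene set
#'
#' Stores the Pearson correlation matrix of the candidate genes, the signed
#' adjacency `a_ij = ((1 + cor_ij)/2)^beta`, the dissimilarity `1 - a`
#' (the adjacency is used directly as the topological overlap matrix), the
#' PAM partition chosen by maximal mean silhouette width, per-gene
#' silhouettes and medoids.
#'
#' @export
setClass("CoexpressionModel", representation(
    genes = "character",
    correlation = "matrix",
    power = "numeric",
    scaleFreeFit = "data.frame",
    adjacency = "matrix",
    dissimilarity = "matrix",
    partition = "integer",
    medoids = "character",
    silhouette = "numeric",
    k = "integer"))

setValidity("CoexpressionModel", function(object) {
    a <- object@adjacency
    if (length(a)) {
        if (any(a < -1e-8 | a > 1 + 1e-8))
            return("adjacency must lie in [0, 1]")
        if (max(abs(a - t(a))) > 1e-8)
            return("adjacency must be symmetric")
        if (max(abs(diag(a) - 1)) > 1e-8)
            return("adjacency diagonal must be 1")
        if (max(abs(diag(object@dissimilarity))) > 1e-8)
            return("dissimilarity diagonal must be 0")
    }
    if (length(object@silhouette) &&
        any(object@silhouette < -1 - 1e-8 | object@silhouette > 1 + 1e-8))
        return("silhouette widths must lie in [-1, 1]")
    TRUE
})

#' @export
setMethod("show", "CoexpressionModel", function(object) {
    cat(sprintf("CoexpressionModel: %d genes, power %g, k = %d modules\n",
                length(object@genes), object@power, object@k))
    cat(sprintf("  module sizes: %s\n",
                paste(table(object@partition), collapse = ", ")))
    cat(sprintf("  mean silhouette width: %.3f\n",
                mean(object@silhouette)))
})
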