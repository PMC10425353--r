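#' @import methods
NULL

#' Subject table accessor
#'
#' Retrieve the per-subject behavior table attached to a
#' [BowerExperiment].
#'
#' @param x A `BowerExperiment`.
#' @return A `data.frame` of subject records (one row per test animal).
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname subjects
#' @param value A validated subject `data.frame` (see [validateSubjects()]).
#' @export
setGeneric("subjects<-", function(x, value) standardGeneric("subjects<-"))

#' Per-nucleus panel score
#'
#' Count, for every nucleus, how many genes of a panel are detected
#' (count > 0). The same operation serves IEG scores, proneurogenic scores,
#' quiescence/cycling/differentiation state scores, and co-expression module
#' scores.
#'
#' @param x A `BowerExperiment` or a genes x nuclei count matrix
#'   (base matrix or `Matrix`).
#' @param panel Character vector of gene identifiers; all must be present.
#' @return Integer vector, one score in `0..length(panel)` per nucleus.
#' @export
setGeneric("panelScore", function(x, panel) standardGeneric("panelScore"))

#' Normalized gene-set score
#'
#' Per-nucleus fraction of expressed genes that belong to a gene set:
#' (number of set genes with count > 0) / (number of all genes with
#' count > 0). Nuclei expressing no gene at all get `NA` and are excluded
#' downstream.
#'
#' @param x A `BowerExperiment` or a genes x nuclei count matrix.
#' @param geneSet Character vector of gene identifiers (non-empty).
#' @return Numeric vector in `[0, 1]` (or `NA`) per nucleus.
#' @export
setGeneric("normalizedSetScore",
           function(x, geneSet) standardGeneric("normalizedSetScore"))
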