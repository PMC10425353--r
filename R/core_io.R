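#' @importFrom Matrix readMM writeMM sparseMatrix colSums rowSums t
#' @importFrom GenomicRanges GRanges strand start end seqnames
#' @importFrom IRanges IRanges
NULL

.log <- function(...) {
    if (isTRUE(getOption("bowerbrain.verbose", FALSE)))
        message("[bowerbrain] ", sprintf(...))
}

#' Validate a subject table
#'
#' A subject table has one row per test animal with columns `subject_id`,
#' `pair_id`, `pool_id`, `batch_id`, `condition` (`"building"` or
#' `"control"`), `bai` (Bower Activity Index, >= 0), `quiver_log`
#' (log-normalized quiver count), `gsi` (gonadosomatic index, % =
#' gonad mass / body mass x 100, >= 0) and `standard_length` (cm, > 0).
#' Each pair must contain exactly one building and one control subject.
#'
#' @param subjects A `data.frame`.
#' @return `subjects`, invisibly, if valid; otherwise an error.
#' @export
validateSubjects <- function(subjects) {
    need <- c("subject_id", "pair_id", "pool_id", "batch_id", "condition",
              "bai", "quiver_log", "gsi", "standard_length")
    miss <- setdiff(need, colnames(subjects))
    if (length(miss))
        stop("subject table missing column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(subjects$subject_id))
        stop("duplicate subject_id values")
    if (!all(subjects$condition %in% c("building", "control")))
        stop("condition must be 'building' or 'control'")
    if (any(subjects$gsi < 0)) stop("gsi must be >= 0")
    if (any(subjects$bai < 0)) stop("bai must be >= 0")
    if (any(subjects$standard_length <= 0))
        stop("standard_length must be > 0")
    bad <- vapply(split(subjects$condition, subjects$pair_id), function(cc) {
        !(length(cc) == 2L && sum(cc == "building") == 1L)
    }, logical(1))
    if (any(bad))
        stop("each pair must contain exactly one building and one control ",
             "subject (offending pair(s): ",
             paste(utils::head(names(bad)[bad], 3), collapse = ", "), ")")
    invisible(subjects)
}

#' Read a subject table from CSV
#'
#' @param path CSV file with the columns described in [validateSubjects()].
#' @return A validated subject `data.frame`.
#' @export
readSubjects <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    validateSubjects(df)
    df
}

#' Read per-nucleus metadata from CSV
#'
#' @param path CSV file with columns `nucleus_id`, `subject_id`,
#'   `cluster_primary`, `cluster_secondary` and optionally `subcluster`.
#' @return A `data.frame`.
#' @export
readNucleusMeta <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("nucleus_id", "subject_id", "cluster_primary",
              "cluster_secondary")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("nucleus metadata missing column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$nucleus_id)) stop("duplicate nucleus_id values")
    df
}

.checkCounts <- function(m) {
    v <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
    if (length(v) && (anyNA(v) || any(v < 0)))
        stop("count matrix contains negative or missing entries")
    if (length(v) && any(v != round(v)))
        stop("count matrix contains non-integer entries")
    invisible(m)
}

#' Read a genes x nuclei count matrix
#'
#' Two layouts are supported: a MatrixMarket triplet directory containing
#' `matrix.mtx`, `features.tsv` (gene identifiers, first column) and
#' `barcodes.tsv` (nucleus identifiers), or a dense CSV with gene
#' identifiers as row names and nucleus identifiers as header. The order of
#' the gene and barcode lists is preserved, and integer data round-trip
#' bit-exactly through [writeCountMatrix()].
#'
#' @param path Directory (mtx) or file (csv).
#' @param format `"mtx"` or `"csv"`.
#' @return A sparse `dgCMatrix` with dimnames.
#' @export
readCountMatrix <- function(path, format = c("mtx", "csv")) {
    format <- match.arg(format)
    if (format == "mtx") {
        fm <- file.path(path, "matrix.mtx")
        ff <- file.path(path, "features.tsv")
        fb <- file.path(path, "barcodes.tsv")
        for (f in c(fm, ff, fb))
            if (!file.exists(f)) stop("missing file: ", f)
        m <- methods::as(readMM(fm), "CsparseMatrix")
        feats <- utils::read.delim(ff, header = FALSE,
                                   colClasses = "character")[[1L]]
        bcs <- utils::read.delim(fb, header = FALSE,
                                 colClasses = "character")[[1L]]
        if (length(feats) != nrow(m) || length(bcs) != ncol(m))
            stop(sprintf(paste0("dimension mismatch: matrix is %d x %d but ",
                                "feature/barcode lists have %d / %d entries"),
                         nrow(m), ncol(m), length(feats), length(bcs)))
        dimnames(m) <- list(feats, bcs)
    } else {
        df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
        m <- methods::as(as.matrix(df), "CsparseMatrix")
    }
    if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
    if (anyDuplicated(colnames(m))) stop("duplicate nucleus identifiers")
    .checkCounts(m)
    m
}

#' Write a count matrix
#'
#' Inverse of [readCountMatrix()]; integer data round-trip bit-exactly.
#'
#' @param counts genes x nuclei matrix with dimnames.
#' @param path Target directory (mtx) or file (csv).
#' @param format `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(counts, path, format = c("mtx", "csv")) {
    format <- match.arg(format)
    .checkCounts(counts)
    if (format == "mtx") {
        dir.create(path, showWarnings = FALSE, recursive = TRUE)
        writeMM(methods::as(
            methods::as(counts, "CsparseMatrix"), "generalMatrix"),
            file.path(path, "matrix.mtx"))
        writeLines(rownames(counts), file.path(path, "features.tsv"))
        writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
    } else {
        utils::write.csv(as.matrix(counts), path)
    }
    invisible(path)
}

#' Quality-control thresholds
#'
#' Defaults follow standard snRNA-seq practice for this assay: nuclei with
#' fewer than 300 genes, fewer than 500 transcripts, or more than 5%
#' mitochondrial transcripts are treated as low quality; nuclei with more
#' than 3000 genes or 8000 transcripts are treated as putative doublets.
#'
#' @param min_genes,min_transcripts Lower bounds (strict: "fewer than").
#' @param max_mito_frac Upper bound on mitochondrial fraction (strict).
#' @param max_genes,max_transcripts Doublet bounds (strict: "more than").
#' @return A named list of class `QcThresholds`.
#' @export
qcThresholds <- function(min_genes = 300L, min_transcripts = 500L,
                         max_mito_frac = 0.05, max_genes = 3000L,
                         max_transcripts = 8000L) {
    stopifnot(min_genes < max_genes, min_transcripts < max_transcripts,
              max_mito_frac > 0, max_mito_frac < 1)
    structure(list(min_genes = min_genes, min_transcripts = min_transcripts,
                   max_mito_frac = max_mito_frac, max_genes = max_genes,
                   max_transcripts = max_transcripts),
              class = "QcThresholds")
}

#' Per-barcode QC statistics
#'
#' @param counts genes x nuclei count matrix.
#' @param mito_genes Character vector of genes flagged mitochondrial in the
#'   annotation (an input flag, never inferred from gene names).
#' @return `data.frame` with columns `barcode`, `n_genes`, `n_transcripts`,
#'   `mito_frac`.
#' @export
perBarcodeStats <- function(counts, mito_genes = character()) {
    nt <- Matrix::colSums(counts)
    ng <- Matrix::colSums(counts > 0)
    mt <- if (length(mito_genes)) {
        Matrix::colSums(counts[rownames(counts) %in% mito_genes, ,
                               drop = FALSE])
    } else rep(0, ncol(counts))
    data.frame(barcode = colnames(counts), n_genes = as.integer(ng),
               n_transcripts = as.integer(nt),
               mito_frac = ifelse(nt > 0, mt / nt, 0),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition barcodes into kept / low-quality / doublet sets
#'
#' Low-quality barcodes have `n_genes < min_genes` OR
#' `n_transcripts < min_transcripts` OR `mito_frac > max_mito_frac`.
#' Barcodes surviving that filter are flagged as doublets when
#' `n_genes > max_genes` OR `n_transcripts > max_transcripts`. A barcode
#' failing both filters is attributed to the low-quality set, which is
#' applied first. The three sets always partition the input.
#'
#' @param stats `data.frame` from [perBarcodeStats()] (columns `barcode`,
#'   `n_genes`, `n_transcripts`, `mito_frac`; no missing values).
#' @param thresholds A [qcThresholds()] object.
#' @return List with character vectors `kept`, `removed_low`,
#'   `removed_doublet` and a one-row `summary` data.frame
#'   (`n_total`, `n_kept`, `n_low`, `n_doublet`, `pct_low`, `pct_doublet`,
#'   percentages of the total).
#' @export
qcFilter <- function(stats, thresholds = qcThresholds()) {
    need <- c("barcode", "n_genes", "n_transcripts", "mito_frac")
    miss <- setdiff(need, colnames(stats))
    if (length(miss))
        stop("stats missing column(s): ", paste(miss, collapse = ", "))
    if (anyNA(stats[need]))
        stop("missing QC statistic for at least one barcode")
    if (any(stats$mito_frac < 0 | stats$mito_frac > 1))
        stop("mito_frac must lie in [0, 1]")
    th <- thresholds
    low <- stats$n_genes < th$min_genes |
        stats$n_transcripts < th$min_transcripts |
        stats$mito_frac > th$max_mito_frac
    dbl <- !low & (stats$n_genes > th$max_genes |
                   stats$n_transcripts > th$max_transcripts)
    kept <- !low & !dbl
    n <- nrow(stats)
    res <- list(kept = stats$barcode[kept],
                removed_low = stats$barcode[low],
                removed_doublet = stats$barcode[dbl],
                summary = data.frame(
                    n_total = n, n_kept = sum(kept), n_low = sum(low),
                    n_doublet = sum(dbl),
                    pct_low = 100 * sum(low) / n,
                    pct_doublet = 100 * sum(dbl) / n))
    .log("qcFilter: kept %d / %d barcodes (%d low-quality, %d doublet)",
         sum(kept), n, sum(low), sum(dbl))
    res
}

#' Read gene annotation as GRanges
#'
#' Coordinates are 1-based inclusive internally (GFF3 convention); BED input
#' is converted on read. Every gene must carry a defined strand.
#'
#' @param path GFF3 or BED file.
#' @param format `"gff3"` or `"bed"`.
#' @return `GRanges` with an mcols column `gene_id`.
#' @export
readGeneAnnotation <- function(path, format = c("gff3", "bed")) {
    format <- match.arg(format)
    gr <- rtracklayer::import(path, format = format)
    if (format == "gff3") {
        if ("type" %in% colnames(S4Vectors::mcols(gr)))
            gr <- gr[gr$type == "gene"]
        id <- if ("ID" %in% colnames(S4Vectors::mcols(gr))) gr$ID
              else gr$Name
    } else {
        id <- gr$name
    }
    if (is.null(id) || anyNA(id)) stop("annotation lacks gene identifiers")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = as.character(id))
    if (any(as.character(strand(gr)) == "*"))
        stop("strand must be defined for every gene")
    gr
}

#' Write gene annotation to GFF3
#'
#' @param genes `GRanges` with a `gene_id` column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(genes, path) {
    g <- genes
    g$type <- "gene"
    g$ID <- g$gene_id
    rtracklayer::export(g, path, format = "gff3")
    invisible(path)
}
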