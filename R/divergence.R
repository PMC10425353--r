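#' Filter variant sites on per-group missingness
#'
#' Biallelic sites are retained iff the fraction of species with missing
#' genotypes is below 0.5 in both groups ("50% or more" missing excludes
#' the site), and the site is polymorphic across the two groups combined.
#'
#' @param variants List with `sites` (`chrom`, `pos`, `ref`, `alt`) and
#'   `genotypes` (sites x species ALT dosages 0/1/2, `NA` missing), as
#'   produced by [simulateVariants()] or [readVcfGenotypes()].
#' @param group_a,group_b Character vectors of species (column) names;
#'   disjoint, each with at least two species.
#' @return `variants` restricted to retained sites, with attribute
#'   `kept_idx` (integer indices into the input).
#' @export
siteFilter <- function(variants, group_a, group_b) {
    gt <- variants$genotypes
    if (length(intersect(group_a, group_b)))
        stop("groups must be disjoint")
    if (length(group_a) < 2 || length(group_b) < 2)
        stop("each group needs at least two species")
    miss <- function(g) rowMeans(is.na(gt[, g, drop = FALSE]))
    ok <- miss(group_a) < 0.5 & miss(group_b) < 0.5
    both <- gt[, c(group_a, group_b), drop = FALSE]
    ac <- rowSums(both, na.rm = TRUE)
    an <- 2 * rowSums(!is.na(both))
    poly <- an > 0 & ac > 0 & ac < an
    keep <- which(ok & poly)
    if (!length(keep)) warning("no polymorphic sites retained")
    out <- variants
    out$sites <- variants$sites[keep, , drop = FALSE]
    out$genotypes <- gt[keep, , drop = FALSE]
    attr(out, "kept_idx") <- keep
    out
}

# Weir & Cockerham (1984) variance components per site for two diploid
# populations: a (among populations), b (among individuals within), c
# (within individuals), computed from sample sizes, allele frequencies and
# observed heterozygosities.
.wcComponents <- function(gt, group_a, group_b) {
    comp <- function(g) {
        sub <- gt[, g, drop = FALSE]
        n <- rowSums(!is.na(sub))
        p <- rowSums(sub, na.rm = TRUE) / (2 * n)
        h <- rowSums(sub == 1L, na.rm = TRUE) / n
        list(n = n, p = p, h = h)
    }
    A <- comp(group_a); B <- comp(group_b)
    r <- 2
    nbar <- (A$n + B$n) / r
    nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
    pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
    s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
    hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
    a <- nbar / nc *
        (s2 - 1 / (nbar - 1) *
             (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
             (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    usable <- A$n >= 1 & B$n >= 1 & nbar > 1
    data.frame(a = a, b = b, c = cc, usable = usable)
}

#' Windowed Weir-Cockerham F_ST between two groups
#'
#' Per-site variance components a/b/c are summed over non-overlapping
#' windows; the windowed (weighted) estimate is the ratio of sums
#' `sum(a) / sum(a + b + c)`, never the mean of per-site ratios. Species
#' are treated as diploid sampling units. Windows with no usable sites are
#' omitted; windows whose denominator sums to zero are omitted with a
#' warning.
#'
#' @param variants As in [siteFilter()] (apply the filter first).
#' @param group_a,group_b Species name vectors.
#' @param window_bp Window size in bp (default 10000; windows tile each
#'   contig from position 1).
#' @return `GRanges` of windows with mcols `fst`, `n_sites`, `a_sum`,
#'   `b_sum`, `c_sum`.
#' @export
weirFstWindows <- function(variants, group_a, group_b,
                           window_bp = 10000L) {
    comp <- .wcComponents(variants$genotypes, group_a, group_b)
    use <- comp$usable & is.finite(comp$a)
    sites <- variants$sites[use, , drop = FALSE]
    comp <- comp[use, , drop = FALSE]
    if (!nrow(sites)) stop("no usable sites")
    win <- (sites$pos - 1L) %/% window_bp
    key <- paste(sites$chrom, win, sep = ":")
    aS <- tapply(comp$a, key, sum)
    bS <- tapply(comp$b, key, sum)
    cS <- tapply(comp$c, key, sum)
    nS <- tapply(comp$a, key, length)
    ks <- names(aS)
    chrom <- sub(":[^:]*$", "", ks)
    w <- as.integer(sub(".*:", "", ks))
    denom <- aS + bS + cS
    drop <- denom == 0
    if (any(drop))
        warning(sum(drop), " window(s) with zero total variance omitted")
    gr <- GRanges(chrom[!drop],
                  IRanges(w[!drop] * window_bp + 1L,
                          (w[!drop] + 1L) * window_bp))
    gr$fst <- as.numeric(aS[!drop] / denom[!drop])
    gr$n_sites <- as.integer(nS[!drop])
    gr$a_sum <- as.numeric(aS[!drop])
    gr$b_sum <- as.numeric(bS[!drop])
    gr$c_sum <- as.numeric(cS[!drop])
    sort(gr)
}

#' Intersect two divergence contrasts
#'
#' Keeps the windows whose F_ST strictly exceeds the threshold in both
#' contrasts (matched by contig and start). Window tilings must agree in
#' width.
#'
#' @param pit_castle,rock_castle `GRanges` from [weirFstWindows()].
#' @param threshold Strict lower bound (default 0.20).
#' @return `GRanges` of retained windows with both F_ST values as mcols.
#' @export
castleDivergentWindows <- function(pit_castle, rock_castle,
                                   threshold = 0.20) {
    w1 <- unique(GenomicRanges::width(pit_castle))
    w2 <- unique(GenomicRanges::width(rock_castle))
    if (length(w1) != 1L || length(w2) != 1L || w1 != w2 ||
        any((start(pit_castle) - 1L) %% w1 != 0L) ||
        any((start(rock_castle) - 1L) %% w1 != 0L))
        stop("mismatched window tilings")
    k1 <- paste(seqnames(pit_castle), start(pit_castle))
    k2 <- paste(seqnames(rock_castle), start(rock_castle))
    common <- intersect(k1, k2)
    i1 <- match(common, k1); i2 <- match(common, k2)
    keep <- pit_castle$fst[i1] > threshold & rock_castle$fst[i2] > threshold
    out <- pit_castle[i1[keep]]
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        fst_pit_castle = pit_castle$fst[i1[keep]],
        fst_rock_castle = rock_castle$fst[i2[keep]])
    out
}

.resolveNearest <- function(sites, genes) {
    # nearest gene per site; ties broken by lower start, then gene_id
    ord <- order(as.character(seqnames(genes)), start(genes), genes$gene_id)
    g <- genes[ord]
    hits <- GenomicRanges::distanceToNearest(sites, g, select = "all")
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    pick <- tapply(seq_along(qh), qh, function(ii) ii[1L])
    idx <- rep(NA_integer_, length(sites))
    dist <- rep(NA_integer_, length(sites))
    idx[as.integer(names(pick))] <- sh[unlist(pick)]
    dist[as.integer(names(pick))] <-
        S4Vectors::mcols(hits)$distance[unlist(pick)]
    list(gene = g[ifelse(is.na(idx), 1L, idx)]$gene_id,
         geneIdx = match(ifelse(is.na(idx), NA,
                                g[ifelse(is.na(idx), 1L, idx)]$gene_id),
                         genes$gene_id),
         distance = dist, missing = is.na(idx))
}

#' Genes near genomic features
#'
#' Reports every gene whose interval lies strictly within `max_dist_bp` of
#' at least one feature (distance 0 when overlapping), with the minimum
#' distance per gene.
#'
#' @param features `GRanges` (e.g. divergent windows).
#' @param annotation `GRanges` with a `gene_id` mcols column.
#' @param max_dist_bp Strict distance bound (default 25000).
#' @return `data.frame` `gene_id`, `distance` (bp), sorted by gene_id.
#' @export
genesNearFeatures <- function(features, annotation, max_dist_bp = 25000L) {
    if (!length(features) || !length(annotation))
        return(data.frame(gene_id = character(), distance = integer()))
    hits <- GenomicRanges::distanceToNearest(annotation, features)
    d <- S4Vectors::mcols(hits)$distance
    qh <- S4Vectors::queryHits(hits)
    keep <- d < max_dist_bp
    out <- data.frame(gene_id = annotation$gene_id[qh[keep]],
                      distance = as.integer(d[keep]),
                      stringsAsFactors = FALSE)
    out[order(out$gene_id), , drop = FALSE]
}

#' Scan sequences for estrogen response elements
#'
#' Finds every occurrence of the palindromic inverted-repeat motif
#' `AGGTCA-NNN-TGACCT` (15 bp; the spacer must be unambiguous A/C/G/T and
#' ambiguity codes never match). Because the motif equals its own reverse
#' complement up to the spacer, a single-strand scan suffices. Each site
#' is assigned its nearest gene (ties: lower start, then gene_id) and
#' classified `intragenic` (overlapping the gene interval), `promoter`
#' (within 5 kb upstream of the strand-aware gene start), `distal`
#' (otherwise, nearer than 25 kb) or `unassigned`. A direct-repeat mode
#' (`AGGTCA-NNN-AGGTCA`, both strands scanned) is available behind the
#' `mode` flag.
#'
#' @param sequences A `DNAStringSet` (or path to a FASTA file).
#' @param annotation `GRanges` with `gene_id`, or `NULL` to skip
#'   classification.
#' @param promoter_bp,max_dist_bp Classification bounds (5 kb / 25 kb).
#' @param mode `"inverted"` (default) or `"direct"`.
#' @return `GRanges` of 15-bp sites with mcols `orientation`,
#'   `assigned_gene`, `klass`, `distance_bp`.
#' @export
ereScan <- function(sequences, annotation = NULL, promoter_bp = 5000L,
                    max_dist_bp = 25000L, mode = c("inverted", "direct")) {
    mode <- match.arg(mode)
    if (is.character(sequences))
        sequences <- Biostrings::readDNAStringSet(sequences)
    if (!length(sequences)) stop("empty sequence set")
    names(sequences) <- sub("\\s.*", "", names(sequences))
    allHits <- list()
    for (ct in names(sequences)) {
        sq <- toupper(as.character(sequences[[ct]]))
        if (mode == "inverted") {
            pos <- .motifHits(sq, "AGGTCA", "TGACCT")
            if (length(pos))
                allHits[[length(allHits) + 1L]] <- data.frame(
                    contig = ct, position = pos,
                    orientation = "inverted-repeat-fwd")
        } else {
            posF <- .motifHits(sq, "AGGTCA", "AGGTCA")
            posR <- .motifHits(sq, "TGACCT", "TGACCT")
            if (length(posF))
                allHits[[length(allHits) + 1L]] <- data.frame(
                    contig = ct, position = posF,
                    orientation = "direct-repeat-fwd")
            if (length(posR))
                allHits[[length(allHits) + 1L]] <- data.frame(
                    contig = ct, position = posR,
                    orientation = "direct-repeat-rev")
        }
    }
    if (!length(allHits)) {
        gr <- GRanges()
        gr$orientation <- character()
        return(gr)
    }
    df <- do.call(rbind, allHits)
    gr <- GRanges(df$contig, IRanges(df$position, df$position + 14L))
    gr$orientation <- df$orientation
    gr <- sort(gr)
    if (is.null(annotation) || !length(annotation)) {
        gr$assigned_gene <- NA_character_
        gr$klass <- "unassigned"
        gr$distance_bp <- NA_integer_
        return(gr)
    }
    nn <- .resolveNearest(gr, annotation)
    gr$assigned_gene <- ifelse(nn$missing, NA_character_, nn$gene)
    gr$distance_bp <- nn$distance
    klass <- rep("unassigned", length(gr))
    gidx <- match(gr$assigned_gene, annotation$gene_id)
    for (i in seq_along(gr)) {
        if (nn$missing[i]) next
        gene <- annotation[gidx[i]]
        d <- nn$distance[i]
        if (d == 0) { klass[i] <- "intragenic"; next }
        upstream <- if (as.character(strand(gene)) == "+")
            end(gr[i]) < start(gene) else start(gr[i]) > end(gene)
        if (upstream && d <= promoter_bp) klass[i] <- "promoter"
        else if (d < max_dist_bp) klass[i] <- "distal"
    }
    gr$klass <- klass
    gr
}

# positions where head + unambiguous 3-base spacer + tail occurs
.motifHits <- function(seqchar, head, tail) {
    s <- Biostrings::DNAString(seqchar)
    hits <- Biostrings::start(Biostrings::matchPattern(head, s))
    keep <- hits[hits + 14L <= length(s)]
    if (!length(keep)) return(integer(0))
    tails <- as.character(Biostrings::extractAt(
        s, IRanges::IRanges(keep + 9L, keep + 14L)))
    spacers <- as.character(Biostrings::extractAt(
        s, IRanges::IRanges(keep + 6L, keep + 8L)))
    keep[tails == tail & !grepl("[^ACGT]", spacers)]
}

#' Read genotypes from a VCF
#'
#' Minimal GT-field reader for biallelic SNPs; missing genotypes (`./.`)
#' become `NA`.
#'
#' @param path VCF file (plain text).
#' @return List with `sites`, `genotypes` (ALT dosage 0/1/2) — the
#'   structure [siteFilter()] and [weirFstWindows()] consume.
#' @export
readVcfGenotypes <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "."
    fix <- fix[biallelic, , drop = FALSE]
    gt <- gt[biallelic, , drop = FALSE]
    dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                     dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dosage[clean == "0/0"] <- 0L
    dosage[clean %in% c("0/1", "1/0")] <- 1L
    dosage[clean == "1/1"] <- 2L
    list(sites = data.frame(chrom = fix[, "CHROM"],
                            pos = as.integer(fix[, "POS"]),
                            ref = fix[, "REF"], alt = fix[, "ALT"],
                            stringsAsFactors = FALSE),
         genotypes = dosage)
}

#' Write a minimal VCF
#'
#' Plain-text VCF with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT and GT
#' columns; `NA` dosages become `./.`.
#'
#' @param variants List with `sites` and `genotypes`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeVcfMinimal <- function(variants, path) {
    gt <- variants$genotypes
    gtStr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt))
    gtStr[is.na(gt)] <- "./."
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", colnames(gt)),
                      collapse = "\t"))
    body <- apply(cbind(variants$sites$chrom, variants$sites$pos, ".",
                        variants$sites$ref, variants$sites$alt, ".",
                        "PASS", ".", "GT", gtStr), 1L, paste,
                  collapse = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}
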