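mkVariants <- function(gt, pos = NULL) {
    n <- nrow(gt)
    list(sites = data.frame(chrom = "contig1",
                            pos = if (is.null(pos)) seq_len(n) * 10L
                                  else pos,
                            ref = "A", alt = "G",
                            stringsAsFactors = FALSE),
         genotypes = gt)
}

test_that("the missingness filter applies the 50% rule per group", {
    castle <- sprintf("c%d", 1:9)
    pit <- sprintf("p%d", 1:11)
    gt <- matrix(1L, 3, 20, dimnames = list(NULL, c(pit, castle)))
    gt[, 1] <- c(0L, 0L, 2L)  # keep sites polymorphic
    gt[1, castle[1:5]] <- NA  # 5/9 = 56% missing -> excluded
    gt[2, castle[1:4]] <- NA  # 4/9 = 44%
    gt[2, pit[1:5]] <- NA     # 5/11 = 45% -> retained
    v <- mkVariants(gt)
    f <- siteFilter(v, pit, castle)
    expect_identical(attr(f, "kept_idx"), c(2L, 3L))
    expect_error(siteFilter(v, pit, c(pit[1], castle)), "disjoint")
    expect_error(siteFilter(v, "p1", castle), "two species")
    mono <- mkVariants(matrix(2L, 2, 20,
                              dimnames = list(NULL, c(pit, castle))))
    expect_warning(siteFilter(mono, pit, castle), "no polymorphic")
})

test_that("fixed differences give windowed F_ST of exactly 1", {
    ga <- sprintf("a%d", 1:6); gb <- sprintf("b%d", 1:6)
    gt <- cbind(matrix(0L, 5, 6), matrix(2L, 5, 6))
    colnames(gt) <- c(ga, gb)
    w <- weirFstWindows(mkVariants(gt), ga, gb, window_bp = 1000L)
    expect_length(w, 1L)
    expect_equal(w$fst, 1)
    expect_equal(w$n_sites, 5L)
})

test_that("per-site and windowed components equal the scalar oracle", {
    set.seed(8)
    for (i in 1:100) {
        na <- sample(2:6, 1); nb <- sample(2:6, 1)
        ns <- sample(1:5, 1)
        ga <- sprintf("a%d", seq_len(na)); gb <- sprintf("b%d", seq_len(nb))
        repeat {
            gt <- matrix(sample(0:2, ns * (na + nb), TRUE), ns,
                         dimnames = list(NULL, c(ga, gb)))
            if (i %% 3 == 0)  # a third of the cases carry missingness
                gt[sample(length(gt), ceiling(length(gt) / 10))] <- NA
            ok <- apply(gt, 1, function(r) {
                sum(!is.na(r[ga])) >= 1 && sum(!is.na(r[gb])) >= 1 &&
                    sum(r, na.rm = TRUE) > 0 &&
                    sum(r, na.rm = TRUE) < 2 * sum(!is.na(r))
            })
            if (all(ok)) break
        }
        v <- mkVariants(gt, pos = sort(sample(1:5000, ns)))
        w <- weirFstWindows(v, ga, gb, window_bp = 10000L)
        orac <- t(vapply(seq_len(ns), function(s)
            wcOracleSite(gt[s, ], ga, gb), numeric(3)))
        expect_equal(w$a_sum, sum(orac[, "a"]), tolerance = 1e-10)
        expect_equal(w$b_sum, sum(orac[, "b"]), tolerance = 1e-10)
        expect_equal(w$c_sum, sum(orac[, "c"]), tolerance = 1e-10)
        expect_equal(w$fst, sum(orac[, "a"]) / sum(orac),
                     tolerance = 1e-10)
    }
})

test_that("windowed F_ST centers on zero for identical populations", {
    set.seed(9)
    ga <- sprintf("a%d", 1:30); gb <- sprintf("b%d", 1:30)
    fst <- numeric(100)
    for (i in 1:100) {
        p <- stats::runif(40, 0.2, 0.8)
        gt <- cbind(matrix(stats::rbinom(40 * 30, 2, p), 40),
                    matrix(stats::rbinom(40 * 30, 2, p), 40))
        colnames(gt) <- c(ga, gb)
        v <- mkVariants(gt, pos = seq_len(40) * 10L)
        keep <- rowSums(gt) > 0 & rowSums(gt) < 2 * ncol(gt)
        v$sites <- v$sites[keep, ]; v$genotypes <- gt[keep, ]
        fst[i] <- weirFstWindows(v, ga, gb, window_bp = 10000L)$fst
    }
    expect_lt(abs(mean(fst)), 0.02)
})

test_that("F_ST is invariant to swapping REF/ALT labels at any site", {
    set.seed(10)
    ga <- sprintf("a%d", 1:5); gb <- sprintf("b%d", 1:5)
    gt <- matrix(sample(0:2, 40, TRUE), 4,
                 dimnames = list(NULL, c(ga, gb)))
    gt[1, 1] <- 1L  # ensure polymorphism
    v <- mkVariants(gt)
    w1 <- weirFstWindows(v, ga, gb, window_bp = 1000L)
    flip <- v
    flip$genotypes[2, ] <- 2L - flip$genotypes[2, ]
    w2 <- weirFstWindows(flip, ga, gb, window_bp = 1000L)
    expect_equal(w1$fst, w2$fst, tolerance = 1e-12)
})

test_that("dual-contrast intersection is strict at the 0.20 threshold", {
    mkWin <- function(starts, fst) {
        gr <- GenomicRanges::GRanges("contig1",
                                     IRanges::IRanges(starts,
                                                      starts + 9999L))
        gr$fst <- fst
        gr
    }
    pc <- mkWin(c(1, 10001, 20001), c(0.25, 0.25, 0.20))
    rc <- mkWin(c(1, 10001, 20001), c(0.25, 0.15, 0.30))
    cd <- castleDivergentWindows(pc, rc)
    expect_equal(GenomicRanges::start(cd), 1L)   # (.25,.25) kept;
    # (.25,.15) dropped; (.20,.30) dropped: "greater than 0.20" is strict
    expect_error(castleDivergentWindows(
        pc, mkWin(c(1, 5001), c(0.3, 0.3))), "mismatched")
})

test_that("gene proximity respects the strict 25 kb bound", {
    win <- GenomicRanges::GRanges("contig1",
                                  IRanges::IRanges(50001, 60000))
    genes <- GenomicRanges::GRanges(
        "contig1",
        IRanges::IRanges(c(25001, 24999, 70000, 100000),
                         c(25002, 25001, 80000, 100100)),
        strand = "+")
    genes$gene_id <- c("far", "nearEdge", "inside25", "out")
    # distances: 50001-25002-1 = 24998 (kept), 24999 (kept), 0-gap cases
    got <- genesNearFeatures(win, genes)
    expect_setequal(got$gene_id, c("far", "nearEdge", "inside25"))
    expect_equal(got$distance[got$gene_id == "nearEdge"], 24999L)
    g2 <- GenomicRanges::GRanges("contig1",
                                 IRanges::IRanges(24999, 25000),
                                 strand = "+")
    g2$gene_id <- "exactly25000"
    expect_equal(nrow(genesNearFeatures(win, g2)), 0L)  # distance 25000
})

test_that("gene proximity matches a brute-force distance oracle", {
    set.seed(11)
    for (i in 1:100) {
        nf <- sample(1:4, 1); ng <- sample(2:8, 1)
        fs <- sort(sample(1:200000, nf))
        feats <- GenomicRanges::GRanges(
            "c", IRanges::IRanges(fs, fs + sample(500:5000, nf, TRUE)))
        gs <- sort(sample(1:200000, ng))
        genes <- GenomicRanges::GRanges(
            "c", IRanges::IRanges(gs, gs + sample(100:3000, ng, TRUE)),
            strand = "+")
        genes$gene_id <- sprintf("g%02d", seq_len(ng))
        got <- genesNearFeatures(feats, genes, max_dist_bp = 25000L)
        # oracle: all-pairs interval gap
        gap <- function(a1, a2, b1, b2) {
            if (a2 >= b1 && b2 >= a1) 0L
            else if (b1 > a2) b1 - a2 - 1L else a1 - b2 - 1L
        }
        want <- character()
        for (j in seq_len(ng)) {
            dmin <- min(vapply(seq_len(nf), function(k)
                gap(GenomicRanges::start(genes)[j],
                    GenomicRanges::end(genes)[j],
                    GenomicRanges::start(feats)[k],
                    GenomicRanges::end(feats)[k]), integer(1)))
            if (dmin < 25000L) want <- c(want, genes$gene_id[j])
        }
        expect_setequal(got$gene_id, want)
    }
})

test_that("ERE scanning finds planted palindromic sites on either strand", {
    left <- paste(rep("ACT", 40), collapse = "")
    right <- paste(rep("GTC", 40), collapse = "")
    site <- "AGGTCAGCATGACCT"
    sq <- Biostrings::DNAStringSet(paste0(
        substr(left, 1, 100), site, right))
    names(sq) <- "c1"
    hits <- ereScan(sq)
    expect_equal(GenomicRanges::start(hits), 101L)
    # the reverse complement of the full sequence carries the same count
    rc <- Biostrings::reverseComplement(sq)
    names(rc) <- "c1"
    expect_length(ereScan(rc), length(hits))
    # ambiguity codes never match
    sqN <- Biostrings::DNAStringSet(paste0(
        substr(left, 1, 100), "AGGTCAGNATGACCT", right))
    names(sqN) <- "c1"
    expect_length(ereScan(sqN), 0L)
    expect_error(ereScan(Biostrings::DNAStringSet()), "empty")
})

test_that("ERE sites are classified by strand-aware gene geometry", {
    cfg <- simulationConfig(seed = 61)
    mot <- data.frame(contig = "contig1",
                      position = c(2000,   # 4 kb upstream of plusGene
                                   10500,  # inside plusGene
                                   26000,  # 4 kb upstream of minusGene end
                                   65000)) # >= 25 kb from everything
    g <- simulateGenome(cfg, motifs = mot,
                        contig_lengths = c(contig1 = 70000))
    genes <- GenomicRanges::GRanges(
        "contig1", IRanges::IRanges(c(6014, 20000), c(12000, 22000)),
        strand = c("+", "-"))
    genes$gene_id <- c("plusGene", "minusGene")
    es <- ereScan(g$seqs, genes)
    k <- stats::setNames(es$klass, GenomicRanges::start(es))
    expect_equal(unname(k["2000"]), "promoter")
    expect_equal(unname(k["10500"]), "intragenic")
    expect_equal(unname(k["26000"]), "promoter")  # upstream of a - gene
    expect_equal(unname(k["65000"]), "unassigned")
    # direct-repeat mode reports both orientations
    dr <- Biostrings::DNAStringSet(paste0(
        paste(rep("ACT", 40), collapse = ""), "AGGTCATTTAGGTCA",
        paste(rep("TCA", 40), collapse = "")))
    names(dr) <- "c1"
    hits <- ereScan(dr, mode = "direct")
    expect_true("direct-repeat-fwd" %in% hits$orientation)
})

test_that("the full divergence chain recovers exactly the planted genes", {
    for (s in 1:3) {
        cfg <- simulationConfig(seed = 2600 + s, n_sites = 1200,
                                contig_length = 120000)
        win <- data.frame(start = 50001, end = 60000)
        v <- simulateVariants(cfg, divergent_windows = win)
        grp <- split(names(v$groups), v$groups)
        f1 <- weirFstWindows(siteFilter(v, grp$pit, grp$castle),
                             grp$pit, grp$castle)
        f2 <- weirFstWindows(siteFilter(v, grp$rock, grp$castle),
                             grp$rock, grp$castle)
        cd <- castleDivergentWindows(f1, f2)
        genes <- GenomicRanges::GRanges(
            "contig1",
            IRanges::IRanges(c(30001, 52000, 70001, 100001),
                             c(31000, 53000, 71000, 101000)),
            strand = "+")
        genes$gene_id <- c("near24k", "inWindow", "within25k", "farAway")
        got <- genesNearFeatures(cd, genes)
        # planted window 50001-60000: near24k gap 19000, inWindow overlap,
        # within25k gap 10000, farAway gap 40000
        expect_setequal(got$gene_id, c("near24k", "inWindow", "within25k"))
    }
})

test_that("VCF writing and reading round-trip genotypes", {
    cfg <- simulationConfig(seed = 71, n_sites = 50,
                            contig_length = 5000, missing_rate = 0.1)
    v <- simulateVariants(cfg)
    f <- tempfile(fileext = ".vcf")
    writeVcfMinimal(v, f)
    back <- readVcfGenotypes(f)
    expect_equal(back$sites$pos, v$sites$pos)
    expect_equal(unname(back$genotypes), unname(v$genotypes))
})
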