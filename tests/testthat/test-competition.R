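fakeFitter <- function(pByModel) {
    function(terms) {
        id <- paste(terms, collapse = "+")
        p <- pByModel[[id]]
        methods::new("ModelFit", modelId = id, family = "beta-binomial",
                     coefficients = data.frame(
                         term = c("(Intercept)", terms),
                         estimate = 0.1, se = 0.05,
                         p = c(0.5, rep(p, length(terms)))),
                     converged = TRUE)
    }
}

buildingModels <- c("bai+quiver_log", "bai+gsi", "bai+quiver_log+gsi",
                    "condition+quiver_log", "condition+gsi",
                    "condition+quiver_log+gsi")

test_that("the harmonic mean p follows its closed form and symmetry", {
    expect_equal(harmonicMeanP(c(0.2, 0.2, 0.2)), 0.2)
    expect_equal(harmonicMeanP(c(0.01, 0.04, 0.2)), 3 / 130)
    expect_equal(harmonicMeanP(c(0.2, 0.01, 0.04)), 3 / 130)
    expect_equal(harmonicMeanP(0.37), 0.37)
    expect_error(harmonicMeanP(c(0, 0.1)), "lie in")
    expect_error(harmonicMeanP(c(0.1, 1.2)), "lie in")
    expect_error(harmonicMeanP(numeric()), "at least one")
    expect_equal(harmonicMeanP(c(0.01, 0.1), weights = c(0.5, 0.5)),
                 1 / (0.5 / 0.01 + 0.5 / 0.1))
    expect_error(harmonicMeanP(c(0.01, 0.1), weights = c(0.7, 0.5)),
                 "sum to 1")
})

test_that("raw hmp is bracketed by min(p)/L and max(p) (property)", {
    set.seed(3)
    for (i in 1:50) {
        L <- sample(2:8, 1)
        p <- stats::runif(L, 1e-6, 1)
        h <- harmonicMeanP(p)
        expect_lte(h, max(p))
        expect_gte(h, min(p) / L)
    }
})

test_that("the asymptotically exact transform behaves like a p-value", {
    p <- c(0.01, 0.04, 0.2)
    raw <- harmonicMeanP(p)
    ex <- harmonicMeanP(p, mode = "asymptotically_exact")
    expect_gte(ex, raw)
    expect_lte(ex, 1)
    # more extreme inputs give a smaller exact p (monotonicity)
    ex2 <- harmonicMeanP(p / 10, mode = "asymptotically_exact")
    expect_lt(ex2, ex)
})

test_that("BH adjustment matches the hand-derived example and is stable", {
    expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(fdrAdjust(0.2), 0.2)
    expect_equal(fdrAdjust(rep(0.07, 5)), rep(0.07, 5))
    set.seed(1)
    p <- stats::runif(20)
    perm <- sample(20)
    expect_equal(fdrAdjust(p)[perm], fdrAdjust(p[perm]))  # order-invariant
    expect_true(all(fdrAdjust(p) >= p))
    expect_error(fdrAdjust(numeric()), "empty")
})

test_that("the dual rule is the exact stated conjunction", {
    # all focal p at 0.5: not significant
    pAll <- stats::setNames(rep(0.5, 6), buildingModels)
    r <- runCompetition(fakeFitter(as.list(pAll)), "building")
    expect_false(r@significant)
    # significant in 5 of 6 models only: not significant even with tiny hmp
    p5 <- stats::setNames(c(rep(1e-6, 5), 0.2), buildingModels)
    r5 <- runCompetition(fakeFitter(as.list(p5)), "building")
    expect_false(r5@significant)
    expect_lt(r5@hmp, 0.05)
    # small everywhere: significant
    pSig <- stats::setNames(rep(0.01, 6), buildingModels)
    rs <- runCompetition(fakeFitter(as.list(pSig)), "building")
    expect_true(rs@significant)
    expect_equal(unname(rs@perModelP), rep(0.01, 6))
    # across-outcome adjustment can revoke significance
    adj <- adjustCompetition(list(rs, r5, r))
    expect_equal(vapply(adj, function(x) x@hmpAdj, numeric(1)),
                 fdrAdjust(c(rs@hmp, r5@hmp, r@hmp)))
})

test_that("quivering and gsi competitions pick their model subsets", {
    pmap <- list()
    for (id in c(buildingModels, "quiver_log+gsi")) pmap[[id]] <- 0.01
    rq <- runCompetition(fakeFitter(pmap), "quivering")
    expect_length(rq@perModelP, 5L)
    rg <- runCompetition(fakeFitter(pmap), "gsi")
    expect_length(rg@perModelP, 5L)
    expect_true(rq@significant && rg@significant)
})

test_that("beta-binomial fits reduce to plain binomial regression", {
    cfg <- simulationConfig(seed = 77, n_pairs = 10,
                            nuclei_per_subject = 100, n_genes = 40,
                            overdispersion = list(rho = 0,
                                                  nb_dispersion = 0.5),
                            random_effect_sds = list(subject = 0, pool = 0,
                                                     batch = 0, pair = 0),
                            effect_sizes = list(build = 0.4, quiver = 0,
                                                gsi = 0))
    sub <- simulateSubjects(cfg)
    be <- simulateCounts(sub, cfg, build_covariate = "condition")
    meta <- as.data.frame(SummarizedExperiment::colData(be))
    sc <- panelScore(be, S4Vectors::metadata(be)$panel)
    mf <- suppressWarnings(fitBetaBinomialMixed(sc, 25, sub, meta))
    sIdx <- match(meta$subject_id, sub$subject_id)
    S <- tapply(sc, factor(sIdx, levels = seq_len(20)), sum)
    nN <- tabulate(sIdx, 20)
    orac <- stats::glm(
        cbind(S, nN * 25 - S) ~ I(as.numeric(condition == "building")) +
            quiver_log, family = stats::binomial(), data = sub)
    expect_lt(max(abs(mf@coefficients$estimate - stats::coef(orac))), 1e-3)
})

test_that("NB fits reduce to Poisson regression at zero dispersion", {
    cfg <- simulationConfig(seed = 78, n_pairs = 10,
                            nuclei_per_subject = 100, n_genes = 40,
                            overdispersion = list(rho = 0,
                                                  nb_dispersion = 0),
                            random_effect_sds = list(subject = 0, pool = 0,
                                                     batch = 0, pair = 0))
    sub <- simulateSubjects(cfg)
    be <- simulateCounts(sub, cfg, build_covariate = "condition")
    meta <- as.data.frame(SummarizedExperiment::colData(be))
    cm <- SummarizedExperiment::assay(be)
    bg <- grep("^gene", rownames(cm), value = TRUE)
    gene <- bg[which.max(Matrix::rowSums(cm[bg, ]))]
    y <- as.integer(cm[gene, ])
    mf <- suppressWarnings(fitCountMixed(y, rep(1, length(y)), sub, meta))
    sIdx <- match(meta$subject_id, sub$subject_id)
    S <- as.vector(tapply(y, factor(sIdx, levels = seq_len(20)), sum))
    nN <- tabulate(sIdx, 20)
    orac <- stats::glm(
        S ~ I(as.numeric(condition == "building")) + quiver_log +
            offset(log(nN)), family = stats::poisson(), data = sub)
    expect_lt(max(abs(mf@coefficients$estimate - stats::coef(orac))), 1e-3)
})

test_that("the pair-observation filter refuses incompletely observed genes", {
    fx <- smallExperiment(seed = 41, n_pairs = 4, nuclei = 40,
                          n_genes = 40)
    y <- integer(ncol(fx$be))   # never observed anywhere
    expect_error(fitCountMixed(y, rep(1, length(y)), fx$subjects, fx$meta),
                 "pair-observation filter")
})

test_that("a planted NB building effect is recovered", {
    est <- numeric(30)
    for (i in seq_len(30)) {
        cfg <- simulationConfig(seed = 8800 + i, n_pairs = 19,
                                nuclei_per_subject = 50, n_genes = 30,
                                deg = list(n_genes = 1,
                                           log_fc = log(2)))
        sub <- simulateSubjects(cfg)
        be <- simulateCounts(sub, cfg, build_covariate = "condition")
        meta <- as.data.frame(SummarizedExperiment::colData(be))
        gene <- S4Vectors::metadata(be)$deg_genes
        y <- as.integer(SummarizedExperiment::assay(be)[gene, ])
        if (!all(tapply(y > 0, sub$pair_id[match(meta$subject_id,
                                                 sub$subject_id)], any)))
            next
        mf <- suppressWarnings(
            fitCountMixed(y, rep(1, length(y)), sub, meta))
        ct <- mf@coefficients
        est[i] <- ct$estimate[ct$term == "condition"]
    }
    est <- est[est != 0]
    expect_gte(length(est), 20)
    expect_lt(abs(mean(est) - log(2)), 0.15)
})

test_that("competition disentangles a planted building effect", {
    hits <- matrix(FALSE, 8, 3,
                   dimnames = list(NULL, c("building", "quivering", "gsi")))
    for (i in seq_len(8)) {
        cfg <- simulationConfig(seed = 9100 + i, n_pairs = 19,
                                nuclei_per_subject = 200, n_genes = 30,
                                effect_sizes = list(build = 0.5,
                                                    quiver = 0, gsi = 0))
        sub <- simulateSubjects(cfg)
        be <- simulateCounts(sub, cfg, build_covariate = "bai")
        meta <- as.data.frame(SummarizedExperiment::colData(be))
        sc <- panelScore(be, S4Vectors::metadata(be)$panel)
        fitter <- function(terms) suppressWarnings(
            fitBetaBinomialMixed(sc, 25, sub, meta, fixed_terms = terms))
        res <- adjustCompetition(lapply(
            c("building", "quivering", "gsi"),
            function(f) runCompetition(fitter, f)))
        hits[i, ] <- vapply(res, function(r) r@significant, logical(1))
    }
    expect_gte(mean(hits[, "building"]), 0.8)
    expect_lte(mean(hits[, "quivering"]), 0.2)
    expect_lte(mean(hits[, "gsi"]), 0.2)
})

test_that("proportion shifts are detected and nulls stay quiet", {
    flagged <- 0L
    for (i in seq_len(10)) {
        fx <- smallExperiment(seed = 880 + i, n_pairs = 19, nuclei = 80,
                              n_genes = 30, n_clusters_secondary = 8)
        cd <- SummarizedExperiment::colData(fx$be)
        # plant a +50% relative shift of building nuclei into cluster c03
        set.seed(1234 + i)
        bld <- cd$subject_id %in%
            fx$subjects$subject_id[fx$subjects$condition == "building"]
        pool <- which(bld & cd$cluster_primary ==
                          unique(cd$cluster_primary[cd$cluster_secondary ==
                                                        "c03"]))
        inC <- pool[cd$cluster_secondary[pool] == "c03"]
        move <- sample(setdiff(pool, inC),
                       size = round(0.5 * length(inC)))
        cd$cluster_secondary[move] <- "c03"
        SummarizedExperiment::colData(fx$be) <- cd
        pc <- suppressWarnings(proportionCompetition(fx$be, "secondary"))
        row <- pc[pc$cluster == "c03", ]
        flagged <- flagged + (row$significant && row$estimate > 0)
    }
    expect_gte(flagged, 8L)
    # null: no planted shift, q < 0.05 calls are rare
    fp <- 0L
    for (i in seq_len(10)) {
        fx <- smallExperiment(seed = 990 + i, n_pairs = 19, nuclei = 80,
                              n_genes = 30, n_clusters_secondary = 20,
                              n_clusters_primary = 2)
        pc <- suppressWarnings(proportionCompetition(fx$be, "secondary"))
        fp <- fp + sum(pc$significant)
    }
    expect_lte(fp / 10, 1)
})

test_that("a subject lacking a cluster contributes zeros, not an error", {
    fx <- smallExperiment(seed = 55, n_pairs = 4, nuclei = 30,
                          n_genes = 30, n_clusters_secondary = 4,
                          n_clusters_primary = 2)
    cd <- SummarizedExperiment::colData(fx$be)
    s1 <- fx$subjects$subject_id[1]
    cd$cluster_secondary[cd$subject_id == s1 &
                             cd$cluster_secondary == "c01"] <- "c02"
    SummarizedExperiment::colData(fx$be) <- cd
    expect_s3_class(suppressWarnings(
        proportionCompetition(fx$be, "secondary")), "data.frame")
})

test_that("the lagged profile localizes a planted 60-min kernel", {
    # the strict argmax = 45-75 bin claim is checked at full replication in
    # the acceptance suite; here: the peak bin always overlaps the kernel
    hits <- 0L
    for (i in seq_len(12)) {
        cfg <- simulationConfig(seed = 7100 + i, n_pairs = 19,
                                nuclei_per_subject = 80, n_genes = 30,
                                effect_sizes = list(build = 0.6,
                                                    quiver = 0, gsi = 0))
        sub <- simulateSubjects(cfg)
        bins <- simulateBehaviorBins(sub, cfg, step_minutes = 15)
        be <- simulateCounts(sub, cfg, behavior_bins = bins)
        meta <- as.data.frame(SummarizedExperiment::colData(be))
        sc <- panelScore(be, S4Vectors::metadata(be)$panel)
        lp <- suppressWarnings(
            laggedAssociationProfile(sc, 25, sub, meta, bins))
        hits <- hits + (lp$peak_bin %in% c("bin_30_60", "bin_45_75",
                                           "bin_60_90"))
    }
    expect_gte(hits, 11L)
})

test_that("the lagged profile is flat when behavior is uninformative", {
    flat <- 0L
    for (i in seq_len(8)) {
        cfg <- simulationConfig(seed = 7300 + i, n_pairs = 19,
                                nuclei_per_subject = 80, n_genes = 30)
        sub <- simulateSubjects(cfg)
        bins <- simulateBehaviorBins(sub, cfg, step_minutes = 15)
        be <- simulateCounts(sub, cfg)   # scores ignore the bins
        meta <- as.data.frame(SummarizedExperiment::colData(be))
        sc <- panelScore(be, S4Vectors::metadata(be)$panel)
        lp <- suppressWarnings(
            laggedAssociationProfile(sc, 25, sub, meta, bins))
        flat <- flat + (max(lp$profile$z) - min(lp$profile$z) < 2)
    }
    expect_gte(flat, 5L)
    # empty bins give a finite, zero-valued covariate
    cfg <- simulationConfig(seed = 7301, n_pairs = 4,
                            nuclei_per_subject = 40, n_genes = 30)
    sub <- simulateSubjects(cfg)
    be <- simulateCounts(sub, cfg)
    meta <- as.data.frame(SummarizedExperiment::colData(be))
    sc <- panelScore(be, S4Vectors::metadata(be)$panel)
    bins <- matrix(0, nrow(sub), 3,
                   dimnames = list(sub$subject_id,
                                   c("bin_0_30", "bin_30_60", "bin_60_90")))
    lp <- suppressWarnings(
        laggedAssociationProfile(sc, 25, sub, meta, bins))
    expect_true(all(is.finite(lp$profile$z)))
    expect_error(laggedAssociationProfile(sc, 25, sub, meta,
                                          bins[, 1, drop = FALSE]),
                 "at least 2 bins")
})

test_that("direction bias uses a Yates-corrected goodness of fit", {
    r <- directionBiasTest(342, 358)
    o <- stats::prop.test(342, 358, p = 0.5, correct = TRUE)
    expect_equal(r$statistic, unname(o$statistic))
    expect_equal(r$p, o$p.value)
    expect_gt(directionBiasTest(10, 20)$p, 0.9)
})
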