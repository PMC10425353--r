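#' @importFrom stats rnorm rpois rbinom rgamma rbeta runif plogis qlogis
#'   rnbinom rmultinom
NULL

.withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    force(expr)
}

#' Simulation configuration
#'
#' One object carries every knob of the synthetic-data generators. Defaults
#' encode the study conditions the analyses assume: 19 building/control
#' pairs pooled 3-4 telencephala at a time into ten pools, a 25-gene
#' IEG-like panel anchored by c-fos/egr1/npas4, beta-binomial overdispersion
#' of per-nucleus detection, nested random intercepts, 10 kb divergence
#' windows over a pit (11) / castle (9) / rock (7) species design, and a
#' palindromic estrogen-response-element motif.
#'
#' @param seed Integer; fixed seed implies byte-identical outputs.
#' @param n_pairs Number of building/control pairs (default 19).
#' @param n_clusters_primary,n_clusters_secondary Cluster counts for the
#'   synthetic taxonomy (secondary clusters nest in primary ones).
#' @param n_genes Total genes, panel included.
#' @param nuclei_per_subject Expected nuclei per subject (totals drawn
#'   Dirichlet-multinomial around equal shares, concentration 50).
#' @param ieg_panel_size Size of the IEG-like panel (default 25; the first
#'   three panel genes are the anchors `cfos`, `egr1`, `npas4`).
#' @param base_detect_prob Baseline per-nucleus detection probability of a
#'   panel gene (default 0.1, giving realistic low scores).
#' @param effect_sizes Named list of logit-scale effects of the behavior
#'   covariates on panel-gene detection: `build` (per SD of BAI, or per
#'   condition contrast), `quiver`, `gsi` (per SD).
#' @param behavior_effects Named list of group differences used when drawing
#'   subjects: `bai` (projection units), `quiver` (log-rate difference),
#'   `gsi` (percentage points).
#' @param overdispersion List with `rho` (beta-binomial intra-nucleus
#'   correlation, default 0.05) and `nb_dispersion` (NB dispersion of
#'   background genes, default 0.5).
#' @param random_effect_sds Named list of SDs for the nested random
#'   intercepts (`subject`, `pool`, `batch`, `pair`).
#' @param module List `n_genes`, `cor`, `background_cor` describing a
#'   planted co-expression module among background genes, or `n_genes = 0`
#'   for none. `cor` is the target pairwise correlation of module genes on
#'   the log1p expression scale (latent-factor loadings are calibrated
#'   against the analytic log1p variance of the count model);
#'   `background_cor` (default 0.15) is a weak factor shared by the
#'   non-module candidate genes, emulating common cell-state covariation.
#'   When a module is planted, all background genes are drawn moderately
#'   expressed, emulating a candidate set of well-detected genes.
#' @param deg List `n_genes`, `log_fc` describing planted building DEGs
#'   among background genes.
#' @param marker_sets Optional list of planted presence-level marker sets;
#'   each element is a list `name`, `n_genes`, `cluster` (a secondary
#'   cluster label), `multiplier` (fold change of detection probability in
#'   that cluster).
#' @param lag_kernel List `peak_min`, `sd_min`: Gaussian lag kernel through
#'   which binned behavior drives panel-gene detection (peak 60 min, the
#'   transcript-peak delay of immediate early genes).
#' @param grid List `nrow`, `ncol`, `pixel_area_cm2`, `noise_sd` for depth
#'   trials (default 60 x 60 at ~0.01 cm^2 px, sensor noise 0.02 cm).
#' @param n_species_per_group Named integer vector for the variant
#'   simulator (`pit`, `castle`, `rock`).
#' @param n_sites,contig_length,window_bp Variant-table geometry.
#' @param missing_rate Per-site, per-species genotype missingness.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             n_pairs = 19L,
                             n_clusters_primary = 4L,
                             n_clusters_secondary = 8L,
                             n_genes = 300L,
                             nuclei_per_subject = 200L,
                             ieg_panel_size = 25L,
                             base_detect_prob = 0.1,
                             effect_sizes = list(build = 0, quiver = 0,
                                                 gsi = 0),
                             behavior_effects = list(bai = 1.5, quiver = 0.8,
                                                     gsi = 0.3),
                             overdispersion = list(rho = 0.05,
                                                   nb_dispersion = 0.5),
                             random_effect_sds = list(subject = 0.1,
                                                      pool = 0.05,
                                                      batch = 0.05,
                                                      pair = 0.05),
                             module = list(n_genes = 0L, cor = 0.8,
                                           background_cor = 0.15),
                             deg = list(n_genes = 0L, log_fc = 0),
                             marker_sets = NULL,
                             lag_kernel = list(peak_min = 60, sd_min = 15),
                             grid = list(nrow = 60L, ncol = 60L,
                                         pixel_area_cm2 = 0.01,
                                         noise_sd = 0.02),
                             n_species_per_group = c(pit = 11L, castle = 9L,
                                                     rock = 7L),
                             n_sites = 400L,
                             contig_length = 100000L,
                             window_bp = 10000L,
                             missing_rate = 0) {
    cfg <- as.list(environment())
    stopifnot(cfg$n_pairs >= 1, cfg$ieg_panel_size >= 3,
              cfg$n_genes > cfg$ieg_panel_size,
              cfg$overdispersion$rho >= 0, cfg$overdispersion$rho < 1,
              cfg$overdispersion$nb_dispersion >= 0,
              all(unlist(cfg$random_effect_sds) >= 0),
              cfg$base_detect_prob > 0, cfg$base_detect_prob < 1)
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields in the file override [simulationConfig()] defaults.
#'
#' @param path YAML file.
#' @return A `SimulationConfig`.
#' @export
readSimulationConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(simulationConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    do.call(simulationConfig, vals)
}

#' Simulate paired building/control subjects
#'
#' Draws `2 * n_pairs` subjects, one building and one control per pair,
#' with building subjects shifted upwards in BAI, quivering and GSI by the
#' configured group effects, and nesting labels assigned: same-condition
#' pairs of subjects share pools (3-4 subjects per pool) and paired
#' building/control pools share a batch.
#'
#' @param config A [simulationConfig()].
#' @return A validated subject `data.frame` (see [validateSubjects()]).
#' @export
simulateSubjects <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    .log("simulateSubjects: seed=%g n_pairs=%g", config$seed,
         config$n_pairs)
    .withSeed(config$seed + 1L, {
        np <- config$n_pairs
        be <- config$behavior_effects
        build <- rep(c(TRUE, FALSE), np)
        pair <- rep(seq_len(np), each = 2L)
        # pools hold 3-4 same-condition subjects; batches pair the pools
        pools_per_cond <- max(1L, ceiling(np / 4L))
        pool_of_pair <- ((pair - 1L) %% pools_per_cond) + 1L
        pool <- ifelse(build, paste0("poolB", pool_of_pair),
                       paste0("poolC", pool_of_pair))
        batch <- paste0("batch", pool_of_pair)
        bai <- pmax(0, rnorm(2 * np, mean = 0.4 + be$bai * build, sd = 0.4))
        quiv <- rpois(2 * np, lambda = exp(1.5 + be$quiver * build))
        gsi <- pmax(0, rnorm(2 * np, mean = 0.5 + be$gsi * build, sd = 0.15))
        sl <- pmax(3, rnorm(2 * np, mean = 6.5, sd = 0.5))
        df <- data.frame(
            subject_id = sprintf("s%02d", seq_len(2 * np)),
            pair_id = sprintf("pair%02d", pair),
            pool_id = pool, batch_id = batch,
            condition = ifelse(build, "building", "control"),
            bai = bai, quiver_log = log1p(quiv), gsi = gsi,
            standard_length = sl, stringsAsFactors = FALSE)
        validateSubjects(df)
        df
    })
}

#' Simulate binned behavior counts per subject
#'
#' Building-event times (minutes before collection) are drawn per subject
#' — concentrated around `config$lag_kernel$peak_min` for building
#' subjects, sparse and uniform for controls — and counted on a tiled or
#' sliding bin grid over the window.
#'
#' @param subjects Subject table.
#' @param config A [simulationConfig()].
#' @param window_minutes,bin_minutes Window and bin widths (minutes).
#' @param step_minutes Bin start spacing (equal to `bin_minutes` for tiled
#'   bins; smaller values give sliding bins).
#' @return Matrix subjects x bins of building-event counts; column names
#'   `bin_<start>_<end>` give the interval in minutes before collection.
#' @export
simulateBehaviorBins <- function(subjects, config, window_minutes = 100,
                                 bin_minutes = 30,
                                 step_minutes = bin_minutes) {
    .withSeed(config$seed + 7L, {
        starts <- seq(0, window_minutes - 1e-9, by = step_minutes)
        ends <- pmin(starts + bin_minutes, window_minutes)
        n <- nrow(subjects)
        lagm <- config$lag_kernel$peak_min
        lags <- config$lag_kernel$sd_min
        bins <- matrix(0, n, length(starts))
        times <- vector("list", n)
        for (i in seq_len(n)) {
            if (subjects$condition[i] == "building") {
                tt <- rnorm(rpois(1L, 60), lagm, lags)
                tt <- tt[tt >= 0 & tt <= window_minutes]
            } else {
                tt <- runif(rpois(1L, 3), 0, window_minutes)
            }
            times[[i]] <- tt
            bins[i, ] <- vapply(seq_along(starts), function(b)
                sum(tt >= starts[b] & tt < ends[b]), numeric(1))
        }
        colnames(bins) <- sprintf("bin_%g_%g", starts, ends)
        rownames(bins) <- subjects$subject_id
        names(times) <- subjects$subject_id
        attr(bins, "event_times") <- times
        bins
    })
}

.dirichlet <- function(n, alpha) {
    g <- rgamma(n, shape = alpha, rate = 1)
    g / sum(g)
}

# analytic variance of log1p(X) for X ~ NB(mu, dispersion) (Poisson if 0)
.varLog1pNB <- function(mu, disp) {
    kmax <- ceiling(mu + 12 * sqrt(mu + disp * mu^2)) + 5
    k <- 0:kmax
    p <- if (disp > 0) stats::dnbinom(k, mu = mu, size = 1 / disp)
         else stats::dpois(k, mu)
    p <- p / sum(p)
    m <- sum(p * log1p(k))
    sum(p * (log1p(k) - m)^2)
}

# latent loading such that two genes sharing a N(0,1) factor z, with
# counts NB(mu0 * exp(lam * z - lam^2/2), disp), have pairwise correlation
# ~ r on the log1p scale. Deterministic: Gauss-Hermite over z, NB pmf in k.
.calibrateLoading <- function(r, mu0, disp, nodes = 31L) {
    gh <- function(n) {  # Golub-Welsch nodes/weights for E[f(Z)], Z~N(0,1)
        i <- seq_len(n - 1L)
        J <- matrix(0, n, n)
        J[cbind(i, i + 1L)] <- sqrt(i)
        J <- J + t(J)
        ev <- eigen(J, symmetric = TRUE)
        list(x = ev$values, w = ev$vectors[1L, ]^2)
    }
    g <- gh(nodes)
    icc <- function(lam) {
        mu <- mu0 * exp(lam * g$x - lam^2 / 2)
        mcond <- vcond <- numeric(length(mu))
        for (j in seq_along(mu)) {
            if (mu[j] > 5e3) {  # lognormal regime; weights out here are tiny
                mcond[j] <- log(mu[j])
                vcond[j] <- log(1 + disp)
                next
            }
            kmax <- ceiling(mu[j] + 12 * sqrt(mu[j] + disp * mu[j]^2)) + 5
            k <- 0:kmax
            p <- if (disp > 0) stats::dnbinom(k, mu = mu[j],
                                              size = 1 / disp)
                 else stats::dpois(k, mu[j])
            p <- p / sum(p)
            mcond[j] <- sum(p * log1p(k))
            vcond[j] <- sum(p * (log1p(k) - mcond[j])^2)
        }
        mbar <- sum(g$w * mcond)
        vb <- sum(g$w * (mcond - mbar)^2)
        vw <- sum(g$w * vcond)
        vb / (vb + vw)
    }
    if (icc(4) < r) return(4)
    stats::uniroot(function(l) icc(l) - r, c(0.01, 4), tol = 1e-4)$root
}

#' Simulate a nuclei x gene count experiment
#'
#' Nuclei are assigned to subjects (Dirichlet-multinomial around equal
#' shares, mimicking pooling of size-matched telencephala) and to nested
#' primary/secondary clusters. Panel genes (anchors included) are detected
#' with per-nucleus probability logit-linear in the subject's behavior
#' covariates plus nested random intercepts, with beta-binomial
#' overdispersion `rho` shared by the panel within each nucleus. Background
#' genes are negative-binomial with a log link, lognormal library-size
#' offsets, optional planted building DEGs, an optional planted
#' latent-factor co-expression module, and optional presence-level marker
#' sets boosted in chosen clusters.
#'
#' @param subjects Subject table from [simulateSubjects()].
#' @param config A [simulationConfig()].
#' @param behavior_bins Optional subjects x bins matrix (from
#'   [simulateBehaviorBins()]); when given, the building covariate driving
#'   panel detection is the lag-kernel-weighted sum of binned counts rather
#'   than BAI.
#' @param build_covariate `"bai"` (standardized BAI) or `"condition"`
#'   (binary contrast) as the driver of the planted building effect.
#' @return A [BowerExperiment-class] with the subject table attached.
#' @export
simulateCounts <- function(subjects, config, behavior_bins = NULL,
                           build_covariate = c("bai", "condition")) {
    stopifnot(nrow(subjects) > 0)
    build_covariate <- match.arg(build_covariate)
    .log(paste("simulateCounts: seed=%g n_genes=%g nuclei_per_subject=%g",
               "rho=%g driver=%s"), config$seed, config$n_genes,
         config$nuclei_per_subject, config$overdispersion$rho,
         build_covariate)
    .withSeed(config$seed + 2L, {
        ns <- nrow(subjects)
        totalN <- ns * config$nuclei_per_subject
        shares <- .dirichlet(ns, 50)
        nPer <- as.integer(rmultinom(1, totalN, shares))
        if (any(nPer == 0))
            stop("a subject received zero nuclei; increase ",
                 "nuclei_per_subject")
        subjIdx <- rep(seq_len(ns), nPer)
        N <- length(subjIdx)

        nc2 <- config$n_clusters_secondary
        nc1 <- config$n_clusters_primary
        if (nc2 < nc1) stop("need at least one secondary cluster per primary")
        parent <- sort(rep_len(seq_len(nc1), nc2))
        clProb <- .dirichlet(nc2, 20)
        cl2 <- sample.int(nc2, N, replace = TRUE, prob = clProb)
        cl1 <- parent[cl2]

        m <- config$ieg_panel_size
        panel <- c("cfos", "egr1", "npas4",
                   sprintf("ieg%02d", seq_len(m - 3L) + 3L))
        nbg <- config$n_genes - m
        bg <- sprintf("gene%04d", seq_len(nbg))
        genes <- c(panel, bg)

        es <- config$effect_sizes
        zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
                          else x * 0
        xq <- zs(subjects$quiver_log)
        xg <- zs(subjects$gsi)
        xb <- if (!is.null(behavior_bins)) {
            # the generative exposure weights each event by the lag kernel
            # directly; the analysis bin grid never enters the model
            times <- attr(behavior_bins, "event_times")
            lagm <- config$lag_kernel$peak_min
            lags <- config$lag_kernel$sd_min
            drive <- if (!is.null(times)) {
                vapply(subjects$subject_id, function(s)
                    sum(exp(-(times[[s]] - lagm)^2 / (2 * lags^2))),
                    numeric(1))
            } else {
                starts <- as.numeric(sub("bin_([0-9.]+)_.*", "\\1",
                                         colnames(behavior_bins)))
                ends <- as.numeric(sub(".*_([0-9.]+)$", "\\1",
                                       colnames(behavior_bins)))
                centers <- (starts + ends) / 2
                w <- exp(-(centers - lagm)^2 / (2 * lags^2))
                as.numeric(behavior_bins %*% w)
            }
            zs(drive)
        } else if (build_covariate == "bai") zs(subjects$bai)
        else as.numeric(subjects$condition == "building")

        sds <- config$random_effect_sds
        uS <- rnorm(ns, 0, sds$subject)
        uPool <- rnorm(length(unique(subjects$pool_id)), 0, sds$pool)
        names(uPool) <- unique(subjects$pool_id)
        uBatch <- rnorm(length(unique(subjects$batch_id)), 0, sds$batch)
        names(uBatch) <- unique(subjects$batch_id)
        uPair <- rnorm(length(unique(subjects$pair_id)), 0, sds$pair)
        names(uPair) <- unique(subjects$pair_id)
        eta <- qlogis(config$base_detect_prob) +
            es$build * xb + es$quiver * xq + es$gsi * xg +
            uS + uPool[subjects$pool_id] + uBatch[subjects$batch_id] +
            uPair[subjects$pair_id]
        mu <- plogis(eta)[subjIdx]

        rho <- config$overdispersion$rho
        pNuc <- if (rho > 0) {
            a <- mu * (1 - rho) / rho
            b <- (1 - mu) * (1 - rho) / rho
            rbeta(N, a, b)
        } else mu
        panelHits <- matrix(rbinom(N * m, 1L, rep(pNuc, each = m)),
                            nrow = m)
        panelCounts <- panelHits * (1L + matrix(rpois(N * m, 0.5), nrow = m))

        sf <- exp(rnorm(N, 0, 0.3))
        disp <- config$overdispersion$nb_dispersion
        hasModule <- config$module$n_genes > 0
        baseMu <- if (hasModule) exp(rnorm(nbg, log(2), 0.5))
                  else exp(rnorm(nbg, log(0.2), 1))
        lfc <- numeric(nbg)
        if (config$deg$n_genes > 0)
            lfc[seq_len(config$deg$n_genes)] <- config$deg$log_fc
        lam <- lamW <- numeric(nbg)
        modIdx <- integer(0)
        if (hasModule) {
            modIdx <- config$deg$n_genes + seq_len(config$module$n_genes)
            # loadings calibrated (deterministically) so the configured
            # correlations are realized on the log1p expression scale
            lam[modIdx] <- .calibrateLoading(config$module$cor, 3, disp)
            baseMu[modIdx] <- 3
            rb <- config$module$background_cor
            if (rb > 0)
                lamW[setdiff(seq_len(nbg), modIdx)] <-
                    .calibrateLoading(rb, 2, disp)
        }
        z <- rnorm(N)
        w <- rnorm(N)
        cond <- as.numeric(subjects$condition == "building")[subjIdx]
        logMu <- matrix(log(sf), nbg, N, byrow = TRUE) + log(baseMu) -
            (lam^2 + lamW^2) / 2 + outer(lfc, cond) +
            outer(lam, z) + outer(lamW, w)
        muBg <- exp(logMu)
        bgCounts <- if (disp > 0)
            matrix(rnbinom(nbg * N, mu = muBg, size = 1 / disp), nrow = nbg)
        else matrix(rpois(nbg * N, muBg), nrow = nbg)

        # planted presence-level marker sets in chosen secondary clusters
        markerGenes <- list()
        if (!is.null(config$marker_sets)) {
            used <- config$deg$n_genes + config$module$n_genes
            for (msSet in config$marker_sets) {
                idx <- used + seq_len(msSet$n_genes)
                if (max(idx) > nbg) stop("marker sets exceed gene count")
                used <- max(idx)
                p0 <- config$base_detect_prob
                inCl <- cl2 == match(msSet$cluster,
                                     sprintf("c%02d", seq_len(nc2)))
                if (all(!inCl))
                    inCl <- cl2 == suppressWarnings(as.integer(msSet$cluster))
                p <- ifelse(inCl, pmin(1, msSet$multiplier * p0), p0)
                hits <- matrix(rbinom(msSet$n_genes * N, 1L,
                                      rep(p, each = msSet$n_genes)),
                               nrow = msSet$n_genes)
                bgCounts[idx, ] <- hits *
                    (1L + matrix(rpois(msSet$n_genes * N, 0.5),
                                 nrow = msSet$n_genes))
                markerGenes[[msSet$name]] <- bg[idx]
            }
        }

        counts <- rbind(panelCounts, bgCounts)
        dimnames(counts) <- list(genes, sprintf("nuc%06d", seq_len(N)))
        meta <- data.frame(
            nucleus_id = colnames(counts),
            subject_id = subjects$subject_id[subjIdx],
            cluster_primary = sprintf("p%02d", cl1),
            cluster_secondary = sprintf("c%02d", cl2),
            stringsAsFactors = FALSE)
        be <- BowerExperiment(methods::as(counts, "CsparseMatrix"), meta,
                              subjects = subjects)
        metadata(be)$panel <- panel
        metadata(be)$module_genes <- bg[modIdx]
        metadata(be)$deg_genes <- bg[seq_len(config$deg$n_genes)]
        metadata(be)$marker_genes <- markerGenes
        be
    })
}

.plantRect <- function(nr, nc, row0, col0, n_px) {
    h <- max(1L, floor(sqrt(n_px)))
    w <- ceiling(n_px / h)
    if (row0 + h - 1L > nr || col0 + w - 1L > nc)
        stop("planted region larger than grid or out of bounds")
    cells <- expand.grid(r = row0:(row0 + h - 1L), c = col0:(col0 + w - 1L))
    cells <- cells[order(cells$c, cells$r), ][seq_len(n_px), ]
    cbind(cells$r, cells$c)
}

#' Simulate a depth trial: elevation-change grid plus event stream
#'
#' The grid contains planted contiguous regions of exact pixel counts and
#' signed elevation change, i.i.d. Gaussian sensor noise, and masked holes
#' (`NA`). The event stream carries timestamped building (scoop/spit/
#' multiple) and quiver events over the window preceding collection, with
#' an optional burst interval concentrating building events.
#'
#' @param config A [simulationConfig()].
#' @param regions `data.frame` with columns `row`, `col`, `n_px`, `dh`
#'   (cm); one planted rectangle-ish region per row. `NULL` for none.
#' @param n_holes,hole_px Number and size of masked holes.
#' @param n_build_events,n_quiver_events Event totals.
#' @param burst Length-2 numeric: minutes-before-collection interval into
#'   which building events are concentrated, or `NULL` for uniform.
#' @param window_minutes Trial window (minutes before collection).
#' @return List with `grid` (matrix, cm elevation change, `NA` = hole),
#'   `events` (`data.frame` `t_min` minutes before collection, `type`),
#'   and `pixel_area_cm2`.
#' @export
simulateDepthTrial <- function(config, regions = NULL, n_holes = 0L,
                               hole_px = 3L, n_build_events = 50L,
                               n_quiver_events = 10L, burst = NULL,
                               window_minutes = 100) {
    .withSeed(config$seed + 3L, {
        g <- config$grid
        grid <- matrix(rnorm(g$nrow * g$ncol, 0, g$noise_sd),
                       g$nrow, g$ncol)
        if (!is.null(regions)) {
            for (i in seq_len(nrow(regions))) {
                px <- .plantRect(g$nrow, g$ncol, regions$row[i],
                                 regions$col[i], regions$n_px[i])
                grid[px] <- grid[px] + regions$dh[i]
            }
        }
        if (n_holes > 0) {
            for (i in seq_len(n_holes)) {
                r0 <- sample.int(g$nrow - 1L, 1L)
                c0 <- sample.int(g$ncol - 1L, 1L)
                px <- .plantRect(g$nrow, g$ncol, r0, c0,
                                 min(hole_px,
                                     (g$nrow - r0 + 1L) * (g$ncol - c0 + 1L)))
                grid[px] <- NA_real_
            }
        }
        tb <- if (is.null(burst)) runif(n_build_events, 0, window_minutes)
              else runif(n_build_events, burst[1], burst[2])
        tq <- runif(n_quiver_events, 0, window_minutes)
        events <- data.frame(
            t_min = c(tb, tq),
            type = c(sample(c("scoop", "spit", "multiple"),
                            n_build_events, replace = TRUE),
                     rep("quiver", n_quiver_events)),
            stringsAsFactors = FALSE)
        events <- events[order(events$t_min), , drop = FALSE]
        rownames(events) <- NULL
        list(grid = grid, events = events,
             pixel_area_cm2 = g$pixel_area_cm2)
    })
}

#' Simulate a multi-species variant table
#'
#' Biallelic sites with group allele frequencies drawn around a shared
#' background frequency; inside planted windows the castle group is pushed
#' to frequency `castle_freq` while pit and rock sit at `other_freq`, so
#' both pit-castle and rock-castle contrasts diverge. Species are diploid;
#' genotypes are drawn binomially from the group frequency, with optional
#' per-site missingness.
#'
#' @param config A [simulationConfig()].
#' @param divergent_windows `data.frame` with columns `start`, `end`
#'   (1-based bp on the single synthetic contig), or `NULL`.
#' @param castle_freq,other_freq Planted-window allele frequencies.
#' @return List with `sites` (`data.frame` `chrom`, `pos`, `ref`, `alt`),
#'   `genotypes` (sites x species integer matrix of ALT-allele dosages
#'   0/1/2, `NA` = missing) and `groups` (named character vector mapping
#'   species to `pit`/`castle`/`rock`).
#' @export
simulateVariants <- function(config, divergent_windows = NULL,
                             castle_freq = 0.95, other_freq = 0.05) {
    nspg <- config$n_species_per_group
    if (any(nspg < 2L)) stop("need at least two species per group")
    .log("simulateVariants: seed=%g n_sites=%g missing_rate=%g",
         config$seed, config$n_sites, config$missing_rate)
    .withSeed(config$seed + 4L, {
        groups <- rep(names(nspg), nspg)
        species <- sprintf("%s%02d", groups, unlist(lapply(nspg, seq_len)))
        names(groups) <- species
        pos <- sort(sample.int(config$contig_length, config$n_sites))
        p0 <- runif(config$n_sites, 0.1, 0.9)
        freq <- sapply(names(nspg), function(g)
            rbeta(config$n_sites, p0 * 60, (1 - p0) * 60))
        if (!is.null(divergent_windows)) {
            inWin <- rep(FALSE, config$n_sites)
            for (i in seq_len(nrow(divergent_windows)))
                inWin <- inWin | (pos >= divergent_windows$start[i] &
                                  pos <= divergent_windows$end[i])
            freq[inWin, "castle"] <- castle_freq
            freq[inWin, c("pit", "rock")] <- other_freq
        }
        gt <- matrix(NA_integer_, config$n_sites, length(species),
                     dimnames = list(NULL, species))
        for (j in seq_along(species))
            gt[, j] <- rbinom(config$n_sites, 2L, freq[, groups[j]])
        if (config$missing_rate > 0) {
            drop <- matrix(runif(length(gt)) < config$missing_rate,
                           nrow(gt), ncol(gt))
            gt[drop] <- NA_integer_
        }
        bases <- c("A", "C", "G", "T")
        ref <- sample(bases, config$n_sites, replace = TRUE)
        alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
        list(sites = data.frame(chrom = "contig1", pos = pos, ref = ref,
                                alt = unname(alt),
                                stringsAsFactors = FALSE),
             genotypes = gt, groups = groups)
    })
}

.ereMotifHits <- function(seqchar) {
    .motifHits(seqchar, "AGGTCA", "TGACCT")
}

#' Simulate a genome with planted ERE motifs and genes
#'
#' Background sequence is uniform random ACGT, scrubbed of chance
#' occurrences of the inverted-repeat estrogen-response-element motif by
#' rejection; motifs are then planted at the recorded positions (15 bp:
#' `AGGTCA` + 3-base spacer + `TGACCT`) and genes at the recorded
#' intervals. Planted features must not overlap.
#'
#' @param config A [simulationConfig()].
#' @param motifs `data.frame` with columns `contig`, `position` (1-based
#'   start of the 15-bp site), or `NULL`.
#' @param genes `GRanges` with `gene_id` mcols (intervals to annotate), or
#'   `NULL`.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return List with `seqs` (`DNAStringSet`) and `genes` (`GRanges`).
#' @export
simulateGenome <- function(config, motifs = NULL, genes = NULL,
                           contig_lengths = c(contig1 = 50000L)) {
    .withSeed(config$seed + 5L, {
        if (!is.null(motifs)) {
            ir <- IRanges::IRanges(motifs$position, motifs$position + 14L)
            grp <- motifs$contig
            for (ct in unique(grp)) {
                irc <- ir[grp == ct]
                if (length(IRanges::findOverlaps(irc, irc)) > length(irc))
                    stop("overlapping planted motifs")
                if (any(IRanges::end(irc) > contig_lengths[[ct]]))
                    stop("planted motif extends beyond its contig")
            }
        }
        seqs <- lapply(names(contig_lengths), function(ct) {
            n <- contig_lengths[[ct]]
            x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
            sq <- paste(x, collapse = "")
            repeat {  # rejection: scrub chance motif occurrences
                hits <- .ereMotifHits(sq)
                if (!length(hits)) break
                for (h in hits) {
                    cur <- substr(sq, h, h)
                    substr(sq, h, h) <- sample(setdiff(c("A", "C", "G", "T"),
                                                       cur), 1L)
                }
            }
            if (!is.null(motifs)) {
                mh <- motifs[motifs$contig == ct, , drop = FALSE]
                for (i in seq_len(nrow(mh))) {
                    spacer <- paste(sample(c("A", "C", "G", "T"), 3L,
                                           replace = TRUE), collapse = "")
                    substr(sq, mh$position[i], mh$position[i] + 14L) <-
                        paste0("AGGTCA", spacer, "TGACCT")
                }
            }
            sq
        })
        dss <- Biostrings::DNAStringSet(unlist(seqs))
        names(dss) <- names(contig_lengths)
        list(seqs = dss, genes = genes)
    })
}
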