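#' Harmonic-mean p-value
#'
#' Combines possibly dependent p-values. In `raw` mode the (weighted)
#' harmonic mean `sum(w) / sum(w / p)` is returned (equal weights by
#' default), the form entering the dual significance rule. In
#' `asymptotically_exact` mode the harmonic mean is transformed through its
#' heavy-tailed null distribution (the reciprocal of the harmonic mean of L
#' uniform p-values is asymptotically Landau with location
#' `log(L) + 0.874` and scale `pi/2`), so the result is itself a valid
#' p-value.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param weights Optional weights summing to 1.
#' @param mode `"raw"` (default) or `"asymptotically_exact"`.
#' @return A single combined p-value.
#' @examples
#' harmonicMeanP(c(0.01, 0.04, 0.2))  # 3/130
#' @export
harmonicMeanP <- function(p, weights = NULL,
                          mode = c("raw", "asymptotically_exact")) {
    mode <- match.arg(mode)
    if (length(p) == 0) stop("need at least one p-value")
    if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
    if (is.null(weights)) weights <- rep(1 / length(p), length(p))
    if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
    hm <- 1 / sum(weights / p)
    if (mode == "raw") return(hm)
    L <- length(p)
    if (L == 1L) return(p)
    x <- (1 / hm - (log(L) + 0.874)) / (pi / 2)
    # upper tail of the standard Landau distribution
    tail <- stats::integrate(function(t)
        exp(-t * log(t) - x * t) * sin(pi * t) / t,
        lower = 0, upper = Inf, rel.tol = 1e-9,
        stop.on.error = FALSE)$value / pi
    min(1, max(tail, 0))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values: monotone, each at least its raw p, idempotent.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same order as input.
#' @export
fdrAdjust <- function(p) {
    if (length(p) == 0) stop("empty p-value list")
    if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

.covariateData <- function(subjects, fixed_terms) {
    df <- data.frame(row.names = seq_len(nrow(subjects)))
    for (term in fixed_terms) {
        df[[term]] <- switch(term,
            bai = subjects$bai,
            condition = as.numeric(subjects$condition == "building"),
            quiver_log = subjects$quiver_log,
            gsi = subjects$gsi,
            stop("unknown fixed term: ", term))
    }
    df$pool_id <- factor(subjects$pool_id)
    df$batch_id <- factor(subjects$batch_id)
    df$pair_id <- factor(subjects$pair_id)
    df$subject_id <- factor(subjects$subject_id)
    df
}

# containment-style degrees of freedom: for each fixed term, the number of
# levels of the coarsest grouping factor within which the term is constant
# (the level at which the covariate is really replicated), minus the number
# of fixed-effect parameters
.containmentDf <- function(dat, fixed_terms) {
    p <- length(fixed_terms) + 1L
    df <- vapply(fixed_terms, function(tm) {
        x <- dat[[tm]]
        Ls <- integer()
        for (g in c("subject_id", "pool_id", "batch_id", "pair_id")) {
            if (!g %in% names(dat)) next
            const <- all(vapply(split(x, dat[[g]]),
                                function(v) length(unique(v)) == 1L,
                                logical(1)))
            if (const) Ls <- c(Ls, length(unique(dat[[g]])))
        }
        L <- if (length(Ls)) min(Ls) else nrow(dat)
        max(1L, L - p)
    }, numeric(1))
    c("(Intercept)" = max(1L, nrow(dat) - p), df)
}

.tidyTMB <- function(fit, modelId, family, df = NULL) {
    co <- summary(fit)$coefficients$cond
    ctab <- data.frame(term = rownames(co), estimate = co[, 1L],
                       se = co[, 2L], p = co[, 4L], row.names = NULL,
                       stringsAsFactors = FALSE)
    if (!is.null(df)) {
        dfv <- df[ctab$term]
        dfv[is.na(dfv)] <- max(df)
        ctab$df <- unname(dfv)
        tt <- ctab$estimate / ctab$se
        ctab$p <- 2 * stats::pt(-abs(tt), ctab$df)
    }
    conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess) &&
        all(is.finite(co[, 2L])) && all(co[, 2L] > 0)
    methods::new("ModelFit", modelId = modelId, family = family,
                 coefficients = ctab, converged = conv)
}

# fit with the full random-effect structure; when a variance hits the
# boundary and the Hessian degenerates, refit with progressively fewer
# random terms (a standard simplification for singular mixed fits)
.tmbFitFallback <- function(fixed_terms, re_terms, response, dat, family,
                            modelId, familyLabel, extra = list(),
                            df = NULL) {
    sets <- lapply(length(re_terms):0, function(k) re_terms[seq_len(k)])
    fit <- NULL
    for (re in sets) {
        form <- stats::reformulate(c(fixed_terms, re), response = response)
        args <- c(list(form, data = dat, family = family, REML = TRUE),
                  extra)
        fit <- try(suppressMessages(suppressWarnings(
            do.call(glmmTMB::glmmTMB, args))), silent = TRUE)
        if (inherits(fit, "try-error")) next
        mf <- .tidyTMB(fit, modelId, familyLabel, df)
        if (mf@converged) return(mf)
    }
    if (!is.null(fit) && !inherits(fit, "try-error")) return(mf)
    methods::new("ModelFit", modelId = modelId, family = familyLabel,
                 coefficients = data.frame(term = character(),
                                           estimate = numeric(),
                                           se = numeric(), p = numeric()),
                 converged = FALSE)
}

#' Beta-binomial mixed model for panel scores
#'
#' Fits a logit-link beta-binomial regression of the per-nucleus panel
#' score (out of `m` panel genes) on behavior covariates. By default
#' (`method = "subject"`) nuclei are aggregated to one overdispersed
#' binomial observation per subject — total detections out of
#' `m x nuclei` — with pool, batch and pair random intercepts; the
#' beta-binomial dispersion absorbs subject-level variation. With
#' `method = "nuclei"` the model is fitted at the nucleus level with
#' batch, pool, subject and pair random intercepts. Estimation is
#' restricted maximum likelihood via Laplace approximation (glmmTMB);
#' p-values are Wald tests against a t reference with containment-style
#' degrees of freedom (the number of levels of the coarsest grouping in
#' which the covariate is constant — pools for the binary condition, which
#' is pooled by condition in this design — minus the fixed-parameter
#' count), guarding against the anticonservativeness of normal-reference
#' Wald tests at these group counts. Random-effect variances that collapse
#' to the boundary trigger a refit with the degenerate terms removed.
#'
#' @param score Integer per-nucleus scores in `0..m` (see [panelScore()]).
#' @param m Panel size.
#' @param subjects Subject table (see [validateSubjects()]).
#' @param meta Per-nucleus metadata aligned with `score` (needs
#'   `subject_id`); a `BowerExperiment` colData data.frame works.
#' @param fixed_terms Character vector out of `"bai"`, `"condition"`,
#'   `"quiver_log"`, `"gsi"`.
#' @param method `"subject"` (default) or `"nuclei"`.
#' @return A [ModelFit-class]; non-convergence is flagged, not an error.
#' @export
fitBetaBinomialMixed <- function(score, m, subjects, meta,
                                 fixed_terms = c("condition", "quiver_log"),
                                 method = c("subject", "nuclei")) {
    method <- match.arg(method)
    if (any(score < 0 | score > m)) stop("scores must lie in 0..m")
    for (cond in c("building", "control"))
        if (sum(subjects$condition == cond) < 2)
            stop("need at least two subjects per condition")
    if (all(score == 0))
        stop("all scores are zero: boundary case, model not identifiable")
    sIdx <- match(meta$subject_id, subjects$subject_id)
    if (anyNA(sIdx)) stop("nuclei assigned to unknown subjects")
    cov <- .covariateData(subjects, fixed_terms)
    modelId <- paste(fixed_terms, collapse = "+")
    if (method == "subject") {
        S <- as.vector(tapply(score, factor(sIdx,
                                            levels = seq_len(nrow(subjects))),
                              sum, default = 0))
        nNuc <- tabulate(sIdx, nbins = nrow(subjects))
        keep <- nNuc > 0
        dat <- cov[keep, , drop = FALSE]
        dat$S <- S[keep]
        dat$Fail <- nNuc[keep] * m - S[keep]
        re <- c("(1 | pool_id)", "(1 | batch_id)", "(1 | pair_id)")
    } else {
        dat <- cov[sIdx, , drop = FALSE]
        dat$S <- score
        dat$Fail <- m - score
        re <- c("(1 | subject_id)", "(1 | pool_id)", "(1 | batch_id)",
                "(1 | pair_id)")
    }
    df <- .containmentDf(dat, fixed_terms)
    mf <- .tmbFitFallback(fixed_terms, re, "cbind(S, Fail)", dat,
                          glmmTMB::betabinomial(), modelId,
                          "beta-binomial", df = df)
    if (!mf@converged) {
        # zero-overdispersion boundary: the beta-binomial likelihood
        # degenerates; the binomial sub-model is its limit
        mf <- .tmbFitFallback(fixed_terms, re, "cbind(S, Fail)", dat,
                              stats::binomial(), modelId,
                              "beta-binomial (binomial boundary)", df = df)
    }
    if (!mf@converged)
        warning("beta-binomial fit '", modelId, "' did not converge")
    mf
}

#' Library-size or median-ratio size factors
#'
#' @param counts genes x nuclei count matrix.
#' @param method `"library"` (default: column totals scaled to mean 1) or
#'   `"median-ratio"` (geometric-mean reference).
#' @return Positive numeric vector, one per nucleus.
#' @export
sizeFactors <- function(counts, method = c("library", "median-ratio")) {
    method <- match.arg(method)
    if (method == "library") {
        ls <- Matrix::colSums(counts)
        if (any(ls == 0)) stop("nuclei with zero total counts")
        return(as.numeric(ls / mean(ls)))
    }
    lg <- log(as.matrix(counts))
    lg[!is.finite(lg)] <- NA
    ref <- rowMeans(lg, na.rm = TRUE)
    use <- is.finite(ref)
    sf <- apply(lg[use, , drop = FALSE] - ref[use], 2,
                stats::median, na.rm = TRUE)
    as.numeric(exp(sf))
}

#' Per-gene dispersion by method of moments with a trend shrink
#'
#' Normalized counts `y / sf` give per-gene mean and variance; the raw
#' NB dispersion estimate `(var - mean) / mean^2` (floored at 0) is shrunk
#' halfway (on the log scale) toward a mean-dispersion trend fitted by
#' linear regression.
#'
#' @param counts genes x nuclei count matrix.
#' @param size_factors From [sizeFactors()].
#' @return Named numeric vector of dispersions (>= 0).
#' @export
estimateDispersion <- function(counts, size_factors) {
    yn <- sweep(as.matrix(counts), 2, size_factors, "/")
    mu <- rowMeans(yn)
    v <- apply(yn, 1, stats::var)
    raw <- pmax(0, (v - mu) / mu^2)
    ok <- mu > 0 & raw > 0
    out <- raw
    if (sum(ok) >= 5) {
        fit <- stats::lm(log(raw[ok]) ~ log(mu[ok]))
        trend <- exp(cbind(1, log(pmax(mu, 1e-8))) %*% stats::coef(fit))
        out <- exp((log(pmax(raw, 1e-8)) + log(pmax(trend, 1e-8))) / 2)
        out[raw == 0] <- pmin(out[raw == 0], trend[raw == 0])
    }
    stats::setNames(as.numeric(out), rownames(counts))
}

#' Negative-binomial mixed model for one gene
#'
#' Log-link NB regression of per-nucleus counts on behavior covariates with
#' a log size-factor offset, gene-specific dispersion and the same nested
#' random intercepts as [fitBetaBinomialMixed()]. Genes not observed in
#' every pair are refused (the pair-observation filter). With
#' `method = "subject"` (default) counts and size factors are summed per
#' subject first.
#'
#' @param y Integer per-nucleus counts for one gene.
#' @param size_factor Positive per-nucleus size factors.
#' @param subjects,meta,fixed_terms,method As in [fitBetaBinomialMixed()].
#' @param dispersion Optional fixed NB dispersion (variance
#'   `mu + dispersion * mu^2`); estimated when `NULL`.
#' @return A [ModelFit-class].
#' @export
fitCountMixed <- function(y, size_factor, subjects, meta,
                          fixed_terms = c("condition", "quiver_log"),
                          dispersion = NULL,
                          method = c("subject", "nuclei")) {
    method <- match.arg(method)
    if (any(size_factor <= 0)) stop("size factors must be positive")
    sIdx <- match(meta$subject_id, subjects$subject_id)
    if (anyNA(sIdx)) stop("nuclei assigned to unknown subjects")
    pairHit <- tapply(y > 0, subjects$pair_id[sIdx], any)
    if (!all(unlist(pairHit)) || length(pairHit) <
        length(unique(subjects$pair_id)))
        stop("gene not observed in every pair: excluded by the ",
             "pair-observation filter")
    cov <- .covariateData(subjects, fixed_terms)
    modelId <- paste(fixed_terms, collapse = "+")
    if (method == "subject") {
        f <- factor(sIdx, levels = seq_len(nrow(subjects)))
        dat <- cov
        dat$y <- as.vector(tapply(y, f, sum, default = 0))
        dat$off <- log(as.vector(tapply(size_factor, f, sum, default = 1)))
        re <- c("(1 | pool_id)", "(1 | batch_id)", "(1 | pair_id)")
    } else {
        dat <- cov[sIdx, , drop = FALSE]
        dat$y <- y
        dat$off <- log(size_factor)
        re <- c("(1 | subject_id)", "(1 | pool_id)", "(1 | batch_id)",
                "(1 | pair_id)")
    }
    extra <- list()
    if (!is.null(dispersion) && dispersion > 0) {
        extra$start <- list(betad = log(1 / dispersion))
        extra$map <- list(betad = factor(NA))
    }
    df <- .containmentDf(dat, fixed_terms)
    mf <- .tmbFitFallback(c(fixed_terms, "offset(off)"), re, "y", dat,
                          glmmTMB::nbinom2(), modelId, "negative-binomial",
                          extra, df = df)
    if (!mf@converged && !length(extra)) {
        # zero-dispersion boundary: Poisson is the NB limit
        mf <- .tmbFitFallback(c(fixed_terms, "offset(off)"), re, "y", dat,
                              stats::poisson(), modelId,
                              "negative-binomial (Poisson boundary)",
                              df = df)
    }
    if (!mf@converged)
        warning("NB fit '", modelId, "' did not converge")
    mf
}

.modelSpecs <- list(
    m1 = c("bai", "quiver_log"),
    m2 = c("bai", "gsi"),
    m3 = c("bai", "quiver_log", "gsi"),
    m4 = c("condition", "quiver_log"),
    m5 = c("condition", "gsi"),
    m6 = c("condition", "quiver_log", "gsi"),
    m7 = c("quiver_log", "gsi"))

.focalPlan <- list(
    building = list(models = paste0("m", 1:6),
                    term = c(m1 = "bai", m2 = "bai", m3 = "bai",
                             m4 = "condition", m5 = "condition",
                             m6 = "condition")),
    quivering = list(models = c("m1", "m3", "m4", "m6", "m7"),
                     term = c(m1 = "quiver_log", m3 = "quiver_log",
                              m4 = "quiver_log", m6 = "quiver_log",
                              m7 = "quiver_log")),
    gsi = list(models = c("m2", "m3", "m5", "m6", "m7"),
               term = c(m2 = "gsi", m3 = "gsi", m5 = "gsi", m6 = "gsi",
                        m7 = "gsi")))

#' Run the multi-model significance competition
#'
#' Fits every model of the seven-specification suite containing the focal
#' covariate (building: six models, three with BAI and three with the
#' binary condition; quivering and gsi: five models each), collects the raw
#' p-value of the focal term from each, combines them by the raw harmonic
#' mean, and applies the dual rule: significant iff every raw p < alpha
#' AND the FDR-adjusted harmonic-mean p < alpha. When results for several
#' outcomes are to be adjusted jointly, leave `hmp_adj = NULL` here and
#' use [adjustCompetition()] afterwards.
#'
#' @param fitter A function taking a character vector of fixed terms and
#'   returning a [ModelFit-class] — typically a closure over
#'   [fitBetaBinomialMixed()] or [fitCountMixed()].
#' @param focal `"building"`, `"quivering"` or `"gsi"`.
#' @param alpha Significance level of the dual rule (default 0.05).
#' @param hmp_adj FDR-adjusted harmonic-mean p; defaults to the unadjusted
#'   harmonic mean (single-outcome case).
#' @return A [CompetitionResult-class].
#' @export
runCompetition <- function(fitter, focal = c("building", "quivering", "gsi"),
                           alpha = 0.05, hmp_adj = NULL) {
    focal <- match.arg(focal)
    plan <- .focalPlan[[focal]]
    fits <- lapply(plan$models, function(mid) fitter(.modelSpecs[[mid]]))
    names(fits) <- plan$models
    pvals <- vapply(plan$models, function(mid) {
        ctab <- fits[[mid]]@coefficients
        p <- ctab$p[ctab$term == plan$term[[mid]]]
        if (length(p) != 1L || !is.finite(p))
            stop("focal term '", plan$term[[mid]], "' missing from model ",
                 mid)
        max(p, .Machine$double.xmin)
    }, numeric(1))
    converged <- all(vapply(fits, function(f) f@converged, logical(1)))
    if (!converged)
        warning("competition for '", focal,
                "' includes non-converged fits; reported non-significant")
    hmp <- harmonicMeanP(pvals)
    if (is.null(hmp_adj)) hmp_adj <- hmp
    sig <- converged && all(pvals < alpha) && hmp_adj < alpha
    methods::new("CompetitionResult", focal = focal, fits = fits,
                 perModelP = pvals, hmp = hmp, hmpAdj = hmp_adj,
                 alpha = alpha, significant = sig, converged = converged)
}

#' Adjust a family of competition results across outcomes
#'
#' BH-adjusts the harmonic-mean p-values of a list of
#' [CompetitionResult-class] objects (e.g. one per cell population) and
#' re-applies the dual rule with the adjusted values.
#'
#' @param results List of `CompetitionResult`s.
#' @return The list with `hmpAdj` and `significant` updated.
#' @export
adjustCompetition <- function(results) {
    if (!length(results)) stop("empty result list")
    adj <- fdrAdjust(vapply(results, function(r) r@hmp, numeric(1)))
    mapply(function(r, a) {
        r@hmpAdj <- a
        r@significant <- r@converged && all(r@perModelP < r@alpha) &&
            a < r@alpha
        methods::validObject(r)
        r
    }, results, adj, SIMPLIFY = FALSE)
}

#' Building-associated changes in cluster proportions
#'
#' Per cluster, each nucleus is a Bernoulli trial — member or not of the
#' cluster within its denominator (all nuclei for primary clusters, the
#' primary parent's nuclei for secondary clusters, all subclustered nuclei
#' for subclusters). Trials are aggregated per subject and fitted with a
#' binomial mixed model (condition, GSI and quivering as fixed effects, a
#' random subject intercept absorbing overdispersion); the building
#' p-values are BH-adjusted across clusters. Subjects with an empty
#' denominator are dropped with a warning; a subject simply lacking the
#' cluster contributes zero successes.
#'
#' @param x A [BowerExperiment-class] with subjects attached.
#' @param level `"primary"`, `"secondary"` or `"subcluster"`.
#' @param alpha Significance level applied to the adjusted values.
#' @return `data.frame` with one row per cluster: `cluster`, `estimate`
#'   (building log-odds), `se`, `p`, `q`, `significant`.
#' @export
proportionCompetition <- function(x, level = c("primary", "secondary",
                                               "subcluster"),
                                  alpha = 0.05) {
    level <- match.arg(level)
    sub <- subjects(x)
    if (is.null(sub)) stop("no subject table attached")
    cd <- as.data.frame(colData(x))
    labcol <- switch(level, primary = "cluster_primary",
                     secondary = "cluster_secondary",
                     subcluster = "subcluster")
    if (!labcol %in% colnames(cd))
        stop("missing metadata column: ", labcol)
    keep <- !is.na(cd[[labcol]])
    cd <- cd[keep, , drop = FALSE]
    clusters <- sort(unique(as.character(cd[[labcol]])))
    cov <- .covariateData(sub, c("condition", "gsi", "quiver_log"))
    rows <- lapply(clusters, function(cc) {
        inCl <- cd[[labcol]] == cc
        denom <- if (level == "secondary") {
            parent <- unique(cd$cluster_primary[inCl])
            cd$cluster_primary %in% parent
        } else rep(TRUE, nrow(cd))
        f <- factor(cd$subject_id, levels = sub$subject_id)
        k <- tapply(inCl & denom, f, sum, default = 0)
        n <- tapply(denom, f, sum, default = 0)
        use <- n > 0
        if (any(!use))
            warning("cluster ", cc, ": ", sum(!use),
                    " subject(s) with empty denominator dropped")
        dat <- cov[use, , drop = FALSE]
        dat$k <- as.vector(k)[use]
        dat$n <- as.vector(n)[use]
        fit <- suppressMessages(suppressWarnings(lme4::glmer(
            cbind(k, n - k) ~ condition + gsi + quiver_log +
                (1 | subject_id),
            data = dat, family = stats::binomial())))
        co <- summary(fit)$coefficients
        data.frame(cluster = cc, estimate = co["condition", 1L],
                   se = co["condition", 2L], p = co["condition", 4L],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- fdrAdjust(out$p)
    out$significant <- out$q < alpha
    rownames(out) <- NULL
    out
}

#' Lagged association profile of behavior with panel scores
#'
#' For each temporal bin of the pre-collection window, the building (or
#' quivering) covariate in the score model is replaced by that bin's
#' standardized event count and the absolute Wald z of the focal term is
#' recorded, tracing when the behavior driving the expression signal was
#' performed.
#'
#' @param score,m,subjects,meta As in [fitBetaBinomialMixed()].
#' @param behavior_bins subjects x bins count matrix (rows aligned with
#'   `subjects`), e.g. from [simulateBehaviorBins()] or
#'   [summarizeEvents()] applied per subject.
#' @param focal `"building"` or `"quivering"`.
#' @return List with `profile` (`data.frame` `bin`, `z`) and `peak_bin`
#'   (column name of the argmax bin).
#' @export
laggedAssociationProfile <- function(score, m, subjects, meta,
                                     behavior_bins,
                                     focal = c("building", "quivering")) {
    focal <- match.arg(focal)
    if (ncol(behavior_bins) < 2) stop("need at least 2 bins")
    zvals <- vapply(seq_len(ncol(behavior_bins)), function(b) {
        x <- behavior_bins[, b]
        x <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
        sub2 <- subjects
        sub2$bai <- x          # the binned covariate rides the bai slot
        terms <- if (focal == "building") c("bai", "quiver_log")
                 else c("bai", "gsi")
        mf <- fitBetaBinomialMixed(score, m, sub2, meta,
                                   fixed_terms = terms)
        ctab <- mf@coefficients
        est <- ctab$estimate[ctab$term == "bai"]
        se <- ctab$se[ctab$term == "bai"]
        if (!length(est) || !is.finite(se) || se == 0) return(0)
        abs(est / se)
    }, numeric(1))
    profile <- data.frame(bin = colnames(behavior_bins), z = zvals,
                          stringsAsFactors = FALSE)
    list(profile = profile,
         peak_bin = colnames(behavior_bins)[which.max(zvals)])
}

#' Direction-bias goodness of fit
#'
#' Tests whether up- versus downregulated effects split evenly, with a
#' Yates-corrected 1-df chi-squared goodness-of-fit against 0.5.
#'
#' @param n_up Number of upregulated effects.
#' @param n_total Total number of effects.
#' @return List with `statistic` and `p`.
#' @export
directionBiasTest <- function(n_up, n_total) {
    stopifnot(n_up >= 0, n_up <= n_total, n_total > 0)
    ht <- stats::prop.test(n_up, n_total, p = 0.5, correct = TRUE)
    list(statistic = unname(ht$statistic), p = ht$p.value)
}
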