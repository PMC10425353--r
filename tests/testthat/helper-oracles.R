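# Independent oracles kept deliberately separate from the implementations
# they check.

# brute-force flood fill: repeated frontier expansion from each unvisited
# TRUE pixel, using arr.ind coordinates and set unions
floodFillOracle <- function(mask, connectivity = 4L) {
    mask[is.na(mask)] <- FALSE
    nr <- nrow(mask); nc <- ncol(mask)
    seen <- matrix(FALSE, nr, nc)
    comps <- list()
    neigh <- if (connectivity == 4L)
        rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    else
        as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
        if (!mask[r, cc] || seen[r, cc]) next
        frontier <- matrix(c(r, cc), 1L)
        seen[r, cc] <- TRUE
        member <- frontier
        while (nrow(frontier) > 0) {
            nxt <- NULL
            for (i in seq_len(nrow(frontier))) {
                for (j in seq_len(nrow(neigh))) {
                    r2 <- frontier[i, 1] + neigh[j, 1]
                    c2 <- frontier[i, 2] + neigh[j, 2]
                    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
                        mask[r2, c2] && !seen[r2, c2]) {
                        seen[r2, c2] <- TRUE
                        nxt <- rbind(nxt, c(r2, c2))
                    }
                }
            }
            member <- rbind(member, nxt)
            frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 2) else nxt
        }
        comps[[length(comps) + 1L]] <-
            sort((member[, 2] - 1L) * nr + member[, 1])
    }
    comps
}

# Weir & Cockerham (1984) per-site components, scalar arithmetic written
# straight from the definitional sums over the two populations
wcOracleSite <- function(gtRow, ga, gb) {
    stats <- function(g) {
        x <- gtRow[g]
        x <- x[!is.na(x)]
        list(n = length(x), p = sum(x) / (2 * length(x)),
             h = sum(x == 1) / length(x))
    }
    s1 <- stats(ga); s2 <- stats(gb)
    r <- 2
    nbar <- mean(c(s1$n, s2$n))
    nc <- (r * nbar - (s1$n^2 + s2$n^2) / (r * nbar)) / (r - 1)
    pbar <- (s1$n * s1$p + s2$n * s2$p) / (r * nbar)
    s2v <- (s1$n * (s1$p - pbar)^2 + s2$n * (s2$p - pbar)^2) /
        ((r - 1) * nbar)
    hbar <- (s1$n * s1$h + s2$n * s2$h) / (r * nbar)
    a <- (nbar / nc) *
        (s2v - (1 / (nbar - 1)) *
             (pbar * (1 - pbar) - ((r - 1) / r) * s2v - hbar / 4))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2v -
             ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    c(a = a, b = b, c = cc)
}

# exhaustive PAM objective: best total distance-to-medoid over all medoid
# subsets of size k
pamObjectiveOracle <- function(D, k) {
    n <- nrow(D)
    best <- Inf
    for (med in utils::combn(n, k, simplify = FALSE)) {
        cost <- sum(apply(D[, med, drop = FALSE], 1, min))
        if (cost < best) best <- cost
    }
    best
}

# two-sided Fisher p by exhaustive hypergeometric enumeration over the
# support of cell a given fixed margins
fisherOracle <- function(a, b, cc, d) {
    m1 <- a + b; m2 <- cc + d; n1 <- a + cc
    lo <- max(0, n1 - m2); hi <- min(n1, m1)
    probs <- vapply(lo:hi, function(x)
        exp(lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(m1 + m2, n1)),
        numeric(1))
    pObs <- probs[a - lo + 1L]
    sum(probs[probs <= pObs * (1 + 1e-7)])
}
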