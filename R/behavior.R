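#' Bower detection parameters
#'
#' @param min_pixels Minimum contiguous pixels for a region (default 1000,
#'   about 10 cm^2 at the default pixel scale).
#' @param height_threshold Absolute elevation change (cm) a pixel must
#'   exceed (strictly) to join a region; default 0.2 cm, the level below
#'   which depth change is attributable to non-building activity.
#' @param connectivity 4 or 8 pixel connectivity (default 4).
#' @param smoothing_sigma Gaussian smoothing SD in pixels (default 1).
#' @param max_hole_px Missing regions up to this many pixels are filled by
#'   nearest-neighbor interpolation; larger holes stay missing.
#' @return Named list of class `BowerDetectionParams`.
#' @export
bowerDetectionParams <- function(min_pixels = 1000L, height_threshold = 0.2,
                                 connectivity = c(4L, 8L),
                                 smoothing_sigma = 1,
                                 max_hole_px = 25L) {
    connectivity <- as.integer(connectivity)[1L]
    stopifnot(min_pixels >= 1, height_threshold > 0,
              connectivity %in% c(4L, 8L), smoothing_sigma >= 0,
              max_hole_px >= 0)
    structure(list(min_pixels = as.integer(min_pixels),
                   height_threshold = height_threshold,
                   connectivity = connectivity,
                   smoothing_sigma = smoothing_sigma,
                   max_hole_px = as.integer(max_hole_px)),
              class = "BowerDetectionParams")
}

# label connected components of a logical matrix; returns integer matrix
# (0 = background). BFS flood fill over a queue of linear indices.
.labelComponents <- function(mask, connectivity = 4L) {
    nr <- nrow(mask); nc <- ncol(mask)
    lab <- matrix(0L, nr, nc)
    mask[is.na(mask)] <- FALSE
    nextLab <- 0L
    offs <- if (connectivity == 4L) {
        list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
    } else {
        list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
             c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
    }
    todo <- which(mask)
    for (start in todo) {
        if (lab[start] != 0L) next
        nextLab <- nextLab + 1L
        queue <- start
        lab[start] <- nextLab
        while (length(queue)) {
            cur <- queue[length(queue)]
            queue <- queue[-length(queue)]
            r <- ((cur - 1L) %% nr) + 1L
            cc <- ((cur - 1L) %/% nr) + 1L
            for (o in offs) {
                r2 <- r + o[1L]; c2 <- cc + o[2L]
                if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
                idx <- (c2 - 1L) * nr + r2
                if (mask[idx] && lab[idx] == 0L) {
                    lab[idx] <- nextLab
                    queue <- c(queue, idx)
                }
            }
        }
    }
    lab
}

# NA-aware Gaussian smoothing: conv(grid * valid) / conv(valid), which
# preserves constants and reduces to plain convolution away from edges/NAs.
.gaussSmooth <- function(grid, sigma) {
    if (sigma <= 0) return(grid)
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    valid <- !is.na(grid)
    g0 <- grid; g0[!valid] <- 0
    convolveShift <- function(m, kern, margin) {
        out <- matrix(0, nrow(m), ncol(m))
        n <- if (margin == 1L) nrow(m) else ncol(m)
        for (i in seq_along(kern)) {
            sh <- i - r - 1L
            src <- seq_len(n) + sh
            ok <- src >= 1L & src <= n
            if (margin == 1L) {
                out[ok, ] <- out[ok, ] + kern[i] * m[src[ok], , drop = FALSE]
            } else {
                out[, ok] <- out[, ok] + kern[i] * m[, src[ok], drop = FALSE]
            }
        }
        out
    }
    num <- convolveShift(convolveShift(g0, k, 1L), k, 2L)
    den <- convolveShift(convolveShift(valid + 0, k, 1L), k, 2L)
    out <- num / den
    out[!valid] <- NA_real_
    out[den == 0] <- NA_real_
    out
}

#' Clean an elevation-change grid
#'
#' Missing regions of at most `max_hole_px` contiguous pixels are filled by
#' nearest-neighbor interpolation (value of the closest observed pixel, ties
#' broken by scan order); Gaussian smoothing with `smoothing_sigma` is then
#' applied. Larger holes remain missing and are excluded from region
#' growing.
#'
#' @param grid Numeric matrix of elevation change (cm); `NA` marks holes.
#' @param params A [bowerDetectionParams()].
#' @return Cleaned numeric matrix (same dimensions).
#' @export
cleanDepth <- function(grid, params = bowerDetectionParams()) {
    if (!is.matrix(grid) || !is.numeric(grid))
        stop("grid must be a numeric matrix")
    if (all(is.na(grid))) stop("grid is entirely missing")
    holes <- .labelComponents(is.na(grid), 4L)
    if (any(holes > 0L)) {
        sizes <- tabulate(holes)
        fillable <- which(sizes <= params$max_hole_px)
        if (length(fillable)) {
            obs <- which(!is.na(grid), arr.ind = TRUE)
            for (h in fillable) {
                for (idx in which(holes == h)) {
                    r <- ((idx - 1L) %% nrow(grid)) + 1L
                    cc <- ((idx - 1L) %/% nrow(grid)) + 1L
                    d2 <- (obs[, 1L] - r)^2 + (obs[, 2L] - cc)^2
                    nn <- obs[which.min(d2), , drop = FALSE]
                    grid[idx] <- grid[nn[1L, 1L], nn[1L, 2L]]
                }
            }
        }
    }
    .gaussSmooth(grid, params$smoothing_sigma)
}

#' Detect bower regions in a cleaned grid
#'
#' Connected components (4- or 8-connectivity) of pixels whose elevation
#' change strictly exceeds `height_threshold` in the same direction;
#' components of at least `min_pixels` pixels are reported. Elevated and
#' depressed regions are grown separately. `NA` pixels never join a region.
#'
#' @param grid Cleaned elevation-change matrix (cm).
#' @param params A [bowerDetectionParams()].
#' @param pixel_area_cm2 Area of one pixel (cm^2), used for region volume.
#' @param standard_length Optional subject standard length (cm); when
#'   given, each region also carries `sl_adjusted_volume = volume / SL^3`,
#'   the size-standardized measure of building activity.
#' @return A `data.frame` with one row per region (`direction`, `n_px`,
#'   `volume_cm3`, optionally `sl_adjusted_volume`) and a `pixels` list
#'   column of linear pixel indices.
#' @export
detectBowerRegions <- function(grid, params = bowerDetectionParams(),
                               pixel_area_cm2 = 0.01,
                               standard_length = NULL) {
    res <- list()
    for (dir in c("+", "-")) {
        mask <- if (dir == "+") grid > params$height_threshold
                else grid < -params$height_threshold
        mask[is.na(mask)] <- FALSE
        lab <- .labelComponents(mask, params$connectivity)
        if (!any(lab > 0L)) next
        sizes <- tabulate(lab)
        for (comp in which(sizes >= params$min_pixels)) {
            px <- which(lab == comp)
            vol <- sum(abs(grid[px])) * pixel_area_cm2
            res[[length(res) + 1L]] <- data.frame(
                direction = dir, n_px = length(px), volume_cm3 = vol,
                stringsAsFactors = FALSE)
            attr(res[[length(res)]], "pixels") <- px
        }
    }
    if (!length(res)) {
        out <- data.frame(direction = character(), n_px = integer(),
                          volume_cm3 = numeric())
        out$pixels <- list()
        return(out)
    }
    pixels <- lapply(res, attr, "pixels")
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out$pixels <- pixels
    if (!is.null(standard_length))
        out$sl_adjusted_volume <- out$volume_cm3 / standard_length^3
    out
}

#' Summarize an event stream
#'
#' Totals and binned counts of building (scoop/spit/multiple) and quiver
#' events over the window preceding collection. Timestamps are minutes
#' before collection; negative values (events after collection) are an
#' error. The quiver total is returned alongside its log-normalized value
#' `log(1 + count)`.
#'
#' @param events `data.frame` with columns `t_min` (minutes before
#'   collection, >= 0) and `type`.
#' @param window_minutes Analysis window (default 100).
#' @param bin_minutes Bin width (default 30).
#' @param step_minutes Bin start spacing; equal to `bin_minutes` for tiled
#'   bins (default), smaller for sliding bins.
#' @return List with `build_total`, `quiver_total`, `quiver_log`,
#'   `bins` (a `data.frame` `start`, `end`, `build`, `quiver`; bin
#'   intervals are `[start, end)` in minutes before collection, the last
#'   tiled bin closed at the window edge).
#' @export
summarizeEvents <- function(events, window_minutes = 100, bin_minutes = 30,
                            step_minutes = bin_minutes) {
    stopifnot(is.data.frame(events),
              all(c("t_min", "type") %in% colnames(events)))
    if (nrow(events) && any(events$t_min < 0))
        stop("events timestamped after collection time")
    ev <- events[events$t_min <= window_minutes, , drop = FALSE]
    isBuild <- ev$type %in% c("scoop", "spit", "multiple")
    isQuiv <- ev$type == "quiver"
    starts <- seq(0, window_minutes - 1e-9, by = step_minutes)
    ends <- pmin(starts + bin_minutes, window_minutes)
    inBin <- function(t, s, e) t >= s & (t < e | (e == window_minutes &
                                                  t <= e))
    bins <- data.frame(
        start = starts, end = ends,
        build = vapply(seq_along(starts), function(i)
            sum(isBuild & inBin(ev$t_min, starts[i], ends[i])), numeric(1)),
        quiver = vapply(seq_along(starts), function(i)
            sum(isQuiv & inBin(ev$t_min, starts[i], ends[i])), numeric(1)))
    list(build_total = sum(isBuild), quiver_total = sum(isQuiv),
         quiver_log = log1p(sum(isQuiv)), bins = bins)
}

#' Bower Activity Index
#'
#' Combines predicted building events and size-adjusted depth change into a
#' single scalar: an ordinary least-squares line of depth change on event
#' count is fitted across subjects, every subject is orthogonally projected
#' onto that line, and the BAI is the Euclidean distance along the line
#' from the projection of the anchor (0 events, 0 depth change) to the
#' subject's projection, clamped at 0 for projections below the anchor.
#' Axes are used in raw units.
#'
#' @param event_count Numeric vector of predicted building events.
#' @param depth_change Numeric vector of size-adjusted depth change.
#' @return List with `bai` (numeric vector), `slope`, `intercept`, and
#'   `r_squared` of the fitted line.
#' @examples
#' # points on the line y = 2x through the origin
#' computeBAI(c(0, 5, 10), c(0, 10, 20))$bai
#' @export
computeBAI <- function(event_count, depth_change) {
    stopifnot(length(event_count) == length(depth_change))
    if (length(event_count) < 3)
        stop("need at least 3 subjects to fit the regression line")
    if (stats::sd(event_count) == 0)
        stop("degenerate fit: all event counts are equal")
    fit <- stats::lm(depth_change ~ event_count)
    a <- unname(stats::coef(fit)[1L])
    b <- unname(stats::coef(fit)[2L])
    d <- c(1, b) / sqrt(1 + b^2)          # unit direction along the line
    tProj <- (event_count - 0) * d[1L] + (depth_change - a) * d[2L]
    tAnchor <- (0 - 0) * d[1L] + (0 - a) * d[2L]
    bai <- pmax(0, tProj - tAnchor)
    list(bai = bai, slope = b, intercept = a,
         r_squared = suppressWarnings(summary(fit)$r.squared))
}
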