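# Mid-contour edge analysis: biosensor normalization, windowed
# outer/inner/mid contours, normal-line edge trajectories, velocity and
# signal kymographs, and velocity-peak-aligned statistics. The pipeline is
# applied identically to simulated and experimental stacks.

# ---------------------------------------------------------------------------
# Normalization
# ---------------------------------------------------------------------------

#' Normalize a biosensor stack
#'
#' Clips the series to [median - madFactor * MAD, median + madFactor * MAD]
#' (median and plain median absolute deviation computed over the whole
#' series), then min-max scales to [0, 1]. The optional outlier rule drops
#' sparse histogram outliers (pixels outside median +/- 5 when fewer than 20
#' of them exist) from the min/max computation.
#'
#' @param stack 3D numeric array (rows x cols x frames).
#' @param madFactor clip half-width in MAD units.
#' @param outlierRule apply the sparse-outlier rule (default off).
#' @param mask optional logical array of the same shape: statistics are then
#'   computed over in-mask (in-cell) pixels only, so that empty background
#'   does not distort the median/MAD (simulated stacks are zero outside the
#'   cell).
#' @return Array of the same shape with values in [0, 1].
#' @export
normalizeBiosensor <- function(stack, madFactor = 6, outlierRule = FALSE,
                               mask = NULL) {
  if (!all(is.finite(stack))) stop("stack contains non-finite values")
  ref <- if (is.null(mask)) stack else stack[mask != 0]
  med <- median(ref)
  madI <- mad(ref, constant = 1)
  lo <- med - madFactor * madI
  hi <- med + madFactor * madI
  out <- pmin(pmax(stack, lo), hi)
  keep <- if (is.null(mask)) out else out[mask != 0]
  if (outlierRule) {
    outl <- abs(keep - med) > 5
    if (sum(outl) < 20 && sum(outl) > 0) keep <- keep[!outl]
  }
  mn <- min(keep); mx <- max(keep)
  if (mx <= mn) {
    warning("constant stack: normalization returns zeros")
    return(array(0, dim(stack)))
  }
  pmin(pmax((out - mn) / (mx - mn), 0), 1)
}

# ---------------------------------------------------------------------------
# Contours
# ---------------------------------------------------------------------------

# boundary polygon of a binary mask as an n x 2 matrix of (row, col) pixel
# coordinates (Moore tracing via EBImage, converted to 1-based)
traceContour <- function(mask) {
  m <- if (is(mask, "CellMask")) mask@mask else (mask != 0)
  oc <- EBImage::ocontour(EBImage::Image(m * 1))
  if (length(oc) == 0L) stop("mask has no object to trace")
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  pts + 1  # EBImage coordinates are 0-based
}

#' Arc-length resampling of a closed contour
#'
#' @param pts n x 2 matrix of vertex coordinates (closed implicitly).
#' @param spacing target spacing between consecutive points (px).
#' @return m x 2 matrix with m = round(perimeter / spacing) points.
#' @export
resampleContour <- function(pts, spacing = 1) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  keep <- c(TRUE, seg > 1e-12)
  closed <- closed[keep, , drop = FALSE]
  s <- c(0, cumsum(sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)))
  L <- s[length(s)]
  n <- max(4L, round(L / spacing))
  at <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  cbind(approx(s, closed[, 1], xout = at)$y,
        approx(s, closed[, 2], xout = at)$y)
}

# circular moving average of a closed contour (tangent stabilization for
# staircase pixel outlines; the contour points themselves are not displaced)
smoothClosed <- function(pts, window = 5L) {
  if (window < 2L || nrow(pts) <= window) return(pts)
  n <- nrow(pts)
  h <- (window - 1L) %/% 2L
  out <- pts
  for (d in seq_len(h)) {
    out <- out + pts[c((d + 1):n, 1:d), , drop = FALSE] +
           pts[c((n - d + 1):n, 1:(n - d)), , drop = FALSE]
  }
  out / (2 * h + 1)
}

# unit tangents by central difference on a closed resampled contour,
# estimated on a smoothed copy so that pixel staircase does not dominate
contourTangents <- function(pts, smooth = 5L) {
  sp <- smoothClosed(pts, smooth)
  n <- nrow(sp)
  nxt <- sp[c(2:n, 1), , drop = FALSE]
  prv <- sp[c(n, 1:(n - 1)), , drop = FALSE]
  t_ <- nxt - prv
  t_ / pmax(sqrt(rowSums(t_^2)), 1e-12)
}

# outward unit normals (oriented away from the polygon centroid)
contourNormals <- function(pts, smooth = 5L) {
  tg <- contourTangents(pts, smooth)
  nrm <- cbind(-tg[, 2], tg[, 1])
  ctr <- colMeans(pts)
  flip <- rowSums(nrm * sweep(pts, 2, ctr)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm
}

# intersections of the line p + t*dir with the closed polygon `poly`;
# returns sorted t values (possibly empty)
lineContourIntersections <- function(p, dir, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  den <- dir[1] * ey - dir[2] * ex
  wx <- a[, 1] - p[1]; wy <- a[, 2] - p[2]
  t_ <- (wx * ey - wy * ex) / den
  u <- (wx * dir[2] - wy * dir[1]) / den
  ok <- is.finite(t_) & is.finite(u) & u >= 0 & u < 1
  sort(t_[ok])
}

# mean distance from points to a polyline (point-to-segment, closed)
meanDistToContour <- function(pts, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  len2 <- pmax(ex^2 + ey^2, 1e-12)
  d <- vapply(seq_len(nrow(pts)), function(q) {
    px <- pts[q, 1]; py <- pts[q, 2]
    tt <- pmin(pmax(((px - a[, 1]) * ex + (py - a[, 2]) * ey) / len2, 0), 1)
    min((px - (a[, 1] + tt * ex))^2 + (py - (a[, 2] + tt * ey))^2)
  }, numeric(1))
  mean(sqrt(d))
}

# one normal-midpoint sweep: from each point of `from`, intersect the normal
# line with `to` and take the midpoint of the nearest intersection; stray
# intersections farther than `maxDist` are discarded (they produce
# self-intersecting polygons on jagged pixel contours)
normalMidpoints <- function(from, to, maxDist = Inf) {
  nrm <- contourNormals(from)
  out <- matrix(NA_real_, nrow(from), 2)
  for (q in seq_len(nrow(from))) {
    ts <- lineContourIntersections(from[q, ], nrm[q, ], to)
    if (length(ts) == 0) next
    t0 <- ts[which.min(abs(ts))]
    if (abs(t0) > maxDist) next
    out[q, ] <- from[q, ] + 0.5 * t0 * nrm[q, ]
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Mid-contour between nested contours
#'
#' Alternating normal-midpoint construction: Contour 1 collects midpoints of
#' the outer contour's normals to the inner contour, Contour 2 those of the
#' inner contour's normals to the outer one; the pair then replaces
#' outer/inner and the procedure iterates until the average distance between
#' the two new contours falls below the tolerance.
#'
#' @param outer,inner n x 2 closed contours (inner inside outer), ideally
#'   resampled at 1-px spacing.
#' @param tol convergence tolerance on the average inter-contour distance
#'   (px).
#' @param maxIter iteration cap.
#' @return The averaged mid-contour (resampled at 1 px), with attributes
#'   \code{iterations} and \code{finalDistance}.
#' @export
midContour <- function(outer, inner, tol = 0.1, maxIter = 100L) {
  d0 <- meanDistToContour(outer, inner)
  if (d0 < tol) {
    out <- resampleContour(outer, 1)
    attr(out, "iterations") <- 0L
    attr(out, "finalDistance") <- d0
    return(out)
  }
  A <- resampleContour(outer, 1)
  B <- resampleContour(inner, 1)
  nCap <- 2L * max(nrow(A), nrow(B))  # guard against scatter blow-up
  dPrev <- d0
  for (it in seq_len(maxIter)) {
    jump <- max(5, 3 * dPrev)
    C1 <- normalMidpoints(A, B, maxDist = jump)
    C2 <- normalMidpoints(B, A, maxDist = jump)
    if (nrow(C1) < 4L || nrow(C2) < 4L)
      stop("mid-contour construction lost its contours (degenerate input)")
    C1 <- resampleContour(C1, 1)
    C2 <- resampleContour(C2, 1)
    if (nrow(C1) > nCap || nrow(C2) > nCap)
      stop("mid-contour iteration diverged (self-intersecting contour)")
    d <- (meanDistToContour(C1, C2) + meanDistToContour(C2, C1)) / 2
    if (d < tol) {
      # final averaged contour: C1 vertices moved halfway to C2
      mid <- normalMidpoints(C1, C2, maxDist = jump)
      if (nrow(mid) < 4L) mid <- C1
      out <- resampleContour(mid, 1)
      attr(out, "iterations") <- it
      attr(out, "finalDistance") <- d
      return(out)
    }
    dPrev <- d
    A <- C1
    B <- C2
  }
  stop("mid-contour iteration did not converge in ", maxIter,
       " iterations (last average distance ", signif(d, 4), " px)")
}

#' Windowed outer/inner/mid contours of a mask stack
#'
#' Splits the series into windows (20 frames by default); per window, the
#' outer contour bounds the union of the window's masks and the inner contour
#' their intersection; both are arc-length resampled at 1 px and the
#' mid-contour is constructed between them.
#'
#' @param maskStack logical/binary 3D array (rows x cols x frames).
#' @param window window length in frames.
#' @param tol mid-contour tolerance (px).
#' @return List of \linkS4class{ContourSet}, one per window.
#' @export
windowContours <- function(maskStack, window = 20L, tol = 0.1) {
  nf <- dim(maskStack)[3]
  starts <- seq(1L, nf, by = window)
  lapply(starts, function(s0) {
    fr <- s0:min(s0 + window - 1L, nf)
    sub <- maskStack[, , fr, drop = FALSE] != 0
    cnt <- rowSums(sub, dims = 2)
    uni <- cnt > 0
    int <- cnt == length(fr)
    if (sum(int) < 9)
      stop("mask intersection in frames ", min(fr), "-", max(fr),
           " is empty or degenerate: the cell moved too far; shorten the window")
    outer <- resampleContour(traceContour(uni), 1)
    inner <- resampleContour(traceContour(int), 1)
    mid <- midContour(outer, inner, tol = tol)
    new("ContourSet", outer = outer, inner = inner, mid = mid,
        frames = as.integer(fr))
  })
}

# ---------------------------------------------------------------------------
# Trajectories
# ---------------------------------------------------------------------------

# per-window raw tracking: for each mid-contour vertex, the signed coordinate
# (along the outward normal) of the cell outline in every frame of the window
trackWindow <- function(cs, maskStack, margin = 2, jumpCap = 5) {
  mid <- cs@mid
  nrm <- contourNormals(mid)
  frames <- cs@frames
  nm <- nrow(mid)
  nfw <- length(frames)
  s <- matrix(NA_real_, nm, nfw)
  # normal segment bounds from the inner/outer contours; when a normal misses
  # one of them, fall back to a band wide enough for the window's excursions
  halfBand <- meanDistToContour(cs@outer, cs@inner) / 2 + margin + 2
  tmin <- rep(-halfBand, nm); tmax <- rep(halfBand, nm)
  for (q in seq_len(nm)) {
    ti <- lineContourIntersections(mid[q, ], nrm[q, ], cs@inner)
    to <- lineContourIntersections(mid[q, ], nrm[q, ], cs@outer)
    if (length(ti)) tmin[q] <- ti[which.min(abs(ti))] - margin
    if (length(to)) tmax[q] <- to[which.min(abs(to))] + margin
    if (tmin[q] > tmax[q]) { tmin[q] <- -halfBand; tmax[q] <- halfBand }
  }
  outlines <- lapply(seq_len(nfw), function(fi)
    resampleContour(traceContour(maskStack[, , frames[fi]]), 1))
  for (fi in seq_len(nfw)) {
    O <- outlines[[fi]]
    for (q in seq_len(nm)) {
      ts <- lineContourIntersections(mid[q, ], nrm[q, ], O)
      ts <- ts[ts >= tmin[q] & ts <= tmax[q]]
      if (!length(ts)) next
      if (fi > 1L && !is.na(s[q, fi - 1L])) {
        ref <- s[q, fi - 1L]
        # a jump beyond the trust radius means the outline left this normal
        # (or a different outline branch crossed it): treat as missing
        if (min(abs(ts - ref)) > jumpCap) next
      } else {
        ref <- 0
      }
      s[q, fi] <- ts[which.min(abs(ts - ref))]
    }
  }
  # single-frame gaps are interpolated; longer gaps truncate the trajectory
  for (q in seq_len(nm)) {
    nas <- which(is.na(s[q, ]))
    for (fi in nas) {
      if (fi > 1L && fi < nfw && !is.na(s[q, fi - 1L]) && !is.na(s[q, fi + 1L]))
        s[q, fi] <- 0.5 * (s[q, fi - 1L] + s[q, fi + 1L])
    }
    bad <- which(is.na(s[q, ]))
    if (length(bad)) s[q, min(bad):nfw] <- NA_real_
  }
  list(mid = mid, normal = nrm, s = s, frames = frames)
}

#' Build edge trajectories from windowed contours
#'
#' Per mid-contour vertex, a normal segment clipped to the inner/outer band;
#' per frame, the cell-outline intersection nearest the previous frame's
#' point becomes the trajectory point. Across consecutive windows, normals
#' are matched greedily by the proximity of the last and first intersection
#' points (distance cap \code{matchCap}); unmatched normals start or end
#' trajectories.
#'
#' @param contourSets output of \code{\link{windowContours}}.
#' @param maskStack the mask stack the contours were computed from.
#' @param matchCap maximum endpoint distance (px) for continuing a trajectory
#'   across windows.
#' @return A \linkS4class{TrajectoryBundle} (signal slot empty; see
#'   \code{\link{kymographs}}).
#' @export
buildTrajectories <- function(contourSets, maskStack, matchCap = 5) {
  nf <- dim(maskStack)[3]
  tracks <- lapply(contourSets, trackWindow, maskStack = maskStack)
  rows_x <- list(); rows_y <- list(); rows_v <- list()
  open_idx <- integer(0)   # row id of the open trajectory per current vertex
  prev <- NULL
  nextRow <- 0L
  for (w in seq_along(tracks)) {
    tw <- tracks[[w]]
    nm <- nrow(tw$mid)
    assign_row <- integer(nm)
    if (is.null(prev)) {
      assign_row <- seq_len(nm)
      nextRow <- nm
      for (q in seq_len(nm)) {
        rows_x[[q]] <- rep(NA_real_, nf); rows_y[[q]] <- rep(NA_real_, nf)
        rows_v[[q]] <- rep(NA_real_, nf)
      }
    } else {
      # endpoints of open trajectories vs first intersections of new normals
      lastF <- max(prev$frames)
      pl <- prev$s[, length(prev$frames)]
      pxy <- prev$mid + prev$normal * cbind(pl, pl)
      f1 <- tw$s[, 1]
      nxy <- tw$mid + tw$normal * cbind(f1, f1)
      cand <- which(!is.na(pl) & open_idx > 0L)
      new_ok <- which(!is.na(f1))
      if (length(cand) && length(new_ok)) {
        dm <- outer(cand, new_ok, function(a, b)
          sqrt((pxy[a, 1] - nxy[b, 1])^2 + (pxy[a, 2] - nxy[b, 2])^2))
        ord <- order(dm)
        used_p <- logical(length(cand)); used_n <- logical(length(new_ok))
        for (o in ord) {
          if (dm[o] > matchCap) break
          ai <- (o - 1L) %% length(cand) + 1L
          bi <- (o - 1L) %/% length(cand) + 1L
          if (used_p[ai] || used_n[bi]) next
          used_p[ai] <- TRUE; used_n[bi] <- TRUE
          assign_row[new_ok[bi]] <- open_idx[cand[ai]]
        }
      }
      for (q in seq_len(nm)) {
        if (assign_row[q] == 0L) {
          nextRow <- nextRow + 1L
          assign_row[q] <- nextRow
          rows_x[[nextRow]] <- rep(NA_real_, nf)
          rows_y[[nextRow]] <- rep(NA_real_, nf)
          rows_v[[nextRow]] <- rep(NA_real_, nf)
        }
      }
    }
    # fill coordinates and within-window velocities
    for (q in seq_len(nm)) {
      ri <- assign_row[q]
      for (fi in seq_along(tw$frames)) {
        sv <- tw$s[q, fi]
        if (is.na(sv)) next
        fr <- tw$frames[fi]
        rows_x[[ri]][fr] <- tw$mid[q, 1] + sv * tw$normal[q, 1]
        rows_y[[ri]][fr] <- tw$mid[q, 2] + sv * tw$normal[q, 2]
        if (fi > 1L && !is.na(tw$s[q, fi - 1L])) {
          rows_v[[ri]][fr] <- sv - tw$s[q, fi - 1L]
        } else if (fi == 1L && w > 1L) {
          # junction velocity: previous point projected onto the new normal
          fr0 <- fr - 1L
          px <- rows_x[[ri]][fr0]; py <- rows_y[[ri]][fr0]
          if (!is.na(px)) {
            s0 <- (px - tw$mid[q, 1]) * tw$normal[q, 1] +
                  (py - tw$mid[q, 2]) * tw$normal[q, 2]
            v0 <- sv - s0
            # junction displacements beyond the match cap are mismatches
            if (abs(v0) <= matchCap) rows_v[[ri]][fr] <- v0
          }
        }
      }
    }
    open_idx <- assign_row
    prev <- tw
  }
  X <- do.call(rbind, rows_x)
  Y <- do.call(rbind, rows_y)
  V <- do.call(rbind, rows_v)
  new("TrajectoryBundle", x = X, y = Y, velocity = V,
      signal = matrix(NA_real_, nrow(X), ncol(X)))
}

# mean of the normalized stack over the in-mask disc around a point
sampleDiscMean <- function(frameImg, frameMask, x, y, radius) {
  nr <- nrow(frameImg); nc <- ncol(frameImg)
  r0 <- max(1L, floor(x - radius)); r1 <- min(nr, ceiling(x + radius))
  c0 <- max(1L, floor(y - radius)); c1 <- min(nc, ceiling(y + radius))
  if (r0 > r1 || c0 > c1) return(NA_real_)
  rr <- r0:r1; cc <- c0:c1
  dg <- outer(rr - x, cc - y, function(a, b) a^2 + b^2) <= radius^2
  sel <- dg & (frameMask[rr, cc, drop = FALSE] != 0)
  if (!any(sel)) return(NA_real_)
  mean(frameImg[rr, cc, drop = FALSE][sel])
}

#' Velocity and signal kymographs
#'
#' Velocity is the signed per-frame displacement along the trajectory
#' (positive outward, i.e. protrusion); signal is the mean of the normalized
#' intensities over the in-mask disc of radius \code{radius} around each
#' trajectory point.
#'
#' @param bundle a \linkS4class{TrajectoryBundle}.
#' @param stack normalized biosensor stack (see
#'   \code{\link{normalizeBiosensor}}).
#' @param maskStack the mask stack.
#' @param radius signal-sampling neighborhood radius (px).
#' @return List with elements \code{velocity} and \code{signal}, both
#'   \linkS4class{Kymograph}s.
#' @export
kymographs <- function(bundle, stack, maskStack, radius = 2) {
  nt <- nrow(bundle@x); nf <- ncol(bundle@x)
  if (nt == 0L) stop("empty trajectory bundle")
  S <- matrix(NA_real_, nt, nf)
  for (fr in seq_len(nf)) {
    img <- stack[, , fr]
    msk <- maskStack[, , fr]
    for (ti in seq_len(nt)) {
      if (!is.na(bundle@x[ti, fr]))
        S[ti, fr] <- sampleDiscMean(img, msk, bundle@x[ti, fr],
                                    bundle@y[ti, fr], radius)
    }
  }
  list(velocity = new("Kymograph", data = bundle@velocity, kind = "velocity",
                      peaks = data.frame(trajectory = integer(0),
                                         frame = integer(0))),
       signal = new("Kymograph", data = S, kind = "signal",
                    peaks = data.frame(trajectory = integer(0),
                                       frame = integer(0))))
}

# ---------------------------------------------------------------------------
# Peak-aligned analysis
# ---------------------------------------------------------------------------

# velocity-peak detection shared by the aligned analysis and the kymograph
# annotations: SD trajectory filter, MAD region rule, size filter, strict
# local maxima, interior-window restriction
detectVelocityPeaks <- function(V, peakRule = "as-printed", halfWindow = 20L,
                                regionMinSize = 10L, sdFilter = 20) {
  vAll <- V[is.finite(V)]
  sdv <- sd(vAll)
  keep <- apply(V, 1, function(r) !any(abs(r) > sdFilter * sdv, na.rm = TRUE))
  V[!keep, ] <- NA_real_
  thr <- median(vAll) +
    (if (peakRule == "plus") 2 else -2) * mad(vAll, constant = 1)
  inRegion <- !is.na(V) & V > thr
  lab <- EBImage::bwlabel(EBImage::Image(inRegion * 1))
  labm <- EBImage::imageData(lab)
  sizes <- table(labm[labm > 0])
  good <- as.integer(names(sizes)[sizes >= regionMinSize])
  region <- matrix(labm %in% good, nrow(V), ncol(V))
  pk <- localMaxima2D(V, region)
  nf <- ncol(V)
  if (nrow(pk))
    pk <- pk[pk[, 2] > halfWindow & pk[, 2] <= nf - halfWindow, , drop = FALSE]
  pk
}

# strict 2D local maxima of `v` restricted to TRUE cells of `region`
localMaxima2D <- function(v, region) {
  nr <- nrow(v); nc <- ncol(v)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- ifelse(is.na(v), -Inf, v)
  best <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbv <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc, drop = FALSE]
    best <- best & (ifelse(is.na(v), -Inf, v) > nbv)
  }
  which(best & region, arr.ind = TRUE)
}

#' Velocity-peak-aligned analysis of kymographs
#'
#' (1) drops trajectories containing any |v| > 20 SD (segmentation-artifact
#' filter); (2) thresholds the velocity kymograph at median - 2 MAD (rule
#' \code{"as-printed"}; \code{"plus"} uses median + 2 MAD) and keeps
#' connected regions of at least \code{regionMinSize} pixels; (3) locates
#' strict local velocity maxima inside the regions; (4) extracts +/- 20-frame
#' windows of velocity and signal around each peak; (5) averages across peaks
#' with 97.5\% confidence half-widths. The signal derivative is the
#' difference from the previous frame; the edge coordinate is the running
#' integral (cumulative sum) of the mean velocity trace.
#'
#' @param velKym,sigKym aligned velocity/signal \linkS4class{Kymograph}s.
#' @param peakRule sign of the MAD term in the region criterion.
#' @param halfWindow frames on each side of a peak (20).
#' @param regionMinSize minimum region size in kymograph pixels.
#' @param sdFilter trajectory filter threshold in velocity SDs.
#' @return A \linkS4class{PeakSummary}; empty (nPeaks = 0) with a warning
#'   when no admissible peak exists.
#' @export
peakAlignedAnalysis <- function(velKym, sigKym,
                                peakRule = c("as-printed", "plus"),
                                halfWindow = 20L, regionMinSize = 10L,
                                sdFilter = 20) {
  peakRule <- match.arg(peakRule)
  V <- velKym@data
  S <- sigKym@data
  stopifnot(identical(dim(V), dim(S)))
  pk <- detectVelocityPeaks(V, peakRule = peakRule, halfWindow = halfWindow,
                            regionMinSize = regionMinSize,
                            sdFilter = sdFilter)
  if (nrow(pk) == 0L) {
    warning("no velocity peaks found; returning empty summary")
    return(new("PeakSummary", velocity = numeric(0), signal = numeric(0),
               signalDeriv = numeric(0), coordinate = numeric(0),
               ciVelocity = numeric(0), ciSignal = numeric(0),
               nPeaks = 0L, lag = NA_real_))
  }
  win <- -halfWindow:halfWindow
  vtr <- matrix(NA_real_, nrow(pk), length(win))
  str_ <- matrix(NA_real_, nrow(pk), length(win))
  for (q in seq_len(nrow(pk))) {
    vtr[q, ] <- V[pk[q, 1], pk[q, 2] + win]
    str_[q, ] <- S[pk[q, 1], pk[q, 2] + win]
  }
  z <- qnorm(0.975)
  cm <- function(m) colMeans(m, na.rm = TRUE)
  chw <- function(m) {
    n <- colSums(!is.na(m))
    z * apply(m, 2, sd, na.rm = TRUE) / sqrt(pmax(n, 1))
  }
  mv <- cm(vtr); ms <- cm(str_)
  new("PeakSummary",
      velocity = mv, signal = ms,
      signalDeriv = c(NA_real_, diff(ms)),
      coordinate = cumsum(ifelse(is.na(mv), 0, mv)),
      ciVelocity = chw(vtr), ciSignal = chw(str_),
      nPeaks = nrow(pk),
      lag = as.numeric(which.max(ms) - (halfWindow + 1L)))
}

# ---------------------------------------------------------------------------
# Unit calibration
# ---------------------------------------------------------------------------

# global autocorrelation of a kymograph along one dimension
kymAutocorrelation <- function(K, along = c("time", "space"), maxLag = NULL) {
  along <- match.arg(along)
  M <- if (along == "time") K else t(K)
  M <- sweep(M, 1, rowMeans(M, na.rm = TRUE))
  nl <- ncol(M) - 1L
  if (!is.null(maxLag)) nl <- min(nl, maxLag)
  v0 <- mean(M^2, na.rm = TRUE)
  vapply(0:nl, function(l) {
    if (l == 0L) return(1)
    a <- M[, seq_len(ncol(M) - l), drop = FALSE]
    b <- M[, seq_len(ncol(M) - l) + l, drop = FALSE]
    mean(a * b, na.rm = TRUE) / v0
  }, numeric(1))
}

# first (interpolated) lag at which the curve crosses below `threshold`
decorrelationScale <- function(acfv, threshold = exp(-1)) {
  below <- which(acfv < threshold)
  if (!length(below)) stop("flat autocorrelation: no decorrelation observed")
  i <- below[1]
  if (i == 1L) return(0)
  (i - 2L) + (acfv[i - 1L] - threshold) / (acfv[i - 1L] - acfv[i])
}

#' Calibrate simulation units against an experimental kymograph
#'
#' Matches the temporal and spatial decorrelation scales (first crossing of
#' the autocorrelation below \code{threshold}) of a simulated and an
#' experimental velocity kymograph. With no experimental input the stored
#' reference constants are returned: 0.65 s and 10.127 microns per a.u.
#'
#' @param simKym simulated velocity \linkS4class{Kymograph} (or matrix).
#' @param expKym experimental counterpart; \code{NULL} returns the stored
#'   constants.
#' @param threshold decorrelation threshold (default 1/e).
#' @param secondsPerExpFrame,micronsPerExpPixel units of the experimental
#'   kymograph axes.
#' @return List with the decorrelation scales, the resulting
#'   \code{secondsPerAU} and \code{micronsPerAU}, and the autocorrelation
#'   curves.
#' @export
calibrateUnits <- function(simKym, expKym = NULL, threshold = exp(-1),
                           secondsPerExpFrame = 1, micronsPerExpPixel = 1) {
  if (is.null(expKym))
    return(list(secondsPerAU = 0.65, micronsPerAU = 10.127,
                source = "stored reference constants"))
  Ks <- if (is(simKym, "Kymograph")) simKym@data else simKym
  Ke <- if (is(expKym, "Kymograph")) expKym@data else expKym
  if (!length(Ks) || !length(Ke)) stop("empty kymograph")
  acfs <- list(simT = kymAutocorrelation(Ks, "time"),
               simS = kymAutocorrelation(Ks, "space"),
               expT = kymAutocorrelation(Ke, "time"),
               expS = kymAutocorrelation(Ke, "space"))
  tauSimT <- decorrelationScale(acfs$simT, threshold)
  tauSimS <- decorrelationScale(acfs$simS, threshold)
  tauExpT <- decorrelationScale(acfs$expT, threshold)
  tauExpS <- decorrelationScale(acfs$expS, threshold)
  list(secondsPerAU = tauExpT * secondsPerExpFrame / max(tauSimT, 1e-12),
       micronsPerAU = tauExpS * micronsPerExpPixel / max(tauSimS, 1e-12),
       scales = c(simTime = tauSimT, simSpace = tauSimS,
                  expTime = tauExpT, expSpace = tauExpS),
       acf = acfs, source = "autocorrelation matching")
}

# ---------------------------------------------------------------------------
# End-to-end and utilities
# ---------------------------------------------------------------------------

#' Run the full edge pipeline on a stack
#'
#' Normalization, windowed contours, trajectories, kymographs and
#' peak-aligned analysis in one call.
#'
#' @param maskStack binary 3D array.
#' @param signalStack raw biosensor 3D array.
#' @param window contour window length (frames).
#' @param radius signal-sampling radius (px).
#' @param peakRule see \code{\link{peakAlignedAnalysis}}.
#' @param halfWindow peak-alignment half window (frames).
#' @return List with \code{contours}, \code{bundle}, \code{kymographs}
#'   (velocity/signal) and \code{summary} (a \linkS4class{PeakSummary}).
#' @export
analyzeStack <- function(maskStack, signalStack, window = 20L, radius = 2,
                         peakRule = "as-printed", halfWindow = 20L) {
  norm <- normalizeBiosensor(signalStack, mask = maskStack)
  cs <- windowContours(maskStack, window = window)
  bundle <- buildTrajectories(cs, maskStack)
  kym <- kymographs(bundle, norm, maskStack, radius = radius)
  summary <- peakAlignedAnalysis(kym$velocity, kym$signal,
                                 peakRule = peakRule,
                                 halfWindow = halfWindow)
  pk <- detectVelocityPeaks(kym$velocity@data, peakRule = peakRule,
                            halfWindow = halfWindow)
  ann <- data.frame(trajectory = as.integer(pk[, 1]),
                    frame = as.integer(pk[, 2]))
  kym$velocity@peaks <- ann
  kym$signal@peaks <- ann
  list(contours = cs, bundle = bundle, kymographs = kym, summary = summary)
}

#' Basic mask extraction from raw intensity (convenience only)
#'
#' Global Otsu threshold followed by largest connected component and hole
#' filling. Proper segmentation is out of the pipeline's scope; masks are
#' normally accepted as input.
#'
#' @param img numeric matrix.
#' @return Logical mask matrix.
#' @export
maskFromIntensity <- function(img) {
  rng <- range(img)
  sc <- (img - rng[1]) / max(rng[2] - rng[1], 1e-12)
  th <- EBImage::otsu(EBImage::Image(sc))
  bw <- sc > th
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  if (max(lab) == 0) return(bw)
  big <- which.max(tabulate(lab[lab > 0]))
  filled <- EBImage::fillHull(EBImage::Image((lab == big) * 1))
  EBImage::imageData(filled) > 0
}
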