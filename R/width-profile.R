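## Bilinear interpolation of matrix `m` at 0-based pixel coordinates
## (x = col, y = row); points outside the image sample as 0.
sample_bilinear <- function(m, x, y) {
  nr <- nrow(m)
  nc <- ncol(m)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  get <- function(r, c) {
    ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
    out <- numeric(length(r))
    out[ok] <- m[cbind(r[ok] + 1, c[ok] + 1)]
    out
  }
  v00 <- get(y0, x0)
  v01 <- get(y0, x0 + 1)
  v10 <- get(y0 + 1, x0)
  v11 <- get(y0 + 1, x0 + 1)
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

moving_average <- function(v, window) {
  if (window <= 1) {
    return(v)
  }
  kern <- rep(1 / window, window)
  out <- stats::filter(v, kern, sides = 2)
  out[is.na(out)] <- v[is.na(out)]
  as.numeric(out)
}

## Local maxima indices of a numeric vector (strict rise, non-strict fall,
## so plateau starts count once).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) {
    return(integer(0))
  }
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

## Sub-sample refinement of a peak at index i of profile v with abscissae s:
## local quadratic regression over samples within `halfwin` of the peak
## (falls back to the discrete position when the fit is not concave).
refine_peak <- function(s, v, i, halfwin = 3 * (s[2] - s[1])) {
  sel <- which(abs(s - s[i]) <= halfwin)
  if (length(sel) < 3) {
    return(s[i])
  }
  x <- s[sel] - s[i]
  fit <- stats::lm.fit(cbind(1, x, x^2), v[sel])
  b <- fit$coefficients
  if (!is.finite(b[3]) || b[3] >= 0) {
    return(s[i])
  }
  vertex <- -b[2] / (2 * b[3])
  if (abs(vertex) > halfwin) {
    return(s[i])
  }
  s[i] + vertex
}

## 0.5-crossing positions of a mask profile: first crossing from the left
## and first from the right, linearly interpolated. Returns c(NA, NA) when
## the line misses the component.
mask_crossings <- function(s, mvals) {
  inside <- which(mvals >= 0.5)
  if (!length(inside)) {
    return(c(NA_real_, NA_real_))
  }
  il <- inside[1]
  ir <- inside[length(inside)]
  left <- if (il == 1) {
    s[1]
  } else {
    s[il - 1] + (0.5 - mvals[il - 1]) / (mvals[il] - mvals[il - 1]) *
      (s[il] - s[il - 1])
  }
  right <- if (ir == length(s)) {
    s[ir]
  } else {
    s[ir] + (mvals[ir] - 0.5) / (mvals[ir] - mvals[ir + 1]) *
      (s[ir + 1] - s[ir])
  }
  c(left, right)
}

#' Width profile along a cell's medial axis
#'
#' At every axis point the cross-sectional diameter is measured along the
#' line perpendicular to the local axis direction. The base measurement is
#' the sub-pixel 0.5-crossing span of the filled component; when the source
#' `image` is supplied, each boundary is refined to the membrane intensity
#' ridge (quadratic sub-pixel peak fit), the blur-invariant landmark of a
#' stained membrane. Axis points within `cap_factor` times the median
#' diameter of either axis end fall on the hemispherical poles and are
#' excluded from the width mean (`retained = FALSE`).
#'
#' @param mask A [segment_image()] result.
#' @param axis A [extract_medial_axis()] result for the same component.
#' @param image Optional source intensity image for ridge refinement.
#' @param cap_factor Pole exclusion distance as a fraction of the median
#'   profile diameter.
#' @param step_px Sampling step along the perpendicular, pixels.
#' @param max_halfwidth_um Half-length of the probed perpendicular, um.
#' @param smooth_window Moving-average window (samples) for the intensity
#'   profile before peak finding.
#' @return Tibble: `index`, `arc_pos_um`, `diameter_um`, `retained`.
#' @export
width_profile <- function(mask, axis, image = NULL,
                          cap_factor = 0.5, step_px = 0.2,
                          max_halfwidth_um = 1.6, smooth_window = 3L) {
  stopifnot(inherits(axis, "medial_axis"))
  if (nrow(axis$points) < 2) abort("axis must have >= 2 points.")
  px <- mask$pixel_size
  comp <- 1 * mask_component(mask, axis$label)
  P <- cbind(axis$points$x_um, axis$points$y_um) / px # axis in px coords
  n <- nrow(P)
  ## tangents by central differences (forward/backward at the ends)
  if (n == 2) {
    tx <- rep(P[2, 1] - P[1, 1], 2)
    ty <- rep(P[2, 2] - P[1, 2], 2)
  } else {
    tx <- c(P[2, 1] - P[1, 1], P[3:n, 1] - P[1:(n - 2), 1], P[n, 1] - P[n - 1, 1])
    ty <- c(P[2, 2] - P[1, 2], P[3:n, 2] - P[1:(n - 2), 2], P[n, 2] - P[n - 1, 2])
  }
  tl <- sqrt(tx^2 + ty^2)
  tl[tl == 0] <- 1
  nx <- -ty / tl
  ny <- tx / tl
  svals <- seq(-max_halfwidth_um, max_halfwidth_um, by = step_px * px)

  diam <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    xs <- P[i, 1] + (svals / px) * nx[i]
    ys <- P[i, 2] + (svals / px) * ny[i]
    mvals <- sample_bilinear(comp, xs, ys)
    cr <- mask_crossings(svals, mvals)
    if (anyNA(cr)) next
    d <- cr[2] - cr[1]
    if (!is.null(image)) {
      ivals <- moving_average(sample_bilinear(image, xs, ys), smooth_window)
      base <- min(ivals)
      pk <- local_maxima(ivals)
      pk <- pk[ivals[pk] - base >= 0.5 * (max(ivals) - base)]
      mid <- (cr[1] + cr[2]) / 2
      lpk <- pk[svals[pk] < mid & svals[pk] >= cr[1] - 2 * px]
      rpk <- pk[svals[pk] > mid & svals[pk] <= cr[2] + 2 * px]
      if (length(lpk) && length(rpk)) {
        lpos <- refine_peak(svals, ivals, lpk[1], halfwin = 1.5 * px)
        rpos <- refine_peak(svals, ivals, rpk[length(rpk)], halfwin = 1.5 * px)
        if (rpos - lpos > 0) d <- rpos - lpos
      }
    }
    diam[i] <- d
  }

  seg <- sqrt(diff(P[, 1])^2 + diff(P[, 2])^2) * px
  arc <- c(0, cumsum(seg))
  total <- arc[n]
  d_cap <- cap_factor * median(diam, na.rm = TRUE)
  retained <- !is.na(diam) & arc >= d_cap & arc <= total - d_cap
  tibble::tibble(
    index = seq_len(n),
    arc_pos_um = arc,
    diameter_um = diam,
    retained = retained
  )
}

#' Cell diameter from an intensity line profile
#'
#' The manual cross-check used with membrane stains: sample the intensity
#' along a probe line drawn roughly perpendicular to the cell's long axis,
#' smooth it, and report the distance between the two highest local maxima
#' on opposite sides of the line midpoint -- the peak-to-peak span of the
#' two membrane crossings.
#'
#' @param image 2-D intensity matrix.
#' @param p0,p1 Probe line endpoints, `(x, y)` in micrometres.
#' @param pixel_size Micrometres per pixel.
#' @param smooth_window Moving-average window, samples.
#' @param step_px Sampling step along the line, pixels.
#' @param min_prominence Minimum peak height above background, as a
#'   fraction of the profile's dynamic range.
#' @return Diameter in micrometres.
#' @export
profile_maxima_width <- function(image, p0, p1, pixel_size,
                                 smooth_window = 5L, step_px = 0.25,
                                 min_prominence = 0.3) {
  stopifnot(is.matrix(image), length(p0) == 2, length(p1) == 2)
  L <- sqrt(sum((p1 - p0)^2))
  if (L <= 0) abort("probe line has zero length.")
  svals <- seq(0, L, by = step_px * pixel_size)
  xs <- (p0[1] + svals / L * (p1[1] - p0[1])) / pixel_size
  ys <- (p0[2] + svals / L * (p1[2] - p0[2])) / pixel_size
  ivals <- moving_average(sample_bilinear(image, xs, ys), smooth_window)
  base <- min(ivals)
  rng <- max(ivals) - base
  pk <- local_maxima(ivals)
  pk <- pk[ivals[pk] - base >= min_prominence * rng]
  mid <- L / 2
  lpk <- pk[svals[pk] < mid]
  rpk <- pk[svals[pk] > mid]
  if (!length(lpk) || !length(rpk)) {
    abort("no membrane peaks: the probe line must cross one cell perpendicular to its axis.")
  }
  li <- lpk[which.max(ivals[lpk])]
  ri <- rpk[which.max(ivals[rpk])]
  hw <- 1.5 * pixel_size
  abs(refine_peak(svals, ivals, ri, hw) - refine_peak(svals, ivals, li, hw))
}
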