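## Zhang-Suen binary thinning, vectorised over the whole matrix.
## Returns a 1-pixel-wide 8-connected skeleton.
thin_binary <- function(m) {
  stopifnot(is.logical(m) || all(m %in% c(0, 1)))
  m <- m != 0
  nr <- nrow(m)
  nc <- ncol(m)
  ## pad with FALSE so neighbour shifts stay in range
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  shift <- function(mm, dr, dc) {
    out <- matrix(FALSE, nrow(mm), ncol(mm))
    r_src <- (1 + max(0, -dr)):(nrow(mm) - max(0, dr))
    c_src <- (1 + max(0, -dc)):(ncol(mm) - max(0, dc))
    out[r_src + dr, c_src + dc] <- mm[r_src, c_src]
    out
  }
  ## neighbours P2..P9 clockwise from north (row - 1)
  offs <- list(
    c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
    c(1, 0), c(1, -1), c(0, -1), c(-1, -1)
  )
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- lapply(offs, function(o) shift(p, -o[1], -o[2]))
      ## nb[[k]][i,j] is the value at the neighbour offset offs[[k]] of (i,j)
      B <- Reduce(`+`, nb)
      seqmat <- c(nb, nb[1])
      A <- matrix(0L, nrow(p), ncol(p))
      for (k in 1:8) {
        A <- A + (!seqmat[[k]] & seqmat[[k + 1]])
      }
      if (sub == 1) {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[5]]) # P2*P4*P6 == 0
        c2 <- !(nb[[3]] & nb[[5]] & nb[[7]]) # P4*P6*P8 == 0
      } else {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[7]]) # P2*P4*P8 == 0
        c2 <- !(nb[[1]] & nb[[5]] & nb[[7]]) # P2*P6*P8 == 0
      }
      del <- p & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        p[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nr + 1), 2:(nc + 1)]
}

#' Extract the medial axis of one segmented cell
#'
#' Computes the topological skeleton of the component (Zhang-Suen
#' thinning), prunes it to its single longest path between skeleton
#' endpoints, orients it along the component's principal axis, and smooths
#' it with an endpoint-preserving moving average. The skeleton of a
#' spherocylindrical cell terminates about half a width inside each pole,
#' so the axis arc length approximates `length - width`.
#'
#' Thinning shortens skeleton ends by a few pixels beyond the geometric
#' `w/2` inset, so each end is extended along its local tangent across the
#' (bilinearly interpolated) distance transform: extension stops where the
#' boundary distance starts falling at the rate characteristic of a
#' hemispherical cap, which recovers the cylinder-segment endpoints.
#'
#' @param mask A [segment_image()] result.
#' @param label Component label.
#' @param smooth_window Moving-average window (odd, points).
#' @return A list of class `medial_axis`: `points` (tibble `x_um`, `y_um`,
#'   ordered pole to pole), `arc_length_um`, `label`; or `NULL` when the
#'   component's skeleton has no path of at least 2 pixels (too-small /
#'   spherical components, handled downstream as minicell candidates).
#' @export
extract_medial_axis <- function(mask, label, smooth_window = 5L) {
  comp <- mask_component(mask, label)
  if (sum(comp) < 2) {
    return(NULL)
  }
  px <- mask$pixel_size
  idx <- which(comp, arr.ind = TRUE)
  r0 <- min(idx[, 1]) - 1L
  c0 <- min(idx[, 2]) - 1L
  sub <- comp[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]),
    drop = FALSE
  ]
  skel <- thin_binary(sub)
  pts <- which(skel, arr.ind = TRUE)
  if (nrow(pts) < 2) {
    return(NULL)
  }

  ## 8-connected skeleton graph, edges weighted by euclidean step length
  key <- paste(pts[, 1], pts[, 2])
  id <- seq_len(nrow(pts))
  lut <- stats::setNames(id, key)
  edges <- NULL
  wts <- NULL
  for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nk <- paste(pts[, 1] + o[1], pts[, 2] + o[2])
    hit <- !is.na(lut[nk])
    if (any(hit)) {
      edges <- rbind(edges, cbind(id[hit], unname(lut[nk[hit]])))
      wts <- c(wts, rep(sqrt(sum(o^2)), sum(hit)))
    }
  }
  if (is.null(edges)) {
    return(NULL)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  if (igraph::vcount(g) < nrow(pts)) {
    g <- igraph::add_vertices(g, nrow(pts) - igraph::vcount(g))
  }
  comps <- igraph::components(g)
  main <- which.max(comps$csize)
  vmain <- which(comps$membership == main)
  deg <- igraph::degree(g)
  ends <- intersect(vmain, which(deg <= 1))
  if (length(ends) < 2) ends <- vmain[seq_len(min(30, length(vmain)))]
  dm <- igraph::distances(g, v = ends, to = ends)
  far <- which(dm == max(dm[is.finite(dm)]), arr.ind = TRUE)[1, ]
  path <- igraph::shortest_paths(
    g,
    from = ends[far[1]], to = ends[far[2]], output = "vpath"
  )$vpath[[1]]
  path <- as.integer(path)
  if (length(path) < 2) {
    return(NULL)
  }

  ## 0-based pixel coords (x = col, y = row), back in the full image frame
  xy <- cbind(
    x = pts[path, 2] - 1 + c0,
    y = pts[path, 1] - 1 + r0
  )
  ## orient along the component's principal axis
  full <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  pc <- eigen(stats::cov(full))$vectors[, 1]
  proj <- xy %*% pc
  if (proj[1] > proj[length(path)]) xy <- xy[rev(seq_len(nrow(xy))), ]

  ## thinning leaves residual tails running into the hemispherical caps
  ## (skeleton endpoints are topologically protected); cut path ends where
  ## the boundary distance is still climbing at the cap's characteristic
  ## rate, leaving the on-ridge body of the axis
  if (nrow(xy) > 6) {
    Dm <- as.matrix(EBImage::distmap(EBImage::Image(1 * comp)))
    dv <- sample_bilinear(Dm, xy[, 1], xy[, 2])
    steep <- function(ord) {
      k <- 1L
      nn <- length(ord)
      while (nn - k > 5 && k + 2 <= nn) {
        i <- ord[k]
        j <- ord[k + 2]
        ds <- sqrt(sum((xy[j, ] - xy[i, ])^2))
        if (ds > 0 && (dv[j] - dv[i]) / ds > 0.35) k <- k + 1L else break
      }
      k
    }
    kh <- steep(seq_len(nrow(xy)))
    kt <- steep(rev(seq_len(nrow(xy))))
    xy <- xy[kh:(nrow(xy) - kt + 1L), , drop = FALSE]
  }

  ## endpoint-preserving moving average: symmetric window that shrinks at
  ## the ends, so the poles of the axis are not pulled inward
  n <- nrow(xy)
  k <- (as.integer(smooth_window) - 1L) %/% 2L
  sm <- xy
  if (k > 0 && n > 2) {
    for (i in seq_len(n)) {
      ki <- min(k, i - 1L, n - i)
      if (ki > 0) sm[i, ] <- colMeans(xy[(i - ki):(i + ki), , drop = FALSE])
    }
  }
  sm <- extend_axis_ends(sm, comp)

  seg <- sqrt(diff(sm[, 1])^2 + diff(sm[, 2])^2)
  structure(
    list(
      points = tibble::tibble(x_um = sm[, 1] * px, y_um = sm[, 2] * px),
      arc_length_um = sum(seg) * px,
      label = label
    ),
    class = "medial_axis"
  )
}

## Extend both ends of an axis polyline (0-based px coords) along the local
## tangent using the interpolated distance transform. On the ridge the
## boundary distance equals the local radius r; inside a hemispherical cap
## it falls off at 1 px per px travelled. Each end walks until the distance
## has dropped clearly below its local ridge reference, then trims back by
## the distance deficit, landing the endpoint where the cap begins.
extend_axis_ends <- function(xy, comp, step = 0.5, overshoot = 1.5) {
  D <- as.matrix(EBImage::distmap(EBImage::Image(1 * comp)))
  dist_at <- function(x, y) sample_bilinear(D, x, y)
  n <- nrow(xy)
  ridge <- dist_at(xy[, 1], xy[, 2])
  tang <- function(a, b) {
    v <- a - b
    L <- sqrt(sum(v^2))
    if (L == 0) c(1, 0) else v / L
  }
  cmat <- 1 * comp
  ## sub-pixel 0.5-crossing of the bilinearly interpolated mask along the
  ## ray p0 + s*dir, s in (0, smax]; NA when the ray never leaves the mask
  ray_exit <- function(p0, dir, smax) {
    sv <- seq(0, smax, by = 0.125)
    cv <- sample_bilinear(cmat, p0[1] + sv * dir[1], p0[2] + sv * dir[2])
    out <- which(cv < 0.5)
    out <- out[out > 1]
    if (!length(out)) {
      return(NA_real_)
    }
    i <- out[1]
    sv[i - 1] + (cv[i - 1] - 0.5) / (cv[i - 1] - cv[i]) * 0.125
  }
  ## trace the distance-transform ridge outward from the skeleton end,
  ## re-centring laterally every step (so curved cells are followed along
  ## their own centreline), until the distance drops sharply -- the
  ## signature of entering a hemispherical cap. The final endpoint is then
  ## placed by the boundary-inset rule: walk a straight ray to the mask's
  ## sub-pixel pole boundary and step back by the local mask radius (half
  ## the perpendicular 0.5-crossing span). Both landmarks share one
  ## boundary convention, so under the uniform edge dilation of a blurred,
  ## thresholded capsule the endpoint lands on the cylinder-segment end,
  ## half a width inside the pole.
  walk <- function(p0, dir0, r_ref) {
    pts <- NULL
    p <- p0
    dir <- dir0
    recent <- dist_at(p0[1], p0[2])
    cap_entry <- p0
    cap_dir <- dir0
    for (k in seq_len(400)) {
      q <- p + step * dir
      nrm <- c(-dir[2], dir[1])
      cs <- seq(-0.75, 0.75, by = 0.25)
      dv <- dist_at(q[1] + cs * nrm[1], q[2] + cs * nrm[2])
      off <- refine_peak(cs, dv, which.max(dv), halfwin = 0.5)
      q <- q + off * nrm
      v <- q - p
      vl <- sqrt(sum(v^2))
      if (vl == 0 || sum(v * dir) <= 0) break
      d <- dist_at(q[1], q[2])
      ref <- median(tail(recent, 8))
      if (d < ref - 0.8 || d <= 0.5) {
        cap_entry <- p
        cap_dir <- dir
        break
      }
      pts <- rbind(pts, q)
      recent <- c(recent, d)
      dir <- v / vl
      p <- q
      cap_entry <- p
      cap_dir <- dir
    }
    ## sub-pixel landing from the cap entry
    nrm <- c(-cap_dir[2], cap_dir[1])
    half_span <- function(sgn) ray_exit(cap_entry, sgn * nrm, 3 * r_ref + 4)
    r_loc <- mean(c(half_span(1), half_span(-1)), na.rm = TRUE)
    if (!is.finite(r_loc)) r_loc <- r_ref
    s_cross <- ray_exit(cap_entry, cap_dir, 3 * r_ref + 8)
    if (!is.na(s_cross)) {
      reach <- s_cross - r_loc
      if (!is.null(pts)) {
        proj <- as.numeric((pts - matrix(cap_entry, nrow(pts), 2,
          byrow = TRUE
        )) %*% cap_dir)
        pts <- pts[proj < reach - 1e-9, , drop = FALSE]
      }
      q_end <- cap_entry + reach * cap_dir
      ## append as long as the landing lies beyond the skeleton end itself
      if (sum((q_end - p0) * dir0) > 0.01) pts <- rbind(pts, q_end)
    }
    pts
  }
  i0 <- min(4, n)
  ## re-centre the walk start on the distance-transform ridge: the thinned
  ## skeleton can sit a fraction of a pixel off the true centreline, which
  ## would bias both the walk line and its ridge reference
  recentre <- function(p, dir) {
    nrm <- c(-dir[2], dir[1])
    cs <- seq(-1.5, 1.5, by = 0.25)
    dv <- dist_at(p[1] + cs * nrm[1], p[2] + cs * nrm[2])
    i <- which.max(dv)
    off <- refine_peak(cs, dv, i, halfwin = 0.75)
    p + off * nrm
  }
  head_dir <- tang(xy[1, ], xy[i0, ])
  tail_dir <- tang(xy[n, ], xy[n - i0 + 1, ])
  head_p <- recentre(xy[1, ], head_dir)
  tail_p <- recentre(xy[n, ], tail_dir)
  pre <- walk(head_p, head_dir, dist_at(head_p[1], head_p[2]))
  post <- walk(tail_p, tail_dir, dist_at(tail_p[1], tail_p[2]))
  if (!is.null(pre)) xy <- rbind(pre[rev(seq_len(nrow(pre))), , drop = FALSE], xy)
  if (!is.null(post)) xy <- rbind(xy, post)
  xy
}
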