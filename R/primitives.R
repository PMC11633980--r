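# Low-level raster primitives shared by the detectors. Morphology and
# convolution are delegated to EBImage; the Canny detector, Hough transform,
# polygon simplification and the 8-connectivity merge are implemented here.
# Convention throughout: matrices are indexed [row, col]; exported coordinates
# are 0-based with x = column, y = row.

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# 2-D convolution returning a plain matrix (EBImage::filter2 yields an Image,
# whose dims would be dropped by arithmetic like pmin/pmax).
conv2 <- function(x, k, boundary = "replicate") {
  out <- EBImage::filter2(x, k, boundary = boundary)
  matrix(as.numeric(EBImage::imageData(out)), nrow(x), ncol(x))
}

# Binary dilation/erosion with a disc structuring element.
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::dilate(mask * 1, disc_brush(radius)) > 0
}

erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::erode(mask * 1, disc_brush(radius)) > 0
}

# Grayscale maximum filter over a size x size square window.
max_filter <- function(px, size) {
  if (size <= 1) return(px)
  out <- EBImage::dilate(px, EBImage::makeBrush(as.integer(size), shape = "box"))
  matrix(as.numeric(EBImage::imageData(out)), nrow(px), ncol(px))
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected; labels
# touching only diagonally are merged afterwards through union-find.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a <- lab[-h, -w]; b <- lab[-1, -1]       # down-right diagonal
  c_ <- lab[-h, -1]; d <- lab[-1, -w]      # down-left diagonal
  pairs <- rbind(
    cbind(as.vector(a), as.vector(b)),
    cbind(as.vector(c_), as.vector(d))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

# Per-label tight bounding boxes as a tibble of 0-based half-open coordinates.
component_boxes <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(label = integer(), x_left = integer(), y_top = integer(),
                          x_right = integer(), y_bottom = integer(),
                          w = integer(), h = integer(), area = integer()))
  }
  h <- nrow(lab)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  labs <- lab[idx]
  tibble::tibble(
    label = as.integer(tapply(labs, labs, function(v) v[1])),
    x_left = as.integer(tapply(cols, labs, min)) - 1L,
    y_top = as.integer(tapply(rows, labs, min)) - 1L,
    x_right = as.integer(tapply(cols, labs, max)),
    y_bottom = as.integer(tapply(rows, labs, max)),
    area = as.integer(tapply(labs, labs, length))
  ) |>
    dplyr::mutate(w = .data$x_right - .data$x_left, h = .data$y_bottom - .data$y_top)
}

# Outer contours of labelled components, as 0-based (x, y) point matrices.
component_contours <- function(lab) {
  oc <- EBImage::ocontour(lab)
  lapply(oc, function(p) cbind(x = p[, 2], y = p[, 1]))  # ocontour: (dim1, dim2) = (row, col)
}

# Douglas-Peucker simplification of a closed contour. The polygon is split at
# the two mutually most distant anchor points (approximate: farthest point from
# the first vertex, then farthest from that) and each open chain is simplified.
simplify_polygon <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 3) return(pts)
  d1 <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
  a <- which.max(d1)
  d2 <- (pts[, 1] - pts[a, 1])^2 + (pts[, 2] - pts[a, 2])^2
  b <- which.max(d2)
  i <- min(a, b); j <- max(a, b)
  chain1 <- pts[i:j, , drop = FALSE]
  chain2 <- pts[c(j:n, 1:i), , drop = FALSE]
  v <- rbind(dp_chain(chain1, eps), dp_chain(chain2, eps)[-1, , drop = FALSE])
  v[-nrow(v), , drop = FALSE]   # last point duplicates the first
}

dp_chain <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  p0 <- pts[1, ]; p1 <- pts[n, ]
  seg <- p1 - p0
  len <- sqrt(sum(seg^2))
  d <- if (len < .Machine$double.eps) {
    sqrt((pts[, 1] - p0[1])^2 + (pts[, 2] - p0[2])^2)
  } else {
    abs(seg[2] * (pts[, 1] - p0[1]) - seg[1] * (pts[, 2] - p0[2])) / len
  }
  k <- which.max(d)
  if (d[k] <= eps) {
    rbind(p0, p1)
  } else {
    rbind(dp_chain(pts[1:k, , drop = FALSE], eps),
          dp_chain(pts[k:n, , drop = FALSE], eps)[-1, , drop = FALSE])
  }
}

# Interior angles (degrees) at each vertex of a closed polygon, plus the
# orientations (degrees in [0, 180)) of the two incident edges.
polygon_vertex_geometry <- function(v) {
  n <- nrow(v)
  prev <- v[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- v[c(2:n, 1), , drop = FALSE]
  e_in <- v - prev; e_out <- nxt - v
  ang <- function(e) (atan2(e[, 2], e[, 1]) * 180 / pi) %% 180
  dot <- rowSums(-e_in * e_out)
  nrm <- sqrt(rowSums(e_in^2)) * sqrt(rowSums(e_out^2))
  inner <- acos(pmin(1, pmax(-1, dot / pmax(nrm, .Machine$double.eps)))) * 180 / pi
  list(angle = inner, dir_in = ang(e_in), dir_out = ang(e_out),
       len_in = sqrt(rowSums(e_in^2)), len_out = sqrt(rowSums(e_out^2)))
}

# Canny edge detector: Gaussian blur, Sobel gradients, non-maximum suppression
# (ties kept, so symmetric step edges retain both candidate columns), double
# threshold with hysteresis through 8-connected weak-edge components.
canny_edges <- function(px, low = 50, high = 150, sigma = 1) {
  px <- as.matrix(px) * 1.0
  if (sigma > 0) {
    size <- max(3L, 2L * ceiling(2 * sigma) + 1L)
    px <- conv2(px, EBImage::makeBrush(size, "gaussian", sigma = sigma))
  }
  kx <- outer(c(1, 2, 1), c(-1, 0, 1))    # d/dx (columns)
  ky <- outer(c(-1, 0, 1), c(1, 2, 1))    # d/dy (rows)
  gx <- conv2(px, kx)
  gy <- conv2(px, ky)
  mag <- sqrt(gx^2 + gy^2)
  h <- nrow(mag); w <- ncol(mag)
  theta <- atan2(gy, gx) * 180 / pi
  theta <- theta %% 180
  sector <- ifelse(theta < 22.5 | theta >= 157.5, 1L,        # horizontal gradient
            ifelse(theta < 67.5, 2L,                          # diagonal /
            ifelse(theta < 112.5, 3L, 4L)))                   # vertical, diagonal \
  pad <- matrix(0, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- mag
  nb <- function(dr, dc) pad[2:(h + 1) + dr, 2:(w + 1) + dc]
  keep <- (sector == 1L & mag >= nb(0, -1) & mag >= nb(0, 1)) |
          (sector == 2L & mag >= nb(-1, 1) & mag >= nb(1, -1)) |
          (sector == 3L & mag >= nb(-1, 0) & mag >= nb(1, 0)) |
          (sector == 4L & mag >= nb(-1, -1) & mag >= nb(1, 1))
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  if (!any(strong)) return(matrix(FALSE, h, w))
  lab <- label_components(weak)
  keep_labels <- unique(lab[strong])
  keep_labels <- keep_labels[keep_labels > 0]
  matrix(lab %in% keep_labels, h, w)
}

# Hough transform with segment extraction. Returns one row per detected
# segment: the line parameters (theta in radians, rho in pixels) and the
# 0-based endpoint/bounding extents of the supporting pixel run. Runs are
# maximal projections of near-line pixels with gaps <= max_gap.
hough_segments <- function(mask, min_len = 15, max_gap = 4, band = 1.5,
                           max_lines = 8, theta_step_deg = 1) {
  idx <- which(mask)
  if (length(idx) < min_len) return(empty_segments())
  h <- nrow(mask)
  y <- ((idx - 1L) %% h)
  x <- ((idx - 1L) %/% h)
  thetas <- seq(0, pi, by = theta_step_deg * pi / 180)
  thetas <- thetas[-length(thetas)]
  diag_len <- ceiling(sqrt(nrow(mask)^2 + ncol(mask)^2))
  acc <- matrix(0L, nrow = 2L * diag_len + 1L, ncol = length(thetas))
  for (j in seq_along(thetas)) {
    rho <- round(x * cos(thetas[j]) + y * sin(thetas[j]))
    acc[, j] <- tabulate(rho + diag_len + 1L, nbins = 2L * diag_len + 1L)
  }
  segs <- list()
  for (k in seq_len(max_lines)) {
    peak <- which.max(acc)
    if (acc[peak] < min_len) break
    pr <- ((peak - 1L) %% nrow(acc)) + 1L
    pc <- ((peak - 1L) %/% nrow(acc)) + 1L
    th <- thetas[pc]; rh <- pr - diag_len - 1L
    # suppress the neighbourhood so the next peak is a genuinely different line
    rrange <- max(1, pr - 5):min(nrow(acc), pr + 5)
    crange <- unique((((pc - 4):(pc + 4)) - 1L) %% length(thetas) + 1L)
    acc[rrange, crange] <- 0L
    d <- x * cos(th) + y * sin(th) - rh
    on_line <- abs(d) <= band
    if (sum(on_line) < min_len) next
    t_ <- -x[on_line] * sin(th) + y[on_line] * cos(th)
    xs <- x[on_line]; ys <- y[on_line]
    ord <- order(t_)
    t_ <- t_[ord]; xs <- xs[ord]; ys <- ys[ord]
    run_start <- 1L
    for (i in seq_along(t_)) {
      gap_next <- if (i < length(t_)) t_[i + 1L] - t_[i] else Inf
      if (gap_next > max_gap) {
        if (t_[i] - t_[run_start] + 1 >= min_len) {
          rng <- run_start:i
          segs[[length(segs) + 1L]] <- tibble::tibble(
            theta = th, rho = rh,
            length = t_[i] - t_[run_start] + 1,
            x0 = xs[run_start], y0 = ys[run_start], x1 = xs[i], y1 = ys[i],
            xmin = min(xs[rng]), xmax = max(xs[rng]),
            ymin = min(ys[rng]), ymax = max(ys[rng])
          )
        }
        run_start <- i + 1L
      }
    }
  }
  if (length(segs) == 0) return(empty_segments())
  dplyr::bind_rows(segs)
}

empty_segments <- function() {
  tibble::tibble(theta = numeric(), rho = numeric(), length = numeric(),
                 x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
                 xmin = numeric(), xmax = numeric(), ymin = numeric(), ymax = numeric())
}

# TRUE iff two segments' supporting lines are non-parallel (angle difference
# beyond tol) and intersect within both segments' padded bounding extents.
segments_cross <- function(s1, s2, parallel_tol_deg = 5, pad = 3) {
  dtheta <- abs(s1$theta - s2$theta) * 180 / pi
  dtheta <- min(dtheta, 180 - dtheta)
  if (dtheta <= parallel_tol_deg) return(FALSE)
  a <- matrix(c(cos(s1$theta), sin(s1$theta), cos(s2$theta), sin(s2$theta)),
              2, 2, byrow = TRUE)
  det_a <- a[1, 1] * a[2, 2] - a[1, 2] * a[2, 1]
  if (abs(det_a) < 1e-9) return(FALSE)
  p <- solve(a, c(s1$rho, s2$rho))
  within <- function(s) {
    p[1] >= s$xmin - pad && p[1] <= s$xmax + pad &&
      p[2] >= s$ymin - pad && p[2] <= s$ymax + pad
  }
  within(s1) && within(s2)
}
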