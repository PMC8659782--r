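# Shape and size descriptors of the segmented specimen.
#
# Geometry convention: the rasterised specimen is treated as a union of unit
# pixel squares.  The ordered outer contour (through pixel centers) gives the
# perimeter; rectangles and the enclosing circle are computed on the convex
# hull of the boundary pixels' corners, so a filled 100 x 100 square measures
# exactly 100 x 100.  Area is the foreground pixel count (projected area).

# Ordered outer contour of the single foreground object, as an n x 2 matrix
# of (x, y) pixel-center coordinates (x = column, y = row, 1-based).
outer_contour <- function(mask) {
  oc <- EBImage::ocontour(t(mask))
  if (length(oc) == 0L) abort("empty mask: no contour")
  pts <- oc[[which.max(vapply(oc, nrow, 1L))]]
  cbind(x = pts[, 1] + 1, y = pts[, 2] + 1)
}

# The four unit-square corners of each boundary pixel.
corner_cloud <- function(pts) {
  rbind(
    cbind(pts[, 1] - 0.5, pts[, 2] - 0.5),
    cbind(pts[, 1] + 0.5, pts[, 2] - 0.5),
    cbind(pts[, 1] - 0.5, pts[, 2] + 0.5),
    cbind(pts[, 1] + 0.5, pts[, 2] + 0.5)
  )
}

# Minimum-area enclosing rectangle by rotating calipers over the convex hull.
# Returns sorted c(short side, long side).
min_area_rect <- function(pts) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(hull) == 1L) return(c(0, 0))
  if (nrow(hull) == 2L) {
    d <- sqrt(sum((hull[1, ] - hull[2, ])^2))
    return(c(0, d))
  }
  edges <- diff(rbind(hull, hull[1, , drop = FALSE]))
  angles <- unique(atan2(edges[, 2], edges[, 1]) %% (pi / 2))
  best <- Inf
  sides <- c(0, 0)
  for (th in angles) {
    # rotate by -th so the edge at angle th lies along the x-axis
    rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    r <- hull %*% rot
    w <- diff(range(r[, 1]))
    h <- diff(range(r[, 2]))
    if (w * h < best) {
      best <- w * h
      sides <- sort(c(w, h))
    }
  }
  sides
}

# Smallest enclosing circle (Welzl's incremental algorithm over hull points).
min_enclosing_circle <- function(pts) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  n <- nrow(hull)
  circ_2 <- function(p, q) {
    c((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
  }
  circ_3 <- function(p, q, r) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)  # collinear
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  inside <- function(circ, p) {
    sqrt((p[1] - circ[1])^2 + (p[2] - circ[2])^2) <= circ[3] + 1e-9
  }
  if (n == 1L) return(c(hull[1, ], 0))
  circ <- circ_2(hull[1, ], hull[2, ])
  if (n >= 3L) for (i in 3:n) {
    if (inside(circ, hull[i, ])) next
    circ <- circ_2(hull[i, ], hull[1, ])
    for (j in seq_len(i - 1L)) {
      if (inside(circ, hull[j, ])) next
      circ <- circ_2(hull[i, ], hull[j, ])
      for (k in seq_len(j - 1L)) {
        if (inside(circ, hull[k, ])) next
        c3 <- circ_3(hull[i, ], hull[j, ], hull[k, ])
        if (!is.null(c3)) circ <- c3
      }
    }
  }
  circ
}

#' Extract the nine shape and size features of a segmented specimen
#'
#' Computes projected area `A` (foreground pixel count), contour perimeter
#' `Perimeter`, axis-aligned bounding-rectangle width and height `Rect_w`,
#' `Rect_h`, minimum-area rectangle sides `Min_w` (shorter) and `Min_h`
#' (longer), elongation `E = Min_h / Min_w` (>= 1), duty cycle
#' `Duty = A / (Min_w * Min_h)` (rectangularity, <= 1) and the radius of the
#' smallest enclosing circle `Radius`.
#'
#' @param mask {0,1} matrix with exactly one connected foreground component.
#' @return A one-row tibble with the nine canonical shape columns.
#' @export
extract_shape_features <- function(mask) {
  check_mask(mask)
  if (sum(mask) == 0) abort("empty mask")
  n_comp <- max(EBImage::imageData(EBImage::bwlabel(t(mask))))
  if (n_comp != 1L)
    abort(sprintf("mask must have exactly one connected component (found %d)",
                  n_comp))
  pts <- outer_contour(mask)
  closed <- rbind(pts, pts[1, , drop = FALSE])
  perimeter <- sum(sqrt(rowSums(diff(closed)^2)))
  corners <- corner_cloud(pts)
  rect_w <- diff(range(corners[, 1]))
  rect_h <- diff(range(corners[, 2]))
  mr <- min_area_rect(corners)
  circ <- min_enclosing_circle(corners)
  area <- sum(mask)
  tibble::tibble(
    A = area, Perimeter = perimeter,
    Rect_w = rect_w, Rect_h = rect_h,
    Min_w = mr[1], Min_h = mr[2],
    E = mr[2] / mr[1],
    Duty = area / (mr[1] * mr[2]),
    Radius = circ[3]
  )
}
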