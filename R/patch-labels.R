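# Patch-label assignment against region annotations.

#' Assign binary patch labels from polygon annotations
#'
#' Labels each patch of a bag 1 when it falls inside an annotated region of
#' any class, 0 otherwise. Patch footprints are half-open
#' `[x, x + patch_size) x [y, y + patch_size)` squares anchored at the stored
#' top-left coordinates. Two rules are available:
#'
#' * `"center_in"` (default): the patch center point lies inside (or on the
#'   boundary of) some polygon. This is the common convention for coarse
#'   patch grids and avoids sliver-overlap ambiguity at region borders.
#' * `"any_overlap"`: the patch footprint and some polygon share positive
#'   area.
#'
#' Enlarging a polygon can never flip a label from 1 to 0, and
#' `any_overlap` always labels a superset of `center_in`.
#'
#' @param bag An [instance_bag()].
#' @param ann An [annotation_set()] for the same slide. An empty region list
#'   yields an all-zero label vector.
#' @param rule Labeling rule, `"center_in"` or `"any_overlap"`.
#' @param classes Optional character vector restricting which annotation
#'   classes count as positive (default: all).
#' @return Integer vector of length N with values in \{0, 1\}.
#' @export
assign_patch_labels <- function(bag, ann, rule = c("center_in", "any_overlap"),
                                classes = NULL) {
  stopifnot(inherits(bag, "instance_bag"), inherits(ann, "annotation_set"))
  rule <- match.arg(rule)
  if (bag$slide_id != ann$slide_id)
    stop("assign_patch_labels: bag and annotation slide_id differ")
  n <- nrow(bag$coords)
  labels <- integer(n)
  regions <- ann$regions
  if (!is.null(classes))
    regions <- Filter(function(r) r$class_label %in% classes, regions)
  if (!length(regions)) return(labels)
  ps <- bag$patch_size
  if (rule == "center_in") {
    cx <- bag$coords[, 1L] + ps / 2
    cy <- bag$coords[, 2L] + ps / 2
    for (r in regions) {
      inside <- pracma::inpolygon(cx, cy, r$polygon[, 1L], r$polygon[, 2L],
                                  boundary = TRUE)
      labels[inside] <- 1L
    }
  } else {
    for (r in regions) {
      for (i in which(labels == 0L)) {
        a <- clipped_polygon_area(r$polygon,
                                  bag$coords[i, 1L], bag$coords[i, 2L],
                                  bag$coords[i, 1L] + ps,
                                  bag$coords[i, 2L] + ps)
        if (a > 1e-9) labels[i] <- 1L
      }
    }
  }
  labels
}

# Area of a polygon clipped to the axis-aligned rectangle
# [xmin,xmax] x [ymin,ymax], via Sutherland-Hodgman clipping.
clipped_polygon_area <- function(poly, xmin, ymin, xmax, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    if (!nrow(pts)) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1L) n else i - 1L, ]
      cin <- inside(cur); pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, x) {  # intersection with vertical line x
    t <- (x - p[1]) / (q[1] - p[1]); c(x, p[2] + t * (q[2] - p[2]))
  }
  iy <- function(p, q, y) {
    t <- (y - p[2]) / (q[2] - p[2]); c(p[1] + t * (q[1] - p[1]), y)
  }
  pts <- poly
  pts <- clip_edge(pts, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin))
  pts <- clip_edge(pts, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax))
  pts <- clip_edge(pts, function(p) p[2] >= ymin, function(p, q) iy(p, q, ymin))
  pts <- clip_edge(pts, function(p) p[2] <= ymax, function(p, q) iy(p, q, ymax))
  if (nrow(pts) < 3L) return(0)
  x <- pts[, 1L]; y <- pts[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}
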