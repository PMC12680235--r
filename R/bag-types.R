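#' Construct an instance bag
#'
#' An `instance_bag` holds one slide's worth of patch-level data: the feature
#' matrix produced by a patch encoder, the grid coordinates of each patch on
#' the slide (top-left corners, level-0 pixels), the weak slide-level label,
#' and optionally per-patch ground-truth labels derived from region
#' annotations.
#'
#' @param slide_id Character scalar identifying the slide.
#' @param features Numeric matrix, one row per patch (N x d; d = 1024 for the
#'   usual ResNet50 features).
#' @param coords Integer matrix N x 2 of top-left patch corners in level-0
#'   pixels. Coordinates must be non-negative and unique.
#' @param bag_label Integer class index (0-based) of the slide.
#' @param patch_size Patch edge length in pixels (default 256).
#' @param patch_labels Optional binary vector of length N marking patches
#'   inside an annotated region of interest.
#' @param level Pyramid level the coordinates refer to (default 0).
#' @return An object of class `instance_bag`.
#' @export
instance_bag <- function(slide_id, features, coords, bag_label,
                         patch_size = 256L, patch_labels = NULL, level = 0L) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  n <- nrow(features)
  if (n < 1L) stop("instance_bag: bag must contain at least one instance")
  if (nrow(coords) != n || ncol(coords) != 2L)
    stop("instance_bag: coords must be an N x 2 matrix matching features")
  if (any(coords < 0L)) stop("instance_bag: coords must be non-negative")
  if (anyDuplicated(paste(coords[, 1L], coords[, 2L])))
    stop("instance_bag: coords must be unique")
  if (!is.null(patch_labels)) {
    patch_labels <- as.integer(patch_labels)
    if (length(patch_labels) != n || !all(patch_labels %in% c(0L, 1L)))
      stop("instance_bag: patch_labels must be a binary vector of length N")
  }
  structure(
    list(slide_id = as.character(slide_id), features = features,
         coords = coords, patch_size = as.integer(patch_size),
         bag_label = as.integer(bag_label), patch_labels = patch_labels,
         level = as.integer(level)),
    class = "instance_bag")
}

#' @export
print.instance_bag <- function(x, ...) {
  cat(sprintf("<instance_bag> %s: %d instances x %d features, label %d%s\n",
              x$slide_id, nrow(x$features), ncol(x$features), x$bag_label,
              if (is.null(x$patch_labels)) ""
              else sprintf(", %d ROI patches", sum(x$patch_labels))))
  invisible(x)
}

#' Construct an annotation set
#'
#' Labeled polygon regions for one slide, in level-0 pixel coordinates.
#' Polygons are stored as open rings (first vertex not repeated); each must
#' have at least three vertices and be simple (non-self-intersecting).
#'
#' @param slide_id Character scalar.
#' @param regions List of regions, each a list with elements `class_label`
#'   (character) and `polygon` (numeric matrix V x 2 of vertices).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(slide_id, regions = list()) {
  regions <- lapply(regions, function(r) {
    poly <- as.matrix(r$polygon)
    storage.mode(poly) <- "double"
    # drop an explicitly closed ring's duplicate last vertex
    if (nrow(poly) > 1L && all(poly[1L, ] == poly[nrow(poly), ]))
      poly <- poly[-nrow(poly), , drop = FALSE]
    if (nrow(poly) < 3L)
      stop("annotation_set: polygon must have at least 3 vertices")
    if (ncol(poly) != 2L)
      stop("annotation_set: polygon vertices must be x,y pairs")
    if (!polygon_is_simple(poly))
      stop("annotation_set: polygon is self-intersecting")
    list(class_label = as.character(r$class_label), polygon = poly)
  })
  structure(list(slide_id = as.character(slide_id), regions = regions),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d region(s) [%s]\n", x$slide_id,
              length(x$regions),
              paste(unique(vapply(x$regions, `[[`, "", "class_label")),
                    collapse = ", ")))
  invisible(x)
}

# Segment-intersection test for polygon simplicity (shared endpoints of
# adjacent edges are allowed).
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1L else i + 1L, ])
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p, q) {
    d1 <- cross(q[1, ], q[2, ], p[1, ]); d2 <- cross(q[1, ], q[2, ], p[2, ])
    d3 <- cross(p[1, ], p[2, ], q[1, ]); d4 <- cross(p[1, ], p[2, ], q[2, ])
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  if (n <= 3L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (!adjacent && intersects(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

#' Construct a patch score set
#'
#' Per-patch scores emitted by a MIL model for one slide. The `channel` tags
#' how the scores arise: `"attention"` (convex weights summing to one),
#' `"patch_prob"` (per-instance class probabilities in \[0, 1\]), or
#' `"selection"` (max-pool argmax occupancy fractions in \[0, 1\]).
#'
#' @param slide_id Character scalar.
#' @param scores Numeric vector, one score per patch.
#' @param channel One of `"attention"`, `"patch_prob"`, `"selection"`.
#' @param class_context Integer class index the scores refer to (multi-class
#'   probability channels); `NA` for class-agnostic channels.
#' @return An object of class `patch_score_set`.
#' @export
patch_score_set <- function(slide_id, scores, channel, class_context = NA_integer_) {
  channel <- match.arg(channel, c("attention", "patch_prob", "selection"))
  scores <- as.numeric(scores)
  if (length(scores) < 1L) stop("patch_score_set: empty score vector")
  if (channel == "attention" && abs(sum(scores) - 1) > 1e-6)
    stop("patch_score_set: attention scores must sum to 1")
  if (channel %in% c("patch_prob", "selection") &&
      (any(scores < -1e-9) || any(scores > 1 + 1e-9)))
    stop(sprintf("patch_score_set: %s scores must lie in [0, 1]", channel))
  structure(list(slide_id = as.character(slide_id), scores = scores,
                 channel = channel, class_context = as.integer(class_context)),
            class = "patch_score_set")
}

#' @export
print.patch_score_set <- function(x, ...) {
  cat(sprintf("<patch_score_set> %s: %d scores, channel '%s'\n",
              x$slide_id, length(x$scores), x$channel))
  invisible(x)
}
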