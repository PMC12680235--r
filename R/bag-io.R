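# Bag / annotation / label file plumbing.
#
# A bag file is a single JSON document mirroring the usual patch-feature
# archive layout: datasets "features" (N x d) and "coords" (N x 2) plus the
# attributes patch_size, level, bag_label and optional patch_labels. Doubles
# are serialized at full precision so a write/read round trip is exact.

#' Write an instance bag to a JSON bag file
#'
#' @param bag An [instance_bag()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bag <- function(bag, path) {
  stopifnot(inherits(bag, "instance_bag"))
  obj <- list(
    slide_id = bag$slide_id,
    patch_size = bag$patch_size,
    level = bag$level,
    bag_label = bag$bag_label,
    features = bag$features,
    coords = bag$coords)
  if (!is.null(bag$patch_labels)) obj$patch_labels <- bag$patch_labels
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read an instance bag from a JSON bag file
#'
#' @param path Bag file written by [write_bag()].
#' @return An [instance_bag()].
#' @export
read_bag <- function(path) {
  if (!file.exists(path)) stop("read_bag: file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("slide_id", "patch_size", "bag_label", "features", "coords")) {
    if (is.null(obj[[field]]))
      stop(sprintf("read_bag: bag file lacks required field '%s'", field))
  }
  feats <- as.matrix(obj$features)
  coords <- as.matrix(obj$coords)
  if (ncol(coords) != 2L)
    stop("read_bag: malformed field 'coords' (need N x 2)")
  if (nrow(feats) != nrow(coords))
    stop("read_bag: shape mismatch between 'features' and 'coords'")
  instance_bag(obj$slide_id, feats, coords, obj$bag_label,
               patch_size = obj$patch_size,
               patch_labels = obj$patch_labels,
               level = if (is.null(obj$level)) 0L else obj$level)
}

#' Write an annotation set as GeoJSON
#'
#' Emits a `FeatureCollection` of closed `Polygon` features carrying the
#' region class in the `classification` property, the common interchange
#' format for slide region annotations.
#'
#' @param ann An [annotation_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  features <- lapply(ann$regions, function(r) {
    ring <- rbind(r$polygon, r$polygon[1L, ])  # GeoJSON rings are closed
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(i) ring[i, ]))),
      properties = list(classification = r$class_label))
  })
  obj <- list(type = "FeatureCollection", slide_id = ann$slide_id,
              features = features)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read an annotation set from GeoJSON
#'
#' @param path GeoJSON file; each feature must be a `Polygon` with a
#'   `classification` property.
#' @param slide_id Slide id to attach when the file carries none.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, slide_id = NULL) {
  if (!file.exists(path)) stop("read_annotations: file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$type) || obj$type != "FeatureCollection")
    stop("read_annotations: not a GeoJSON FeatureCollection")
  id <- if (!is.null(obj$slide_id)) obj$slide_id else slide_id
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  regions <- lapply(obj$features, function(f) {
    if (is.null(f$geometry) || f$geometry$type != "Polygon")
      stop("read_annotations: feature geometry must be 'Polygon'")
    ring <- f$geometry$coordinates[[1L]]
    poly <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    cls <- f$properties$classification
    if (is.null(cls)) stop("read_annotations: feature lacks 'classification'")
    list(class_label = cls, polygon = poly)
  })
  annotation_set(id, regions)
}

#' Read or write a slide label table
#'
#' The label table is a CSV with columns `slide_id`, `label` (integer class
#' index) and `split` (`train` / `val` / `test`).
#'
#' @param labels Data frame with columns `slide_id`, `label`, `split`.
#' @param path CSV file path.
#' @return `read_labels` returns the data frame; `write_labels` returns
#'   `path` invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("slide_id", "label", "split") %in% names(labels)))
  utils::write.csv(labels[, c("slide_id", "label", "split")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("read_labels: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("slide_id", "label", "split"), names(df))
  if (length(miss))
    stop("read_labels: label CSV lacks column(s): ", paste(miss, collapse = ", "))
  df$slide_id <- as.character(df$slide_id)
  df$label <- as.integer(df$label)
  df
}

#' Write a full dataset (bags, annotations, labels) to a directory
#'
#' Layout: `bags/<slide_id>.json`, `annotations/<slide_id>.geojson` (only for
#' slides that have regions) and `labels.csv` at the top level.
#'
#' @param dataset A list with elements `bags`, `annotations`, `labels` as
#'   returned by [make_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "bags"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
  for (bag in dataset$bags)
    write_bag(bag, file.path(dir, "bags", paste0(bag$slide_id, ".json")))
  for (ann in dataset$annotations) {
    if (length(ann$regions))
      write_annotations(ann, file.path(dir, "annotations",
                                       paste0(ann$slide_id, ".geojson")))
  }
  write_labels(dataset$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A list with elements `bags`, `annotations`, `labels`; bags are
#'   ordered as in `labels.csv`.
#' @export
read_dataset <- function(dir) {
  labels <- read_labels(file.path(dir, "labels.csv"))
  bags <- lapply(labels$slide_id, function(id)
    read_bag(file.path(dir, "bags", paste0(id, ".json"))))
  anns <- lapply(labels$slide_id, function(id) {
    p <- file.path(dir, "annotations", paste0(id, ".geojson"))
    if (file.exists(p)) read_annotations(p, id) else annotation_set(id)
  })
  list(bags = bags, annotations = anns, labels = labels)
}
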