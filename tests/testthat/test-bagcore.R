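test_that("bag files round-trip exactly", {
  set.seed(1)
  bag <- instance_bag("s1", matrix(rnorm(12), 3, 4),
                      cbind(c(0L, 256L, 512L), c(0L, 0L, 256L)),
                      bag_label = 1L, patch_labels = c(1L, 0L, 0L))
  f <- withr::local_tempfile(fileext = ".json")
  write_bag(bag, f)
  back <- read_bag(f)
  expect_identical(back$features, bag$features)
  expect_identical(back$coords, bag$coords)
  expect_identical(back$slide_id, bag$slide_id)
  expect_identical(back$bag_label, bag$bag_label)
  expect_identical(back$patch_labels, bag$patch_labels)
  expect_identical(back$patch_size, bag$patch_size)
})

test_that("malformed bag files raise format errors naming the field", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(slide_id = "s", patch_size = 256, bag_label = 0,
                            features = matrix(1, 2, 2)),
                       f, auto_unbox = TRUE)
  expect_error(read_bag(f), "coords")
  expect_error(read_bag(file.path(tempdir(), "absent.json")), "not found")
})

test_that("a large synthetic dataset survives a disk round trip", {
  set.seed(42)
  bags <- lapply(seq_len(1000), function(i)
    toy_bag(matrix(rnorm(6), 3, 2), label = i %% 2, slide_id = sprintf("b%04d", i)))
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "bags"))
  for (b in bags) write_bag(b, file.path(dir, "bags", paste0(b$slide_id, ".json")))
  back <- lapply(bags, function(b)
    read_bag(file.path(dir, "bags", paste0(b$slide_id, ".json"))))
  expect_identical(vapply(back, `[[`, "", "slide_id"),
                   vapply(bags, `[[`, "", "slide_id"))
  # checksum over all feature matrices
  expect_identical(sum(vapply(back, function(b) sum(b$features), 0)),
                   sum(vapply(bags, function(b) sum(b$features), 0)))
})

test_that("annotations and label tables round-trip", {
  ann <- annotation_set("s1", list(
    list(class_label = "tumor", polygon = rect_poly(256, 256, 768, 768)),
    list(class_label = "necrosis", polygon = rbind(c(0, 0), c(100, 0), c(50, 80)))))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_identical(back$slide_id, "s1")
  expect_equal(back$regions[[1]]$polygon, ann$regions[[1]]$polygon)
  expect_identical(vapply(back$regions, `[[`, "", "class_label"),
                   c("tumor", "necrosis"))

  labels <- data.frame(slide_id = c("a", "b"), label = c(0L, 1L),
                       split = c("train", "test"))
  g <- withr::local_tempfile(fileext = ".csv")
  write_labels(labels, g)
  expect_identical(read_labels(g), labels)
  expect_error(read_labels(g2 <- {
    writeLines("slide_id,label\na,0", tmp <- withr::local_tempfile()); tmp
  }), "split")
})

test_that("self-intersecting polygons are rejected", {
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(annotation_set("s", list(list(class_label = "x", polygon = bowtie))),
               "self-intersecting")
})

test_that("center_in labels exactly the patches whose centers fall inside", {
  # 4x4 grid of 256-px patches; square region (256,256)-(768,768) covers the
  # four patches anchored at (256,256), (512,256), (256,512), (512,512),
  # whose centers (384|640, 384|640) lie strictly inside.
  bag <- toy_bag(matrix(0, 16, 2), grid = 4)
  ann <- annotation_set("toy", list(
    list(class_label = "tumor", polygon = rect_poly(256, 256, 768, 768))))
  lab <- assign_patch_labels(bag, ann, "center_in")
  inside <- bag$coords[, 1] %in% c(256L, 512L) & bag$coords[, 2] %in% c(256L, 512L)
  expect_identical(lab, as.integer(inside))
  expect_identical(sum(lab), 4L)
  # the patch anchored at (256,256) with center (384,384) is labeled 1
  expect_identical(lab[bag$coords[, 1] == 256L & bag$coords[, 2] == 256L][1], 1L)
})

test_that("no annotation yields an all-zero label vector", {
  bag <- toy_bag(matrix(0, 9, 2))
  expect_identical(assign_patch_labels(bag, annotation_set("toy")),
                   integer(9))
})

test_that("polygon boundary points count as inside", {
  bag <- toy_bag(matrix(0, 4, 2), grid = 2)
  # edge passes exactly through the center (128,128) of the first patch
  ann <- annotation_set("toy", list(
    list(class_label = "t", polygon = rect_poly(128, 128, 600, 600))))
  expect_identical(assign_patch_labels(bag, ann, "center_in")[1], 1L)
})

test_that("labeling is monotone and any_overlap dominates center_in", {
  set.seed(99)
  for (rep in 1:20) {
    g <- sample(3:5, 1)
    bag <- toy_bag(matrix(0, g * g, 2), grid = g)
    x0 <- runif(1, 0, g * 256 / 2); y0 <- runif(1, 0, g * 256 / 2)
    w <- runif(1, 100, g * 256 / 2); h <- runif(1, 100, g * 256 / 2)
    small <- annotation_set("toy", list(
      list(class_label = "t", polygon = rect_poly(x0, y0, x0 + w, y0 + h))))
    big <- annotation_set("toy", list(
      list(class_label = "t",
           polygon = rect_poly(x0 - 50, y0 - 50, x0 + w + 50, y0 + h + 50))))
    for (rule in c("center_in", "any_overlap")) {
      l_small <- assign_patch_labels(bag, small, rule)
      l_big <- assign_patch_labels(bag, big, rule)
      expect_true(all(l_big >= l_small))   # enlarging never flips 1 -> 0
    }
    expect_true(all(assign_patch_labels(bag, small, "any_overlap") >=
                      assign_patch_labels(bag, small, "center_in")))
  }
})

test_that("bag invariants are enforced", {
  expect_error(instance_bag("s", matrix(1, 2, 2), rbind(c(0, 0), c(0, 0)), 0),
               "unique")
  expect_error(instance_bag("s", matrix(1, 2, 2), rbind(c(-1, 0), c(0, 0)), 0),
               "non-negative")
  expect_error(instance_bag("s", matrix(1, 2, 2), rbind(c(0, 0), c(256, 0)), 0,
                            patch_labels = c(2L, 0L)), "binary")
  expect_error(patch_score_set("s", c(0.5, 0.4), "attention"), "sum to 1")
  expect_error(patch_score_set("s", c(1.5, 0.4), "patch_prob"), "0, 1")
})
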