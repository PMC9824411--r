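test_that("generate_scene is seed-deterministic and boxes stay in frame", {
  sp <- scene_spec(image_size = 96, seed = 42)
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  expect_identical(s1$image[[1]], s2$image[[1]])
  expect_identical(s1$boxes[[1]], s2$boxes[[1]])
  validate_boxes(s1$boxes[[1]], width = 96, height = 96)
  s3 <- generate_scene(scene_spec(image_size = 96, seed = 43))
  expect_false(identical(s1$boxes[[1]], s3$boxes[[1]]))
})

test_that("a zero-object scene is background only", {
  sp <- scene_spec(image_size = 64, objects_per_image = c(0, 0), seed = 7)
  s <- generate_scene(sp)
  expect_equal(nrow(s$boxes[[1]]), 0)
  expect_equal(dim(s$image[[1]]), c(64, 64, 3))
})

test_that("rendered objects occupy exactly their ground-truth boxes", {
  sp <- scene_spec(image_size = 96, objects_per_image = c(1, 1), seed = 3)
  s <- generate_scene(sp)
  b <- s$boxes[[1]]
  img <- s$image[[1]]
  # pixels inside the box must differ from a pure-background render
  bg <- pestvision:::with_seed(pestvision:::derive_seed(3, 0), {
    NULL
  })
  inside <- img[(floor(b$y1[1]) + 2):(ceiling(b$y2[1]) - 2),
                (floor(b$x1[1]) + 2):(ceiling(b$x2[1]) - 2), 1]
  expect_gt(stats::sd(as.numeric(inside)), 0)
})

test_that("requested density classes are realized", {
  for (target in c("A", "B", "C", "D")) {
    sp <- scene_spec(image_size = 256, density_class = target, seed = 11)
    s <- generate_scene(sp)
    expect_equal(density_label(s$boxes[[1]]), target)
    expect_equal(s$density_class, target)
  }
})

test_that("generate_dataset honours preset counts exactly", {
  man <- generate_dataset(c(a = 5, b = 5), classes = tibble::tibble(
    name = c("a", "b"), size_min = 10, size_max = 20,
    archetype = c("ellipse", "elongated"), r = c(200, 40), g = c(40, 40), b = c(40, 200)
  ), image_size = 64, seed = 2, render = FALSE)
  expect_equal(nrow(man), 10)
  ct <- class_table(man)
  expect_equal(ct$n_images, c(5, 5))
})

test_that("life-stage archetypes order median box areas egg < larva < adult", {
  preset <- tibble::tibble(
    class_name = c("X (egg)", "X (larva)", "X (adult)"),
    n_images = c(15L, 15L, 15L)
  )
  man <- generate_dataset(preset, image_size = 256, seed = 5, render = FALSE)
  area_of <- function(stage) {
    rows <- purrr::map_lgl(man$boxes, ~ any(grepl(stage, .x$class_name, fixed = TRUE)))
    pop <- box_population(man[rows, ])
    median(pop$w * pop$h)
  }
  expect_lt(area_of("(egg)"), area_of("(larva)"))
  expect_lt(area_of("(larva)"), area_of("(adult)"))
})

test_that("box_population extracts every annotation in stable order", {
  m <- manifest(
    annotated_image("i1", 100, 100, make_boxes(c(5, 5, 15, 25))),
    annotated_image("i2", 100, 100, make_boxes(c(0, 0, 7, 7), c(10, 10, 30, 20)))
  )
  pop <- box_population(m)
  expect_equal(nrow(pop), 3)
  expect_equal(pop$w, c(10, 7, 20))
  expect_equal(pop$h, c(20, 7, 10))
})

test_that("inventory presets reproduce their printed totals", {
  pest <- preset_class_counts("pest")
  disease <- preset_class_counts("disease")
  expect_equal(nrow(pest), 36)
  expect_equal(sum(pest$n_images), 11708)
  expect_equal(nrow(disease), 8)
  expect_equal(sum(disease$n_images), 7199)
  expect_equal(sum(preset_class_counts("full")$n_images), 18907)
  # the documented extremes of the imbalance
  expect_equal(pest$n_images[pest$class_name == "Clostera anachoreta (egg)"], 62)
  expect_equal(pest$n_images[pest$class_name == "Anoplophora chinensis (adult)"], 758)
})

test_that("dataset files round-trip through the annotation writers", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(c(beetle_adult = 3), classes = default_scene_classes(64),
                          image_size = 64, seed = 9, render = TRUE,
                          out_dir = dir, dialect = "coco_json")
  expect_true(file.exists(file.path(dir, "annotations.json")))
  expect_length(list.files(dir, pattern = "\\.png$"), 3)
  back <- read_annotations(file.path(dir, "annotations.json"), "coco_json")
  expect_equal(nrow(back), 3)
  for (i in 1:3) {
    expect_equal(as.matrix(back$boxes[[i]][, 1:4]),
                 as.matrix(man$boxes[[i]][, 1:4]), tolerance = 1e-6)
  }
})
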