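# Shared fixtures: tiny manifests and detection tables built in code.

make_boxes <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    bbox(r[1], r[2], r[3], r[4],
         class_id = if (length(r) > 4) r[5] else 0L,
         class_name = if (length(r) > 4) as.character(r[5]) else "0")
  }))
}

make_dets <- function(df) {
  d <- tibble::as_tibble(df)
  if (!"class_id" %in% names(d)) d$class_id <- 0L
  if (!"class_name" %in% names(d)) d$class_name <- as.character(d$class_id)
  if (!"source" %in% names(d)) d$source <- "inc_yolo"
  d
}

tiny_manifest <- function(n = 10, seed = 1, classes = c("a", "b")) {
  with_seed_local(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      cl <- classes[(i - 1) %% length(classes) + 1]
      x1 <- runif(1, 0, 60); y1 <- runif(1, 0, 60)
      b <- bbox(x1, y1, x1 + runif(1, 5, 30), y1 + runif(1, 5, 30),
                class_id = match(cl, sort(classes)) - 1L, class_name = cl)
      annotated_image(sprintf("im%03d", i), 100, 100, b)
    })
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Pixel-rasterization IoU oracle for integer boxes (independent of the
# analytic implementation).
raster_iou <- function(a, b, grid = 64) {
  ga <- matrix(FALSE, grid, grid); gb <- ga
  ga[(a[2] + 1):a[4], (a[1] + 1):a[3]] <- TRUE
  gb[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- TRUE
  inter <- sum(ga & gb); uni <- sum(ga | gb)
  inter / uni
}
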