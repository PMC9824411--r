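#' Class archetypes for synthetic pest scenes
#'
#' Each synthetic class is a row: a name, a size range in pixels (at the
#' reference 256 px image, rescaled for other sizes), a shape archetype
#' (`"ellipse"` for compact adult/pupal bodies, `"elongated"` for larvae,
#' `"dots"` for egg clusters) and a base RGB colour. The default three
#' classes emulate the structure of a pest inventory — an adult beetle, a
#' larva and an egg cluster — with median box areas ordered
#' egg < larva < adult, the ordering that drives detection difficulty across
#' life stages.
#'
#' @param image_size image side in pixels used to scale the size ranges.
#' @return A tibble with columns `name`, `size_min`, `size_max`, `archetype`,
#'   `r`, `g`, `b`.
#' @export
default_scene_classes <- function(image_size = 256) {
  s <- image_size / 256
  tibble(
    name = c("beetle_adult", "larva", "egg_cluster"),
    size_min = c(48, 32, 16) * s,
    size_max = c(96, 64, 32) * s,
    archetype = c("ellipse", "elongated", "dots"),
    r = c(150, 225, 238), g = c(40, 200, 232), b = c(35, 60, 205)
  )
}

#' Specify a synthetic pest scene
#'
#' @param image_size image side in pixels (square scenes).
#' @param classes class table as from [default_scene_classes()].
#' @param objects_per_image inclusive range of object counts (overridden by
#'   `density_class`).
#' @param density_class optional target crowding label `"A"`-`"D"`; the
#'   generator then chooses counts/overlaps so that [density_label()] of the
#'   result equals the target.
#' @param background named list: `base` RGB, `noise_sd`, `texture_amp` of the
#'   low-frequency leaf-like texture.
#' @param seed integer; fixes all randomness of the scene.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_size = 256, classes = default_scene_classes(image_size),
                       objects_per_image = c(1, 3), density_class = NULL,
                       background = list(base = c(52, 110, 48), noise_sd = 5,
                                         texture_amp = 22),
                       seed = 1L) {
  if (any(classes$size_max >= image_size)) {
    abort("class size ranges must fit inside the image")
  }
  structure(list(image_size = image_size, classes = classes,
                 objects_per_image = objects_per_image,
                 density_class = density_class,
                 background = background, seed = seed),
            class = "scene_spec")
}

# Analytic axis-aligned extents of one placed object; also carries the
# parameters needed to rasterize it. Boxes are exact: the rasterizer fills
# precisely the analytic region.
place_object <- function(cls, image_size, center = NULL) {
  size <- runif(1, cls$size_min, cls$size_max)
  phi <- runif(1, 0, pi)
  if (cls$archetype == "ellipse") {
    a <- size / 2
    b <- a * runif(1, 0.6, 0.85)
  } else if (cls$archetype == "elongated") {
    a <- size / 2
    b <- a / runif(1, 2.5, 4)
  } else {
    a <- size / 2
    b <- size / 2
  }
  ex <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
  ey <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
  if (is.null(center)) {
    center <- c(runif(1, ex + 1, image_size - ex - 1),
                runif(1, ey + 1, image_size - ey - 1))
  } else {
    center[1] <- min(max(center[1], ex + 1), image_size - ex - 1)
    center[2] <- min(max(center[2], ey + 1), image_size - ey - 1)
  }
  obj <- list(cx = center[1], cy = center[2], a = a, b = b, phi = phi,
              archetype = cls$archetype, color = c(cls$r, cls$g, cls$b),
              class_name = cls$name)
  if (cls$archetype == "dots") {
    ndots <- sample(4:7, 1)
    rad <- size / 7
    ang <- runif(ndots, 0, 2 * pi)
    dist <- runif(ndots, 0, size / 2 - rad)
    obj$dots_x <- center[1] + dist * cos(ang)
    obj$dots_y <- center[2] + dist * sin(ang)
    obj$dots_r <- rad * runif(ndots, 0.7, 1.1)
    obj$x1 <- max(0, min(obj$dots_x - obj$dots_r))
    obj$x2 <- min(image_size, max(obj$dots_x + obj$dots_r))
    obj$y1 <- max(0, min(obj$dots_y - obj$dots_r))
    obj$y2 <- min(image_size, max(obj$dots_y + obj$dots_r))
  } else {
    obj$x1 <- center[1] - ex; obj$x2 <- center[1] + ex
    obj$y1 <- center[2] - ey; obj$y2 <- center[2] + ey
  }
  obj
}

object_boxes <- function(objects, classes) {
  if (!length(objects)) return(empty_boxes())
  lv <- sort(classes$name)
  purrr::map_dfr(objects, function(o) {
    tibble(x1 = o$x1, y1 = o$y1, x2 = o$x2, y2 = o$y2,
           class_id = match(o$class_name, lv) - 1L, class_name = o$class_name)
  })
}

render_background <- function(image_size, bg) {
  H <- image_size
  img <- array(0, dim = c(H, H, 3))
  coarse <- 8
  for (ch in 1:3) {
    grid <- matrix(runif(coarse * coarse, -bg$texture_amp, bg$texture_amp), coarse, coarse)
    up <- upsample_bilinear(grid, H)
    img[, , ch] <- bg$base[ch] + up + rnorm(H * H, 0, bg$noise_sd)
  }
  img[img < 0] <- 0; img[img > 255] <- 255
  img
}

upsample_bilinear <- function(grid, H) {
  n <- nrow(grid)
  pos <- (seq_len(H) - 0.5) / H * (n - 1) + 1
  i0 <- pmin(floor(pos), n - 1)
  f <- pos - i0
  rows <- grid[i0, , drop = FALSE] * (1 - f) + grid[i0 + 1, , drop = FALSE] * f
  cols <- rows[, i0, drop = FALSE] * rep(1 - f, each = H) +
    rows[, i0 + 1, drop = FALSE] * rep(f, each = H)
  cols
}

render_object <- function(img, o) {
  H <- dim(img)[1]
  xs <- max(1, floor(o$x1)):min(H, ceiling(o$x2))
  ys <- max(1, floor(o$y1)):min(H, ceiling(o$y2))
  px <- rep(xs - 0.5, each = length(ys))
  py <- rep(ys - 0.5, times = length(xs))
  if (o$archetype == "dots") {
    inside <- rep(FALSE, length(px))
    for (k in seq_along(o$dots_x)) {
      inside <- inside | ((px - o$dots_x[k])^2 + (py - o$dots_y[k])^2 <= o$dots_r[k]^2)
    }
  } else {
    dx <- px - o$cx; dy <- py - o$cy
    u <- cos(o$phi) * dx + sin(o$phi) * dy
    v <- -sin(o$phi) * dx + cos(o$phi) * dy
    inside <- (u / o$a)^2 + (v / o$b)^2 <= 1
  }
  if (!any(inside)) return(img)
  shade <- rnorm(sum(inside), 0, 8)
  for (ch in 1:3) {
    plane <- img[, , ch]
    lin <- cbind(rep(ys, times = length(xs))[inside], rep(xs, each = length(ys))[inside])
    vals <- o$color[ch] + shade
    vals[vals < 0] <- 0; vals[vals > 255] <- 255
    plane[lin] <- vals
    img[, , ch] <- plane
  }
  img
}

# Object count range and overlap plan for a target crowding label.
density_plan <- function(target) {
  switch(target,
    A = list(count = 1:2, overlaps = 0),
    B = list(count = 3:5, overlaps = 0),
    C = list(count = 6:9, overlaps = 2),
    D = list(count = 10:13, overlaps = 3)
  )
}

#' Generate one synthetic pest scene
#'
#' Renders a leaf-textured background and a seeded set of objects drawn from
#' the spec's class archetypes, and returns the scene with exact ground-truth
#' boxes (the rasterizer fills exactly the analytic extents recorded in the
#' boxes). When a `density_class` target is set, object counts and forced
#' overlaps are chosen to achieve it and the result is verified against
#' [density_label()], retrying with derived seeds; an unreachable target
#' raises an error. Identical seeds give byte-identical scenes.
#'
#' @param spec a [scene_spec()].
#' @param image_id id for the resulting annotated image.
#' @param render render pixels (default TRUE); with `FALSE` only geometry is
#'   generated (fast path for large manifests).
#' @return A one-row manifest tibble; the rendered array (0-255,
#'   `H x W x 3`) sits in the `image` list-column.
#' @export
generate_scene <- function(spec, image_id = "scene_1", render = TRUE) {
  for (attempt in 0:19) {
    out <- with_seed(derive_seed(spec$seed, attempt * 1000003L), {
      gen_scene_once(spec, render)
    })
    lab <- density_label(out$boxes)
    if (is.null(spec$density_class) || lab == spec$density_class) {
      return(annotated_image(image_id, spec$image_size, spec$image_size,
                             out$boxes, density_class = lab, image = out$image))
    }
  }
  abort(paste0("could not realize density class ", spec$density_class,
               " with image size ", spec$image_size))
}

gen_scene_once <- function(spec, render) {
  H <- spec$image_size
  if (!is.null(spec$density_class)) {
    plan <- density_plan(spec$density_class)
    n_obj <- sample(plan$count, 1)
    n_overlap <- plan$overlaps
  } else {
    n_obj <- sample(spec$objects_per_image[1]:spec$objects_per_image[2], 1)
    n_overlap <- 0
  }
  if (n_obj * mean(spec$classes$size_max)^2 > 4 * H * H) {
    abort("infeasible density: too many objects for the image size")
  }
  objects <- list()
  for (i in seq_len(n_obj)) {
    cls <- spec$classes[sample.int(nrow(spec$classes), 1), ]
    if (i > 1 && n_overlap > 0) {
      # force an overlapping placement near an existing object
      anchor_obj <- objects[[sample.int(length(objects), 1)]]
      off <- runif(2, -0.25, 0.25) * c(anchor_obj$x2 - anchor_obj$x1,
                                       anchor_obj$y2 - anchor_obj$y1)
      obj <- place_object(cls, H, center = c((anchor_obj$x1 + anchor_obj$x2) / 2 + off[1],
                                             (anchor_obj$y1 + anchor_obj$y2) / 2 + off[2]))
      n_overlap <- n_overlap - 1
    } else {
      obj <- place_object(cls, H)
      if (!is.null(spec$density_class) && spec$density_class == "A") {
        # sparse scenes must stay overlap-free
        tries <- 0
        while (tries < 30 && length(objects) &&
               max(iou(object_boxes(list(obj), spec$classes),
                       object_boxes(objects, spec$classes))) > 0) {
          obj <- place_object(cls, H)
          tries <- tries + 1
        }
      }
    }
    objects[[i]] <- obj
  }
  img <- NULL
  if (render) {
    img <- render_background(H, spec$background)
    for (o in objects) img <- render_object(img, o)
  }
  list(image = img, boxes = object_boxes(objects, spec$classes))
}

#' Generate a whole synthetic dataset from a class-count preset
#'
#' Produces, for every class in the preset, exactly the requested number of
#' images (each image carries objects of that class), with per-image seeds
#' derived from `seed` so the dataset is reproducible end to end. Optionally
#' writes PNG images and annotations in a chosen dialect.
#'
#' @param preset a tibble with `class_name` and `n_images` (see
#'   [preset_class_counts()]), or a named integer vector.
#' @param classes class archetype table; defaults to archetypes inferred from
#'   the preset's life stages when available, else [default_scene_classes()].
#' @param image_size scene side in pixels.
#' @param objects_per_image inclusive range of objects per scene.
#' @param seed integer master seed.
#' @param render render pixel data into the manifest (`TRUE`) or keep
#'   geometry only (`FALSE`, fast).
#' @param out_dir optional directory; when given, PNGs (if rendered) and
#'   annotations are written there.
#' @param dialect annotation dialect for `out_dir`.
#' @return A manifest tibble with one row per generated image.
#' @export
generate_dataset <- function(preset, classes = NULL, image_size = 64,
                             objects_per_image = c(1, 3), seed = 1L,
                             render = TRUE, out_dir = NULL,
                             dialect = "coco_json") {
  if (!is.data.frame(preset)) {
    preset <- tibble(class_name = names(preset), n_images = as.integer(preset))
  }
  stopifnot(all(preset$n_images >= 0))
  if (is.null(classes)) classes <- classes_for_preset(preset, image_size)
  rows <- vector("list", sum(preset$n_images))
  idx <- 0L
  for (ci in seq_len(nrow(preset))) {
    cls_tab <- classes[classes$name == preset$class_name[ci], ]
    if (nrow(cls_tab) == 0) abort(paste0("no archetype for class ", preset$class_name[ci]))
    for (j in seq_len(preset$n_images[ci])) {
      idx <- idx + 1L
      sp <- scene_spec(image_size, cls_tab, objects_per_image,
                       seed = derive_seed(seed, idx))
      sp$classes_all <- classes
      scene <- generate_scene_with_vocab(sp, sprintf("img_%05d", idx), render, classes)
      rows[[idx]] <- scene
    }
  }
  man <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (render) {
      for (i in seq_len(nrow(man))) {
        png::writePNG(man$image[[i]] / 255,
                      file.path(out_dir, paste0(man$image_id[i], ".png")))
      }
    }
    ann_path <- if (dialect == "coco_json") file.path(out_dir, "annotations.json") else out_dir
    write_annotations(man, ann_path, dialect)
  }
  man
}

# Scenes in a dataset share one class vocabulary, so class ids must come from
# the full class table, not the single-class scene spec.
generate_scene_with_vocab <- function(sp, image_id, render, vocab) {
  scene <- generate_scene(sp, image_id, render)
  b <- scene$boxes[[1]]
  if (nrow(b)) {
    lv <- sort(vocab$name)
    b$class_id <- match(b$class_name, lv) - 1L
    scene$boxes[[1]] <- b
  }
  scene
}

# Infer archetypes from life-stage suffixes in preset class names; classes
# without a recognizable stage get the generic ellipse archetype.
classes_for_preset <- function(preset, image_size) {
  s <- image_size / 256
  stage_of <- function(nm) {
    m <- regmatches(nm, regexpr("\\((egg|larva|cocoon|pupa|adult)\\)", nm))
    if (length(m)) gsub("[()]", "", m) else NA_character_
  }
  stages <- vapply(preset$class_name, stage_of, character(1))
  known <- default_scene_classes(image_size)
  arch <- list(
    egg = list(size = c(12, 24), archetype = "dots", col = c(238, 232, 205)),
    larva = list(size = c(28, 56), archetype = "elongated", col = c(225, 200, 60)),
    cocoon = list(size = c(32, 56), archetype = "ellipse", col = c(200, 170, 120)),
    pupa = list(size = c(32, 56), archetype = "ellipse", col = c(160, 120, 70)),
    adult = list(size = c(44, 90), archetype = "ellipse", col = c(150, 40, 35))
  )
  rows <- purrr::map_dfr(seq_len(nrow(preset)), function(i) {
    nm <- preset$class_name[i]
    st <- stages[i]
    if (!is.na(st)) {
      a <- arch[[st]]
      tibble(name = nm, size_min = a$size[1] * s, size_max = a$size[2] * s,
             archetype = a$archetype, r = a$col[1], g = a$col[2], b = a$col[3])
    } else if (nm %in% known$name) {
      known[known$name == nm, ]
    } else {
      tibble(name = nm, size_min = 32 * s, size_max = 64 * s,
             archetype = "ellipse",
             r = 60 + (i * 53) %% 180, g = 40 + (i * 97) %% 180,
             b = 30 + (i * 151) %% 180)
    }
  })
  rows
}

#' Ground-truth box sizes of a manifest
#'
#' Extracts every annotation's (width, height) in a stable order — the input
#' to anchor clustering.
#'
#' @param manifest a manifest tibble.
#' @return A tibble with `w` and `h`, one row per ground-truth box.
#' @export
box_population <- function(manifest) {
  purrr::map_dfr(manifest$boxes, function(b) {
    if (nrow(b) == 0) return(tibble(w = double(), h = double()))
    tibble(w = b$x2 - b$x1, h = b$y2 - b$y1)
  })
}

#' Class-count presets mirroring a published pest/disease inventory
#'
#' `"pest"` is a 36-class inventory of 14 woodland pest species crossed with
#' life stages (egg/larva/cocoon/pupa/adult; 11,708 images in total, heavily
#' imbalanced — from 34 images of *Psilogramma menephron* larvae to 758 of
#' *Anoplophora chinensis* adults). `"disease"` is an 8-class foliar disease
#' inventory over 6 host species (7,199 images). `"full"` is their union
#' (18,907 images). These replicate the structure of a real collection so
#' imbalance and weak-class experiments are structurally faithful without
#' shipping photographs.
#'
#' @param name `"pest"`, `"disease"` or `"full"`.
#' @return A tibble with `class_name`, `n_images`, `species`, `stage`
#'   (stage is `NA` for diseases).
#' @export
preset_class_counts <- function(name = c("pest", "disease", "full")) {
  name <- match.arg(name)
  pest <- tibble(
    species = rep(c(
      "Anoplophora chinensis", "Micromelalopha troglodyta",
      "Apriona germari", "Erthesina fullo", "Sericinus montelus",
      "Cnidocampa flavescens", "Clostera anachoreta", "Hyphantria cunea",
      "Psilogramma menephron", "Plagiodera versicolora", "Parasa consocia",
      "Monochamus alternatus", "Drosicha corpulenta", "Spilarctia subcarnea"
    ), times = c(2, 2, 2, 3, 3, 3, 3, 4, 3, 3, 2, 2, 2, 2)),
    stage = c(
      "larva", "adult",            # Anoplophora chinensis
      "larva", "adult",            # Micromelalopha troglodyta
      "larva", "adult",            # Apriona germari
      "egg", "larva", "adult",     # Erthesina fullo
      "egg", "larva", "adult",     # Sericinus montelus
      "larva", "cocoon", "adult",  # Cnidocampa flavescens
      "egg", "larva", "adult",     # Clostera anachoreta
      "egg", "larva", "pupa", "adult", # Hyphantria cunea
      "larva", "pupa", "adult",    # Psilogramma menephron
      "egg", "larva", "adult",     # Plagiodera versicolora
      "larva", "adult",            # Parasa consocia
      "larva", "adult",            # Monochamus alternatus
      "larva", "adult",            # Drosicha corpulenta
      "larva", "adult"             # Spilarctia subcarnea
    ),
    n_images = c(
      276L, 758L,
      398L, 322L,
      371L, 385L,
      338L, 419L, 247L,
      244L, 367L, 295L,
      472L, 43L, 392L,
      62L, 288L, 387L,
      264L, 343L, 276L, 38L,
      34L, 355L, 459L,
      501L, 521L, 298L,
      534L, 45L,
      58L, 442L,
      487L, 72L,
      492L, 425L
    )
  )
  pest$class_name <- paste0(pest$species, " (", pest$stage, ")")
  pest <- pest[, c("class_name", "n_images", "species", "stage")]
  disease <- tibble(
    class_name = c("peach bacterial spot", "pepper bacterial spot",
                   "potato early blight", "potato late blight",
                   "squash powdery mildew", "strawberry leaf scorch",
                   "tomato curl virus", "tomato mosaic virus"),
    n_images = c(378L, 896L, 952L, 977L, 914L, 1253L, 965L, 864L),
    species = c("peach", "pepper", "potato", "potato", "squash",
                "strawberry", "tomato", "tomato"),
    stage = NA_character_
  )
  switch(name, pest = pest, disease = disease,
         full = dplyr::bind_rows(pest, disease))
}

#' Plot a synthetic scene with its boxes
#'
#' @param scene a one-row manifest tibble with rendered `image`.
#' @param ... unused.
#' @return A ggplot showing the raster and ground-truth boxes.
#' @export
plot_scene <- function(scene, ...) {
  img <- scene$image[[1]]
  if (is.null(img)) abort("scene has no rendered image")
  H <- dim(img)[1]; W <- dim(img)[2]
  df <- expand.grid(y = seq_len(H), x = seq_len(W))
  df$col <- grDevices::rgb(img[, , 1] / 255, img[, , 2] / 255, img[, , 3] / 255)
  b <- scene$boxes[[1]]
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df, ggplot2::aes(x = .data$x, y = .data$y,
                                                 fill = I(.data$col))) +
    ggplot2::geom_rect(data = b, ggplot2::aes(xmin = .data$x1, xmax = .data$x2,
                                              ymin = .data$y1, ymax = .data$y2,
                                              color = .data$class_name),
                       fill = NA, linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, color = "class") +
    ggplot2::theme_void()
}
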