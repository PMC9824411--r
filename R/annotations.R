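#' Read box annotations in a standard dialect
#'
#' Parses VOC XML (one file per image, or a directory of them), COCO JSON
#' (one file for the whole set) or YOLO text (one `.txt` per image with
#' normalized `class cx cy w h` lines) and converts every box to the
#' package's canonical 0-based half-open corner convention:
#'
#' * VOC XML stores 1-based inclusive corners, so `x1 = xmin - 1`, `x2 = xmax`.
#' * COCO stores 0-based `[x, y, w, h]`, so `x2 = x + w`.
#' * YOLO stores normalized centers; pixel sizes come from `image_info` or
#'   from a PNG of the same stem sitting next to the label file.
#'
#' @param path a file or directory, per dialect.
#' @param dialect `"voc_xml"`, `"coco_json"` or `"yolo_txt"`.
#' @param image_info for `yolo_txt`: a tibble with `image_id`, `width`,
#'   `height` (YOLO label files do not record image size).
#' @param class_names for `yolo_txt`: character vector mapping 0-based class
#'   ids to names.
#' @return A manifest tibble (see [annotated_image()]).
#' @export
read_annotations <- function(path, dialect = c("voc_xml", "coco_json", "yolo_txt"),
                             image_info = NULL, class_names = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
    voc_xml = read_voc_xml(path),
    coco_json = read_coco_json(path),
    yolo_txt = read_yolo_txt(path, image_info, class_names)
  )
}

#' Write box annotations in a standard dialect
#'
#' Inverse of [read_annotations()]: converts the canonical boxes back to each
#' dialect's native convention with deterministic field ordering, so
#' write-then-read round-trips boxes exactly (within 0.5 px for the
#' normalized YOLO dialect).
#'
#' @param images a manifest tibble.
#' @param path output directory (`voc_xml`, `yolo_txt`) or file (`coco_json`).
#' @inheritParams read_annotations
#' @return `path`, invisibly.
#' @export
write_annotations <- function(images, path, dialect = c("voc_xml", "coco_json", "yolo_txt")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    voc_xml = write_voc_xml(images, path),
    coco_json = write_coco_json(images, path),
    yolo_txt = write_yolo_txt(images, path)
  )
  invisible(path)
}

read_voc_xml <- function(path) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
  } else path
  purrr::map_dfr(files, function(f) {
    doc <- tryCatch(xml2::read_xml(f),
                    error = function(e) abort(paste0("malformed VOC XML '", f, "': ", conditionMessage(e))))
    id <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
    id <- sub("\\.(png|jpg|jpeg|xml)$", "", id, ignore.case = TRUE)
    w <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
    h <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
    objs <- xml2::xml_find_all(doc, "./object")
    num <- function(o, fld) as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0("./bndbox/", fld))))
    boxes <- purrr::map_dfr(objs, function(o) {
      tibble(
        x1 = num(o, "xmin") - 1, y1 = num(o, "ymin") - 1,
        x2 = num(o, "xmax"), y2 = num(o, "ymax"),
        class_name = xml2::xml_text(xml2::xml_find_first(o, "./name"))
      )
    })
    boxes <- finish_classes(boxes)
    annotated_image(id, w, h, boxes)
  })
}

write_voc_xml <- function(images, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(images))) {
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", paste0(images$image_id[i], ".png"))
    size <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(size, "width", as.character(images$width[i]))
    xml2::xml_add_child(size, "height", as.character(images$height[i]))
    xml2::xml_add_child(size, "depth", "3")
    b <- images$boxes[[i]]
    for (j in seq_len(nrow(b))) {
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", b$class_name[j])
      bb <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bb, "xmin", format_px(b$x1[j] + 1))
      xml2::xml_add_child(bb, "ymin", format_px(b$y1[j] + 1))
      xml2::xml_add_child(bb, "xmax", format_px(b$x2[j]))
      xml2::xml_add_child(bb, "ymax", format_px(b$y2[j]))
    }
    xml2::write_xml(doc, file.path(path, paste0(images$image_id[i], ".xml")))
  }
}

format_px <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, as.character(round(x)), format(x, digits = 10))
}

read_coco_json <- function(path) {
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) abort(paste0("malformed COCO JSON '", path, "': ", conditionMessage(e))))
  cats <- setNames(
    purrr::map_chr(j$categories, ~ as.character(.x$name)),
    purrr::map_chr(j$categories, ~ as.character(.x$id))
  )
  anns_by_img <- split(j$annotations, purrr::map_chr(j$annotations, ~ as.character(.x$image_id)))
  purrr::map_dfr(j$images, function(im) {
    anns <- anns_by_img[[as.character(im$id)]] %||% list()
    boxes <- purrr::map_dfr(anns, function(a) {
      bb <- as.numeric(unlist(a$bbox))
      if (length(bb) != 4) abort(paste0("malformed COCO bbox in annotation id ", a$id))
      tibble(x1 = bb[1], y1 = bb[2], x2 = bb[1] + bb[3], y2 = bb[2] + bb[4],
             class_name = unname(cats[[as.character(a$category_id)]]))
    })
    boxes <- finish_classes(boxes)
    id <- sub("\\.(png|jpg|jpeg)$", "", im$file_name %||% as.character(im$id))
    annotated_image(id, im$width, im$height, boxes)
  })
}

write_coco_json <- function(images, path) {
  all_classes <- sort(unique(unlist(purrr::map(images$boxes, "class_name"))))
  cat_id <- function(nm) match(nm, all_classes)
  images_json <- purrr::imap(seq_len(nrow(images)), function(i, ...) {
    list(id = i, file_name = paste0(images$image_id[i], ".png"),
         width = images$width[i], height = images$height[i])
  })
  ann_id <- 0L
  anns <- list()
  for (i in seq_len(nrow(images))) {
    b <- images$boxes[[i]]
    for (j in seq_len(nrow(b))) {
      ann_id <- ann_id + 1L
      anns[[ann_id]] <- list(
        id = ann_id, image_id = i, category_id = cat_id(b$class_name[j]),
        bbox = c(b$x1[j], b$y1[j], b$x2[j] - b$x1[j], b$y2[j] - b$y1[j]),
        area = (b$x2[j] - b$x1[j]) * (b$y2[j] - b$y1[j]), iscrowd = 0L
      )
    }
  }
  cats <- purrr::imap(all_classes, function(nm, i) list(id = i, name = nm))
  jsonlite::write_json(
    list(images = images_json, annotations = anns, categories = cats),
    path, auto_unbox = TRUE, digits = NA
  )
}

read_yolo_txt <- function(path, image_info = NULL, class_names = NULL) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  } else path
  purrr::map_dfr(files, function(f) {
    id <- sub("\\.txt$", "", basename(f))
    if (!is.null(image_info) && id %in% image_info$image_id) {
      row <- image_info[image_info$image_id == id, ]
      w <- row$width[1]; h <- row$height[1]
    } else {
      png_path <- file.path(dirname(f), paste0(id, ".png"))
      if (!file.exists(png_path)) {
        abort(paste0("image size for '", id, "' unknown: supply image_info or a sibling PNG"))
      }
      img <- png::readPNG(png_path)
      h <- dim(img)[1]; w <- dim(img)[2]
    }
    lines <- readLines(f)
    lines <- lines[nzchar(trimws(lines))]
    boxes <- purrr::imap_dfr(lines, function(ln, k) {
      parts <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (length(parts) != 5 || any(is.na(parts))) {
        abort(paste0("malformed YOLO line ", k, " in '", f, "': ", ln))
      }
      cid <- as.integer(parts[1])
      tibble(
        x1 = (parts[2] - parts[4] / 2) * w, y1 = (parts[3] - parts[5] / 2) * h,
        x2 = (parts[2] + parts[4] / 2) * w, y2 = (parts[3] + parts[5] / 2) * h,
        class_id = cid,
        class_name = if (!is.null(class_names)) class_names[cid + 1] else as.character(cid)
      )
    })
    if (nrow(boxes) == 0) boxes <- empty_boxes()
    annotated_image(id, w, h, boxes)
  })
}

write_yolo_txt <- function(images, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(images))) {
    b <- images$boxes[[i]]
    w <- images$width[i]; h <- images$height[i]
    lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                     b$class_id,
                     (b$x1 + b$x2) / 2 / w, (b$y1 + b$y2) / 2 / h,
                     (b$x2 - b$x1) / w, (b$y2 - b$y1) / h)
    writeLines(lines, file.path(path, paste0(images$image_id[i], ".txt")))
  }
}

# Ensure class_id/class_name columns exist and are consistent: ids are
# assigned 0-based in sorted name order when absent.
finish_classes <- function(boxes) {
  if (nrow(boxes) == 0) return(empty_boxes())
  if (!"class_id" %in% names(boxes)) {
    lv <- sort(unique(boxes$class_name))
    boxes$class_id <- match(boxes$class_name, lv) - 1L
  }
  boxes[, c("x1", "y1", "x2", "y2", "class_id", "class_name")]
}
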