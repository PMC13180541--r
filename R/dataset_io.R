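# Dataset serialisation: PNG images plus YOLO-txt or COCO-JSON boxes.
#
# Conventions, enforced by the converters: internal boxes are normalized
# center-size (cx, cy, w, h); YOLO-txt stores the same at 6-decimal fixed
# point; COCO-JSON stores pixel xywh with 0-based top-left origin.

#' Write a phantom dataset to disk
#'
#' Images are saved as grayscale PNG. `yolo_txt` writes one label file per
#' image ("class cx cy w h", 6-decimal fixed point) plus a `data.yaml`
#' descriptor listing class names; `coco_json` writes a single
#' `annotations.json` with pixel xywh boxes. A `manifest.json` records the
#' seed, configuration and per-class counts.
#'
#' @param samples non-empty list of `image_sample` objects
#' @param out_dir output directory (created if missing)
#' @param format "yolo_txt" or "coco_json"
#' @param config optional [phantom_config()] recorded in the manifest
#' @return the manifest, invisibly
#' @export
write_dataset <- function(samples, out_dir, format = c("yolo_txt", "coco_json"),
                          config = NULL) {
  if (length(samples) == 0L) stop("samples must be non-empty")
  format <- match.arg(format)
  img_dir <- file.path(out_dir, "images")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop("cannot create output directory: ", out_dir)
  stem <- sprintf("%06d", seq_along(samples))
  for (i in seq_along(samples)) {
    png::writePNG(samples[[i]]$image,
                  file.path(img_dir, paste0(stem[i], ".png")))
  }
  if (format == "yolo_txt") {
    lab_dir <- file.path(out_dir, "labels")
    dir.create(lab_dir, showWarnings = FALSE)
    for (i in seq_along(samples)) {
      b <- samples[[i]]$boxes
      lines <- if (nrow(b) == 0L) character(0) else {
        sprintf("%d %.6f %.6f %.6f %.6f", as.integer(b[, 1]),
                b[, 2], b[, 3], b[, 4], b[, 5])
      }
      writeLines(lines, file.path(lab_dir, paste0(stem[i], ".txt")))
    }
    yaml::write_yaml(list(nc = 4L, names = PHANTOM_CLASSES),
                     file.path(out_dir, "data.yaml"))
  } else {
    S <- nrow(samples[[1]]$image)
    images <- lapply(seq_along(samples), function(i) {
      list(id = i, file_name = paste0("images/", stem[i], ".png"),
           width = ncol(samples[[i]]$image), height = nrow(samples[[i]]$image))
    })
    anns <- list()
    aid <- 0L
    for (i in seq_along(samples)) {
      b <- samples[[i]]$boxes
      Si <- nrow(samples[[i]]$image)
      for (k in seq_len(nrow(b))) {
        aid <- aid + 1L
        anns[[aid]] <- list(
          id = aid, image_id = i, category_id = as.integer(b[k, 1]),
          bbox = c((b[k, 2] - b[k, 4] / 2) * Si, (b[k, 3] - b[k, 5] / 2) * Si,
                   b[k, 4] * Si, b[k, 5] * Si),
          area = b[k, 4] * Si * b[k, 5] * Si, iscrowd = 0L)
      }
    }
    cats <- lapply(0:3, function(cid) {
      list(id = cid, name = PHANTOM_CLASSES[cid + 1L])
    })
    jsonlite::write_json(list(images = images, annotations = anns,
                              categories = cats),
                         file.path(out_dir, "annotations.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  counts <- tabulate(vapply(samples, function(s) s$class_id, 0L) + 1L, 4L)
  names(counts) <- PHANTOM_CLASSES
  manifest <- list(n = length(samples), format = format,
                   class_counts = as.list(counts),
                   seed = if (!is.null(config)) config$seed else NULL,
                   config = if (!is.null(config)) {
                     config[setdiff(names(config), "class_names")]
                   } else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' Inverse of the writer. A missing YOLO label file is treated as zero
#' boxes with a warning (lesion-free images); malformed label lines and
#' out-of-range class ids raise errors naming the file and line.
#'
#' @param dir dataset directory
#' @param format "yolo_txt" or "coco_json"
#' @return list of `image_sample` objects
#' @export
read_dataset <- function(dir, format = c("yolo_txt", "coco_json")) {
  format <- match.arg(format)
  img_dir <- file.path(dir, "images")
  files <- sort(list.files(img_dir, pattern = "\\.png$"))
  if (length(files) == 0L) stop("no PNG images found under ", img_dir)
  samples <- vector("list", length(files))
  imgs <- lapply(file.path(img_dir, files), function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  })
  if (format == "yolo_txt") {
    for (i in seq_along(files)) {
      lab <- file.path(dir, "labels", sub("\\.png$", ".txt", files[i]))
      boxes <- matrix(numeric(0), 0L, 5L)
      if (!file.exists(lab)) {
        warning("missing label file ", lab, "; treating as zero boxes")
      } else {
        lines <- readLines(lab)
        lines <- lines[nzchar(trimws(lines))]
        if (length(lines) > 0L) {
          rows <- lapply(seq_along(lines), function(j) {
            parts <- strsplit(trimws(lines[j]), "\\s+")[[1]]
            vals <- suppressWarnings(as.numeric(parts))
            if (length(parts) != 5L || any(is.na(vals))) {
              stop("malformed label line in ", lab, " line ", j, ": ",
                   lines[j])
            }
            if (vals[1] < 0 || vals[1] > 3 || vals[1] != floor(vals[1])) {
              stop("class id out of range [0, 3] in ", lab, " line ", j)
            }
            vals
          })
          boxes <- do.call(rbind, rows)
        }
      }
      colnames(boxes) <- c("class_id", "cx", "cy", "w", "h")
      cid <- if (nrow(boxes) > 0L) as.integer(boxes[1L, 1L]) else 0L
      samples[[i]] <- structure(list(image = imgs[[i]], boxes = boxes,
                                     class_id = cid, meta = list()),
                                class = "image_sample")
    }
  } else {
    ann <- jsonlite::read_json(file.path(dir, "annotations.json"),
                               simplifyVector = TRUE)
    for (i in seq_along(files)) {
      Si <- nrow(imgs[[i]])
      rows <- ann$annotations[ann$annotations$image_id == i, , drop = FALSE]
      boxes <- matrix(numeric(0), 0L, 5L)
      if (nrow(rows) > 0L) {
        bb <- do.call(rbind, rows$bbox)
        cid <- rows$category_id
        if (any(cid < 0 | cid > 3)) {
          stop("class id out of range [0, 3] in annotations.json, image ", i)
        }
        boxes <- cbind(cid, (bb[, 1] + bb[, 3] / 2) / Si,
                       (bb[, 2] + bb[, 4] / 2) / Si,
                       bb[, 3] / Si, bb[, 4] / Si)
      }
      colnames(boxes) <- c("class_id", "cx", "cy", "w", "h")
      cid1 <- if (nrow(boxes) > 0L) as.integer(boxes[1L, 1L]) else 0L
      samples[[i]] <- structure(list(image = imgs[[i]], boxes = boxes,
                                     class_id = cid1, meta = list()),
                                class = "image_sample")
    }
  }
  samples
}
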