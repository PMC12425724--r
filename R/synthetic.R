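# Synthetic brain-MRI-like detection scenes with YOLO-format annotations.
# The generator emulates the schema of the four-class axial-slice tumor
# dataset (glioma / meningioma / no tumor / pituitary): a dark field, a
# bright skull ellipse enclosing textured brain tissue, and one
# class-conditional bright blob per tumor image. Classes differ in blob
# intensity, position, size and boundary irregularity, so the task is
# learnable at micro scale and even a mean-intensity threshold separates
# the classes.

#' Class names of the synthetic dataset
#' @export
braindet_classes <- function() c("glioma", "meningioma", "no_tumor", "pituitary")

# Deterministic per-image seed derivation from one master seed
# (multiply-xor-shift mix, folded into the 31-bit range R accepts).
derive_seed <- function(master, i) {
  x <- (as.numeric(master) * 2654435761 + as.numeric(i) * 40503 + 12345) %% 2^31
  x <- (x * 1103515245 + 12345) %% 2^31
  x <- (x * 69069 + 1) %% 2^31
  as.integer(x %% 2147483647)
}

# Class-conditional blob priors in normalized image units. Intensities are
# deliberately separated (gaps >> texture noise) so that a trivial
# threshold classifier works on the rendered blobs.
class_priors <- function(class_id) {
  switch(as.character(class_id),
    "0" = list(intensity = 0.72, int_jitter = 0.02, diam = c(0.18, 0.34),
               offset = c(0.08, 0.22), irregular = 0.22, lobes = 5:7,
               cy_shift = -0.05),
    "1" = list(intensity = 0.95, int_jitter = 0.02, diam = c(0.14, 0.26),
               offset = c(0.20, 0.30), irregular = 0.05, lobes = 3:4,
               cy_shift = 0),
    "3" = list(intensity = 0.84, int_jitter = 0.02, diam = c(0.09, 0.16),
               offset = c(0.00, 0.05), irregular = 0.08, lobes = 4:5,
               cy_shift = 0.12),
    stop("no blob priors for class ", class_id))
}

#' Scene specification for one synthetic image
#'
#' Draws the blob and background parameters for a single scene from the
#' class-conditional priors, deterministically under the given seed.
#'
#' @param class_id Integer class 0-3 (glioma, meningioma, no_tumor,
#'   pituitary).
#' @param image_size Square image side in pixels (default 640).
#' @param seed Integer seed; the same seed reproduces the scene bit for
#'   bit.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(class_id, image_size = 640L, seed = 0L) {
  if (!class_id %in% 0:3) stop("scene_spec: class_id must be in 0..3")
  with_local_seed(seed, {
    brain <- list(cx = 0.5 + runif(1, -0.01, 0.01),
                  cy = 0.5 + runif(1, -0.01, 0.01),
                  a = runif(1, 0.36, 0.40), b = runif(1, 0.42, 0.46),
                  skull = 0.035, tissue = 0.35, noise_sd = 0.03)
    blob <- NULL
    if (class_id != 2L) {
      pr <- class_priors(class_id)
      diam <- runif(1, pr$diam[1], pr$diam[2])
      r_off <- runif(1, pr$offset[1], pr$offset[2])
      th <- runif(1, 0, 2 * pi)
      cx <- brain$cx + r_off * cos(th) * brain$a
      cy <- brain$cy + r_off * sin(th) * brain$b + pr$cy_shift
      amp <- pr$irregular
      half <- diam / 2 * (1 + amp)
      # keep the blob inside the brain ellipse (and hence the image)
      cx <- min(max(cx, brain$cx - brain$a + half + 0.02),
                brain$cx + brain$a - half - 0.02)
      cy <- min(max(cy, brain$cy - brain$b + half + 0.02),
                brain$cy + brain$b - half - 0.02)
      blob <- list(cx = cx, cy = cy,
                   ax = diam / 2, ay = diam / 2 * runif(1, 0.75, 1.0),
                   rot = runif(1, 0, pi),
                   intensity = pr$intensity + runif(1, -1, 1) * pr$int_jitter,
                   irregular = amp, lobes = sample(pr$lobes, 1),
                   phase = runif(1, 0, 2 * pi), texture_sd = 0.03)
      if (blob$cx - half < 0 || blob$cx + half > 1 ||
          blob$cy - half < 0 || blob$cy + half > 1)
        stop("scene_spec: blob would exceed image bounds")
    }
    structure(list(class_id = as.integer(class_id),
                   image_size = as.integer(image_size),
                   seed = as.integer(seed), brain = brain, blob = blob,
                   noise_seed = derive_seed(seed, 7L)),
              class = "scene_spec")
  })
}

#' Render a synthetic scene
#'
#' Renders the grayscale image for a [scene_spec()] together with its
#' YOLO-style annotation records. Tumor scenes carry exactly one blob whose
#' bounding box is recomputed from the rendered blob mask (tight to the
#' foreground pixels); "no tumor" scenes render no blob and are annotated
#' with one box covering the brain ellipse (class 2), mirroring datasets in
#' which the absent-tumor state is itself a detected class.
#'
#' @param spec A `scene_spec`.
#' @param annotate_no_tumor If `FALSE`, "no tumor" scenes get an empty
#'   annotation list instead of the brain-region box.
#' @return A list with `image` (matrix `size x size`, values in `[0, 1]`),
#'   `records` (data.frame `class_id, cx, cy, w, h`, normalized), and
#'   `blob_mask` (logical matrix).
#' @export
generate_image <- function(spec, annotate_no_tumor = TRUE) {
  n <- spec$image_size
  # pixel-center coordinates in normalized units; row i = y, col j = x
  xs <- (seq_len(n) - 0.5) / n
  px <- matrix(xs, n, n, byrow = TRUE)
  py <- matrix(xs, n, n)
  br <- spec$brain
  exn <- ((px - br$cx) / br$a)^2 + ((py - br$cy) / br$b)^2
  skull_out <- ((px - br$cx) / (br$a + br$skull))^2 +
    ((py - br$cy) / (br$b + br$skull))^2
  img <- matrix(0.05, n, n)
  img[skull_out <= 1] <- 0.9                     # skull shell
  brain_mask <- exn <= 1
  img[brain_mask] <- br$tissue

  blob_mask <- matrix(FALSE, n, n)
  records <- data.frame(class_id = integer(0), cx = numeric(0),
                        cy = numeric(0), w = numeric(0), h = numeric(0))
  if (!is.null(spec$blob)) {
    bl <- spec$blob
    dx <- px - bl$cx; dy <- py - bl$cy
    u <- (dx * cos(bl$rot) + dy * sin(bl$rot)) / bl$ax
    v <- (-dx * sin(bl$rot) + dy * cos(bl$rot)) / bl$ay
    rho <- sqrt(u^2 + v^2)
    phi <- atan2(v, u)
    edge <- 1 + bl$irregular * sin(bl$lobes * phi + bl$phase)
    blob_mask <- rho <= edge
    img[blob_mask] <- bl$intensity
  }
  old <- with_local_seed(spec$noise_seed, {
    img <- img + matrix(rnorm(n * n, sd = br$noise_sd), n, n) * brain_mask
    if (!is.null(spec$blob))
      img[blob_mask] <- spec$blob$intensity +
        rnorm(sum(blob_mask), sd = spec$blob$texture_sd)
    img
  })
  img <- pmin(pmax(old, 0), 1)

  if (!is.null(spec$blob)) {
    ii <- which(blob_mask, arr.ind = TRUE)
    x1 <- (min(ii[, 2]) - 1) / n; x2 <- max(ii[, 2]) / n
    y1 <- (min(ii[, 1]) - 1) / n; y2 <- max(ii[, 1]) / n
    records <- data.frame(class_id = spec$class_id,
                          cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                          w = x2 - x1, h = y2 - y1)
  } else if (annotate_no_tumor) {
    records <- data.frame(class_id = 2L, cx = br$cx, cy = br$cy,
                          w = 2 * (br$a + br$skull), h = 2 * (br$b + br$skull))
  }
  list(image = img, records = records, blob_mask = blob_mask)
}

#' Read and write YOLO-format label files
#'
#' One line per box: `class cx cy w h`, center/extent normalized to (0, 1],
#' written at 6 decimal places. An empty file round-trips to an empty
#' record set.
#'
#' @param path Label file path.
#' @return `read_yolo_labels` returns a data.frame with columns
#'   `class_id, cx, cy, w, h`.
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                    w = numeric(0), h = numeric(0))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(f))
    if (length(f) != 5 || any(is.na(vals)))
      stop("malformed YOLO label at ", path, " line ", i, ": '", lines[i], "'")
    out <- rbind(out, data.frame(class_id = as.integer(vals[1]), cx = vals[2],
                                 cy = vals[3], w = vals[4], h = vals[5]))
  }
  out
}

#' @rdname read_yolo_labels
#' @param records Data frame with columns `class_id, cx, cy, w, h`.
#' @export
write_yolo_labels <- function(records, path) {
  lines <- if (nrow(records) == 0) character(0) else
    sprintf("%d %.6f %.6f %.6f %.6f", records$class_id, records$cx,
            records$cy, records$w, records$h)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic detection dataset on disk
#'
#' Writes PNG images, YOLO label files and a YAML manifest for train/val
#' splits. The default per-class counts are the dataset schema the
#' generator emulates (train 1153/1449/711/1424, val 136/140/100/136),
#' scaled by `scale` for desk-size runs.
#'
#' @param out_dir Output directory (created if missing).
#' @param scale Multiplier applied to the default per-class counts
#'   (default 0.02).
#' @param counts Optional explicit list
#'   `list(train = c(...4 counts...), val = c(...))` overriding `scale`.
#' @param image_size Square image side in pixels.
#' @param seed Master seed; each image derives its own seed from it.
#' @param annotate_no_tumor See [generate_image()].
#' @return A `dataset_manifest` object (invisibly written as
#'   `data.yaml`).
#' @export
generate_dataset <- function(out_dir, scale = 0.02, counts = NULL,
                             image_size = 640L, seed = 0L,
                             annotate_no_tumor = TRUE) {
  base <- list(train = c(1153L, 1449L, 711L, 1424L),
               val = c(136L, 140L, 100L, 136L))
  if (is.null(counts))
    counts <- lapply(base, function(v) pmax(1L, as.integer(round(v * scale))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  class_names <- braindet_classes()
  files <- list()
  img_idx <- 0L
  for (split in names(counts)) {
    idir <- file.path(out_dir, "images", split)
    ldir <- file.path(out_dir, "labels", split)
    dir.create(idir, recursive = TRUE, showWarnings = FALSE)
    dir.create(ldir, recursive = TRUE, showWarnings = FALSE)
    cls_seq <- rep(0:3, times = counts[[split]])
    paths <- character(length(cls_seq))
    for (i in seq_along(cls_seq)) {
      img_idx <- img_idx + 1L
      sseed <- derive_seed(seed, img_idx)
      sc <- scene_spec(cls_seq[i], image_size, seed = sseed)
      sc_img <- generate_image(sc, annotate_no_tumor = annotate_no_tumor)
      stem <- sprintf("%s_%05d_c%d", split, i, cls_seq[i])
      png::writePNG(sc_img$image, file.path(idir, paste0(stem, ".png")))
      write_yolo_labels(sc_img$records, file.path(ldir, paste0(stem, ".txt")))
      paths[i] <- file.path("images", split, paste0(stem, ".png"))
    }
    files[[split]] <- paths
  }
  manifest <- structure(list(path = normalizePath(out_dir),
                             train = "images/train", val = "images/val",
                             names = class_names,
                             counts = counts, files = files,
                             image_size = as.integer(image_size),
                             seed = as.integer(seed)),
                        class = "dataset_manifest")
  yaml::write_yaml(list(path = manifest$path, train = manifest$train,
                        val = manifest$val, names = as.list(class_names),
                        counts = lapply(counts, as.integer),
                        image_size = as.integer(image_size)),
                   file.path(out_dir, "data.yaml"))
  manifest
}

#' Load a dataset manifest written by [generate_dataset()]
#'
#' @param path Directory containing `data.yaml`, or the YAML file itself.
#' @export
read_manifest <- function(path) {
  yml <- if (dir.exists(path)) file.path(path, "data.yaml") else path
  m <- yaml::read_yaml(yml)
  root <- m$path
  files <- lapply(c(train = "train", val = "val"), function(split) {
    idir <- file.path(root, "images", split)
    file.path("images", split, list.files(idir, pattern = "\\.png$"))
  })
  structure(list(path = root, train = m$train, val = m$val,
                 names = unlist(m$names), counts = m$counts, files = files,
                 image_size = m$image_size %||% NA_integer_),
            class = "dataset_manifest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Load one image as an (H, W, 3) array in [0, 1]; grayscale inputs are
# replicated to 3 channels.
load_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) {
    array(img, dim = c(dim(img), 3))
  } else if (dim(img)[3] >= 3) {
    img[, , 1:3, drop = FALSE]
  } else {
    array(img[, , 1], dim = c(dim(img)[1:2], 3))
  }
}

# Label path corresponding to an image path inside a manifest root.
label_path_for <- function(img_rel) {
  sub("\\.png$", ".txt", sub("^images/", "labels/", img_rel))
}
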