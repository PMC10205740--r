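# Dataset layout: a CSV manifest with one row per sample, an images/
# directory and (for annotated samples) a masks/ directory. Images are
# 8-bit RGB PNGs; masks encode the three classes either as a grayscale PNG
# with values {0,1,2} or as an RGB PNG whose colors are looked up in a
# palette table (default: black = background, green = healthy epidermis,
# red = damaged epidermis).

TISSUES <- c("human_skin", "human_skin_model", "porcine_skin")
STAININGS <- c("CPD", "64PP", "MAA", "MAC")

MANIFEST_REQUIRED <- c("sample_id", "image_path", "tissue", "staining", "s_nuclei")

#' Default mask palette
#'
#' Maps RGB triplets (0-255) in mask PNG files to the three label classes:
#' background/other (0), healthy epidermis (1), damaged epidermis (2).
#'
#' @return A data.frame with columns `class`, `r`, `g`, `b`.
#' @export
mask_palette <- function() {
  data.frame(class = 0:2,
             r = c(0L, 0L, 255L),
             g = c(0L, 255L, 0L),
             b = c(0L, 0L, 0L))
}

new_manifest <- function(df, resolution_um_per_px, image_height_px,
                         image_width_px, base_dir = ".") {
  structure(df,
            resolution_um_per_px = resolution_um_per_px,
            image_height_px = image_height_px,
            image_width_px = image_width_px,
            base_dir = base_dir,
            class = c("epiderm_manifest", "data.frame"))
}

#' @export
`[.epiderm_manifest` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("resolution_um_per_px", "image_height_px", "image_width_px",
                "base_dir"))
      attr(out, a) <- attr(x, a)
    class(out) <- unique(c("epiderm_manifest", class(out)))
  }
  out
}

validate_manifest_df <- function(df) {
  missing_cols <- setdiff(MANIFEST_REQUIRED, names(df))
  if (length(missing_cols) > 0)
    ep_stop(paste0("manifest is missing required column(s): ",
                   paste(missing_cols, collapse = ", ")), "epiderm_schema_error")
  if (anyDuplicated(df$sample_id))
    ep_stop(paste0("duplicate sample_id: ",
                   paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")),
            "epiderm_validation_error")
  if (any(!is.finite(df$s_nuclei)) || any(df$s_nuclei < 0 | df$s_nuclei > 1))
    ep_stop("s_nuclei must lie in [0, 1]", "epiderm_validation_error")
  bad_t <- setdiff(unique(df$tissue), TISSUES)
  if (length(bad_t) > 0)
    ep_stop(paste0("unknown tissue: ", paste(bad_t, collapse = ", ")),
            "epiderm_validation_error")
  bad_s <- setdiff(unique(df$staining), STAININGS)
  if (length(bad_s) > 0)
    ep_stop(paste0("unknown staining: ", paste(bad_s, collapse = ", ")),
            "epiderm_validation_error")
  if ("s_area" %in% names(df)) {
    sa <- df$s_area[!is.na(df$s_area)]
    if (any(sa < 0 | sa > 1))
      ep_stop("s_area must lie in [0, 1]", "epiderm_validation_error")
  }
  invisible(df)
}

#' Load a dataset manifest
#'
#' Reads and validates the CSV manifest describing a dataset. Required
#' columns: `sample_id`, `image_path`, `tissue`, `staining`, `s_nuclei`.
#' An optional `mask_path` column marks samples with pixel-wise annotation;
#' rows with an empty or missing mask path get `has_segmentation = FALSE`.
#' Per-dataset metadata (`resolution_um_per_px`, `image_height_px`,
#' `image_width_px`) is carried as constant columns and must be identical
#' across rows.
#'
#' @param path Path to the manifest CSV.
#' @param exclude Character vector of `sample_id`s to drop (default none).
#' @return An `epiderm_manifest`: a data.frame of sample records with the
#'   dataset resolution and image geometry attached as attributes.
#' @export
load_manifest <- function(path, exclude = character()) {
  if (!file.exists(path)) ep_stop(paste0("no manifest at ", path), "epiderm_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest_df(df)
  if (!"mask_path" %in% names(df)) df$mask_path <- rep(NA_character_, nrow(df))
  df$mask_path[!is.na(df$mask_path) & df$mask_path == ""] <- NA_character_
  df$has_segmentation <- !is.na(df$mask_path)
  if (!"s_area" %in% names(df)) df$s_area <- rep(NA_real_, nrow(df))
  res <- if ("resolution_um_per_px" %in% names(df)) df$resolution_um_per_px else 0.645
  hh <- if ("image_height_px" %in% names(df)) df$image_height_px else NA_integer_
  ww <- if ("image_width_px" %in% names(df)) df$image_width_px else NA_integer_
  if (length(unique(res)) > 1)
    ep_stop("all records must share one declared resolution", "epiderm_validation_error")
  df <- df[!(df$sample_id %in% exclude), , drop = FALSE]
  rownames(df) <- NULL
  new_manifest(df, res[1], hh[1], ww[1], base_dir = dirname(path))
}

#' Write a dataset manifest
#'
#' Inverse of [load_manifest()]: writes the record table (including the
#' resolution/geometry metadata columns) so that loading it back yields
#' field-identical records.
#'
#' @param manifest An `epiderm_manifest`.
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  df$resolution_um_per_px <- attr(manifest, "resolution_um_per_px")
  df$image_height_px <- attr(manifest, "image_height_px")
  df$image_width_px <- attr(manifest, "image_width_px")
  df$has_segmentation <- NULL  # derived on load
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    EBImage::imageData(EBImage::readImage(path))
  } else {
    png::readPNG(path)
  }
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

decode_mask <- function(a, palette = mask_palette()) {
  if (length(dim(a)) == 3 && dim(a)[3] >= 3) {
    key <- round(a[, , 1] * 255) * 65536 + round(a[, , 2] * 255) * 256 + round(a[, , 3] * 255)
    pal_key <- palette$r * 65536 + palette$g * 256 + palette$b
    m <- array(NA_integer_, dim(key))
    for (i in seq_len(nrow(palette))) m[key == pal_key[i]] <- palette$class[i]
    if (anyNA(m)) {
      bad <- key[is.na(m)][1]
      ep_stop(sprintf("unknown mask value rgb(%d,%d,%d)",
                      bad %/% 65536, (bad %/% 256) %% 256, bad %% 256),
              "epiderm_mask_error")
    }
  } else {
    if (length(dim(a)) == 3) a <- a[, , 1]
    m <- round(a * 255)
    bad <- setdiff(unique(c(m)), palette$class)
    if (length(bad) > 0)
      ep_stop(paste0("unknown mask value ", bad[1]), "epiderm_mask_error")
    storage.mode(m) <- "integer"
  }
  m
}

#' Load one sample (image and optional label mask)
#'
#' @param record One-row slice of an `epiderm_manifest` (or a list with
#'   `image_path` and optional `mask_path`).
#' @param base_dir Directory that relative paths are resolved against;
#'   defaults to the manifest's own directory when `record` comes from one.
#' @param palette Color table used to decode RGB-coded masks; see
#'   [mask_palette()].
#' @return A list with `image` (H x W x 3 array, values 0-255) and `mask`
#'   (integer H x W matrix with classes 0/1/2, or `NULL`).
#' @export
load_sample <- function(record, base_dir = NULL, palette = mask_palette()) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    if (is.null(base_dir)) base_dir <- attr(record, "base_dir")
    record <- as.list(record)
  }
  if (is.null(base_dir)) base_dir <- "."
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  img_path <- resolve(record$image_path)
  if (!file.exists(img_path))
    ep_stop(paste0("image file not found: ", record$image_path), "epiderm_io_error")
  image <- read_image_file(img_path)
  mask <- NULL
  if (!is.null(record$mask_path) && length(record$mask_path) == 1 &&
      !is.na(record$mask_path) && nzchar(record$mask_path)) {
    mp <- resolve(record$mask_path)
    if (!file.exists(mp))
      ep_stop(paste0("mask file not found: ", record$mask_path), "epiderm_io_error")
    mask <- decode_mask(png::readPNG(mp), palette)
    if (!all(dim(mask) == dim(image)[1:2]))
      ep_stop(sprintf("mask dims %dx%d do not match image dims %dx%d",
                      nrow(mask), ncol(mask), dim(image)[1], dim(image)[2]),
              "epiderm_shape_error")
  }
  list(image = image, mask = mask)
}

#' Write a label mask as an RGB-coded PNG
#'
#' @param mask Integer matrix with classes 0/1/2.
#' @param path Output path.
#' @param palette Color table; see [mask_palette()].
#' @export
write_mask <- function(mask, path, palette = mask_palette()) {
  stopifnot(all(mask %in% palette$class))
  a <- array(0, c(dim(mask), 3))
  for (i in seq_len(nrow(palette))) {
    sel <- mask == palette$class[i]
    a[, , 1][sel] <- palette$r[i] / 255
    a[, , 2][sel] <- palette$g[i] / 255
    a[, , 3][sel] <- palette$b[i] / 255
  }
  png::writePNG(a, path)
  invisible(path)
}

#' Validate a dataset against its manifest
#'
#' Never errors: all problems are collected into the report.
#'
#' @param manifest An `epiderm_manifest`.
#' @return A list with per-tissue and per-staining counts, the number of
#'   samples with segmentation masks, and the paths of unreadable files.
#' @export
validate_dataset <- function(manifest) {
  df <- as.data.frame(manifest)
  base_dir <- attr(manifest, "base_dir")
  if (is.null(base_dir)) base_dir <- "."
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))
  unreadable <- character()
  if (nrow(df) > 0) {
    ip <- resolve(df$image_path)
    unreadable <- c(unreadable, df$image_path[!file.exists(ip)])
    has_mask <- !is.na(df$mask_path)
    if (any(has_mask)) {
      mp <- resolve(df$mask_path[has_mask])
      unreadable <- c(unreadable, df$mask_path[has_mask][!file.exists(mp)])
    }
  }
  count_by <- function(values, levels) {
    out <- table(factor(values, levels = levels))
    stats::setNames(as.integer(out), levels)
  }
  list(n = nrow(df),
       by_tissue = count_by(df$tissue, TISSUES),
       by_staining = count_by(df$staining, STAININGS),
       n_with_segmentation = if (nrow(df) > 0) sum(df$has_segmentation) else 0L,
       unreadable = unreadable)
}
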