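# Reading, normalizing and resizing slice images; assembling subject stacks.

#' Load a grayscale slice image from a PNG file
#'
#' Reads an 8- or 16-bit PNG, collapses RGB to luminance (Rec. 601 weights),
#' and rescales intensities to `[0, 1]` by min-max over the slice.  A
#' constant (zero-variance) image maps to all zeros with a warning, so
#' degenerate inputs still flow through the pipeline.
#'
#' @param path Path to a PNG file.
#' @return A numeric matrix with values in `[0, 1]` and attribute `source`
#'   set to `path`.
#' @seealso [save_slice()], [resize_slice()]
#' @export
load_slice <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read slice image: file not found: %s", path),
         call. = FALSE)
  img <- tryCatch(png::readPNG(path),
                  error = function(e)
                    stop(sprintf("cannot decode PNG %s: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]  # gray(+alpha)
  }
  rng <- range(img)
  if (rng[1] == rng[2]) {
    warning(sprintf("constant image %s rescaled to all zeros", path),
            call. = FALSE)
    img[] <- 0
  } else {
    img <- (img - rng[1]) / (rng[2] - rng[1])
  }
  attr(img, "source") <- path
  img
}

#' Write a slice image to a PNG file
#'
#' Clips to `[0, 1]` and writes an 8-bit grayscale PNG.
#'
#' @param x Numeric image matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_slice <- function(x, path) {
  x <- pmin(pmax(x, 0), 1)
  png::writePNG(x, target = path)
  invisible(path)
}

#' Resize a slice to the working resolution
#'
#' Bilinear resampling to the working grid (256 x 256 by default, the
#' resolution at which features are extracted).  An input already at the
#' target size is returned unchanged; output intensities are clipped to
#' `[0, 1]`.
#'
#' @param x Numeric image matrix with at least 8 rows and 8 columns.
#' @param size Target dimensions `c(rows, cols)`.
#' @return A `size[1]` x `size[2]` numeric matrix in `[0, 1]`.
#' @export
resize_slice <- function(x, size = c(256L, 256L)) {
  stopifnot(is.matrix(x), length(size) == 2L)
  if (nrow(x) < 8L || ncol(x) < 8L)
    stop("input image must be at least 8x8", call. = FALSE)
  size <- as.integer(size)
  if (nrow(x) == size[1] && ncol(x) == size[2]) return(x)
  y <- EBImage::imageData(
    EBImage::resize(EBImage::Image(x), w = size[1], h = size[2],
                    filter = "bilinear"))
  pmin(pmax(y, 0), 1)
}

#' Bundle slices of one subject
#'
#' @param slices List of equally sized slice matrices, in stack order.
#' @param label Class label, `"patient"` or `"control"`.
#' @param subject_id Subject identifier string.
#' @return An object of class `"subject_stack"`.
#' @export
subject_stack <- function(slices, label = c("patient", "control"),
                          subject_id = "subject") {
  label <- match.arg(label)
  stopifnot(is.list(slices), length(slices) >= 1L)
  d <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), d), logical(1))))
    stop("all slices of a subject must have identical dimensions",
         call. = FALSE)
  structure(list(slices = slices, label = label, subject_id = subject_id),
            class = "subject_stack")
}

#' @export
print.subject_stack <- function(x, ...) {
  cat(sprintf("Subject %s (%s): %d slice(s) of %dx%d\n", x$subject_id,
              x$label, length(x$slices), nrow(x$slices[[1]]),
              ncol(x$slices[[1]])))
  invisible(x)
}

#' Read a cohort manifest
#'
#' The manifest is a plain-text tab-separated table with columns
#' `subject_id`, `label` and `path` — one row per slice file, slices of a
#' subject in stack order.  Labels must be `patient` or `control`.
#'
#' @param path Path to the manifest file.
#' @return A `data.frame` with the three columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns subject_id, label, path", call. = FALSE)
  bad <- setdiff(unique(m$label), c("patient", "control"))
  if (length(bad))
    stop("manifest labels must be 'patient' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  m
}

#' Load a cohort of subject stacks from a manifest
#'
#' Reads every slice referenced by the manifest, normalizes and resizes it to
#' the working resolution, and groups slices into per-subject stacks.  When
#' the source images carry more slices than wanted, `slice_range` picks an
#' explicit index range (replacing any manual slice selection upstream).
#'
#' @param manifest A manifest `data.frame` (see [read_manifest()]) or a path
#'   to one.
#' @param size Working resolution, default `c(256, 256)`.
#' @param slice_range Optional integer vector of slice indices to keep per
#'   subject (applied after grouping, e.g. `9:40`).
#' @return A list of [subject_stack()] objects, one per subject, in order of
#'   first appearance.
#' @export
load_cohort <- function(manifest, size = c(256L, 256L), slice_range = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  ids <- unique(manifest$subject_id)
  lapply(ids, function(id) {
    rows <- manifest[manifest$subject_id == id, , drop = FALSE]
    lab <- unique(rows$label)
    if (length(lab) != 1L)
      stop(sprintf("subject %s has inconsistent labels", id), call. = FALSE)
    if (!is.null(slice_range)) {
      keep <- intersect(slice_range, seq_len(nrow(rows)))
      rows <- rows[keep, , drop = FALSE]
    }
    slices <- lapply(rows$path, function(p) resize_slice(load_slice(p), size))
    subject_stack(slices, label = lab, subject_id = id)
  })
}
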