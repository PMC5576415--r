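# Fixed-length per-subject feature vectors from wavelet pyramids.
#
# For the dual-tree transform the feature of a slice is the magnitude of all
# six directional subbands at one scale; for a 256x256 slice at the default
# scale (16x16 subbands) that is 6*16*16 = 1536 numbers per slice and
# 1536*32 = 49,152 per 32-slice subject.  The DWT baseline uses the
# approximation plus the three detail subbands at the same scale
# (4*16*16 = 1024 per slice).

#' Default feature scale for a working image size
#'
#' The scale is defined operationally as the decomposition level whose
#' directional subbands are 16 x 16 — for 256 x 256 slices that is level 4,
#' reproducing the published per-slice feature count of 1536.
#'
#' @param size Image side length (power of two, > 16).
#' @return The level (integer).
#' @export
default_feature_scale <- function(size) {
  lv <- log2(size / 16)
  if (lv < 1 || lv != round(lv))
    stop("no scale with 16x16 subbands exists for image side ", size,
         "; pass `scale` explicitly", call. = FALSE)
  as.integer(lv)
}

.slice_features <- function(x, transform, scale, filters) {
  if (transform == "dtcwt") {
    p <- dtcwt2d(x, levels = scale, filters = filters)
    unlist(lapply(p$levels[[scale]], function(z) as.vector(Mod(z))),
           use.names = FALSE)
  } else {
    p <- dwt2d(x, levels = scale, filters = filters)
    c(as.vector(p$lowpass),
      unlist(lapply(p$levels[[scale]], as.vector), use.names = FALSE))
  }
}

#' Wavelet feature vector of a subject stack
#'
#' Transforms every slice of the stack and concatenates the selected-scale
#' coefficients slice by slice.  Ordering is fixed: slice-major, then subband
#' (orientations `d15, d45, d75, dm75, dm45, dm15` for the DTCWT;
#' approximation then `LH, HL, HH` for the DWT), then column-major within
#' each subband grid.
#'
#' @param stack A [subject_stack()].
#' @param transform `"dtcwt"` (magnitudes of the six complex directional
#'   subbands) or `"dwt"` (real approximation + detail coefficients).
#' @param scale Decomposition level to take features from; default is the
#'   level with 16 x 16 subbands (see [default_feature_scale()]).
#' @param filters Filter bank set.
#' @return Numeric feature vector with attributes `layout` (a list recording
#'   the ordering), `subject_id` and `label`.
#' @examples
#' st <- phantom_subject(phantom_spec(image_size = 64, n_slices = 2), "control", 1)
#' length(stack_features(st))  # 2 * 6 * 16 * 16 = 3072
#' @export
stack_features <- function(stack, transform = c("dtcwt", "dwt"),
                           scale = NULL, filters = dtcwt_filters()) {
  transform <- match.arg(transform)
  stopifnot(inherits(stack, "subject_stack"))
  size <- nrow(stack$slices[[1]])
  if (is.null(scale)) scale <- default_feature_scale(size)
  if (size %% 2L^scale != 0L || size / 2L^scale < 1L)
    stop("scale ", scale, " exceeds the decomposition depth of ", size,
         "-pixel slices", call. = FALSE)
  v <- unlist(lapply(stack$slices, .slice_features, transform = transform,
                     scale = scale, filters = filters), use.names = FALSE)
  sub <- as.integer(size / 2L^scale)
  structure(v,
            layout = list(transform = transform, scale = scale,
                          n_slices = length(stack$slices),
                          subband_dim = c(sub, sub),
                          per_slice = length(v) / length(stack$slices),
                          order = "slice-major, then subband, then column-major"),
            subject_id = stack$subject_id, label = stack$label)
}

#' Feature matrix of a cohort
#'
#' Applies [stack_features()] to every subject and stacks the results into a
#' subjects x features matrix with class labels coded `+1` (patient) and
#' `-1` (control).
#'
#' @param stacks List of [subject_stack()] objects.
#' @inheritParams stack_features
#' @return A numeric matrix of class `"wave_features"`; attributes: `labels`
#'   (`+1`/`-1` per row), `layout` as in [stack_features()], and row names
#'   set to subject ids.
#' @export
cohort_features <- function(stacks, transform = c("dtcwt", "dwt"),
                            scale = NULL, filters = dtcwt_filters()) {
  transform <- match.arg(transform)
  rows <- lapply(stacks, stack_features, transform = transform, scale = scale,
                 filters = filters)
  len <- unique(vapply(rows, length, integer(1)))
  if (length(len) != 1L)
    stop("subjects yielded feature vectors of different lengths; ",
         "slice counts or sizes differ within the cohort", call. = FALSE)
  X <- do.call(rbind, lapply(rows, as.vector))
  rownames(X) <- vapply(rows, attr, "", which = "subject_id")
  labels <- ifelse(vapply(rows, attr, "", which = "label") == "patient",
                   1, -1)
  structure(X, labels = labels, layout = attr(rows[[1]], "layout"),
            class = c("wave_features", class(X)))
}

#' Write / read a feature matrix as TSV + JSON sidecar
#'
#' The matrix is stored as a plain tab-separated table (one row per subject,
#' first two columns `subject_id` and `label`), with a JSON sidecar
#' (`<path>.json`) describing the feature layout.
#'
#' @param x A `"wave_features"` matrix from [cohort_features()].
#' @param path Output TSV path.
#' @return `path`, invisibly (`write_features`); the restored
#'   `"wave_features"` matrix (`read_features`).
#' @export
write_features <- function(x, path) {
  stopifnot(inherits(x, "wave_features"))
  df <- data.frame(subject_id = rownames(x),
                   label = ifelse(attr(x, "labels") > 0, "patient", "control"),
                   unclass(x), check.names = FALSE)
  colnames(df) <- c("subject_id", "label",
                    paste0("f", seq_len(ncol(x))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(attr(x, "layout"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path))
    stop("features file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(X) <- list(df$subject_id, NULL)
  layout <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(X, labels = ifelse(df$label == "patient", 1, -1),
            layout = layout, class = c("wave_features", class(X)))
}
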