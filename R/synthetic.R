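# Synthetic two-class brain phantom cohorts.
#
# Each subject is a stack of 2-D slices through an elliptical "brain": a
# bright textured cortical band, an interior of intermediate intensity with
# smooth low-frequency texture, and two dark elliptical "ventricles".  The
# patient class enlarges the ventricles and thins the cortical band in
# proportion to `effect_size`, mimicking the atrophy-driven morphometric
# differences the pipeline targets; per-subject jitter of the geometry
# models anatomical variability, per-slice scaling emulates moving through
# the volume, and additive Gaussian noise models acquisition noise.

#' Phantom cohort specification
#'
#' @param image_size Slice side length in pixels (default 256, the working
#'   resolution of the pipeline).
#' @param n_slices Slices per subject (default 32, matching the per-subject
#'   stack the feature layout assumes).
#' @param effect_size Non-negative scaling of the class difference; 0 makes
#'   the two classes draws from the same distribution.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise
#'   (intensity units; default 0.05).
#' @param texture_scale Angular frequency of the cortical texture (cycles
#'   around the band; default 8), giving the phantom multiscale directional
#'   structure.
#' @param seed Master seed; every subject derives its own stream from it.
#' @return Object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(image_size = 256L, n_slices = 32L, effect_size = 1,
                         noise_sd = 0.05, texture_scale = 8, seed = 1L) {
  stopifnot(image_size >= 32L, n_slices >= 1L, effect_size >= 0,
            noise_sd >= 0, texture_scale > 0)
  structure(list(image_size = as.integer(image_size),
                 n_slices = as.integer(n_slices),
                 effect_size = effect_size, noise_sd = noise_sd,
                 texture_scale = texture_scale, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("Phantom spec: %dx%d, %d slice(s)/subject, effect %.2f, ",
                     "noise sd %.3f, seed %d\n"),
              x$image_size, x$image_size, x$n_slices, x$effect_size,
              x$noise_sd, x$seed))
  invisible(x)
}

# One slice. All geometry in normalized [-1,1] coordinates.
.phantom_slice <- function(n, zscale, geom, noise_sd, texture_scale, phase) {
  u <- seq(-1, 1, length.out = n)
  Xc <- matrix(u, n, n, byrow = TRUE)       # column coordinate
  Yc <- matrix(u, n, n)                     # row coordinate
  a <- geom$a * zscale; b <- geom$b * zscale
  # elliptical radius of each pixel w.r.t. the brain outline
  r <- sqrt(((Xc - geom$cx) / a)^2 + ((Yc - geom$cy) / b)^2)
  img <- matrix(0.02, n, n)                 # background
  inside <- r < 1
  img[inside] <- 0.55
  # interior low-frequency texture (smooth, direction-rich)
  tex <- 0.06 * sin(pi * texture_scale / 4 * (Xc - geom$cx) + phase) *
         sin(pi * texture_scale / 4 * (Yc - geom$cy) - phase)
  img[inside] <- img[inside] + tex[inside]
  # cortical band: bright rim between band_r and 1, angular texture
  theta <- atan2((Yc - geom$cy) / b, (Xc - geom$cx) / a)
  band <- inside & r >= geom$band_r
  img[band] <- 0.78 + 0.08 * sin(texture_scale * theta[band] + phase)
  # two dark ventricles, mirrored about the midline
  for (s in c(-1, 1)) {
    vx <- geom$cx + s * 0.22 * a
    vy <- geom$cy - 0.05 * b
    rv <- sqrt(((Xc - vx) / (geom$va * a))^2 + ((Yc - vy) / (geom$vb * b))^2)
    img[rv < 1] <- 0.12
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
  pmin(pmax(img, 0), 1)
}

#' Generate one phantom subject
#'
#' Draws subject-specific geometry from a stream derived from the spec's
#' master seed and the subject index, then renders `n_slices` slices whose
#' overall scale varies smoothly through the stack (as slicing an ellipsoid
#' would).  Patients get ventricles enlarged by
#' `1 + 0.35 * effect_size` and a cortical band thinned in proportion to
#' `effect_size`.
#'
#' @param spec A [phantom_spec()].
#' @param label `"patient"` or `"control"`.
#' @param index Positive integer identifying the subject within the cohort;
#'   together with `spec$seed` it determines the subject's random stream.
#' @return A [subject_stack()].
#' @export
phantom_subject <- function(spec, label = c("control", "patient"), index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  label <- match.arg(label)
  index <- as.integer(index)
  seed_i <- (as.numeric(spec$seed) * 2654435 + 7907 * index +
             131 * (label == "patient")) %% 2147483647
  set.seed(as.integer(seed_i))
  es <- spec$effect_size * (label == "patient")
  geom <- list(
    a = 0.80 * stats::runif(1, 0.97, 1.03),
    b = 0.68 * stats::runif(1, 0.97, 1.03),
    cx = stats::runif(1, -0.02, 0.02),
    cy = stats::runif(1, -0.02, 0.02),
    band_r = (0.84 + 0.05 * es) * stats::runif(1, 0.99, 1.01),
    va = 0.16 * (1 + 0.35 * es) * stats::runif(1, 0.95, 1.05),
    vb = 0.30 * (1 + 0.35 * es) * stats::runif(1, 0.95, 1.05))
  phase <- stats::runif(1, 0, 2 * pi)
  z <- if (spec$n_slices == 1L) 0 else
    seq(-0.6, 0.6, length.out = spec$n_slices)
  slices <- lapply(z, function(zz) {
    .phantom_slice(spec$image_size, sqrt(1 - 0.5 * zz^2), geom,
                   spec$noise_sd, spec$texture_scale, phase)
  })
  subject_stack(slices, label = label,
                subject_id = sprintf("%s%03d",
                                     if (label == "patient") "P" else "C",
                                     index))
}

#' Generate a phantom cohort
#'
#' Independent subjects with per-subject streams derived from the master
#' seed; patients take indices `1..n_patients` and controls continue the
#' numbering, so cohorts are reproducible bit-exactly for a fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @param n_patients,n_controls Subject counts (>= 1).
#' @return A list of [subject_stack()]s (patients first).
#' @examples
#' coh <- phantom_cohort(phantom_spec(image_size = 64, n_slices = 2), 3, 3)
#' length(coh)  # 6
#' @export
phantom_cohort <- function(spec, n_patients, n_controls) {
  stopifnot(n_patients >= 1L, n_controls >= 1L)
  c(lapply(seq_len(n_patients), function(i)
      phantom_subject(spec, "patient", i)),
    lapply(seq_len(n_controls), function(i)
      phantom_subject(spec, "control", n_patients + i)))
}

#' Write a cohort as PNG files plus manifest
#'
#' Writes each slice as an 8-bit grayscale PNG under
#' `dir/<subject_id>/slice_<i>.png` and a tab-separated manifest
#' (`manifest.tsv`) with columns `subject_id`, `label`, `path` — the same
#' shape real slice data enters the pipeline in.
#'
#' @param stacks List of [subject_stack()]s.
#' @param dir Output directory.
#' @return Path of the manifest, invisibly.
#' @export
write_cohort_png <- function(stacks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  for (st in stacks) {
    sdir <- file.path(dir, st$subject_id)
    if (!dir.exists(sdir)) dir.create(sdir)
    for (i in seq_along(st$slices)) {
      p <- file.path(sdir, sprintf("slice_%02d.png", i))
      save_slice(st$slices[[i]], p)
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = st$subject_id, label = st$label, path = p)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}
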