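# Synthetic brain phantom: an elliptical "brain" surrounded by a bright
# skull ring, mid-intensity tissue with Gaussian noise, and dark ventricles.
# Stands in for axial brain MR slices so every downstream stage is testable
# without any external dataset.

#' Specification of a synthetic brain phantom
#'
#' @param image_height_px,image_width_px Image dimensions in pixels.
#' @param brain_ellipse Numeric `c(center_row, center_col, semi_axis_r,
#'   semi_axis_c)` in pixels describing the inner-skull (brain) ellipse.
#' @param skull_thickness_px Thickness of the bright skull ring, pixels.
#' @param ventricle_ellipses List of ellipse parameter vectors (same layout
#'   as `brain_ellipse`) for the dark ventricles; each must lie strictly
#'   inside the brain ellipse.
#' @param tissue_mean_intensity Mean tissue intensity, 0-255.
#' @param noise_sigma Gaussian noise standard deviation in intensity units,
#'   `0 <= noise_sigma < 64`.
#' @param seed Integer seed for the noise substream.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(image_height_px = 64L, image_width_px = 64L,
                         brain_ellipse = NULL, skull_thickness_px = 3L,
                         ventricle_ellipses = NULL,
                         tissue_mean_intensity = 120, noise_sigma = 8,
                         seed = 0L) {
  h <- as.integer(image_height_px); w <- as.integer(image_width_px)
  if (is.na(h) || is.na(w) || h < 2L || w < 2L)
    stop("configuration error: image dimensions must be positive (>= 2 px)")
  if (is.null(brain_ellipse))
    brain_ellipse <- c(h / 2, w / 2, h * 0.42, w * 0.42)
  if (is.null(ventricle_ellipses)) {
    cr <- brain_ellipse[1]; cc <- brain_ellipse[2]
    a <- brain_ellipse[3]; b <- brain_ellipse[4]
    ventricle_ellipses <- list(
      c(cr - a * 0.10, cc - b * 0.22, a * 0.30, b * 0.13),
      c(cr - a * 0.10, cc + b * 0.22, a * 0.30, b * 0.13))
  }
  if (!(noise_sigma >= 0 && noise_sigma < 64))
    stop("configuration error: noise_sigma must lie in [0, 64)")
  if (tissue_mean_intensity < 0 || tissue_mean_intensity > 255)
    stop("configuration error: tissue_mean_intensity must lie in [0, 255]")
  spec <- structure(list(
    image_height_px = h, image_width_px = w,
    brain_ellipse = as.numeric(brain_ellipse),
    skull_thickness_px = as.integer(skull_thickness_px),
    ventricle_ellipses = lapply(ventricle_ellipses, as.numeric),
    tissue_mean_intensity = as.numeric(tissue_mean_intensity),
    noise_sigma = as.numeric(noise_sigma),
    seed = as.integer(seed)), class = "phantom_spec")
  .check_ventricles(spec)
  spec
}

# Normalized squared elliptical radius of every pixel: <= 1 inside.
.ellipse_norm <- function(h, w, ell) {
  r <- matrix(seq_len(h), nrow = h, ncol = w)
  c <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
  ((r - ell[1]) / ell[3])^2 + ((c - ell[2]) / ell[4])^2
}

.check_ventricles <- function(spec) {
  h <- spec$image_height_px; w <- spec$image_width_px
  brain <- .ellipse_norm(h, w, spec$brain_ellipse) <= 1
  for (v in spec$ventricle_ellipses) {
    vm <- .ellipse_norm(h, w, v) <= 1
    if (!any(vm) || any(vm & !brain))
      stop("configuration error: ventricle ellipse must lie strictly ",
           "inside the brain ellipse")
  }
  invisible(TRUE)
}

#' Render a brain phantom
#'
#' Deterministic for a fixed spec seed. The returned object carries the
#' pixel matrix together with the brain, ventricle and skull masks so lesion
#' geometry can be clipped against them.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom` object: list with integer matrix `pixels` (0-255),
#'   logical matrices `brain`, `ventricles`, `skull`, and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_height_px; w <- spec$image_width_px
  bn <- .ellipse_norm(h, w, spec$brain_ellipse)
  brain <- bn <= 1
  # skull ring: between the brain ellipse and the same ellipse grown by the
  # skull thickness (in units of the mean semi-axis)
  t_rel <- spec$skull_thickness_px / mean(spec$brain_ellipse[3:4])
  skull <- !brain & bn <= (1 + t_rel)^2
  vent <- matrix(FALSE, h, w)
  for (v in spec$ventricle_ellipses)
    vent <- vent | (.ellipse_norm(h, w, v) <= 1)
  vent <- vent & brain

  img <- matrix(20, h, w)                       # background
  img[brain] <- spec$tissue_mean_intensity      # tissue
  img[skull] <- 230                             # bright skull ring
  img[vent] <- spec$tissue_mean_intensity * 0.35  # dark CSF
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w))
    img <- img + noise
  }
  structure(list(pixels = quantize(img), brain = brain,
                 ventricles = vent, skull = skull, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %dx%d px, brain %d px, ventricles %d px>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$brain),
              sum(x$ventricles)))
  invisible(x)
}

# Accept either a phantom or a bare matrix wherever a grayscale image is
# consumed.
as_pixels <- function(x) {
  if (inherits(x, "phantom")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected a phantom or a 2D intensity matrix")
}
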