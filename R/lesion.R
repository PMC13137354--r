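# Subtype-specific hemorrhage lesion geometry, rendered onto a phantom.
#
# Geometries follow the radiological appearance of each compartment:
#   ICH  parenchymal blob (+ soft edema halo)
#   SDH  crescent hugging the inner skull over a limited angular wedge
#   EDH  biconvex lens: a disc centered on the skull boundary, clipped to brain
#   IVH  blob clipped to the ventricular system
#   SAH  thin diffuse rim along the whole brain boundary

IH_SUBTYPES <- c("ICH", "SDH", "EDH", "IVH", "SAH")

#' Specification of a hemorrhage lesion
#'
#' @param subtype One of `"ICH"`, `"SDH"`, `"EDH"`, `"IVH"`, `"SAH"`.
#' @param center Numeric `c(row, col)`; for SDH/EDH only the direction from
#'   the brain center matters, for IVH it must fall inside a ventricle.
#' @param base_radius_px Base lesion radius in pixels.
#' @param intensity_offset Signed intensity shift applied inside the mask
#'   (acute blood is hyperdense: positive).
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(subtype, center, base_radius_px = 8,
                        intensity_offset = 80) {
  subtype <- match.arg(subtype, IH_SUBTYPES)
  stopifnot(length(center) == 2, base_radius_px > 0)
  structure(list(subtype = subtype, center = as.numeric(center),
                 base_radius_px = as.numeric(base_radius_px),
                 intensity_offset = as.numeric(intensity_offset)),
            class = "lesion_spec")
}

# Rasterize the lesion mask at an arbitrary radius (used by the progression
# simulator to grow/shrink the same lesion).
lesion_mask <- function(phantom, lesion, radius = lesion$base_radius_px) {
  stopifnot(inherits(phantom, "phantom"), inherits(lesion, "lesion_spec"))
  h <- nrow(phantom$pixels); w <- ncol(phantom$pixels)
  ell <- phantom$spec$brain_ellipse
  a_mean <- mean(ell[3:4])
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  disc <- function(ctr, rad) (rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2
  nr <- sqrt(.ellipse_norm(h, w, ell))   # normalized elliptical radius

  m <- switch(lesion$subtype,
    ICH = disc(lesion$center, radius) & phantom$brain,
    IVH = disc(lesion$center, radius) & phantom$ventricles,
    EDH = {
      # disc centered on the inner-skull boundary point in the direction of
      # `center`; the brain clips it into a biconvex cap
      u <- (lesion$center[1] - ell[1]) / ell[3]
      v <- (lesion$center[2] - ell[2]) / ell[4]
      s <- sqrt(u^2 + v^2)
      if (s == 0) stop("EDH center must point away from the brain center")
      bpt <- c(ell[1] + ell[3] * u / s, ell[2] + ell[4] * v / s)
      disc(bpt, radius * 1.25) & phantom$brain
    },
    SDH = {
      # thin band just inside the skull, restricted to an angular wedge
      # around the direction of `center`
      th0 <- atan2(lesion$center[1] - ell[1], lesion$center[2] - ell[2])
      th <- atan2(rr - ell[1], cc - ell[2])
      dth <- abs(((th - th0 + pi) %% (2 * pi)) - pi)
      band <- radius * 0.45 / a_mean
      wedge <- 1.9 * radius / a_mean
      phantom$brain & nr >= (1 - band) & dth <= wedge
    },
    SAH = {
      # thin rim along the entire brain boundary
      band <- max(2, radius * 0.3) / a_mean
      phantom$brain & nr >= (1 - band)
    })
  m
}

#' Render a lesion onto a phantom
#'
#' Pixels inside the subtype-specific mask are shifted by the lesion's
#' intensity offset (clamped to the 8-bit range); ICH lesions additionally
#' get a soft perilesional edema halo at a third of the offset.
#'
#' @param base A `phantom` (from [generate_phantom()]).
#' @param lesion A [lesion_spec()].
#' @param radius,offset Optional overrides of the spec's base radius and
#'   intensity offset (used by the progression simulator).
#' @return A `phantom` whose `pixels` carry the lesion; the logical lesion
#'   mask is attached as element `lesion_mask`.
#' @export
render_lesion <- function(base, lesion, radius = NULL, offset = NULL) {
  stopifnot(inherits(base, "phantom"))
  radius <- radius %||% lesion$base_radius_px
  offset <- offset %||% lesion$intensity_offset
  m <- lesion_mask(base, lesion, radius)
  if (!any(m))
    stop(sprintf(
      "empty lesion mask for subtype %s: geometry constraint violated (%s)",
      lesion$subtype,
      switch(lesion$subtype,
             IVH = "lesion must intersect the ventricle mask",
             ICH = , EDH = "lesion must intersect the brain mask",
             "lesion band must intersect the brain boundary")))
  img <- as.numeric(base$pixels)
  dim(img) <- dim(base$pixels)
  if (lesion$subtype == "ICH") {
    halo <- lesion_mask(base, lesion_spec("ICH", lesion$center, 1,
                                          lesion$intensity_offset),
                        radius * 1.6) & !m
    img[halo] <- img[halo] + offset / 3
  }
  img[m] <- img[m] + offset
  out <- base
  out$pixels <- quantize(img)
  out$lesion_mask <- m
  out
}

#' Simulate temporal progression of a lesion
#'
#' Produces an `n_frames` sequence emulating hematoma expansion followed by
#' therapeutic resorption: the lesion radius is multiplied by the growth
#' factor for the transitions into frames 1 and 2 and by the shrink factor
#' afterwards, while the intensity offset decays after frame 2 (the acute
#' hyperdense clot fading towards hypodensity).
#'
#' @param base A `phantom`.
#' @param lesion A [lesion_spec()].
#' @param params A [progression_params()].
#' @return List of `n_frames` phantoms (frame 0 first), each with its
#'   `lesion_mask`.
#' @export
simulate_progression <- function(base, lesion, params) {
  stopifnot(inherits(params, "progression_params"))
  sched <- progression_schedule(lesion, params)
  frames <- vector("list", params$n_frames)
  brain_area <- sum(base$brain)
  for (t in seq_len(params$n_frames)) {
    fr <- render_lesion(base, lesion, radius = sched$radius[t],
                        offset = sched$offset[t])
    if (lesion$subtype == "ICH" &&
        sum(fr$lesion_mask) < 0.95 * pi * sched$radius[t]^2 &&
        sum(fr$lesion_mask) < brain_area)
      warning(sprintf("frame %d: grown lesion clipped to brain mask", t - 1L),
              call. = FALSE)
    frames[[t]] <- fr
  }
  frames
}

#' Temporal progression parameters
#'
#' @param n_frames Number of time points (default 5: Time 0 ... Time 4).
#' @param growth_factor_per_frame Radius multiplier per transition up to
#'   frame 2 (expansion phase), `> 1` for a growing hematoma.
#' @param shrink_factor_per_frame Radius multiplier per transition after
#'   frame 2 (resorption phase), `< 1` under effective therapy.
#' @param intensity_decay_per_frame Fraction of the intensity offset lost
#'   per frame after frame 2.
#' @param seed Integer substream seed.
#' @return A `progression_params` object.
#' @export
progression_params <- function(n_frames = 5L, growth_factor_per_frame = 1.3,
                               shrink_factor_per_frame = 0.7,
                               intensity_decay_per_frame = 0.3, seed = 0L) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L) stop("n_frames must be >= 2")
  if (!(growth_factor_per_frame >= 1)) stop("growth_factor must be >= 1")
  if (!(shrink_factor_per_frame > 0)) stop("shrink_factor must be > 0")
  if (intensity_decay_per_frame < 0 || intensity_decay_per_frame > 1)
    stop("intensity_decay_per_frame must lie in [0, 1]")
  structure(list(n_frames = n_frames,
                 growth_factor_per_frame = growth_factor_per_frame,
                 shrink_factor_per_frame = shrink_factor_per_frame,
                 intensity_decay_per_frame = intensity_decay_per_frame,
                 seed = as.integer(seed)), class = "progression_params")
}

# Radius and offset at every frame; pure arithmetic, shared by the simulator
# and the label-assignment rules.
progression_schedule <- function(lesion, params) {
  n <- params$n_frames
  radius <- numeric(n); offset <- numeric(n)
  radius[1] <- lesion$base_radius_px
  offset[1] <- lesion$intensity_offset
  for (t in 2:n) {
    f <- if ((t - 1) <= 2) params$growth_factor_per_frame
         else params$shrink_factor_per_frame
    radius[t] <- radius[t - 1] * f
    offset[t] <- if ((t - 1) > 2)
      offset[t - 1] * (1 - params$intensity_decay_per_frame)
    else offset[t - 1]
  }
  list(radius = radius, offset = offset)
}
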