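# Model-selection harness for the progression simulator, mirroring the
# brute-force configuration sweep: every candidate parameter set regenerates
# the sequence and the one with minimum mean squared error against the
# reference sequence wins (MSE averaged over time stamps and pixels).

#' Select progression parameters by minimum MSE against a reference
#'
#' @param candidates List of [progression_params()] (>= 2).
#' @param reference List of reference images (phantoms or matrices), one per
#'   frame; length must equal each candidate's `n_frames`.
#' @param base Phantom the candidate sequences are generated from.
#' @param lesion The [lesion_spec()] shared by all candidates.
#' @return List with `best_params`, `best_index`, and `mse_table` - a
#'   data.frame with one row per candidate (config label, MSE, SSIM, PSNR).
#'   Ties in MSE resolve to the first candidate in list order.
#' @export
select_model_by_mse <- function(candidates, reference, base, lesion) {
  if (length(candidates) < 1L) stop("candidate list must not be empty")
  ref <- lapply(reference, as_pixels)
  rows <- vector("list", length(candidates))
  mses <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    p <- candidates[[i]]
    if (p$n_frames != length(ref))
      stop("reference sequence length must match candidate n_frames")
    gen <- suppressWarnings(simulate_progression(base, lesion, p))
    se <- 0; ss <- 0; ps <- 0
    for (t in seq_along(ref)) {
      g <- as_pixels(gen[[t]])
      se <- se + mean((as.numeric(g) - as.numeric(ref[[t]]))^2)
      ss <- ss + ssim(ref[[t]], g)
      ps <- ps + min(psnr(ref[[t]], g), 99)   # cap keeps the mean finite
    }
    n_t <- length(ref)
    mses[i] <- se / n_t
    rows[[i]] <- data.frame(
      config = sprintf("growth=%.2f shrink=%.2f decay=%.2f",
                       p$growth_factor_per_frame, p$shrink_factor_per_frame,
                       p$intensity_decay_per_frame),
      mse = se / n_t, ssim = ss / n_t, psnr_db = ps / n_t,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  best <- which.min(mses)   # first index on ties
  list(best_params = candidates[[best]], best_index = best, mse_table = tab)
}

#' Assign sentiment and risk labels from the progression geometry
#'
#' Ground-truth rules operate on brute-force rasterized lesion areas:
#' prognosis is positive when the final-frame area has fallen below the
#' initial area, negative when it still exceeds the peak (frame 2) area,
#' neutral otherwise, and uncertain for a static lesion (no shrink, no
#' decay). Therapeutic sentiment reflects the resorption factor alone.
#'
#' @param lesion A [lesion_spec()].
#' @param params A [progression_params()].
#' @param phantom Phantom used to rasterize the masks (default: a standard
#'   64x64 phantom).
#' @return List with `prognosis_sentiment`, `therapeutic_sentiment`,
#'   `risk_level` and the per-frame `areas`.
#' @export
assign_labels <- function(lesion, params, phantom = NULL) {
  if (is.null(phantom)) phantom <- generate_phantom(phantom_spec())
  sched <- progression_schedule(lesion, params)
  areas <- vapply(sched$radius,
                  function(r) sum(lesion_mask(phantom, lesion, r)), 0)
  n <- params$n_frames
  i2 <- min(3L, n)                       # frame index 2 (1-based), peak
  static <- params$shrink_factor_per_frame == 1 &&
    params$intensity_decay_per_frame == 0
  prognosis <- if (static) "uncertain"
    else if (areas[n] < areas[1]) "positive"
    else if (areas[n] > areas[i2]) "negative"
    else "neutral"
  therapeutic <- if (params$shrink_factor_per_frame < 1) "positive"
    else if (params$shrink_factor_per_frame > 1) "negative"
    else if (params$intensity_decay_per_frame > 0) "neutral"
    else "uncertain"
  list(prognosis_sentiment = prognosis,
       therapeutic_sentiment = therapeutic,
       risk_level = risk_level(lesion$subtype),
       areas = areas)
}
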