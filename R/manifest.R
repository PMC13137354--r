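# Dataset manifest: per-split, per-subtype synthetic case records with
# deterministic labels, plus bookkeeping that mirrors a 10-images-per-case
# accounting (5 progression frames replicated by default).

#' Published per-split case counts
#'
#' The reference per-split, per-subtype case counts used for manifest
#' bookkeeping: 378 train / 73 validation / 75 test cases, 10 images per
#' case (5,260 images overall).
#' @return Named list of named integer vectors.
#' @export
table2_counts <- function() {
  list(train = c(ICH = 142L, SDH = 91L, EDH = 58L, IVH = 49L, Mixed = 38L),
       validation = c(ICH = 26L, SDH = 17L, EDH = 11L, IVH = 9L, Mixed = 10L),
       test = c(ICH = 28L, SDH = 18L, EDH = 12L, IVH = 10L, Mixed = 7L))
}

#' Balanced five-subtype benchmark counts
#'
#' The packaged classification benchmark: all five subtypes balanced within
#' each split (350 train / 75 validation / 100 test cases).
#' @return Named list of named integer vectors.
#' @export
benchmark_counts <- function() {
  subs <- c("ICH", "SDH", "EDH", "IVH", "SAH")
  list(train = stats::setNames(rep(70L, 5), subs),
       validation = stats::setNames(rep(15L, 5), subs),
       test = stats::setNames(rep(20L, 5), subs))
}

# The four progression regimes cycled across cases; together they realize
# all four prognosis/therapeutic sentiment classes.
.regimes <- list(
  improving = list(growth = 1.3, shrink = 0.7, decay = 0.3),
  worsening = list(growth = 1.3, shrink = 1.2, decay = 0.0),
  stable = list(growth = 1.0, shrink = 1.0, decay = 0.3),
  uncertain = list(growth = 1.0, shrink = 1.0, decay = 0.0))

.make_case <- function(case_id, subtype, split, regime, n_frames, seed) {
  s <- substream_seed(seed, paste0("case-", case_id))
  reg <- .regimes[[regime]]
  params <- progression_params(n_frames, reg$growth, reg$shrink, reg$decay,
                               seed = s)
  with_seed(s, {
    a <- 64 * 0.42
    pspec <- phantom_spec(
      64L, 64L,
      brain_ellipse = c(32, 32, a * stats::runif(1, 0.93, 1.03),
                        a * stats::runif(1, 0.93, 1.03)),
      tissue_mean_intensity = stats::runif(1, 110, 130),
      noise_sigma = 8, seed = s)
    ph <- generate_phantom(pspec)
    ell <- pspec$brain_ellipse
    theta <- stats::runif(1, 0, 2 * pi)
    boundary_dir <- c(ell[1] + ell[3] * sin(theta),
                      ell[2] + ell[4] * cos(theta))
    lesion <- switch(subtype,
      ICH = {
        r <- stats::runif(1, 0, 0.40); th <- stats::runif(1, 0, 2 * pi)
        lesion_spec("ICH", c(ell[1] + ell[3] * r * sin(th),
                             ell[2] + ell[4] * r * cos(th)),
                    stats::runif(1, 6, 9), stats::runif(1, 70, 95))
      },
      SDH = lesion_spec("SDH", boundary_dir, stats::runif(1, 6, 9),
                        stats::runif(1, 70, 95)),
      EDH = lesion_spec("EDH", boundary_dir, stats::runif(1, 5, 8),
                        stats::runif(1, 70, 95)),
      IVH = {
        vent <- which(ph$ventricles, arr.ind = TRUE)
        ctr <- vent[sample.int(nrow(vent), 1L), ]
        lesion_spec("IVH", as.numeric(ctr), stats::runif(1, 4, 7),
                    stats::runif(1, 70, 95))
      },
      SAH = lesion_spec("SAH", ell[1:2], stats::runif(1, 6, 9),
                        stats::runif(1, 50, 70)),
      Mixed = {
        pair <- sample(IH_SUBTYPES, 2L)
        lesion_spec(pair[1], if (pair[1] == "IVH") {
          vent <- which(ph$ventricles, arr.ind = TRUE)
          as.numeric(vent[sample.int(nrow(vent), 1L), ])
        } else if (pair[1] %in% c("SDH", "EDH")) boundary_dir
        else ell[1:2] + c(3, -3),
        stats::runif(1, 5, 8), stats::runif(1, 60, 90))
      })
    secondary <- if (subtype == "Mixed") {
      others <- setdiff(IH_SUBTYPES, lesion$subtype)
      s2 <- sample(others, 1L)
      lesion_spec(s2, if (s2 == "IVH") {
        vent <- which(ph$ventricles, arr.ind = TRUE)
        as.numeric(vent[sample.int(nrow(vent), 1L), ])
      } else if (s2 %in% c("SDH", "EDH")) boundary_dir
      else ell[1:2] + c(-4, 4),
      stats::runif(1, 4, 7), stats::runif(1, 50, 80))
    } else NULL
    lab <- assign_labels(lesion, params, ph)
    structure(list(case_id = case_id, subtype = subtype, split = split,
                   regime = regime, phantom_spec = pspec, lesion = lesion,
                   secondary_lesion = secondary, params = params,
                   prognosis_sentiment = lab$prognosis_sentiment,
                   therapeutic_sentiment = lab$therapeutic_sentiment,
                   risk_level = if (subtype == "Mixed")
                     risk_level(lesion$subtype) else lab$risk_level,
                   areas = lab$areas, seed = s),
              class = "case_record")
  })
}

#' Build a dataset manifest of synthetic cases
#'
#' Generates `counts[[split]][subtype]` case records per cell; every case
#' carries `frames_per_case` image slots (the `n_frames` progression frames
#' replicated cyclically when `frames_per_case > n_frames`). Image totals
#' always satisfy `images == cases * frames_per_case`. Case records hold
#' specs and labels; images and notes are rendered on demand by
#' [materialize_case()].
#'
#' @param counts Named list (split -> named non-negative integer vector per
#'   subtype). Default [table2_counts()].
#' @param frames_per_case Images per case (default 10).
#' @param n_frames Progression time points per case (default 5).
#' @param seed Integer run seed.
#' @return A `dataset_manifest`.
#' @export
build_manifest <- function(counts = table2_counts(), frames_per_case = 10L,
                           n_frames = 5L, seed = 0L) {
  frames_per_case <- as.integer(frames_per_case)
  if (frames_per_case < 1L) stop("frames_per_case must be >= 1")
  cases <- list()
  for (split in names(counts)) {
    cvec <- counts[[split]]
    if (any(cvec < 0)) stop("negative case count in split ", split)
    k <- 0L
    for (subtype in names(cvec)) {
      n <- cvec[[subtype]]
      if (n == 0L) next
      for (i in seq_len(n)) {
        k <- k + 1L
        regime <- names(.regimes)[(k - 1L) %% length(.regimes) + 1L]
        id <- sprintf("%s-%s-%03d", split, subtype, i)
        cases[[id]] <- .make_case(id, subtype, split, regime, n_frames, seed)
      }
    }
  }
  df <- do.call(rbind, lapply(names(counts), function(split) {
    cv <- counts[[split]]
    data.frame(split = split, subtype = names(cv),
               n_cases = as.integer(cv),
               n_images = as.integer(cv) * frames_per_case,
               stringsAsFactors = FALSE)
  }))
  structure(list(cases = cases, summary = df,
                 frames_per_case = frames_per_case,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "dataset_manifest")
}

#' Totals of a manifest
#' @param manifest A `dataset_manifest`.
#' @return List with `per_split` (data.frame of case and image totals) and
#'   grand totals `cases_total`, `images_total`.
#' @export
manifest_totals <- function(manifest) {
  agg <- stats::aggregate(cbind(n_cases, n_images) ~ split,
                          data = manifest$summary, FUN = sum)
  list(per_split = agg,
       cases_total = sum(manifest$summary$n_cases),
       images_total = sum(manifest$summary$n_images))
}

#' @export
print.dataset_manifest <- function(x, ...) {
  tt <- manifest_totals(x)
  cat(sprintf("<dataset_manifest: %d cases, %d images (%d per case)>\n",
              tt$cases_total, tt$images_total, x$frames_per_case))
  print(tt$per_split, row.names = FALSE)
  invisible(x)
}

#' Render the images and notes of one case
#'
#' @param case A `case_record` from [build_manifest()].
#' @param frames_per_case Images per case; the progression frames are
#'   replicated cyclically to this length.
#' @param seed Run seed used for the note substreams.
#' @param n_frames Number of progression time points.
#' @return The case with `frames` (list of `frames_per_case` phantoms),
#'   `progression` (the distinct time points) and `notes` (named list of
#'   four texts) filled in.
#' @export
materialize_case <- function(case, frames_per_case = 10L, seed = 0L,
                             n_frames = case$params$n_frames) {
  stopifnot(inherits(case, "case_record"))
  ph <- generate_phantom(case$phantom_spec)
  if (!is.null(case$secondary_lesion))
    ph <- render_lesion(ph, case$secondary_lesion)
  frames <- suppressWarnings(
    simulate_progression(ph, case$lesion, case$params))
  idx <- if (frames_per_case %% n_frames == 0L)
    rep(seq_len(n_frames), each = frames_per_case %/% n_frames)
  else rep_len(seq_len(n_frames), frames_per_case)
  case$progression <- frames
  case$frames <- frames[idx]
  case$notes <- stats::setNames(
    lapply(NOTE_KINDS, function(k) generate_clinical_note(case, k, seed)),
    NOTE_KINDS)
  case
}

#' Write a manifest to disk
#'
#' Emits `manifest.json` (splits -> subtype -> case ids, plus totals) and a
#' flat `index.csv` with one row per image slot.
#'
#' @param manifest A `dataset_manifest`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  splits <- split(manifest$cases,
                  vapply(manifest$cases, `[[`, "", "split"))
  js <- list(
    frames_per_case = manifest$frames_per_case,
    totals = manifest_totals(manifest)[c("cases_total", "images_total")],
    splits = lapply(splits, function(cs) {
      sub <- split(names(cs), vapply(cs, `[[`, "", "subtype"))
      lapply(sub, as.list)
    }))
  jpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(js, jpath, auto_unbox = TRUE, pretty = TRUE)
  rows <- do.call(rbind, lapply(manifest$cases, function(cs) {
    data.frame(case_id = cs$case_id, split = cs$split, subtype = cs$subtype,
               frame_idx = seq_len(manifest$frames_per_case) - 1L,
               path = sprintf("images/%s_f%02d.png", cs$case_id,
                              seq_len(manifest$frames_per_case) - 1L),
               prognosis_sentiment = cs$prognosis_sentiment,
               therapeutic_sentiment = cs$therapeutic_sentiment,
               risk_level = cs$risk_level, stringsAsFactors = FALSE)
  }))
  cpath <- file.path(dir, "index.csv")
  utils::write.csv(rows, cpath, row.names = FALSE)
  invisible(c(jpath, cpath))
}
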