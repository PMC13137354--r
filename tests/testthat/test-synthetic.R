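# Phantom, lesion geometry, temporal progression and manifest bookkeeping.

test_that("phantom rendering is deterministic and respects the spec", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0,
                                      tissue_mean_intensity = 120))
  inside <- ph$brain & !ph$ventricles
  expect_true(all(ph$pixels[inside] == 120L))
  expect_true(all(ph$pixels[ph$skull] > ph$pixels[inside][1]))
  expect_true(all(ph$pixels[ph$ventricles] < 120L))

  a <- generate_phantom(phantom_spec(noise_sigma = 10, seed = 3L))
  b <- generate_phantom(phantom_spec(noise_sigma = 10, seed = 3L))
  expect_identical(a$pixels, b$pixels)

  expect_error(phantom_spec(image_height_px = 0), "configuration error")
  expect_error(
    phantom_spec(ventricle_ellipses = list(c(2, 2, 5, 5))),
    "configuration error")
  expect_error(phantom_spec(noise_sigma = 64), "noise_sigma")
})

test_that("lesion rendering matches subtype geometry constraints", {
  ph <- fixture_phantom()
  # identity at zero offset
  les0 <- lesion_spec("ICH", c(32, 32), 8, 0)
  expect_identical(render_lesion(ph, les0)$pixels, ph$pixels)

  # rasterized ICH disc area bracketed by the brute-force oracle
  les <- lesion_spec("ICH", c(32, 32), 8, 80)
  fr <- render_lesion(ph, les)
  area <- sum(fr$lesion_mask)
  expect_equal(area, oracle_disc_area(64, 64, c(32, 32), 8))
  expect_gte(area, pi * 49)
  expect_lte(area, pi * 81)

  # masks stay inside their compartments
  for (sub in c("SDH", "EDH", "SAH")) {
    m <- render_lesion(ph, lesion_spec(sub, c(10, 32), 7, 60))$lesion_mask
    expect_gt(sum(m), 0)
    expect_true(all(ph$brain[m]))
  }
  mi <- render_lesion(ph, lesion_spec("IVH", c(25, 24), 5, 60))$lesion_mask
  expect_true(all(ph$ventricles[mi]))
  # SDH/EDH touch the inner skull boundary (max normalized radius ~ 1)
  for (sub in c("SDH", "EDH")) {
    m <- render_lesion(ph, lesion_spec(sub, c(10, 32), 7, 60))$lesion_mask
    nr <- sqrt(hemofuse:::.ellipse_norm(64, 64, ph$spec$brain_ellipse))
    expect_gt(max(nr[m]), 0.93)
  }
  expect_error(render_lesion(ph, lesion_spec("IVH", c(2, 2), 3, 50)),
               "ventricle")
})

test_that("progression is a fixed point for neutral parameters and unimodal
           under growth then shrink", {
  ph <- fixture_phantom()
  les <- lesion_spec("ICH", c(32, 32), 8, 80)
  fixed <- simulate_progression(ph, les, progression_params(
    growth_factor_per_frame = 1, shrink_factor_per_frame = 1,
    intensity_decay_per_frame = 0))
  for (fr in fixed[-1])
    expect_identical(fr$pixels, fixed[[1]]$pixels)

  frames <- simulate_progression(ph, les, progression_params(
    growth_factor_per_frame = 1.3, shrink_factor_per_frame = 0.7))
  areas <- vapply(frames, function(f) sum(f$lesion_mask), 0)
  expect_true(all(diff(areas[1:3]) > 0))
  expect_true(all(diff(areas[3:5]) < 0))
  # MSE against frame 0 grows during expansion
  mse <- vapply(frames, function(f)
    mean((as.numeric(f$pixels) - as.numeric(frames[[1]]$pixels))^2), 0)
  expect_gt(mse[3], mse[2])
})

test_that("progression model selection minimizes frame-averaged MSE with a
           first-wins tie rule", {
  ph <- fixture_phantom()
  les <- lesion_spec("ICH", c(32, 32), 8, 80)
  good <- progression_params(growth_factor_per_frame = 1.3,
                             shrink_factor_per_frame = 0.7)
  bad <- progression_params(growth_factor_per_frame = 1.6,
                            shrink_factor_per_frame = 1.2,
                            intensity_decay_per_frame = 0)
  reference <- simulate_progression(ph, les, good)
  sel <- select_model_by_mse(list(bad, good), reference, ph, les)
  expect_equal(sel$best_index, 2L)
  expect_equal(sel$mse_table$mse[2], 0)
  # hand-recomputed MSE for the losing candidate
  gen <- simulate_progression(ph, les, bad)
  hand <- mean(vapply(seq_along(gen), function(t)
    mean((as.numeric(gen[[t]]$pixels) -
            as.numeric(reference[[t]]$pixels))^2), 0))
  expect_equal(sel$mse_table$mse[1], hand, tolerance = 1e-12)
  # exact tie resolves to the first candidate
  tie <- select_model_by_mse(list(good, good), reference, ph, les)
  expect_equal(tie$best_index, 1L)
  expect_error(select_model_by_mse(list(), reference, ph, les), "empty")
})

test_that("label assignment follows the area rules and the risk map", {
  ph <- fixture_phantom()
  les <- lesion_spec("ICH", c(32, 32), 8, 80)
  lab <- assign_labels(les, progression_params(
    growth_factor_per_frame = 1.2, shrink_factor_per_frame = 0.6), ph)
  expect_equal(lab$prognosis_sentiment, "positive")
  expect_equal(lab$therapeutic_sentiment, "positive")
  expect_equal(lab$risk_level, "High")
  expect_equal(assign_labels(lesion_spec("EDH", c(10, 32), 6, 60),
                             progression_params(), ph)$risk_level, "Low")
  static <- assign_labels(les, progression_params(
    growth_factor_per_frame = 1, shrink_factor_per_frame = 1,
    intensity_decay_per_frame = 0), ph)
  expect_equal(static$prognosis_sentiment, "uncertain")
  worsening <- assign_labels(les, progression_params(
    growth_factor_per_frame = 1.3, shrink_factor_per_frame = 1.2,
    intensity_decay_per_frame = 0), ph)
  expect_equal(worsening$prognosis_sentiment, "negative")
  expect_equal(worsening$therapeutic_sentiment, "negative")
})

test_that("clinical notes are deterministic, sized, and lexicon-consistent", {
  m <- build_manifest(list(train = c(ICH = 1L, IVH = 1L)), 10L, seed = 5L)
  pos_case <- Filter(function(cs) cs$prognosis_sentiment == "positive",
                     m$cases)[[1]]
  for (kind in c("consultation", "progression", "procedural", "radiology")) {
    note <- generate_clinical_note(pos_case, kind, 5L)
    expect_identical(note, generate_clinical_note(pos_case, kind, 5L))
    n_words <- length(strsplit(note, "\\s+")[[1]])
    expect_gte(n_words, 400); expect_lte(n_words, 900)
    expect_match(note, "intracerebral hemorrhage|intraventricular hemorrhage")
    expect_gt(lexicon_sentiment(note)$pos_count, 0)
  }
  expect_error(generate_clinical_note(pos_case, "operative", 1L),
               "consultation")

  neg <- build_manifest(list(train = c(SDH = 4L)), 10L, seed = 5L)
  neg_case <- Filter(function(cs) cs$therapeutic_sentiment == "negative",
                     neg$cases)[[1]]
  note <- generate_clinical_note(neg_case, "progression", 5L)
  expect_gt(lexicon_sentiment(note)$neg_count, 0)
})

test_that("manifest bookkeeping conserves cases and images", {
  m0 <- build_manifest(list(train = c(ICH = 0L)), 10L)
  expect_equal(manifest_totals(m0)$images_total, 0)

  m1 <- build_manifest(list(train = c(SAH = 1L)), 10L, seed = 2L)
  mc <- materialize_case(m1$cases[[1]], 10L, 2L)
  expect_length(mc$frames, 10L)
  expect_named(mc$notes,
               c("consultation", "progression", "procedural", "radiology"))
  # replicated frames repeat the five distinct time points
  expect_identical(as_pixels(mc$frames[[1]]), as_pixels(mc$frames[[2]]))
  expect_identical(as_pixels(mc$frames[[9]]),
                   as_pixels(mc$progression[[5]]))

  m <- build_manifest(list(train = c(ICH = 3L, SDH = 2L),
                           validation = c(EDH = 2L),
                           test = c(IVH = 1L, SAH = 1L)), 7L, seed = 1L)
  tt <- manifest_totals(m)
  expect_equal(tt$cases_total, 9L)
  expect_equal(tt$images_total, 9L * 7L)
  for (i in seq_len(nrow(tt$per_split)))
    expect_equal(tt$per_split$n_images[i], tt$per_split$n_cases[i] * 7L)
  expect_error(build_manifest(list(train = c(ICH = -1L))), "negative")

  # label determinism across rebuilds
  m2 <- build_manifest(list(train = c(ICH = 3L, SDH = 2L),
                            validation = c(EDH = 2L),
                            test = c(IVH = 1L, SAH = 1L)), 7L, seed = 1L)
  expect_identical(lapply(m$cases, `[[`, "prognosis_sentiment"),
                   lapply(m2$cases, `[[`, "prognosis_sentiment"))
})

test_that("manifest serialization emits a consistent index", {
  m <- build_manifest(list(train = c(ICH = 2L), test = c(SDH = 1L)), 10L,
                      seed = 4L)
  dir <- withr::local_tempdir()
  paths <- write_manifest(m, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(js$totals$images_total, 30L)
  idx <- read.csv(file.path(dir, "index.csv"))
  expect_equal(nrow(idx), 30L)
  expect_equal(sort(unique(idx$case_id)), sort(names(m$cases)))
})
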