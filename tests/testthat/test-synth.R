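test_that("scenes are deterministic for a fixed seed and leave the RNG alone", {
  spec <- scene_spec(objects = c(PMN = 3, NET = 1), seed = 123)
  a <- render_scene(spec)
  set.seed(999)
  before <- .Random.seed
  b <- render_scene(spec)
  expect_identical(.Random.seed, before)
  expect_identical(a$total$pixels, b$total$pixels)
  expect_identical(a$extra$pixels, b$extra$pixels)
  expect_identical(dplyr::select(a$truth, -"pixels"),
                   dplyr::select(b$truth, -"pixels"))
})

test_that("ground truth matches the requested object counts exactly", {
  spec <- scene_spec(objects = c(PMN = 5, RND = 2, NET = 1), seed = 5)
  sc <- render_scene(spec)
  counts <- attr(sc$truth, "counts")
  expect_equal(counts[["PMN"]], 5L)
  expect_equal(counts[["RND"]], 2L)
  expect_equal(counts[["NET"]], 1L)
  expect_equal(nrow(sc$truth), 8L)
  expect_equal(attr(sc$truth, "net_area"),
               sum(sc$truth$area[sc$truth$label == "NET"]))
})

test_that("a PMN-only scene has a pure-background extracellular channel", {
  sc <- render_scene(scene_spec(objects = c(PMN = 5), seed = 9))
  expect_equal(attr(sc$truth, "counts")[["PMN"]], 5L)
  # background 100 + noise sd 5: nothing near the segmentation threshold
  expect_lt(max(sc$extra$pixels), 150)
})

test_that("rendered objects express their generating feature distributions", {
  specs <- class_generation_specs()
  fails <- 0L; n_objects <- 0L
  for (seed in 1:8) {
    sc <- render_scene(scene_spec(
      objects = c(PMN = 2, RND = 2, RUP = 2, PER = 2, NET = 1), seed = seed))
    for (i in seq_len(nrow(sc$truth))) {
      row <- sc$truth[i, ]
      sp <- specs[specs$class == row$label, ]
      px <- row$pixels[[1]]
      n_objects <- n_objects + 1L
      if (row$label %in% c("PMN", "RND", "RUP", "PER")) {
        mt <- mean(sc$total$pixels[px])
        ok <- mt >= sp$mean_total_lo - 100 && mt <= sp$mean_total_hi + 100
        if (row$label == "PER") {
          me <- mean(sc$extra$pixels[px])
          ok <- ok && me >= sp$mean_extra_lo - 100 && me <= sp$mean_extra_hi + 100
        }
        fails <- fails + !ok
      }
      if (row$label == "NET") {
        ev <- sc$extra$pixels[px]
        fails <- fails + !(sd(ev) >= 150 && mean(ev) >= 400 &&
                             mean(ev) <= 2000)
      }
    }
  }
  expect_equal(fails, 0L)
  expect_gt(n_objects, 50)
})

test_that("NET regions are more heterogeneous than artifact patches", {
  sds <- list(NET = numeric(0), EXTRA_ARTIFACT = numeric(0))
  for (seed in 1:6) {
    sc <- render_scene(scene_spec(objects = c(NET = 1, EXTRA_ARTIFACT = 2),
                                  seed = seed))
    for (i in seq_len(nrow(sc$truth))) {
      lbl <- sc$truth$label[i]
      sds[[lbl]] <- c(sds[[lbl]], sd(sc$extra$pixels[sc$truth$pixels[[i]]]))
    }
  }
  expect_gt(min(sds$NET), max(sds$EXTRA_ARTIFACT))
})

test_that("overcrowded non-overlapping scenes fail with a placement error", {
  expect_error(
    render_scene(scene_spec(width = 64, height = 64,
                            objects = c(NET = 8), seed = 1)),
    "placement"
  )
})

test_that("fixture emission writes TIFFs, XMLs, truth CSV and a config", {
  dir <- withr::local_tempdir()
  fx <- emit_fixture_set("uneven_background", dir, n_images = 3, seed = 11)
  expect_length(fx$images, 3)
  expect_true(all(file.exists(fx$images)))
  expect_true(all(file.exists(fx$annotations)))
  expect_true(file.exists(fx$truth_csv))
  expect_true(file.exists(fx$config))

  # every truth file of the uneven-background preset holds smooth patches
  for (xml in fx$annotations) {
    ann <- read_voc_annotations(xml)
    expect_gte(sum(ann$label == "EXTRA_ARTIFACT"), 1)
  }

  # the TIFF round-trips into the scene rasters (16-bit quantization)
  preset <- netquant:::fixture_presets()$uneven_background
  sc <- render_scene(scene_spec(
    objects = preset$objects,
    background_gradient = preset$background_gradient, seed = 11))
  chans <- read_two_channel_tiff(fx$images[1])
  expect_equal(chans$total_dna$pixels, round(sc$total$pixels),
               tolerance = 1.01, ignore_attr = TRUE)
  expect_equal(dim(chans$extracellular_dna$pixels), dim(sc$extra$pixels))

  cfg <- read_config(fx$config)
  expect_s3_class(cfg, "netquant_config")
  expect_error(emit_fixture_set("no_such_preset", dir), "usage")
})
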