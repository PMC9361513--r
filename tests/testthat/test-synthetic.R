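# The synthetic drawing generator: rendering contracts, anomaly injection,
# the severity-score link, and cohort generation.

test_that("base drawings are deterministic, bounded and task-specific", {
  img <- make_base_drawing("clock", 128, rng_seed = 1)
  expect_true(is.matrix(img) && all(dim(img) == c(128, 128)))
  expect_true(all(img >= 0 & img <= 1))
  expect_gt(sum(img < 0.5), 0)            # nonempty ink
  expect_identical(img, make_base_drawing("clock", 128, rng_seed = 1))
  cube1 <- make_base_drawing("cube", 64, rng_seed = 1)
  expect_identical(cube1, make_base_drawing("cube", 64, rng_seed = 1))
  expect_false(identical(cube1, make_base_drawing("cube", 64, rng_seed = 2)))
  expect_error(make_base_drawing("maze", 128), "clock, cube, trail")
  expect_error(make_base_drawing("clock", 32), "canvas_size")
})

test_that("trail drawings contain the configured number of node blobs", {
  img <- make_base_drawing("trail", 64, rng_seed = 2)
  nodes <- attr(img, "layers")$node
  expect_equal(flood_count(nodes), 8)
  img5 <- make_base_drawing("trail", 96,
                            stroke_params = list(n_trail_nodes = 5),
                            rng_seed = 3)
  expect_equal(flood_count(attr(img5, "layers")$node), 5)
})

test_that("anomaly injection honors the severity contract", {
  img <- make_base_drawing("cube", 96, rng_seed = 4)
  out0 <- inject_anomalies(img, "cube", 0, rng_seed = 1)
  expect_identical(out0$image, img)
  expect_equal(sum(out0$mask), 0)
  expect_length(out0$applied_specs, 0)

  out1 <- inject_anomalies(img, "cube", 1, rng_seed = 1)
  expect_gt(sum(out1$mask), 0)
  expect_true(all(dim(out1$mask) == dim(img)))
  for (sp in out1$applied_specs) {
    expect_true(sp$severity_weight >= 0)
    expect_true(all(sp$location >= 1) &&
                  all(sp$location <= nrow(img)))
  }
  expect_identical(out1$image,
                   inject_anomalies(img, "cube", 1, rng_seed = 1)$image)
  expect_error(inject_anomalies(img, "cube", 1.5), "severity")
})

test_that("expected anomaly area grows with severity", {
  imgs <- lapply(c(clock = "clock", trail = "trail"), function(task)
    make_base_drawing(task, 64, rng_seed = 5))
  areas <- function(sev) {
    a <- 0
    for (task in names(imgs))
      for (k in 1:100)
        a <- a + sum(inject_anomalies(imgs[[task]], task, sev,
                                      rng_seed = 1000 * sev + k)$mask)
    a / 200
  }
  expect_gt(areas(0.8), areas(0.2))
})

test_that("severity maps to MoCA-like scores as a clipped linear rule", {
  expect_identical(severity_to_moca(0, 0), 30L)
  expect_identical(severity_to_moca(1, 0), 18L)
  s05 <- severity_to_moca(0.5, 0)
  expect_identical(s05, 24L)
  expect_lt(s05, 25)                      # below the MCI cutoff
  sev <- seq(0, 1, by = 0.05)
  noiseless <- severity_to_moca(sev, 0)
  expect_true(all(diff(noiseless) <= 0))  # nonincreasing step function
  expect_true(all(noiseless >= 0 & noiseless <= 30))
  expect_identical(severity_to_moca(sev, 1, rng_seed = 9),
                   severity_to_moca(sev, 1, rng_seed = 9))
  expect_error(severity_to_moca(1.2, 0), "severity")
  expect_error(severity_to_moca(0.5, -1), "noise_sd")
})

test_that("severity distribution controls the class balance", {
  n <- 1000
  sev <- withr::with_seed(31, runif(n))
  scores <- severity_to_moca(sev, 1, rng_seed = 32)
  # expected MCI fraction: P(round(30 - 12 s + e) < 25) integrated over s
  grid <- seq(0, 1, length.out = 2001)
  p_mci <- mean(pnorm((12 * grid - 5.5) / 1))
  se <- sqrt(p_mci * (1 - p_mci) / n)
  expect_lt(abs(mean(scores < 25) - p_mci), 3 * se + 0.02)
})

test_that("generate_cohort writes a complete, reproducible cohort", {
  d1 <- file.path(tempdir(), "cohA")
  d2 <- file.path(tempdir(), "cohB")
  m1 <- generate_cohort(10, stats::runif, d1, rng_seed = 21,
                        canvas_size = 64)
  m2 <- generate_cohort(10, stats::runif, d2, rng_seed = 21,
                        canvas_size = 64)
  expect_equal(nrow(m1), 10)
  expect_length(list.files(d1, pattern = "_mask\\.png$"), 30)
  expect_length(list.files(d1, pattern = "\\.png$"), 60)
  expect_identical(readBin(file.path(d1, "manifest.csv"), "raw", 1e6),
                   readBin(file.path(d2, "manifest.csv"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "S0003_cube.png"), "raw", 1e6),
                   readBin(file.path(d2, "S0003_cube.png"), "raw", 1e6))
})

test_that("a zero-severity cohort is uniformly healthy with empty masks", {
  d <- cohort_dir(n = 4, seed = 3, canvas = 64, noise_sd = 0,
                  severities = 0)
  man <- read.csv(file.path(d, "manifest.csv"))
  expect_true(all(man$moca_score == 30))
  expect_true(all(hard_label(man$moca_score) == 0))
  mask <- png::readPNG(file.path(d, man$clock_mask_path[1]))
  expect_equal(sum(mask), 0)
})
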