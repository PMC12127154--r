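test_that("beat templates enforce ordering and positive widths", {
  expect_s3_class(beat_template(), "beat_template")
  expect_error(beat_template(widths = c(0.02, -0.01, 0.01, 0.01, 0.05)),
               "positive")
  expect_error(beat_template(centers = c(0.3, 0.2, 0.22, 0.24, 0.45)),
               "increasing")
})

test_that("render_beat matches its closed-form description", {
  ## all amplitudes zero -> all-zero vector
  z <- render_beat(beat_template(amplitudes = rep(0, 5)), fs = 100,
                   duration = 1)
  expect_identical(z, rep(0, 100))
  ## a single Gaussian peaks at its center sample
  tm <- beat_template(amplitudes = c(0, 0, 1, 0, 0),
                      centers = c(0.05, 0.1, 0.25, 0.4, 0.6),
                      widths = c(0.02, 0.01, 0.02, 0.01, 0.05))
  s <- render_beat(tm, fs = 200, duration = 1)
  expect_length(s, 200L)
  expect_equal(which.max(s) - 1L, round(0.25 * 200))
  ## numeric integral vs closed form sum_w a_w sigma_w sqrt(2 pi), within 1%
  tm2 <- beat_template()
  fs <- 500
  s2 <- render_beat(tm2, fs = fs, duration = 2)
  num <- sum(s2) / fs
  closed <- sum(tm2$amplitudes * tm2$widths * sqrt(2 * pi))
  expect_lt(abs(num - closed) / abs(closed), 0.01)
  expect_error(render_beat(tm2, fs = 100, duration = 0.2), "cover")
})

test_that("the no-confounder limit is the clean projected beat train", {
  cfg <- tiny_synth_config()
  r1 <- render_record(1, confounder_intensity = 0, cfg, seed = 99)
  r2 <- render_record(1, confounder_intensity = 0, cfg, seed = 99)
  expect_identical(r1$signals, r2$signals)      # bitwise reproducible
  ## each lead is an exact scalar multiple of the beat train
  base <- r1$signals[1, ] / cfg$lead_projection[1]
  for (i in 2:4)
    expect_equal(r1$signals[i, ], cfg$lead_projection[i] * base,
                 tolerance = 1e-12)
  expect_equal(r1$labels, c(1, 0, 0, 0))
})

test_that("beat tiling count and RR statistics match the rhythm spec", {
  ## rr_cv = 0, rr_mean = 0.8 s, 10 s -> floor(10 / 0.8) +- 1 R peaks
  specs <- list(class_spec(1, rr_mean = 0.8, rr_cv = 0),
                class_spec(2, rr_mean = 0.8, rr_cv = 0))
  cfg <- synth_config(n_leads = 2, class_specs = specs, duration = 10,
                      fs = 100, lead_projection = c(1, 1),
                      confounder = confounder_spec(noise_sd_max = 0))
  rec <- render_record(1, 0, cfg, seed = 1)
  peaks <- collapse_peaks(find_r_peaks(rec$signals[1, ]))
  expect_lte(abs(length(peaks) - floor(10 / 0.8)), 1)
  ## empirical mean RR within 2% of rr_mean at rr_cv = 0.1 over >= 200 beats
  specs2 <- list(class_spec(1, rr_mean = 0.8, rr_cv = 0.1),
                 class_spec(2, rr_mean = 0.8, rr_cv = 0.1))
  cfg2 <- synth_config(n_leads = 2, class_specs = specs2, duration = 200,
                       fs = 100, lead_projection = c(1, 1))
  rec2 <- render_record(1, 0, cfg2, seed = 5)
  peaks2 <- collapse_peaks(find_r_peaks(rec2$signals[1, ]))
  expect_gt(length(peaks2), 200)
  rr <- diff(peaks2) / 100
  expect_lt(abs(mean(rr) - 0.8) / 0.8, 0.02)
})

test_that("label-confounder coupling hits its stated endpoints", {
  z <- rep(c(0, 1), each = 500)
  u <- runif(1000)
  ## rho = 1: intensity is the indicator itself
  expect_identical(causalecg:::couple_intensity(z, 1, u), z)
  ## rho = -1: flipped
  expect_identical(causalecg:::couple_intensity(z, -1, u), 1 - z)
  ## rho = 0: exactly the uniform draws
  expect_identical(causalecg:::couple_intensity(z, 0, u), u)
  ## always inside [0, 1]
  for (rho in c(-0.7, 0.3, 0.9)) {
    i <- causalecg:::couple_intensity(z, rho, u)
    expect_true(all(i >= 0 & i <= 1))
  }
})

test_that("generated datasets control the label-confounder correlation", {
  cfg <- tiny_synth_config()
  ## rho = 0: empirical point-biserial correlation within +-0.1 of 0
  ds0 <- generate_dataset(cfg, n = 500, rho = 0, seed = 21)
  z0 <- as.numeric(ds0$class_ids == cfg$confounded_class)
  expect_lt(abs(cor(ds0$intensities, z0)), 0.1)
  ## rho = 1: deterministic 0/1 intensity
  ds1 <- generate_dataset(cfg, n = 60, rho = 1, seed = 22)
  z1 <- as.numeric(ds1$class_ids == cfg$confounded_class)
  expect_identical(ds1$intensities, z1)
  ## strong rho yields strong positive empirical correlation
  ds8 <- generate_dataset(cfg, n = 500, rho = 0.8, seed = 23)
  z8 <- as.numeric(ds8$class_ids == cfg$confounded_class)
  expect_gt(cor(ds8$intensities, z8), 0.6)
  expect_error(generate_dataset(cfg, n = 10, rho = 1.5, seed = 1),
               "rho")
})

test_that("class draws are uniform within exact multinomial bounds", {
  cfg <- tiny_synth_config()
  ds <- generate_dataset(cfg, n = 500, rho = 0, seed = 33)
  counts <- tabulate(ds$class_ids, nbins = 4)
  ## binomial(500, 1/4) 99% central bounds
  lo <- qbinom(0.005, 500, 0.25); hi <- qbinom(0.995, 500, 0.25)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("datasets are fully deterministic under the seed", {
  cfg <- tiny_synth_config()
  a <- generate_dataset(cfg, n = 12, rho = 0.5, seed = 77)
  b <- generate_dataset(cfg, n = 12, rho = 0.5, seed = 77)
  for (i in seq_len(12))
    expect_identical(a$records[[i]]$signals, b$records[[i]]$signals)
  expect_identical(a$intensities, b$intensities)
  c <- generate_dataset(cfg, n = 12, rho = 0.5, seed = 78)
  expect_false(identical(a$records[[1]]$signals, c$records[[1]]$signals))
})

test_that("class-discriminative signal survives maximal confounding", {
  cfg <- tiny_synth_config()
  ## clean class templates (intensity 0) differ pairwise in L2 norm
  clean <- lapply(1:4, function(k)
    render_record(k, 0, cfg, seed = 1000 + k)$signals)
  for (i in 1:3) for (j in (i + 1):4)
    expect_gt(sqrt(sum((clean[[i]] - clean[[j]])^2)), 0)
})
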