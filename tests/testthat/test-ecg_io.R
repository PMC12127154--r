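test_that("ecg_record validates shape, finiteness and labels", {
  expect_s3_class(ecg_record(matrix(0, 2, 5), fs = 100), "ecg_record")
  expect_error(ecg_record(matrix(0, 1, 5), fs = 100), "2 leads")
  m <- matrix(rnorm(10), 2, 5)
  m[2, 3] <- NaN
  expect_error(ecg_record(m, fs = 100), "lead 2, sample 3")
  m[2, 3] <- Inf
  expect_error(ecg_record(m, fs = 100), "non-finite")
  expect_error(ecg_record(matrix(0, 2, 5), fs = 100, labels = c(0, 2)), "0/1")
  rec <- ecg_record(matrix(0, 12, 4), fs = 100)
  expect_equal(rec$lead_names[1:3], c("I", "II", "III"))
})

test_that("a 12-lead 10 s recording at 100 Hz has shape 12 x 1000", {
  ds <- generate_dataset(synth_config(), n = 4, rho = 0, seed = 7)
  expect_identical(dim(ds$records[[1]]$signals), c(12L, 1000L))
  expect_equal(ds$records[[1]]$fs, 100)
})

test_that("CSV round-trip preserves signals to full numeric precision", {
  ds <- generate_dataset(tiny_synth_config(), n = 4, rho = 0.5, seed = 3)
  rec <- ds$records[[1]]
  path <- tempfile(fileext = ".csv")
  write_record_csv(rec, path)
  back <- load_record(path, format = "csv", fs = rec$fs)
  expect_equal(back$signals, rec$signals, tolerance = 1e-12)
  expect_equal(back$lead_names, rec$lead_names)
  ## zero case: all-zero 2-lead, 5-sample record
  z <- ecg_record(matrix(0, 2, 5), fs = 10)
  pz <- tempfile(fileext = ".csv")
  write_record_csv(z, pz)
  expect_equal(load_record(pz, format = "csv", fs = 10)$signals,
               matrix(0, 2, 5))
})

test_that("CSV reader reports bad cells and missing files", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "x,4"), p)
  expect_error(read_record_csv(p), "non-numeric")
  expect_error(read_record_csv(tempfile()), "no such file")
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "NaN,4"), p2)
  expect_error(read_record_csv(p2), "non-finite sample at row 2, column 1")
})

test_that("npy round-trip and npz reading work for 2-D arrays", {
  m <- matrix(rnorm(60), 4, 15)
  p <- tempfile(fileext = ".npy")
  write_npy(m, p)
  expect_equal(read_npy(p), m, tolerance = 0)
  v <- rnorm(7)
  pv <- tempfile(fileext = ".npy")
  write_npy(v, pv)
  expect_equal(read_npy(pv), v, tolerance = 0)
  rec <- load_record(p, format = "npy", fs = 50)
  expect_identical(dim(rec$signals), c(4L, 15L))
  ## npz written by python-style zip: emulate with R utils::zip if available,
  ## else construct via the package writer + minimal stored zip through python
  skip_if_not(nzchar(Sys.which("python")), "python unavailable for npz fixture")
  pz <- tempfile(fileext = ".npz")
  code <- sprintf(
    "import numpy as np; np.savez('%s', signals=np.arange(8.).reshape(2,4), fs=np.array(100.), labels=np.array([1.,0.]))",
    pz)
  system2("python", c("-c", shQuote(code)))
  rec2 <- read_npz_record(pz)
  expect_equal(rec2$signals, matrix(0:7, 2, 4, byrow = TRUE))
  expect_equal(rec2$fs, 100)
  expect_equal(rec2$labels, c(1, 0))
})

test_that("WFDB format-16 pairs round-trip within ADC quantization", {
  ds <- generate_dataset(tiny_synth_config(), n = 4, rho = 0.3, seed = 11)
  rec <- ds$records[[1]]
  base <- tempfile()
  write_wfdb(rec, base, gain = 2000)
  back <- load_record(paste0(base, ".hea"), format = "wfdb")
  expect_equal(back$fs, rec$fs)
  expect_equal(dim(back$signals), dim(rec$signals))
  expect_lt(max(abs(back$signals - rec$signals)), 1 / 2000)
  expect_error(read_wfdb(tempfile()), "no such file")
})

test_that("label tables round-trip multi-label class sets", {
  labs <- list(r1 = c(1, 0, 1, 0), r2 = c(0, 0, 0, 0), r3 = c(0, 1, 1, 1))
  p <- tempfile(fileext = ".csv")
  write_labels_csv(labs, p)
  back <- read_labels_csv(p, n_classes = 4)
  expect_equal(back, labs)
  writeLines(c("record_id,classes", "r1,\"9\""), p)
  expect_error(read_labels_csv(p, n_classes = 4), "invalid class index")
})

test_that("view splitting partitions leads exactly once", {
  ds <- generate_dataset(synth_config(), n = 4, rho = 0, seed = 5)
  rec <- ds$records[[1]]
  vs <- split_views(rec, "pairs_12")
  expect_length(vs$views, 6L)
  for (v in vs$views) expect_identical(dim(v), c(2L, 1000L))
  ## partition identity: reassembling reproduces the record exactly
  expect_identical(unsplit_views(vs), rec$signals)
  ## pairing follows standard order: view 1 = leads I, II
  expect_identical(vs$views[[1]], rec$signals[1:2, ])
})

test_that("8-lead pairing yields 4 views covering each lead once", {
  cfg8 <- synth_config(n_leads = 8, lead_projection = seq(0.5, 1.9, by = 0.2))
  rec <- generate_dataset(cfg8, n = 4, rho = 0, seed = 2)$records[[1]]
  vs <- split_views(rec, "pairs_8")
  expect_length(vs$views, 4L)
  covered <- sort(unlist(vs$partition))
  expect_identical(covered, 1:8)
  expect_identical(unsplit_views(vs), rec$signals)
})

test_that("defective custom partitions are rejected with the offending leads", {
  rec <- ecg_record(matrix(rnorm(4 * 10), 4, 10), fs = 10)
  expect_error(split_views(rec, view_scheme("custom", list(c(1, 2), c(2, 3)))),
               "repeats")
  expect_error(split_views(rec, view_scheme("custom", list(c(1, 2), c(3, 4),
                                                           c(5, 6)))),
               "out of range")
  expect_error(split_views(rec, view_scheme("custom", list(c(1, 2)))),
               "missing")
})

test_that("dataset splits are exact, disjoint, exhaustive and deterministic", {
  s <- split_dataset(100, c(0.8, 0.1, 0.1), seed = 42)
  expect_identical(lengths(s[c("train", "val", "test")]),
                   c(train = 80L, val = 10L, test = 10L))
  expect_identical(sort(c(s$train, s$val, s$test)), 0:99)
  expect_length(intersect(s$train, s$val), 0L)
  expect_length(intersect(s$train, s$test), 0L)
  s2 <- split_dataset(100, c(0.8, 0.1, 0.1), seed = 42)
  expect_identical(s, s2)
  s3 <- split_dataset(100, c(0.8, 0.1, 0.1), seed = 43)
  expect_false(identical(s$train, s3$train))
  ## sizes within one record of requested ratios for awkward n
  for (n in c(7, 23, 101)) {
    sp <- split_dataset(n, c(0.8, 0.1, 0.1), seed = 1)
    sizes <- lengths(sp[c("train", "val", "test")])
    expect_identical(sum(sizes), as.integer(n))
    expect_true(all(abs(sizes - n * c(0.8, 0.1, 0.1)) <= 1))
  }
  expect_error(split_dataset(10, c(0.5, 0.2, 0.2), seed = 1), "sum to 1")
})

test_that("per-lead z-scoring centers and scales; constant leads map to zero", {
  m <- rbind(rnorm(100, 3, 2), rep(5, 100), rnorm(100, -1, 0.5))
  rec <- ecg_record(rbind(m, rnorm(100)), fs = 10)
  nr <- normalize_record(rec)
  expect_equal(rowMeans(nr$signals), rep(0, 4), tolerance = 1e-12)
  expect_equal(nr$signals[2, ], rep(0, 100))
  sds <- apply(nr$signals, 1, sd)
  expect_equal(sds[-2], rep(1, 3), tolerance = 0.01)
})
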