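test_that("delimited recordings read in both orientations and validate", {
  # samples-by-channels with a header of labels
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  m <- matrix(rnorm(2000), ncol = 2)
  writeLines(c("Fp1,Fp2", apply(m, 1, paste, collapse = ",")), path)
  rec <- read_recording(path, fs = 100)
  expect_equal(dim(rec$data), c(2L, 1000L))
  expect_equal(rec$channel_labels, c("Fp1", "Fp2"))
  expect_equal(unname(rec$data[1, ]), m[, 1])

  # channels-by-samples without header
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(t(m), path2, sep = ",", row.names = FALSE, col.names = FALSE)
  rec2 <- read_recording(path2, fs = 100)
  expect_equal(unname(rec2$data), t(m))

  # a single channel violates the recording contract
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(rnorm(50), collapse = ","), path3)
  expect_error(read_recording(path3, fs = 100), "2 channels")
})

test_that("the default montage has 20 channels and a symmetric neighbor map", {
  mo <- montage_1020()
  expect_length(mo$labels, 20L)
  for (l in mo$labels) {
    for (nb in mo$neighbors[[l]]) {
      expect_true(l %in% mo$neighbors[[nb]])
    }
  }
})

test_that("bad-channel detection flags a high-variance outlier and only that", {
  set.seed(7)
  x <- matrix(rnorm(20 * 2000), nrow = 20)
  x[12, ] <- 50 * x[12, ]
  rec <- recording(x, 250, montage_1020()$labels)
  expect_identical(detect_bad_channels(rec, z_thresh = 3),
                   montage_1020()$labels[12])
  # identical channels: zero dispersion, nothing flagged
  same <- recording(matrix(rep(rnorm(500), each = 20), nrow = 20) , 250,
                    montage_1020()$labels)
  expect_identical(detect_bad_channels(same, 3), character(0))
  expect_identical(detect_bad_channels(rec, z_thresh = Inf), character(0))
  expect_error(detect_bad_channels(recording(x[1:2, ], 250), 3), "3 channels")
})

test_that("preprocess re-references, interpolates and band-passes", {
  fs <- 200
  t_ <- seq(0, 30, by = 1 / fs)[-1]
  set.seed(2)
  # common signal disappears under average reference
  common <- 5 * sin(2 * pi * 3 * t_)
  rec <- recording(matrix(rep(common, 3), nrow = 3, byrow = TRUE), fs)
  out <- preprocess(rec, 0.5, 45)
  expect_lt(max(abs(out$data)), 1e-6)

  # per-sample mean is zero after preprocessing arbitrary data
  labs <- montage_1020()$labels
  rec2 <- recording(matrix(rnorm(20 * length(t_)), nrow = 20), fs, labs)
  out2 <- preprocess(rec2, 0.5, 45)
  expect_lt(max(abs(colMeans(out2$data))), 1e-9 * max(abs(out2$data)))

  # interpolation: a bad channel becomes the mean of its neighbors, i.e.
  # preprocessing with the flag equals preprocessing the manually repaired data
  bad <- "Cz"
  nb <- intersect(montage_1020()$neighbors[[bad]], labs)
  rec3 <- rec2
  rec3$data[bad, ] <- 1e4 * rnorm(length(t_))
  fixed <- rec3
  fixed$data[bad, ] <- colMeans(rec3$data[nb, ])
  expect_equal(preprocess(rec3, 0.5, 45, bad_channels = bad)$data,
               preprocess(fixed, 0.5, 45)$data, tolerance = 1e-12)

  expect_error(preprocess(rec2, 45, 0.5), "band edges")
})

test_that("the band-pass keeps 10 Hz and attenuates 0.1 and 60 Hz by 20 dB", {
  fs <- 200
  t_ <- seq(1 / fs, 60, by = 1 / fs)
  gain_at <- function(f) {
    x <- sin(2 * pi * f * t_)
    y <- rsbagging:::fir_bandpass(x, fs, 0.5, 45)
    # middle half avoids edge transients
    core <- seq(round(length(x) * 0.25), round(length(x) * 0.75))
    20 * log10(stats::sd(y[core]) / stats::sd(x[core]))
  }
  expect_gt(gain_at(10), -1)
  expect_lt(gain_at(0.1), -20)
  expect_lt(gain_at(60), -20)
})

test_that("epoching does stride arithmetic and round-trips the span", {
  fs <- 100
  rec <- recording(matrix(rnorm(2 * 60 * fs), nrow = 2), fs)
  expect_equal(dim(epoch(rec, 2, 0)$epochs)[3], 30L)
  rec10 <- recording(matrix(rnorm(2 * 10 * fs), nrow = 2), fs)
  expect_equal(dim(epoch(rec10, 2, 0.5)$epochs)[3], 9L)
  expect_error(epoch(recording(matrix(rnorm(2 * fs), nrow = 2), fs), 2, 0),
               "shorter than one epoch")
  # concatenation of non-overlapping epochs reproduces the analysed span
  ep <- epoch(rec, 2, 0)
  expect_equal(unepoch(ep)$data, rec$data[, 1:(30 * 2 * fs)])
})

test_that("artifact-threshold rejection drops exactly the peaked epochs", {
  fs <- 100
  set.seed(4)
  rec <- recording(matrix(rnorm(2 * 20 * fs, sd = 10), nrow = 2), fs)
  ep <- epoch(rec, 2, 0)
  ep$epochs[1, 5, 3] <- 400
  ep$epochs[2, 1, 7] <- -300
  kept <- attr(drop_artifacts(ep, 150), "kept")
  expect_identical(kept, setdiff(1:10, c(3L, 7L)))
})

test_that("clinical label tables validate and map to the binary DoC outcome", {
  df <- data.frame(subject_id = c("a", "b", "c"),
                   consciousness = c("awake", "stupor", "deep_coma"),
                   motor_side = c("L", "none", "B"),
                   stroke_side = c("R", "L", "none"))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  got <- read_clinical_labels(path)
  expect_equal(got$consciousness, df$consciousness)
  expect_equal(as.character(doc_label(got$consciousness)),
               c("negative", "positive", "positive"))
  bad <- df; bad$consciousness[2] <- "drowsy"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_clinical_labels(path2), "unknown consciousness")
})

test_that("EDF round-trips data, labels and sampling rate", {
  fs <- 100
  set.seed(9)
  x <- matrix(rnorm(3 * 5 * fs, sd = 40), nrow = 3)
  rec <- recording(x, fs, c("Fp1", "Cz", "O2"), "edfcase")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path)
  expect_equal(back$fs, fs)
  expect_equal(back$channel_labels, rec$channel_labels)
  # 16-bit quantization: error bounded by one digitization step
  step <- 2 * max(abs(x)) / 65535
  expect_lt(max(abs(back$data - x)), 1.01 * step)

  # 20-channel montage survives the trip
  rec20 <- recording(matrix(rnorm(20 * 2 * 500), nrow = 20), 500,
                     montage_1020()$labels)
  path20 <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec20, path20)
  back20 <- read_recording(path20)
  expect_equal(back20$fs, 500)
  expect_length(back20$channel_labels, 20L)
})
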