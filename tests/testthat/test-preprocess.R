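nb_map <- list(Cz = c("Fz", "Pz", "C3", "C4"))

test_that("bad-channel interpolation is the mean of good neighbors", {
  ch <- c("Cz", "Fz", "Pz", "C3", "C4")
  ep <- make_flat_epochs(1, ch, value = 0, epoch_window = c(0, 9),
                         sampling_rate = 1000)
  ep$data[1, 2, ] <- 2; ep$data[1, 3, ] <- 2
  ep$data[1, 4, ] <- 2; ep$data[1, 5, ] <- 2
  ep$data[1, 1, ] <- 99
  out <- interpolate_bad_channels(ep, "Cz", nb_map)
  expect_true(all(out$data[1, 1, ] == 2))

  ep$data[1, 2, ] <- 1; ep$data[1, 3, ] <- 3
  out2 <- interpolate_bad_channels(ep, "Cz", list(Cz = c("Fz", "Pz")))
  expect_true(all(out2$data[1, 1, ] == 2))
  expect_equal(out2$data[1, 2:5, ], ep$data[1, 2:5, ])  # others untouched

  expect_identical(interpolate_bad_channels(ep, character(), nb_map), ep)
  expect_error(
    interpolate_bad_channels(ep, c("Cz", "Fz", "Pz"),
                             list(Cz = c("Fz", "Pz"), Fz = "Cz", Pz = "Cz")),
    "all neighbors")
})

test_that("average reference zeroes the included-channel mean", {
  ep <- make_flat_epochs(1, c("a", "b"), epoch_window = c(0, 4))
  ep$data[1, 1, ] <- 3; ep$data[1, 2, ] <- 1
  out <- rereference_average(ep, exclude = character())
  expect_equal(out$data[1, 1, ], rep(1, 5))
  expect_equal(out$data[1, 2, ], rep(-1, 5))

  # zero-mean input is unchanged; operator is idempotent
  ep$data[1, 1, ] <- 1; ep$data[1, 2, ] <- -1
  out2 <- rereference_average(ep, exclude = character())
  expect_equal(out2$data, ep$data)

  set.seed(8)
  big <- make_flat_epochs(3, epoch_window = c(0, 99))
  big$data[] <- rnorm(length(big$data))
  ref <- rereference_average(big, exclude = "HEOG")
  inc <- which(big$channel_names != "HEOG")
  m <- apply(ref$data[, inc, , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(m)), 1e-10)
  expect_equal(rereference_average(ref, exclude = "HEOG")$data, ref$data)
  expect_equal(ref$data[, 7, ], big$data[, 7, ])  # HEOG untouched

  expect_error(rereference_average(make_flat_epochs(1, "a",
                                                    epoch_window = c(0, 4))),
               "at least 2")
})

test_that("the low-pass filter is zero-phase, DC-preserving and selective", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  ep <- epoch_set(array(5, c(1, 1, length(t))), "Pz", fs,
                  c(0, 2000))
  out <- lowpass_filter(ep, 17)
  expect_equal(out$data[1, 1, ], rep(5, length(t)), tolerance = 1e-9)

  # 50-Hz tone attenuated below 10% of its input amplitude
  x50 <- sin(2 * pi * 50 * t)
  ep$data[1, 1, ] <- x50
  y50 <- lowpass_filter(ep, 17)$data[1, 1, ]
  expect_lt(max(abs(y50[200:1800])), 0.1)

  # 2-Hz tone preserved within 2% with zero phase lag (max cross-correlation
  # at zero lag)
  x2 <- sin(2 * pi * 2 * t)
  ep$data[1, 1, ] <- x2
  y2 <- lowpass_filter(ep, 17)$data[1, 1, ]
  mid <- 200:1800
  expect_equal(max(abs(y2[mid])), 1, tolerance = 0.02)
  lags <- -5:5
  cc <- vapply(lags, function(L)
    sum(y2[mid] * x2[mid + L]), 0)
  expect_equal(lags[which.max(cc)], 0)

  expect_error(lowpass_filter(ep, 600), "Nyquist")
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  ep <- make_flat_epochs(2, c("a", "b"))
  ep$data[] <- 3
  out <- baseline_correct(ep)
  expect_true(all(out$data == 0))
  expect_equal(baseline_correct(out)$data, out$data)

  set.seed(3)
  ep$data[] <- rnorm(length(ep$data))
  out <- baseline_correct(ep)
  idx <- time_window_indices(out, c(-200, 0))
  b <- apply(out$data[, , idx], c(1, 2), mean)
  expect_lt(max(abs(b)), 1e-12)
})

test_that("epoching cuts full windows and drops edge markers with a warning", {
  set.seed(5)
  cont <- matrix(rnorm(2 * 5000), 2, dimnames = list(c("a", "b"), NULL))
  ep <- suppressWarnings(
    epoch_and_baseline(cont, c(100L, 1000L, 2500L, 4950L), 1000))
  expect_equal(dim(ep$data)[1], 2)  # markers 100 and 4950 dropped
  expect_warning(epoch_and_baseline(cont, c(100L, 1000L), 1000),
                 "dropped")
  # epoch content matches the raw slice minus its baseline mean
  raw <- cont[, (1000 - 200):(1000 + 1100)]
  raw <- raw - rowMeans(raw[, 1:201])
  expect_equal(ep$data[1, , ], raw, ignore_attr = TRUE)
})

test_that("the composed pipeline equals the stage sequence, both paths agree", {
  chans <- c("P7", "P8", "P9", "P10", "PO7", "PO8", "HEOG")
  n_sp <- 8000
  tt <- seq_len(n_sp) / 1000
  cont <- t(vapply(1:7, function(i)
    10 * sin(2 * pi * (1 + i) * tt + i) + 4 * cos(2 * pi * 8 * tt),
    numeric(n_sp)))
  rownames(cont) <- chans
  markers <- c(1500L, 4000L, 6500L)
  cfg <- preproc_config()

  composed <- preprocess_continuous(cont, markers, 1000, cfg)

  manual <- cont
  inc <- chans[chans != "HEOG"]
  manual[inc, ] <- sweep(manual[inc, ], 2, colMeans(manual[inc, ]))
  manual[inc, ] <- lowpass_filter(manual[inc, ], 17, sampling_rate = 1000)
  manual_ep <- epoch_and_baseline(manual, markers, 1000)
  expect_equal(composed$data, manual_ep$data, tolerance = 1e-12)

  # direct epoch-level preprocessing agrees with the continuous path away
  # from epoch edges, where the per-epoch mirror padding differs
  ep_first <- epoch_and_baseline(cont, markers, 1000,
                                 baseline_window = c(-200, 0))
  via_epochs <- preprocess_epochs(ep_first, cfg)
  mid <- time_window_indices(composed, c(100, 850))
  expect_lt(max(abs(via_epochs$data[, , mid] - composed$data[, , mid])), 0.2)
})
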