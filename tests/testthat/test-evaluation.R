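mk_truth <- function(x, y, frames = 0:20, w = 5L, h = 5L) {
  tibble::tibble(frame = frames, object_id = "D", x = x, y = y,
                 width = w, height = h, is_pseudo = FALSE)
}

test_that("detection rate counts 5-px matches over evaluated frames", {
  truth <- mk_truth(x = 100 - 2 * (0:20), y = 50)
  hits <- tibble::tibble(frame = 0:20, x = truth$x, y = truth$y,
                         confirmed = TRUE)
  expect_equal(detection_rate(hits, truth, warmup = 0), 1)

  # accurate in 15 of 21 frames
  part <- hits[1:15, ]
  expect_equal(detection_rate(part, truth, warmup = 0), 15 / 21,
               tolerance = 1e-12)
  expect_equal(round(15 / 21, 4), 0.7143)

  none <- hits[0, ]
  expect_equal(detection_rate(none, truth, warmup = 0), 0)

  # a detection just beyond 5 px does not count
  off <- dplyr::mutate(hits, x = x + 5.1)
  expect_equal(detection_rate(off, truth, warmup = 0), 0)
  on <- dplyr::mutate(hits, x = x + 5)
  expect_equal(detection_rate(on, truth, warmup = 0), 1)

  expect_error(detection_rate(hits, truth[0, ], warmup = 0), "target")
})

test_that("warm-up and last-frame windows bound the evaluated frames", {
  truth <- mk_truth(x = 100, y = 50)
  hits <- tibble::tibble(frame = 10:19, x = 100, y = 50, confirmed = TRUE)
  expect_equal(detection_rate(hits, truth, warmup = 10, last_frame = 19), 1)
  expect_equal(detection_rate(hits, truth, warmup = 8, last_frame = 19),
               10 / 12, tolerance = 1e-12)
})

test_that("pixel precision/recall/F1 follow the counting formulas", {
  dims <- c(40, 40, 3)
  truth <- mk_truth(x = 20, y = 20, frames = 0:2)
  # perfect prediction
  pred <- tibble::tibble(frame = 0:2, x = 20, y = 20, confirmed = TRUE)
  out <- pixel_prf(pred, truth, dims, warmup = 0)
  expect_equal(c(out$pr, out$rc, out$f1), c(1, 1, 1))

  # one-pixel horizontal offset: 20 of 25 box pixels overlap
  off <- dplyr::mutate(pred, x = x + 1)
  out2 <- pixel_prf(off, truth, dims, warmup = 0)
  expect_equal(out2$tp, 3L * 20L)
  expect_equal(out2$fp, 3L * 5L)
  expect_equal(out2$fn, 3L * 5L)
  expect_equal(out2$pr, 0.8)
  expect_equal(out2$rc, 0.8)
  expect_equal(out2$f1, 0.8)

  # empty prediction: degenerate convention Pr = Rc = F1 = 0
  out3 <- pixel_prf(pred[0, ], truth, dims, warmup = 0)
  expect_equal(c(out3$pr, out3$rc, out3$f1), c(0, 0, 0))

  # the arithmetic itself: TP 30, FP 10, FN 20
  pr <- 30 / 40; rc <- 30 / 50
  expect_equal(pr, 0.75)
  expect_equal(rc, 0.6)
  expect_equal(2 * pr * rc / (pr + rc), 0.6667, tolerance = 1e-4)
})

test_that("frame order of prediction/truth pairs does not change the scores", {
  dims <- c(30, 30, 4)
  truth <- mk_truth(x = c(5, 10, 15, 20), y = 15, frames = 0:3)
  pred <- tibble::tibble(frame = 0:3, x = c(5, 10, 16, 21), y = 15,
                         confirmed = TRUE)
  perm <- c(3L, 0L, 2L, 1L)
  truth_p <- dplyr::mutate(truth, frame = perm[frame + 1L])
  pred_p <- dplyr::mutate(pred, frame = perm[frame + 1L])
  expect_equal(detection_rate(pred, truth, warmup = 0),
               detection_rate(pred_p, truth_p, warmup = 0))
  expect_equal(pixel_prf(pred, truth, dims, warmup = 0),
               pixel_prf(pred_p, truth_p, dims, warmup = 0))
})

test_that("SNR and VN follow their stated conventions", {
  dims <- c(40, 40, 2)
  truth <- mk_truth(x = 20, y = 20, frames = 0:1)
  resp <- array(0, dims)
  # all energy inside the target region
  resp[21, 21, ] <- 3
  out <- snr_vn(resp, truth, warmup = 0)
  expect_equal(out$vn, 0)

  # equal energy inside and outside
  resp2 <- array(0, dims)
  resp2[21, 21, ] <- 3
  resp2[5, 5, ] <- 3
  expect_equal(snr_vn(resp2, truth, warmup = 0)$vn, 50)

  # peak 10 inside, constant 1 outside: SNR = 10 / 1
  resp3 <- array(1, dims)
  resp3[21, 21, ] <- 10
  out3 <- snr_vn(resp3, truth, warmup = 0)
  expect_equal(out3$snr, 10, tolerance = 1e-9)

  # all-zero response: conventions SNR = 0, VN = 0
  out4 <- snr_vn(array(0, dims), truth, warmup = 0)
  expect_equal(c(out4$snr, out4$vn), c(0, 0))
})

test_that("zeroing any off-target response strictly decreases VN", {
  dims <- c(30, 30, 1)
  truth <- mk_truth(x = 15, y = 15, frames = 0)
  resp <- array(0, dims)
  resp[16, 16, 1] <- 5
  resp[3, 3, 1] <- 2
  resp[25, 8, 1] <- 1
  v0 <- snr_vn(resp, truth, warmup = 0)$vn
  resp2 <- resp; resp2[25, 8, 1] <- 0
  v1 <- snr_vn(resp2, truth, warmup = 0)$vn
  expect_lt(v1, v0)
})

test_that("end-to-end evaluation report is coherent on a mini scene", {
  s <- render_sequence(mini_scene(2))
  res <- msod_detect(s$frames)
  ev <- evaluate_detections(res, s$truth, warmup = 5)
  expect_s3_class(ev, "msod_eval")
  expect_true(ev$dr >= 0 && ev$dr <= 1)
  expect_true(ev$pr >= 0 && ev$pr <= 1 && ev$rc >= 0 && ev$rc <= 1)
  expect_true(ev$vn >= 0 && ev$vn <= 100)
  expect_equal(ev$n_frames_eval,
               res$dims[3] - 1L - res$params$latency - 5L + 1L)
  tall <- tidy(ev)
  expect_true(all(c("metric", "value") %in% names(tall)))
})
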