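test_that("thresholding: empty maps, isolated peaks, NMS separation", {
  z <- array(0, c(20, 20, 3))
  expect_identical(nrow(threshold_detections(z)), 0L)

  one <- array(0, c(20, 20, 1)); one[8, 13, 1] <- 1
  det <- threshold_detections(one, th = 0.2, norm_top = NULL)
  expect_identical(nrow(det), 1L)
  expect_equal(c(det$x, det$y, det$frame), c(12, 7, 0))

  two <- array(0, c(30, 30, 1))
  two[10, 5, 1] <- 1; two[10, 17, 1] <- 1  # 12 px apart
  det <- threshold_detections(two, th = 0.2, nms = 5, norm_top = NULL)
  expect_identical(nrow(det), 2L)

  # adjacent competitors inside one suppression window collapse to one
  close_ <- array(0, c(30, 30, 1))
  close_[10, 5, 1] <- 1; close_[10, 6, 1] <- 0.9
  det <- threshold_detections(close_, th = 0.2, nms = 5, norm_top = NULL)
  expect_identical(nrow(det), 1L)
  expect_equal(det$x, 4)
})

test_that("top-K normalization detects secondary objects under a dominant peak", {
  m <- array(0, c(50, 200, 1))
  m[25 + (-1:1), 30 + (-1:1), 1] <- 10     # dominant blob
  m[25 + (-1:1), 150 + (-1:1), 1] <- 1.5   # weak secondary blob
  with_max <- threshold_detections(m, th = 0.2, norm_top = NULL)
  with_topk <- threshold_detections(m, th = 0.2, norm_top = 100)
  expect_identical(nrow(with_max), 1L)   # secondary falls below 0.2 * max
  expect_identical(nrow(with_topk), 2L)  # but not below 0.2 * top-K mean
})

test_that("linking joins within radius, splits beyond, ties to older track", {
  det <- tibble::tibble(frame = c(0L, 1L), x = c(100, 105), y = c(50, 52),
                        score = 1, norm_score = 1)
  out <- link_trajectories(det, link_radius = 10)
  expect_identical(out$trajectory, c(1L, 1L))

  det2 <- tibble::tibble(frame = c(0L, 1L), x = c(100, 150), y = c(50, 50),
                         score = 1, norm_score = 1)
  out2 <- link_trajectories(det2, link_radius = 10)
  expect_identical(out2$trajectory, c(1L, 2L))

  # one new detection equidistant from two open trajectories
  det3 <- tibble::tibble(frame = c(0L, 0L, 1L), x = c(100, 110, 105),
                         y = c(50, 50, 50), score = 1, norm_score = 1)
  out3 <- link_trajectories(det3, link_radius = 10)
  expect_identical(out3$trajectory, c(1L, 2L, 1L))
})

test_that("gap tolerance scales the distance budget per missed frame", {
  det <- tibble::tibble(frame = c(0L, 2L), x = c(100, 115), y = c(50, 50),
                        score = 1, norm_score = 1)
  strict <- link_trajectories(det, link_radius = 10, gap_max = 0)
  expect_identical(strict$trajectory, c(1L, 2L))
  lenient <- link_trajectories(det, link_radius = 10, gap_max = 1)
  expect_identical(lenient$trajectory, c(1L, 1L))  # 15 px <= 10 * 2 frames
})

test_that("contrast attaches by exact position and cumulative SD is sample SD", {
  t1 <- array(7, c(60, 60, 4))
  det <- tibble::tibble(frame = 0:3, x = c(10, 12, 14, 16), y = rep(30, 4),
                        score = 1, norm_score = 1, trajectory = 1L)
  out <- attach_contrast(det, t1)
  expect_true(all(out$ct == 7))

  out$ct <- c(0, 10, 20, 30)
  sdd <- contrast_sd(out)
  expect_equal(sdd$sd_ct[1], 0)
  expect_equal(sdd$sd_ct[4], stats::sd(c(0, 10, 20, 30)), tolerance = 1e-12)
  expect_equal(sdd$sd_ct[4], 12.90994, tolerance = 1e-4)

  flat <- dplyr::mutate(out, ct = 5)
  expect_true(all(contrast_sd(flat)$sd_ct == 0))

  one <- attach_contrast(det[1, ], t1)
  expect_identical(nrow(contrast_sd(one)), 1L)
  expect_equal(contrast_sd(one)$sd_ct, 0)

  bad <- dplyr::mutate(det, x = 100)
  expect_error(attach_contrast(bad, t1), "outside")
})

test_that("confirmation needs length and contrast variability, monotone in th2", {
  det <- tibble::tibble(frame = 0:5, x = 1:6, y = 1, score = 1, norm_score = 1,
                        trajectory = 1L, ct = c(0, 9, 1, 12, 3, 15))
  sdd <- contrast_sd(det)
  conf <- confirm_objects(sdd, th2 = 4, min_length = 3)
  expect_false(any(conf$confirmed[1:2]))       # too short at first points
  expect_true(any(conf$confirmed))

  # raising th2 never adds confirmations
  for (th2_hi in c(6, 10, 25)) {
    conf_hi <- confirm_objects(sdd, th2 = th2_hi, min_length = 3)
    expect_true(all(which(conf_hi$confirmed) %in% which(conf$confirmed)))
  }

  # near-zero th2 confirms any variable trajectory once long enough
  conf0 <- confirm_objects(sdd, th2 = 1e-9, min_length = 2)
  expect_true(conf0$confirmed[2])
})

test_that("each detection belongs to exactly one trajectory", {
  set.seed(14)
  det <- tibble::tibble(frame = rep(0:5, each = 4),
                        x = runif(24, 0, 200), y = runif(24, 0, 100),
                        score = 1, norm_score = 1)
  out <- link_trajectories(det, link_radius = 15)
  expect_identical(nrow(out), 24L)
  expect_true(all(out$trajectory >= 1L))
  # within a frame, no trajectory id repeats
  expect_true(all(table(paste(out$frame, out$trajectory)) == 1L))
})
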