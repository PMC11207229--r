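test_that("area loss is ~0 for a perfect prediction and exact on a 2x2 case", {
  lab <- rect_mask(6, 6, 2, 2, 4, 5)
  expect_lt(area_loss(lab, lab), 1e-5)
  z <- matrix(0, 4, 4)
  expect_lt(area_loss(z, z), 1e-5)     # empty/empty: dice term killed by eps
  # hand-computed 2x2 case (eps constants as documented)
  lab2 <- matrix(c(1, 0, 0, 0), 2, 2)
  pred <- matrix(c(0.8, 0.2, 0.2, 0.2), 2, 2)
  bce <- -mean(c(log(0.8), log(0.8), log(0.8), log(0.8)))
  dice_term <- 1 - (2 * 0.8 + 1e-6) / (1 + 1.4 + 1e-6)
  expect_equal(area_loss(lab2, pred), bce + dice_term, tolerance = 1e-12)
})

test_that("weighted edge loss uses w0 = edge fraction and is exact on a fixed case", {
  # all-edge label, perfect prediction
  e <- matrix(1, 3, 3)
  expect_lt(weighted_edge_loss(e, matrix(1 - 1e-9, 3, 3)), 1e-5)
  # empty edge label: only the background term contributes (w0 = 0)
  e0 <- matrix(0, 3, 3)
  s <- matrix(0.3, 3, 3)
  expect_equal(weighted_edge_loss(e0, s), -mean(log(0.7)), tolerance = 1e-9)
  # 10x10 with 8 edge pixels: w0 = 0.08, w1 = 0.92
  e8 <- matrix(0, 10, 10); e8[1, 1:8] <- 1
  sp <- matrix(0.25, 10, 10)
  manual <- -sum(0.08 * e8 * log(sp) + 0.92 * (1 - e8) * log(1 - sp)) / 100
  expect_equal(weighted_edge_loss(e8, sp), manual, tolerance = 1e-12)
  # the swap switch exchanges the two class weights
  manual_sw <- -sum(0.92 * e8 * log(sp) + 0.08 * (1 - e8) * log(1 - sp)) / 100
  expect_equal(weighted_edge_loss(e8, sp, swap_weights = TRUE), manual_sw,
               tolerance = 1e-12)
})

test_that("schedule weights follow the linear ramp with the stated endpoints", {
  expect_equal(schedule_weights(joint_schedule(10, e_cur = 0)),
               c(alpha = 1, beta = 0))
  expect_equal(schedule_weights(joint_schedule(10, e_cur = 10)),
               c(alpha = 0, beta = 1))
  expect_equal(schedule_weights(joint_schedule(10, e_cur = 5)),
               c(alpha = 0.5, beta = 0.5))
  expect_equal(schedule_weights(joint_schedule(10, e_total = 30, e_cur = 25)),
               c(alpha = 0, beta = 1))  # saturates past e_thres
  expect_error(schedule_weights(list(e_thres = 5, e_cur = -1)), "nonnegative")
  expect_error(joint_schedule(0), "e_thres")
})

test_that("joint loss interpolates its components as scheduled", {
  s0 <- joint_schedule(8, e_cur = 0)
  expect_equal(joint_loss(1, 0.5, 2, 0.25, s0), 1.5)         # pure pseudo
  s1 <- joint_schedule(8, e_cur = 8)
  expect_equal(joint_loss(1, 0.5, 2, 0.25, s1), 2.25)        # pure sparse
  sh <- joint_schedule(8, e_cur = 4)
  expect_equal(joint_loss(1, 0.5, 2, 0.25, sh), 0.5 * 1.5 + 0.5 * 2.25)
})

test_that("alpha + beta = 1 up to e_thres and the joint loss is continuous in e_cur", {
  for (e in 0:12) {
    w <- schedule_weights(joint_schedule(10, e_total = 20, e_cur = e))
    if (e <= 10) expect_equal(sum(w), 1)
    else expect_equal(unname(w), c(0, 1))
  }
})

test_that("losses are nonnegative and finite for arbitrary clipped predictions", {
  set.seed(3)
  for (i in 1:10) {
    lab <- random_mask(6, 6, runif(1))
    pred <- matrix(runif(36), 6, 6)
    expect_gte(area_loss(lab, pred), 0)
    expect_true(is.finite(area_loss(lab, pred)))
    e <- edge_from_mask(lab)
    expect_gte(weighted_edge_loss(e, pred), 0)
    expect_true(is.finite(weighted_edge_loss(e, pred)))
  }
  # extreme predictions survive the log clip
  lab <- rect_mask(4, 4, 1, 1, 2, 2)
  expect_true(is.finite(area_loss(lab, matrix(0, 4, 4))))
  expect_true(is.finite(area_loss(lab, matrix(1, 4, 4))))
})

test_that("area loss is minimized at the label itself", {
  lab <- rect_mask(5, 5, 2, 2, 4, 4)
  base <- area_loss(lab, lab)
  set.seed(1)
  for (i in 1:10) {
    perturbed <- pmin(pmax(lab + matrix(rnorm(25, sd = 0.05), 5, 5), 0), 1)
    expect_gt(area_loss(lab, perturbed), base)
  }
})
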