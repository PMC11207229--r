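test_that("adjacent-slice scores follow the endpoint/interior averaging rule", {
  H <- 6; W <- 6
  a <- rect_mask(H, W, 1, 1, 3, 3)
  # identical predictions -> all scores 1
  expect_equal(adjacent_dice_scores(list(a, a, a, a)), rep(1, 4))
  # Nu = 2 -> both ends share the single pairwise dice
  b <- rect_mask(H, W, 1, 1, 3, 4)
  expect_equal(adjacent_dice_scores(list(a, b)), rep(dice(a, b), 2))
  # constructed stack with dice(U1,U2) = 0.8, dice(U2,U3) = 0.6
  u1 <- matrix(0, H, W); u1[1, 1:4] <- 1
  u2 <- matrix(0, H, W); u2[1, 1:6] <- 1
  u3 <- matrix(0, H, W); u3[1, 1:3] <- 1; u3[2, 1] <- 1
  expect_equal(dice(u1, u2), 0.8)
  expect_equal(dice(u2, u3), 0.6)
  expect_equal(adjacent_dice_scores(list(u1, u2, u3)), c(0.8, 0.7, 0.6))
  # single-slice case: always selected
  expect_equal(adjacent_dice_scores(list(a)), 0)
})

test_that("adjacent scores equal a brute-force pairwise recomputation", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    stack <- lapply(seq_len(n), function(i) random_mask(7, 7, 0.4))
    sc <- adjacent_dice_scores(stack)
    brute <- vapply(seq_len(n), function(i) {
      if (i == 1) dice(stack[[1]], stack[[2]])
      else if (i == n) dice(stack[[n - 1]], stack[[n]])
      else (dice(stack[[i - 1]], stack[[i]]) + dice(stack[[i]], stack[[i + 1]])) / 2
    }, 0)
    expect_equal(sc, brute, tolerance = 1e-12)
  }
})

test_that("threshold selection picks exactly the below-threshold slices", {
  expect_length(select_slices(c(0.5, 0.9), 0), 0)
  expect_equal(select_slices(c(0.8, 0.7, 0.6), 0.75), c(2L, 3L))
  expect_equal(select_slices(c(0.8, 0.999, 1), 1), c(1L, 2L))
  # lowering the threshold never selects more slices
  set.seed(2)
  sc <- runif(30)
  for (i in 1:10) {
    t1 <- runif(1); t2 <- runif(1, 0, t1)
    expect_lte(length(select_slices(sc, t2)), length(select_slices(sc, t1)))
  }
})

test_that("sparse oracle correction keeps every (interval+1)-th selected slice", {
  gt <- lapply(1:10, function(i) rect_mask(4, 4, 1, 1, 2, i %% 3 + 1))
  oc <- oracle_correct(1:6, gt, interval = 2)
  expect_equal(oc$corrected, c(1L, 4L))
  expect_identical(oc$masks, gt[c(1, 4)])         # doctor replaces with gt bitwise
  expect_equal(oracle_correct(3:8, gt, 0)$corrected, 3:8)
  expect_error(oracle_correct(1:3, gt, -1), "nonnegative")
})

test_that("equivalent workload converts box effort at the 15:1 rate", {
  expect_equal(as.integer(equivalent_workload(320, 10800)), 1040L)
  expect_equal(as.integer(equivalent_workload(0, 11120)), 741L)
  expect_equal(as.integer(equivalent_workload(5, 0)), 5L)
  expect_equal(attr(equivalent_workload(0, 11120), "exact"), 11120 / 15)
  expect_error(equivalent_workload(-1, 0), "nonnegative")
})

test_that("schedules must terminate: interval reaches 0 and threshold reaches 1", {
  s <- iasal_schedule(0.7, 5, 3)
  expect_equal(s$dice_ts, seq(0.7, 1, length.out = 5))
  expect_equal(s$interval, c(3L, 2L, 1L, 0L, 0L))
  expect_error(iasal_schedule(0.7, 3, 5), "non-terminating")
})

test_that("a one-round schedule corrects everything immediately", {
  vols <- tiny_phantom(n_cases = 2, slices = 6, size = 32, seed = 31)
  cfg <- train_config(max_rounds = 2, batch_size = 2, seed = 1)
  model <- swssl(vols, s_int = 2, config = cfg,
                 backbone = backbone_config(2, 2), stages = "sparse")
  res <- run_iasal(model, vols, iasal_schedule(1, 1, 0), cfg, retrain_rounds = 1)
  expect_true(all(unlist(res$state$status) != "bbox_only"))
  expect_equal(nrow(res$metrics), 1)
  # workload reconciliation: final Ss = initial sparse + corrected
  n_sparse <- sum(lengths(lapply(c(6, 6), select_sparse_slices, s_int = 2)))
  expect_equal(res$state$ss, n_sparse + sum(res$corrected_per_round))
  expect_equal(res$state$sbb, 0L)
})

test_that("corrected counts accumulate monotonically across rounds", {
  vols <- tiny_phantom(n_cases = 2, slices = 8, size = 32, seed = 33)
  cfg <- train_config(max_rounds = 2, batch_size = 2, seed = 1)
  model <- swssl(vols, s_int = 3, config = cfg,
                 backbone = backbone_config(2, 2), stages = "sparse")
  res <- run_iasal(model, vols, iasal_schedule(0.7, 3, 1), cfg, retrain_rounds = 1)
  expect_true(all(diff(res$metrics$ss) >= 0))
  expect_true(all(res$corrected_per_round >= 0))
  expect_true(all(unlist(res$state$status) != "bbox_only"))
})
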