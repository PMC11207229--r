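make_samples <- function(n = 2, size = 24, seed = 19) {
  vols <- tiny_phantom(n_cases = 1, slices = n, size = size, seed = seed,
                       thickness_range = c(2, 4))
  swsal:::volume_samples(vols, "bone")
}

test_that("a single slice can be overfit: loss falls over 30 rounds", {
  smp <- make_samples(1)
  cfg <- train_config(max_rounds = 30, batch_size = 1, seed = 2)
  net <- train_stage_sparse(backbone_init(backbone_config(2, 2), seed = 2),
                            smp, cfg)
  h <- attr(net, "history")
  expect_lt(h$loss[30], h$loss[1])
})

test_that("training is deterministic for identical config and seed", {
  smp <- make_samples(3)
  cfg <- train_config(max_rounds = 5, batch_size = 2, seed = 4)
  run <- function() {
    n <- train_stage_sparse(backbone_init(backbone_config(2, 2), seed = 4),
                            smp, cfg)
    list(h = attr(n, "history"), p = n$params)
  }
  a <- run(); b <- run()
  expect_identical(a$h, b$h)
  expect_identical(a$p, b$p)
})

test_that("the returned checkpoint is never worse on validation than any round", {
  vols <- tiny_phantom(n_cases = 2, slices = 4, size = 24, seed = 41,
                       thickness_range = c(2, 4))
  smp <- swsal:::volume_samples(vols[1], "bone")
  val <- swsal:::volume_samples(vols[2], "bone")
  cfg <- train_config(max_rounds = 25, early_stop_patience = 25,
                      batch_size = 2, seed = 3)
  net <- train_stage_sparse(backbone_init(backbone_config(2, 2), seed = 3),
                            smp, cfg, val)
  h <- attr(net, "history")
  # the checkpoint may also be the incoming (round-0) parameters, so it can
  # only be at least as good as every trained round
  expect_gte(swsal:::samples_val_dice(net, val), max(h$val_dice))
})

test_that("an empty sparse training set is a configuration error", {
  cfg <- train_config(max_rounds = 1)
  expect_error(train_stage_sparse(backbone_init(backbone_config(2, 2)), list(), cfg),
               "empty")
})

test_that("the bbox stage freezes the edge head and respects refine_cycles = 0", {
  smp <- make_samples(3)
  net0 <- backbone_init(backbone_config(2, 2), seed = 6)
  cfg0 <- train_config(max_rounds = 4, batch_size = 2, refine_cycles = 0, seed = 6)
  before <- smp
  out <- train_stage_bbox(net0, smp, cfg0)
  # labels unchanged without refinement; edge head untouched bitwise
  expect_identical(lapply(out$samples, `[[`, "mask"), lapply(before, `[[`, "mask"))
  expect_identical(out$net$params$edge1, net0$params$edge1)
  expect_identical(out$net$params$edge2, net0$params$edge2)
  expect_false(identical(out$net$params$seg1, net0$params$seg1))
})

test_that("refinement replaces labels with binarized predictions, keeping empties empty", {
  smp <- make_samples(3)
  smp[[2]]$mask <- smp[[2]]$mask * 0  # an originally-empty slice
  cfg <- train_config(max_rounds = 3, batch_size = 2, refine_cycles = 1, seed = 6)
  out <- train_stage_bbox(backbone_init(backbone_config(2, 2), seed = 6), smp, cfg)
  expect_equal(sum(out$samples[[2]]$mask), 0)
  for (i in c(1, 3)) expect_true(all(out$samples[[i]]$mask %in% c(0, 1)))
})

test_that("an all-empty pseudo-label set aborts with a diagnostic", {
  smp <- make_samples(2)
  for (i in seq_along(smp)) smp[[i]]$mask <- smp[[i]]$mask * 0
  expect_error(train_stage_bbox(backbone_init(backbone_config(2, 2)), smp,
                                train_config(max_rounds = 1)),
               "empty")
})

test_that("joint training warns when the schedule cannot complete and needs both sets", {
  smp <- make_samples(2)
  net <- backbone_init(backbone_config(2, 2), seed = 1)
  expect_error(train_joint(net, list(), smp, train_config(max_rounds = 1)),
               "nonempty")
  cfg <- train_config(max_rounds = 2, e_thres = 5, batch_size = 2, seed = 1)
  expect_warning(train_joint(net, smp, smp, cfg), "schedule")
})

test_that("with e_thres = 1 the joint rounds after the first are pure sparse training", {
  smp <- make_samples(2, seed = 19)
  pse <- make_samples(2, seed = 23)
  cfg <- train_config(max_rounds = 3, e_thres = 1, batch_size = 2, seed = 5)
  suppressWarnings(net <- train_joint(backbone_init(backbone_config(2, 2), seed = 5),
                                      smp, pse, cfg))
  h <- attr(net, "history")
  expect_equal(h$alpha, c(1, 0, 0))
  expect_equal(h$beta, c(0, 1, 1))
  # rounds with alpha = 0 skip the pseudo pass entirely
  expect_equal(h$loss_pseudo[h$alpha == 0], c(0, 0))
})

test_that("swssl returns a classed model with workload counters and methods", {
  vols <- tiny_phantom(n_cases = 2, slices = 6, size = 24, seed = 37,
                       thickness_range = c(2, 4))
  cfg <- train_config(max_rounds = 2, batch_size = 2, refine_cycles = 0,
                      e_thres = 1, seed = 3)
  m <- suppressWarnings(swssl(vols, s_int = 2, config = cfg,
                              backbone = backbone_config(2, 2)))
  expect_s3_class(m, "swssl_model")
  expect_equal(m$ss, 2 * length(select_sparse_slices(6, 2)))
  expect_equal(m$sbb, 2 * 6 - m$ss)
  pr <- predict(m, vols[[1]])
  expect_named(pr, c("prob", "mask"))
  expect_length(pr$mask$bone, 6)
  expect_true(all(unlist(pr$mask$bone) %in% c(0, 1)))
  expect_output(print(m), "workload")
  d <- evaluate_model(m, vols[1])
  expect_true(all(d >= 0 & d <= 1))
})
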