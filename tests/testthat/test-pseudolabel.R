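test_that("bone seed is the integer centre of the box", {
  img <- matrix(0.5, 12, 12)
  expect_equal(select_seed(img, c(3, 3, 7, 9), "bone"), c(5, 6))
  expect_equal(select_seed(img, c(1, 1, 1, 1), "bone"), c(1, 1))
})

test_that("cartilage seed matches the brute-force per-column extent rule", {
  v <- tiny_phantom(n_cases = 1, slices = 3, size = 48, seed = 21)[[1]]
  for (i in 1:3) {
    box <- v$boxes$cartilage[[i]]
    gp <- grow_params("cartilage")
    seed <- select_seed(v$slices[[i]], box, "cartilage", gp)
    # brute-force oracle: same Canny map, explicit per-column min/max scan
    sub <- v$slices[[i]][box[1]:box[3], box[2]:box[4]]
    ed <- canny(sub, gp$canny_sigma, gp$canny_low_q, gp$canny_high_q)
    best <- -1; best_col <- NA; best_mid <- NA
    for (j in seq_len(ncol(ed))) {
      rs <- which(ed[, j] == 1)
      if (length(rs) && diff(range(rs)) > best) {
        best <- diff(range(rs)); best_col <- j
        best_mid <- (min(rs) + max(rs)) %/% 2
      }
    }
    expect_equal(seed, c(box[1] - 1 + best_mid, box[2] - 1 + best_col))
    # the seed must lie inside the box
    expect_true(seed[1] >= box[1] && seed[1] <= box[3])
    expect_true(seed[2] >= box[2] && seed[2] <= box[4])
  }
})

test_that("a featureless cartilage box falls back to the centre with a warning", {
  img <- matrix(0.5, 10, 10)
  expect_warning(s <- select_seed(img, c(2, 2, 8, 8), "cartilage"), "fall")
  expect_equal(s, c(5, 5))
})

test_that("region growing honours the tissue-specific area stop rules", {
  img <- matrix(0.5, 20, 20)
  box <- c(5, 5, 14, 16)
  m <- region_grow(img, c(9, 10), box, grow_params("bone"))
  expect_gte(sum(m), 0.8 * 10 * 12)
  m1 <- region_grow(img, c(3, 3), c(3, 3, 3, 3), grow_params("bone"))
  expect_equal(sum(m1), 1)  # 1x1 box: single pixel already satisfies the rule
  expect_false(attr(m1, "low_confidence"))
})

test_that("pseudo-masks stay inside the box and form one 8-connected component", {
  # 8-connected reachability from the seed, by flood fill
  reach8 <- function(m, seed) {
    r <- matrix(FALSE, nrow(m), ncol(m)); r[seed[1], seed[2]] <- TRUE
    repeat {
      grown <- swsal:::dilate8(r) & (m == 1)
      if (all(grown == r)) return(r)
      r <- grown
    }
  }
  v <- tiny_phantom(n_cases = 1, slices = 4, size = 48, seed = 13)[[1]]
  for (i in 1:4) {
    box <- v$boxes$bone[[i]]
    seed <- select_seed(v$slices[[i]], box, "bone")
    m <- region_grow(v$slices[[i]], seed, box, grow_params("bone"))
    outside <- m
    outside[box[1]:box[3], box[2]:box[4]] <- 0
    expect_equal(sum(outside), 0)
    expect_equal(m[seed[1], seed[2]], 1)
    expect_equal(sum(reach8(m, seed)), sum(m))  # all of it reachable from seed
  }
})

test_that("raising the area stop ratio never shrinks the grown region", {
  v <- tiny_phantom(n_cases = 1, slices = 2, size = 48, seed = 17)[[1]]
  box <- v$boxes$bone[[1]]
  seed <- select_seed(v$slices[[1]], box, "bone")
  m_lo <- region_grow(v$slices[[1]], seed, box, grow_params("bone", area_ratio_stop = 0.5))
  m_hi <- region_grow(v$slices[[1]], seed, box, grow_params("bone", area_ratio_stop = 0.9))
  expect_true(all(m_hi >= m_lo))
})

test_that("bone pseudo-labels recover most of the ground truth on phantoms", {
  vols <- tiny_phantom(n_cases = 5, slices = 4, size = 48, seed = 29)
  ds <- c()
  for (v in vols) {
    pl <- pseudo_labels_for_volume(v)
    for (i in seq_along(v$slices)) {
      d <- dice(pl$masks$bone[[i]], v$masks$bone[[i]])
      ds <- c(ds, d)
      # growing from the seed beats the complement of the grown region
      box_mask <- matrix(0, 48, 48)
      b <- v$boxes$bone[[i]]
      box_mask[b[1]:b[3], b[2]:b[4]] <- 1
      expect_gt(d, dice(box_mask - pl$masks$bone[[i]], v$masks$bone[[i]]))
    }
  }
  expect_gt(mean(ds), 0.5)
})

test_that("volumes without boxes give empty pseudo-masks; with boxes, nonempty", {
  v <- tiny_phantom(n_cases = 1, slices = 3, size = 32, seed = 4)[[1]]
  nob <- lapply(v$boxes, function(per_tis) lapply(per_tis, function(b) NULL))
  pl0 <- pseudo_labels_for_volume(v, boxes = nob)
  expect_true(all(vapply(unlist(pl0$masks, recursive = FALSE), sum, 0) == 0))
  pl <- pseudo_labels_for_volume(v)
  for (tis in v$tissue_names)
    for (i in 1:3)
      if (!is.null(v$boxes[[tis]][[i]]))
        expect_gt(sum(pl$masks[[tis]][[i]]), 0)
})

test_that("boxes and seeds are validated", {
  img <- matrix(0.5, 8, 8)
  expect_error(select_seed(img, c(5, 5, 3, 3), "bone"), "box")
  expect_error(select_seed(img, c(1, 1, 9, 4), "bone"), "box")
  expect_error(region_grow(img, c(1, 1), c(2, 2, 5, 5), grow_params("bone")), "seed")
  expect_error(grow_params("bone", area_ratio_stop = 0), "area_ratio_stop")
})

test_that("pseudo-labels round-trip to disk with a confidence report", {
  v <- tiny_phantom(n_cases = 1, slices = 2, size = 32, seed = 44)[[1]]
  pl <- pseudo_labels_for_volume(v)
  d <- withr::local_tempdir()
  write_pseudo_labels(v, pl, d)
  expect_true(file.exists(file.path(d, paste0(v$case_id, "_pseudo_bone.nii.gz"))))
  expect_true(file.exists(file.path(d, paste0(v$case_id, "_pseudo_confidence.json"))))
  back <- as.array(RNifti::readNifti(file.path(d, paste0(v$case_id, "_pseudo_bone.nii.gz"))))
  expect_equal(back[, , 1], pl$masks$bone[[1]])
})
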