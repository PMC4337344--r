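# Synthetic hormone panels and BOLD-like studies.

small_design <- function(n_scans = 8, n_frames = 60)
  study_design(n_scans = n_scans, n_frames = n_frames)

test_that("hormone simulation is reproducible and follows the cycle contract", {
  p1 <- simulate_hormone_cycle(rng_seed = 7)
  p2 <- simulate_hormone_cycle(rng_seed = 7)
  expect_identical(p1, p2)
  p3 <- simulate_hormone_cycle(rng_seed = 8)
  expect_false(identical(p1$progesterone, p3$progesterone))

  # the noiseless curves: two estradiol peaks, LH surge between the
  # periovulatory estradiol peak and ovulation
  params <- cycle_params()
  cur <- hormone_curves(params, seq(1, 28, by = 0.1))
  e2 <- cur$estradiol
  n_max <- sum(diff(sign(diff(e2))) == -2)
  expect_gte(n_max, 2)
  e2_first_peak <- cur$day[which(diff(sign(diff(e2))) == -2)[1] + 1]
  lh_argmax <- cur$day[which.max(cur$lh)]
  expect_gte(lh_argmax, e2_first_peak)
  expect_lte(lh_argmax, params$ovulation_day)
})

test_that("each session starts on its own cycle day with 2/3-day spacing", {
  p <- simulate_hormone_cycle(rng_seed = 9)
  d1 <- p$cycle_day[p$session_id == 1]
  d2 <- p$cycle_day[p$session_id == 2]
  expect_equal(d1[1], 2)
  expect_equal(d2[1], 6)
  expect_true(all(diff(d1) %% 28 %in% c(2, 3)))
  expect_true(all(p$cycle_day >= 1 & p$cycle_day <= 28))
})

test_that("scan simulation is bitwise reproducible", {
  des <- small_design()
  truth <- ground_truth()
  v1 <- simulate_scan(des, truth, 1, rng_seed = 31)
  v2 <- simulate_scan(des, truth, 1, rng_seed = 31)
  expect_identical(v1$data, v2$data)
  v3 <- simulate_scan(des, truth, 1, rng_seed = 32)
  expect_false(identical(v1$data, v3$data))
  expect_error(simulate_scan(des, truth, 99, rng_seed = 1), "out of range")
})

test_that("coupling raises inter-region correlation above background", {
  des <- small_design(n_frames = 120)
  truth <- ground_truth(coupling = list(list(roi_a = "dlpfc_L",
                                             roi_b = "hippocampus_L",
                                             alpha = 0.8, beta = 0)))
  v <- simulate_scan(des, truth, 1, rng_seed = 41)
  m <- matrix(v$data, ncol = des$n_frames)
  a <- m[roi_lin(truth, "dlpfc_L")[1:12], ]
  b <- m[roi_lin(truth, "hippocampus_L")[1:12], ]
  bg <- m[setdiff(seq_len(nrow(m)),
                  unlist(lapply(names(truth$rois), roi_lin,
                                truth = truth)))[1:40], ]
  cross <- mean(cor(t(a), t(b)))
  background <- mean(abs(cor(t(bg))[upper.tri(diag(40))]))
  expect_gt(cross, background)
  # with alpha = 0.8 the expected pair correlation is ~0.39
  expect_gt(cross, 0.2)
})

test_that("a null scan shows only noise-level inter-region correlation", {
  des <- small_design(n_frames = 120)
  truth <- ground_truth(coupling = list(list(roi_a = "dlpfc_L",
                                             roi_b = "hippocampus_L",
                                             alpha = 0, beta = 0)))
  v <- simulate_scan(des, truth, 1, rng_seed = 43)
  m <- matrix(v$data, ncol = des$n_frames)
  a <- m[roi_lin(truth, "dlpfc_L"), ]
  b <- m[roi_lin(truth, "hippocampus_L"), ]
  cross <- cor(t(a), t(b))
  # independent AR(1) series: var(r) ~ (1/T) (1 + phi^2) / (1 - phi^2),
  # so mean |r| ~ sqrt(2/pi) * sd(r); allow 3 standard errors of the mean
  # (pairs share voxels, so count them as ~T^2/4 independent draws)
  phi <- truth$ar_coef
  sd_r <- sqrt((1 + phi^2) / (1 - phi^2) / des$n_frames)
  expect_lt(abs(mean(abs(cross)) - sqrt(2 / pi) * sd_r),
            3 * sd_r / sqrt(length(cross) / 4))
})

test_that("study bundles are internally consistent and reproducible", {
  des <- small_design()
  st <- simulate_study(design = des, rng_seed = 51)
  expect_length(st$volumes, des$n_scans)
  expect_equal(nrow(st$panel), des$n_scans)
  # manifest weights equal alpha + beta * z_progesterone from the panel
  cp <- st$truth$coupling[[1]]
  expect_equal(st$truth$w_scan[, 1],
               cp$alpha + cp$beta * st$panel$z_progesterone,
               tolerance = 1e-12)
  # same seed reproduces; another seed differs but keeps the layout
  st2 <- simulate_study(design = des, rng_seed = 51)
  expect_identical(st$volumes[[3]]$data, st2$volumes[[3]]$data)
  st3 <- simulate_study(design = des, rng_seed = 52)
  expect_false(identical(st$volumes[[3]]$data, st3$volumes[[3]]$data))
  expect_identical(st$truth$rois, st3$truth$rois)
})

test_that("default full study yields 32 volumes in two sessions of 16", {
  # hormone panel carries the session structure; volumes follow panel order
  st <- simulate_study(design = study_design(n_frames = 10), rng_seed = 53)
  expect_length(st$volumes, 32)
  expect_equal(as.vector(table(st$panel$session_id)), c(16, 16))
  expect_identical(names(st$volumes), st$panel$scan_id)
})

test_that("the generated gray-matter volume masks in every region voxel", {
  des <- small_design()
  truth <- ground_truth()
  gm <- gm_probability(truth, des)
  mask <- make_gm_mask(gm)          # default 4 mm, 0.12
  all_roi <- unlist(lapply(names(truth$rois), roi_lin, truth = truth))
  expect_true(all(all_roi %in% mask$ordering))
  # and leaves background for null statistics
  expect_gt(mask$n_voxels, length(unique(all_roi)))
})

test_that("written studies round trip through NIfTI and CSV", {
  dir <- file.path(tempdir(), "study_out")
  des <- study_design(n_scans = 4, n_frames = 20)
  st <- simulate_study(design = des, rng_seed = 61, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_volume(file.path(dir, paste0(st$panel$scan_id[2], ".nii.gz")))
  expect_identical(back$data, st$volumes[[2]]$data)
  panel <- load_hormone_table(file.path(dir, "hormones.csv"))
  expect_equal(panel$progesterone, st$panel$progesterone)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$rng_seed, 61)
  expect_equal(as.vector(unlist(man$w_scan)), as.vector(st$truth$w_scan),
               tolerance = 1e-12)
})
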