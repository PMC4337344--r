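# Second-level GLM, contrasts, FWE arithmetic, cluster formation.

test_that("the two-session hormone design has the expected structure", {
  panel <- simulate_hormone_cycle(rng_seed = 1)
  des <- build_design(panel, interest = "progesterone",
                      nuisance = "cortisol")
  expect_identical(dim(des$X), c(32L, 4L))
  expect_equal(des$rank, 4)
  expect_equal(des$df_residual, 28)
  expect_identical(colnames(des$X),
                   c("session1", "session2", "progesterone", "cortisol"))
  # session indicators are exclusive 0/1
  expect_true(all(rowSums(des$X[, 1:2]) == 1))
  # covariates centered
  expect_equal(mean(des$X[, "progesterone"]), 0, tolerance = 1e-12)

  expect_error(build_design(panel, interest = c("progesterone",
                                                "progesterone")),
               "collinear")
  expect_error(build_design(panel, interest = "serotonin"), "unknown")
})

test_that("voxel-wise OLS matches the closed-form simple regression", {
  set.seed(9)
  n <- 20
  panel <- simulate_hormone_cycle(design = study_design(n_scans = n),
                                  rng_seed = 2)
  panel$session_id <- rep(1, n)   # single session => plain intercept
  x <- panel$z_progesterone
  maps <- matrix(rnorm(n * 50), n, 50)
  des <- build_design(panel, interest = "progesterone")
  fit <- fit_glm(maps, des)
  xc <- x - mean(x)
  slope_oracle <- colSums(xc * maps) / sum(xc^2)
  expect_lt(max(abs(fit$coefficients["progesterone", ] - slope_oracle)),
            1e-10)
  int_oracle <- colMeans(maps) - slope_oracle * mean(x)
  expect_lt(max(abs(fit$coefficients["session1", ] - int_oracle)), 1e-10)
  # residual variance matches lm() on one voxel
  lmfit <- lm(maps[, 7] ~ x)
  expect_equal(fit$sigma2[7], summary(lmfit)$sigma^2, tolerance = 1e-10)
  # and the contrast t matches lm's t statistic
  st <- t_contrast(fit, "progesterone")
  expect_equal(st$t[7], summary(lmfit)$coefficients["x", "t value"],
               tolerance = 1e-10)
  expect_equal(st$df, n - 2)
})

test_that("noiseless maps are fitted exactly", {
  panel <- simulate_hormone_cycle(rng_seed = 3)
  des <- build_design(panel, interest = "progesterone")
  maps <- matrix(2 * des$X[, "progesterone"], ncol = 1)
  fit <- fit_glm(maps, des)
  expect_equal(unname(fit$coefficients["progesterone", 1]), 2,
               tolerance = 1e-12)
  expect_equal(fit$sigma2[1], 0, tolerance = 1e-20)
  st <- t_contrast(fit, "progesterone")
  expect_identical(st$t[1], Inf)
  expect_equal(st$p[1], .Machine$double.xmin)
})

test_that("a zero effect gives t = 0, one-sided p = 0.5, Z = 0", {
  panel <- simulate_hormone_cycle(rng_seed = 4)
  des <- build_design(panel, interest = "progesterone")
  x <- des$X[, "progesterone"]
  set.seed(2)
  y <- rnorm(32)
  y <- resid(lm(y ~ des$X - 1)) + des$X[, 1:2] %*% c(1, 1)  # orthogonal to x
  fit <- fit_glm(matrix(y, ncol = 1), des)
  st <- t_contrast(fit, "progesterone")
  expect_equal(st$t[1], 0, tolerance = 1e-10)
  expect_equal(st$p[1], 0.5, tolerance = 1e-10)
  expect_equal(st$z[1], 0, tolerance = 1e-8)
})

test_that("hormone t values are invariant to map offsets and raw units", {
  panel <- simulate_hormone_cycle(rng_seed = 6)
  set.seed(3)
  maps <- matrix(rnorm(32 * 40), 32, 40)
  des <- build_design(panel, interest = "progesterone",
                      nuisance = "cortisol")
  t0 <- t_contrast(fit_glm(maps, des), "progesterone")$t
  # adding a constant to every map only moves the session coefficients
  fit_shift <- fit_glm(maps + 5, des)
  expect_equal(t_contrast(fit_shift, "progesterone")$t, t0,
               tolerance = 1e-8)
  # raw-unit covariates give identical t values
  des_raw <- build_design(panel, interest = "progesterone",
                          nuisance = "cortisol", use_z = FALSE)
  t_raw <- t_contrast(fit_glm(maps, des_raw), "progesterone")$t
  expect_equal(t_raw, t0, tolerance = 1e-8)
})

test_that("FWE adjustment matches direct evaluation and is monotone", {
  expect_equal(fwe_adjust(0.001, 575), 0.575)
  expect_equal(fwe_adjust(0.01, 575), 1)
  expect_equal(fwe_adjust(0.001, 575, method = "sidak"), 1 - 0.999^575)
  expect_error(fwe_adjust(0, 10), "\\(0, 1\\]")
  expect_error(fwe_adjust(0.1, 0), ">= 1")
})

test_that("cluster formation matches the flood-fill oracle", {
  d <- c(8, 8, 6)
  mask <- full_mask(d)

  # L-shaped blob of 25 face-connected voxels: one cluster everywhere
  arr <- array(FALSE, dim = d)
  arr[2:6, 2, 2] <- TRUE            # 5
  arr[2, 3:6, 2] <- TRUE            # +4
  arr[2:5, 2, 3:6] <- TRUE          # +16 => 25
  p <- rep(0.5, mask$n_voxels)
  p[match(which(arr), mask$ordering)] <- 1e-5
  for (conn in c(6, 18, 26)) {
    tab <- form_clusters(stat_from_p(p), mask, connectivity = conn)
    expect_equal(nrow(tab), 1)
    expect_equal(tab$k_e, 25)
    expect_identical(sort(attr(tab, "voxels")[[1]]), which(arr))
  }

  # two blobs touching only at a corner: split under 18, merged under 26
  arr2 <- array(FALSE, dim = d)
  arr2[2:3, 2:3, 2:3] <- TRUE
  arr2[4:5, 4:5, 4:5] <- TRUE
  p2 <- rep(0.5, mask$n_voxels)
  p2[match(which(arr2), mask$ordering)] <- 1e-5
  expect_equal(nrow(form_clusters(stat_from_p(p2), mask,
                                  connectivity = 18)), 2)
  expect_equal(nrow(form_clusters(stat_from_p(p2), mask,
                                  connectivity = 26)), 1)

  # random volumes against the igraph oracle
  set.seed(12)
  for (rep in 1:5) {
    supra <- array(runif(prod(d)) < 0.18, dim = d)
    pr <- rep(0.5, mask$n_voxels)
    pr[match(which(supra), mask$ordering)] <- 1e-5
    for (conn in c(6, 18, 26)) {
      tab <- form_clusters(stat_from_p(pr), mask, connectivity = conn)
      want <- oracle_components(supra, conn)
      got <- lapply(attr(tab, "voxels"), sort)
      expect_setequal(vapply(got, paste, "", collapse = ","),
                      vapply(want, paste, "", collapse = ","))
    }
  }
})

test_that("the extent filter drops exactly the small components", {
  d <- c(10, 6, 6)
  mask <- full_mask(d)
  arr <- array(FALSE, dim = d)
  arr[1:3, 1:3, 1:3] <- TRUE                 # 27 voxels
  arr[8, 5, 5] <- TRUE                       # singleton
  p <- rep(0.5, mask$n_voxels)
  p[match(which(arr), mask$ordering)] <- 1e-5
  tab0 <- form_clusters(stat_from_p(p), mask, extent_threshold = 0)
  expect_equal(sort(tab0$k_e), c(1, 27))
  tab20 <- form_clusters(stat_from_p(p), mask, extent_threshold = 20)
  expect_equal(tab20$k_e, 27)
  # a single supra-threshold voxel with extent threshold 20: empty table
  p1 <- rep(0.5, mask$n_voxels)
  p1[40] <- 1e-5
  expect_equal(nrow(form_clusters(stat_from_p(p1), mask,
                                  extent_threshold = 20)), 0)
  # k > 27 is not "exceeded" by 27
  expect_equal(nrow(form_clusters(stat_from_p(p), mask,
                                  extent_threshold = 27)), 0)
})

test_that("cluster labeling is mirror-stable and peaks carry mm coordinates", {
  d <- c(8, 6, 6)
  mask <- full_mask(d)
  set.seed(99)
  pvals <- runif(mask$n_voxels, 0.002, 1)
  hot <- array(FALSE, dim = d)
  hot[2:4, 2:4, 2:4] <- TRUE
  pvals[match(which(hot), mask$ordering)] <-
    runif(sum(hot), 1e-8, 1e-4)   # distinct values: unique peaks
  tab <- form_clusters(stat_from_p(pvals), mask)
  # mirrored volume yields mirrored clusters with identical extents
  parr <- array(pvals, dim = d)
  tabm <- form_clusters(stat_from_p(as.vector(parr[d[1]:1, , ])), mask)
  expect_setequal(tab$k_e, tabm$k_e)
  expect_equal(tabm$x_mm, -tab$x_mm)   # centred affine flips sign
  expect_equal(tabm$y_mm, tab$y_mm)
  # the peak lies inside its cluster
  pk_lin <- which(array(replace(rep(FALSE, prod(d)), mask$ordering,
                                pvals == min(pvals)), d))
  expect_true(any(pk_lin %in% attr(tab, "voxels")[[1]]))
})
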