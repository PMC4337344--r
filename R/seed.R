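# Seed-based functional connectivity: spherical seeds, Fisher-z maps,
# progesterone-covariate second level.

#' Define a spherical seed region
#'
#' Includes every in-mask voxel whose centre lies within `radius_mm`
#' (Euclidean, world space) of `center_mm`.
#'
#' @param center_mm World mm coordinates, length 3.
#' @param radius_mm Sphere radius in mm, >= 0.
#' @param mask A `gm_mask` (supplies the affine and the candidate voxels).
#' @param label Optional seed label.
#' @return An object of class `seed_spec`: `center_mm`, `radius_mm`,
#'   `label`, `voxels` (grid linear indices), `mask_index` (positions in the
#'   mask ordering).
#' @export
make_sphere_seed <- function(center_mm, radius_mm, mask, label = NULL) {
  stopifnot(inherits(mask, "gm_mask"), length(center_mm) == 3)
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || radius_mm < 0)
    stop("make_sphere_seed: radius_mm must be a single non-negative number")
  xyz <- mask_coordinates(mask)
  d2 <- colSums((t(xyz) - center_mm)^2)
  inside <- which(d2 <= radius_mm^2 + 1e-12)
  if (length(inside) == 0)
    stop("make_sphere_seed: no in-mask voxel centre within ", radius_mm,
         " mm of (", paste(center_mm, collapse = ", "), ")")
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 label = label, voxels = mask$ordering[inside],
                 mask_index = inside),
            class = "seed_spec")
}

#' @export
print.seed_spec <- function(x, ...) {
  cat("<seed_spec> ", if (!is.null(x$label)) paste0(x$label, ": "),
      length(x$voxels), " voxel(s), radius ", x$radius_mm, " mm at (",
      paste(round(x$center_mm, 1), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' Mean seed time course
#'
#' Unweighted mean of the seed voxels' time series.
#'
#' @param vol4d A `volume4d`.
#' @param seed A `seed_spec`.
#' @return Numeric vector of length T.
#' @export
seed_timecourse <- function(vol4d, seed) {
  stopifnot(inherits(vol4d, "volume4d"), inherits(seed, "seed_spec"))
  d <- dim(vol4d$data)
  m <- matrix(vol4d$data, nrow = prod(d[1:3]), ncol = d[4])
  colMeans(m[seed$voxels, , drop = FALSE])
}

#' Seed-based Fisher-z connectivity map for one scan
#'
#' Pearson correlation of every in-mask voxel time course with the mean seed
#' time course, Fisher transformed (`z = atanh(r)` with `|r|` clamped to
#' `1 - 1e-7` so the map stays finite). Seed voxels are retained in the map
#' and flagged.
#'
#' @param vol4d A `volume4d`.
#' @param seed A `seed_spec` built on `mask`.
#' @param mask A `gm_mask`.
#' @return An object of class `connectivity_map`: `z` (length
#'   `mask$n_voxels`), `r`, `seed_flag` (logical), `seed`.
#' @export
connectivity_map <- function(vol4d, seed, mask) {
  tc <- seed_timecourse(vol4d, seed)
  if (stats::sd(tc) == 0)
    stop("connectivity_map: seed time course is constant")
  ts <- extract_timeseries(vol4d, mask)
  zt <- center_and_normalize_rows(ts)
  tcn <- (tc - mean(tc))
  tcn <- tcn / sqrt(sum(tcn^2))
  r <- drop(zt %*% tcn)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  seed_flag <- logical(mask$n_voxels)
  seed_flag[seed$mask_index] <- TRUE
  structure(list(z = atanh(r), r = r, seed_flag = seed_flag, seed = seed),
            class = "connectivity_map")
}

#' Second-level GLM over seed connectivity maps
#'
#' Stacks one Fisher-z connectivity map per scan (panel order), fits the
#' session-indicator + covariate design, tests the positive one-sided
#' contrast on the covariate, and forms clusters at an uncorrected
#' voxel-wise threshold with an extent filter (defaults: p < 0.005,
#' k > 20).
#'
#' @param maps List of `connectivity_map` objects, one per panel row, or a
#'   scan-by-voxel numeric matrix of z values.
#' @param panel A `hormone_panel`.
#' @param mask The `gm_mask` the maps live on.
#' @param covariate Covariate of interest (default `"progesterone"`).
#' @param nuisance Nuisance covariates (default none).
#' @param voxel_p Cluster-forming uncorrected p (default 0.005).
#' @param extent Exceeded-extent threshold in voxels (default 20, i.e.
#'   k > 20).
#' @param connectivity Cluster connectivity (default 18).
#' @param use_z_covariate Use z-standardized covariate values (default
#'   `TRUE`).
#' @return A `cluster_table`; attribute `stat` carries the underlying
#'   `stat_map`.
#' @export
seed_second_level <- function(maps, panel, mask, covariate = "progesterone",
                              nuisance = character(0), voxel_p = 0.005,
                              extent = 20, connectivity = 18,
                              use_z_covariate = TRUE) {
  if (is.list(maps) && !is.matrix(maps))
    maps <- do.call(rbind, lapply(maps, function(m) {
      stopifnot(inherits(m, "connectivity_map"))
      m$z
    }))
  if (nrow(maps) != nrow(panel))
    stop("seed_second_level: ", nrow(maps), " maps but ", nrow(panel),
         " panel rows")
  design <- build_design(panel, interest = covariate, nuisance = nuisance,
                         use_z = use_z_covariate)
  fit <- fit_glm(maps, design)
  stat <- t_contrast(fit, covariate, alternative = "greater")
  tab <- form_clusters(stat, mask, voxel_p_threshold = voxel_p,
                       extent_threshold = extent,
                       connectivity = connectivity)
  attr(tab, "stat") <- stat
  tab
}
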