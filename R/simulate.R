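# Synthetic study generator: menstrual-cycle hormone panels and 4D
# BOLD-like volumes with known, hormone-modulated coupling.
#
# Hormone concentrations are in arbitrary units; the analysis consumes
# z-standardized values, so units never enter any statistic.

#' Menstrual-cycle hormone curve parameters
#'
#' Parametric per-day serum curves over one cycle: estradiol as a sum of two
#' Gaussian bumps (a dominant periovulatory peak the day before ovulation
#' and a smaller mid-luteal peak), progesterone as a smoothed rectangle
#' (low follicular, plateau through the luteal phase, falling premenstrually),
#' LH as a narrow Gaussian surge one day after the estradiol peak (i.e. at
#' ovulation day), and cortisol as hormone-independent noise. Multiplicative
#' log-normal measurement noise is applied per scan.
#'
#' @param cycle_length Cycle length in days (default 28).
#' @param ovulation_day Ovulation day (default 14); must satisfy
#'   `0 < ovulation_day < cycle_length`.
#' @param e2_baseline,e2_ovul_amp,e2_ovul_sd Estradiol baseline and
#'   periovulatory bump amplitude / width (days); the bump is centred at
#'   `ovulation_day - 1`.
#' @param e2_luteal_amp,e2_luteal_sd Mid-luteal estradiol bump (centred at
#'   `ovulation_day + 7`).
#' @param p4_baseline,p4_amp Progesterone baseline and luteal plateau
#'   amplitude.
#' @param p4_rise_day,p4_fall_day,p4_rate Logistic rise / fall midpoints
#'   (days) and rate (days).
#' @param lh_baseline,lh_amp,lh_sd LH baseline, surge amplitude and surge
#'   width (days).
#' @param cortisol_mean,cortisol_sd Cortisol level (uncoupled noise).
#' @param noise_cv Log-scale sd of the multiplicative measurement noise.
#' @return A list of class `cycle_params`.
#' @export
cycle_params <- function(cycle_length = 28, ovulation_day = 14,
                         e2_baseline = 0.4, e2_ovul_amp = 2, e2_ovul_sd = 1.5,
                         e2_luteal_amp = 1, e2_luteal_sd = 3,
                         p4_baseline = 0.15, p4_amp = 3,
                         p4_rise_day = NULL, p4_fall_day = NULL, p4_rate = 1,
                         lh_baseline = 0.3, lh_amp = 5, lh_sd = 1,
                         cortisol_mean = 1, cortisol_sd = 0.15,
                         noise_cv = 0.08) {
  if (ovulation_day <= 0 || ovulation_day >= cycle_length)
    stop("cycle_params: need 0 < ovulation_day < cycle_length")
  if (is.null(p4_rise_day)) p4_rise_day <- ovulation_day + 2
  if (is.null(p4_fall_day)) p4_fall_day <- cycle_length - 2
  p <- list(cycle_length = cycle_length, ovulation_day = ovulation_day,
            e2_baseline = e2_baseline, e2_ovul_amp = e2_ovul_amp,
            e2_ovul_sd = e2_ovul_sd, e2_luteal_amp = e2_luteal_amp,
            e2_luteal_sd = e2_luteal_sd, p4_baseline = p4_baseline,
            p4_amp = p4_amp, p4_rise_day = p4_rise_day,
            p4_fall_day = p4_fall_day, p4_rate = p4_rate,
            lh_baseline = lh_baseline, lh_amp = lh_amp, lh_sd = lh_sd,
            cortisol_mean = cortisol_mean, cortisol_sd = cortisol_sd,
            noise_cv = noise_cv)
  amps <- c(e2_ovul_amp, e2_luteal_amp, p4_amp, lh_amp)
  if (any(amps < 0)) stop("cycle_params: amplitudes must be >= 0")
  structure(p, class = "cycle_params")
}

#' Noiseless hormone curves over cycle days
#'
#' @param params A `cycle_params`.
#' @param day Numeric vector of cycle days (1 = menses onset).
#' @return `data.frame` with columns `day`, `estradiol`, `progesterone`,
#'   `lh`.
#' @export
hormone_curves <- function(params, day = seq(1, params$cycle_length, by = 0.25)) {
  stopifnot(inherits(params, "cycle_params"))
  bump <- function(d, center, sd) exp(-(d - center)^2 / (2 * sd^2))
  e2_peak <- params$ovulation_day - 1
  estradiol <- params$e2_baseline +
    params$e2_ovul_amp * bump(day, e2_peak, params$e2_ovul_sd) +
    params$e2_luteal_amp * bump(day, params$ovulation_day + 7,
                                params$e2_luteal_sd)
  progesterone <- params$p4_baseline +
    params$p4_amp * stats::plogis((day - params$p4_rise_day) / params$p4_rate) *
      stats::plogis((params$p4_fall_day - day) / params$p4_rate)
  lh <- params$lh_baseline +
    params$lh_amp * bump(day, e2_peak + 1, params$lh_sd)
  data.frame(day = day, estradiol = estradiol, progesterone = progesterone,
             lh = lh)
}

#' Longitudinal study design
#'
#' Defaults mirror a two-session, 32-scan longitudinal protocol: 16 scans
#' per session taken every second or third day (alternating 2/3-day
#' spacing), each session starting on a different menstrual-cycle day, on a
#' small 3 mm isotropic grid.
#'
#' @param n_scans Total scans (default 32); must be divisible by
#'   `n_sessions`.
#' @param n_sessions Number of scanning sessions (default 2).
#' @param session_start_days Cycle day on which each session starts
#'   (default `c(2, 6)`).
#' @param spacing Repeating between-scan spacing pattern in days (default
#'   `c(2, 3)`).
#' @param grid_dim Spatial grid (default `c(24, 24, 12)`).
#' @param voxel_size_mm Isotropic voxel size (default 3).
#' @param n_frames Frames per scan (default 120; set 300 for a
#'   full-protocol run).
#' @param tr_seconds Repetition time (default 2).
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_scans = 32, n_sessions = 2,
                         session_start_days = c(2, 6), spacing = c(2, 3),
                         grid_dim = c(24, 24, 12), voxel_size_mm = 3,
                         n_frames = 120, tr_seconds = 2) {
  if (n_scans %% n_sessions != 0)
    stop("study_design: n_scans must be divisible by n_sessions")
  if (length(session_start_days) != n_sessions)
    stop("study_design: need one session_start_day per session")
  if (n_frames < 3) stop("study_design: n_frames must be >= 3")
  structure(list(n_scans = n_scans, n_sessions = n_sessions,
                 scans_per_session = n_scans / n_sessions,
                 session_start_days = session_start_days, spacing = spacing,
                 grid_dim = as.integer(grid_dim),
                 voxel_size_mm = voxel_size_mm, n_frames = n_frames,
                 tr_seconds = tr_seconds),
            class = "study_design")
}

# default bilateral ROI boxes on the standard 24 x 24 x 12 grid, scaled to
# other grids proportionally; each box is 4 x 4 x 3 voxels (48 voxels)
default_rois <- function(grid_dim = c(24, 24, 12)) {
  box <- function(x0, y0, z0) {
    g <- expand.grid(i = x0:(x0 + 3), j = y0:(y0 + 3), k = z0:(z0 + 2))
    as.matrix(g)
  }
  s <- grid_dim / c(24, 24, 12)
  at <- function(x, y, z) box(round(x * s[1]), round(y * s[2]), round(z * s[3]))
  list(dlpfc_L = at(4, 16, 7), dlpfc_R = at(17, 16, 7),
       sensorimotor_L = at(5, 9, 9), sensorimotor_R = at(16, 9, 9),
       hippocampus_L = at(6, 5, 3), hippocampus_R = at(15, 5, 3))
}

#' Ground truth for a synthetic study
#'
#' Defines the region layout, the hormone-coupled connectivity model, and the
#' noise model. Each coupling entry names two regions whose voxels share a
#' latent standard-normal signal with scan-specific weight
#' `w_scan = alpha + beta * z_progesterone(scan)`; `beta = 0` (or
#' `coupling = list()`) defines a null study. All other variance is AR(1)
#' noise per voxel.
#'
#' @param grid_dim Spatial grid the regions live on.
#' @param rois Named list of n x 3 voxel-index matrices (1-based).
#' @param coupling List of couplings, each
#'   `list(roi_a=, roi_b=, alpha=, beta=)`.
#' @param ar_coef AR(1) coefficient of the voxel noise (default 0.3).
#' @param noise_sd Marginal noise standard deviation (default 1).
#' @param session_signal_sd Per-session weights of a global shared signal
#'   (default all 0), used to emulate session-level connectivity offsets.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(grid_dim = c(24, 24, 12),
                         rois = default_rois(grid_dim),
                         coupling = list(list(roi_a = "dlpfc_R",
                                              roi_b = "hippocampus_R",
                                              alpha = 0.25, beta = 0.15)),
                         ar_coef = 0.3, noise_sd = 1,
                         session_signal_sd = NULL) {
  for (cp in coupling) {
    if (!all(c(cp$roi_a, cp$roi_b) %in% names(rois)))
      stop("ground_truth: coupling names unknown region(s)")
  }
  if (abs(ar_coef) >= 1) stop("ground_truth: |ar_coef| must be < 1")
  structure(list(grid_dim = as.integer(grid_dim), rois = rois,
                 coupling = coupling, ar_coef = ar_coef, noise_sd = noise_sd,
                 session_signal_sd = session_signal_sd),
            class = "ground_truth")
}

#' Null-study ground truth
#'
#' Same layout and noise as [ground_truth()] but every coupling weight is
#' constant across scans (`beta = 0`), so no hormone-connectivity
#' association exists.
#'
#' @param ... Passed to [ground_truth()].
#' @param alpha Constant coupling weight (default 0.25).
#' @return A `ground_truth` with `beta = 0` couplings.
#' @export
null_ground_truth <- function(..., alpha = 0.25) {
  gt <- ground_truth(...)
  gt$coupling <- lapply(gt$coupling, function(cp) {
    cp$alpha <- alpha; cp$beta <- 0; cp
  })
  gt
}

roi_linear_indices <- function(truth, roi_name) {
  ijk <- truth$rois[[roi_name]]
  d <- truth$grid_dim
  ijk[, 1] + d[1] * (ijk[, 2] - 1) + d[1] * d[2] * (ijk[, 3] - 1)
}

#' Gray-matter probability volume matching a ground truth
#'
#' Probability 1 inside every region and a one-voxel surrounding shell,
#' 0 elsewhere; with the default mask settings (4 mm smoothing, 0.12
#' threshold) the resulting mask contains every region voxel plus
#' surrounding background for null statistics.
#'
#' @param truth A `ground_truth`.
#' @param design A `study_design` (supplies the voxel size / affine).
#' @return A `volume3d` of probabilities.
#' @export
gm_probability <- function(truth, design) {
  d <- truth$grid_dim
  prob <- array(0, dim = d)
  for (nm in names(truth$rois)) prob[roi_linear_indices(truth, nm)] <- 1
  # one-voxel dilation shell
  core <- prob
  for (off in seq_len(nrow(connectivity_offsets(26)))) {
    o <- connectivity_offsets(26)[off, ]
    src <- which(core == 1)
    ijk <- arrayInd(src, d)
    nb <- sweep(ijk, 2, as.numeric(o), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    prob[nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)] <- 1
  }
  volume3d(prob, default_affine(d, rep(design$voxel_size_mm, 3)))
}

# deterministic sub-seed stream derived from one master seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Simulate a per-scan hormone panel
#'
#' Assigns each scan a cycle day (session start day plus the alternating
#' scan spacing, wrapped at the cycle length), evaluates the noiseless
#' hormone curves at those days, applies multiplicative log-normal
#' measurement noise, draws independent cortisol, and fills the
#' z-standardized columns (pooled over all scans).
#'
#' @param params A `cycle_params`.
#' @param design A `study_design`.
#' @param rng_seed Integer seed; identical seeds give identical panels.
#' @return A `hormone_panel` with 1 row per scan in session order.
#' @export
simulate_hormone_cycle <- function(params = cycle_params(),
                                   design = study_design(), rng_seed = 1) {
  stopifnot(inherits(params, "cycle_params"), inherits(design, "study_design"))
  with_seed(rng_seed, {
    rows <- list()
    for (s in seq_len(design$n_sessions)) {
      steps <- rep_len(design$spacing, design$scans_per_session - 1)
      days <- design$session_start_days[s] + c(0, cumsum(steps))
      cycle_day <- ((days - 1) %% params$cycle_length) + 1
      curves <- hormone_curves(params, cycle_day)
      n <- length(cycle_day)
      noise <- function() exp(stats::rnorm(n, 0, params$noise_cv))
      rows[[s]] <- data.frame(
        scan_id = sprintf("S%d_%02d", s, seq_len(n)),
        session_id = s, cycle_day = cycle_day,
        estradiol = curves$estradiol * noise(),
        progesterone = curves$progesterone * noise(),
        lh = curves$lh * noise(),
        cortisol = abs(stats::rnorm(n, params$cortisol_mean,
                                    params$cortisol_sd)))
    }
    panel <- do.call(rbind, rows)
    rownames(panel) <- NULL
    class(panel) <- c("hormone_panel", "data.frame")
    zstandardize(panel)
  })
}

# simulate one scan's 4D array (internal; weights = per-coupling w_scan)
simulate_scan_array <- function(design, truth, weights, session, rng_seed) {
  d <- design$grid_dim
  n_vox <- prod(d)
  Tn <- design$n_frames
  with_seed(rng_seed, {
    innov_sd <- truth$noise_sd * sqrt(1 - truth$ar_coef^2)
    start <- stats::rnorm(n_vox, 0, truth$noise_sd)
    e <- matrix(stats::rnorm((Tn - 1) * n_vox, 0, innov_sd), Tn - 1, n_vox)
    noise <- rbind(start, e)
    if (truth$ar_coef != 0)
      for (t in 2:Tn) noise[t, ] <- truth$ar_coef * noise[t - 1, ] + e[t - 1, ]
    arr <- noise
    for (ci in seq_along(truth$coupling)) {
      cp <- truth$coupling[[ci]]
      latent <- stats::rnorm(Tn)
      vox <- c(roi_linear_indices(truth, cp$roi_a),
               roi_linear_indices(truth, cp$roi_b))
      arr[, vox] <- arr[, vox] + weights[ci] * latent
    }
    if (!is.null(truth$session_signal_sd)) {
      w_sess <- truth$session_signal_sd[session]
      if (w_sess != 0) arr <- arr + w_sess * stats::rnorm(Tn)
    }
    array(t(arr), dim = c(d, Tn))
  })
}

#' Simulate one BOLD-like scan
#'
#' Every voxel carries AR(1) noise; voxels of each coupled region pair
#' additionally share `w_scan x` a latent standard-normal signal, where
#' `w_scan` comes from the study manifest (`alpha + beta * z_progesterone`).
#'
#' @param design A `study_design`.
#' @param truth A `ground_truth` carrying a `w_scan` matrix (filled by
#'   [simulate_study()]); pass `weights` to override.
#' @param scan_index Scan number within the design.
#' @param rng_seed Integer seed.
#' @param weights Optional numeric vector, one weight per coupling
#'   (defaults to `truth$w_scan[scan_index, ]`, or `alpha` if no panel has
#'   been attached).
#' @return A `volume4d`.
#' @export
simulate_scan <- function(design, truth, scan_index, rng_seed,
                          weights = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ground_truth"))
  if (scan_index < 1 || scan_index > design$n_scans)
    stop("simulate_scan: scan_index out of range")
  if (is.null(weights)) {
    weights <- if (!is.null(truth$w_scan)) truth$w_scan[scan_index, ]
    else vapply(truth$coupling, `[[`, numeric(1), "alpha")
  }
  session <- ceiling(scan_index / design$scans_per_session)
  arr <- simulate_scan_array(design, truth, weights, session, rng_seed)
  volume4d(arr, default_affine(design$grid_dim,
                               rep(design$voxel_size_mm, 3)),
           tr_seconds = design$tr_seconds)
}

#' Simulate a complete longitudinal study
#'
#' Generates the hormone panel, fills the per-scan coupling weights
#' `w_scan = alpha + beta * z_progesterone`, simulates every scan, and emits
#' the matching gray-matter probability volume plus a manifest tying scans
#' to hormone rows, weights and seeds. Fully reproducible from `rng_seed`.
#'
#' @param params A `cycle_params`.
#' @param design A `study_design`.
#' @param truth A `ground_truth`.
#' @param rng_seed Integer master seed.
#' @param dir Optional output directory: volumes are written as NIfTI, the
#'   panel as CSV, and the manifest as JSON.
#' @return List of class `synthetic_study`: `panel`, `volumes` (list of
#'   `volume4d`), `gm_prob`, `truth` (with `w_scan` filled), `manifest`.
#' @export
simulate_study <- function(params = cycle_params(), design = study_design(),
                           truth = ground_truth(design$grid_dim),
                           rng_seed = 1, dir = NULL) {
  seeds <- derive_seeds(rng_seed, design$n_scans + 1L)
  panel <- simulate_hormone_cycle(params, design, seeds[1])
  n_cp <- length(truth$coupling)
  w <- matrix(0, design$n_scans, max(1, n_cp))
  if (n_cp > 0)
    for (ci in seq_len(n_cp)) {
      cp <- truth$coupling[[ci]]
      w[, ci] <- cp$alpha + cp$beta * panel$z_progesterone
    }
  truth$w_scan <- w[, seq_len(max(1, n_cp)), drop = FALSE]
  volumes <- vector("list", design$n_scans)
  for (i in seq_len(design$n_scans))
    volumes[[i]] <- simulate_scan(design, truth, i, seeds[i + 1])
  names(volumes) <- panel$scan_id
  gm <- gm_probability(truth, design)
  manifest <- list(
    rng_seed = rng_seed, scan_seeds = seeds[-1], panel_seed = seeds[1],
    n_scans = design$n_scans, n_sessions = design$n_sessions,
    grid_dim = design$grid_dim, n_frames = design$n_frames,
    coupling = truth$coupling, w_scan = truth$w_scan,
    scan_id = panel$scan_id)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(volumes)) {
      f <- file.path(dir, paste0(panel$scan_id[i], ".nii.gz"))
      write_volume(volumes[[i]], f)
    }
    write_hormone_table(panel, file.path(dir, "hormones.csv"))
    write_volume(gm, file.path(dir, "gm_probability.nii.gz"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(panel = panel, volumes = volumes, gm_prob = gm,
                 truth = truth, manifest = manifest),
            class = "synthetic_study")
}
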