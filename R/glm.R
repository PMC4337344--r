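# Second-level voxel-wise GLM, t-contrasts, FWE correction, clustering.

#' Build a second-level design matrix
#'
#' One indicator column per scanning session (no global intercept, so the
#' session columns absorb per-session means), followed by the covariates of
#' interest and then the nuisance covariates. Hormone covariates default to
#' their z-standardized versions (`z_<name>` columns, computed on the fly if
#' absent); contrast t values are invariant to that choice. With
#' `interaction = TRUE` each covariate of interest is additionally split
#' into per-session columns (a session x covariate interaction).
#'
#' @param panel A `hormone_panel`; rows define the scan order.
#' @param interest Character vector of covariate-of-interest column names
#'   (raw names, e.g. `"progesterone"`).
#' @param nuisance Character vector of nuisance covariate names.
#' @param center Mean-center covariates (default `TRUE`; z-scored columns are
#'   centered by construction).
#' @param use_z Use z-standardized covariates (default `TRUE`).
#' @param interaction Add session x interest interaction columns (default
#'   `FALSE`).
#' @return An object of class `ecm_design`: list with `X` (named matrix),
#'   `rank`, `df_residual`, `interest`, `nuisance`, `sessions`.
#' @export
build_design <- function(panel, interest, nuisance = character(0),
                         center = TRUE, use_z = TRUE, interaction = FALSE) {
  validate_panel(panel)
  covars <- c(interest, nuisance)
  if (use_z && !all(paste0("z_", covars) %in% names(panel)))
    panel <- zstandardize(panel)
  get_cov <- function(nm) {
    col <- if (use_z) paste0("z_", nm) else nm
    if (!col %in% names(panel))
      stop("build_design: unknown covariate column '", nm, "'")
    x <- panel[[col]]
    if (center) x - mean(x) else x
  }
  sessions <- sort(unique(panel$session_id))
  X_sess <- sapply(sessions, function(s) as.numeric(panel$session_id == s))
  colnames(X_sess) <- paste0("session", sessions)
  X_int <- if (length(interest) > 0)
    sapply(interest, get_cov) else NULL
  X_nui <- if (length(nuisance) > 0)
    sapply(nuisance, get_cov) else NULL
  X <- cbind(X_sess, X_int, X_nui)
  colnames(X) <- c(colnames(X_sess), interest, nuisance)
  if (interaction && length(interest) > 0) {
    for (nm in interest) for (s in sessions[-1]) {
      X <- cbind(X, X[, nm] * as.numeric(panel$session_id == s))
      colnames(X)[ncol(X)] <- paste0(nm, ":session", s)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("build_design: design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- nrow(X) - qrX$rank
  if (df < 1)
    stop("build_design: no residual degrees of freedom (n = ", nrow(X),
         ", rank = ", qrX$rank, ")")
  structure(list(X = X, rank = qrX$rank, df_residual = df,
                 interest = interest, nuisance = nuisance,
                 sessions = sessions),
            class = "ecm_design")
}

#' @export
print.ecm_design <- function(x, ...) {
  cat("<ecm_design> ", nrow(x$X), " scans x ", ncol(x$X),
      " columns (", paste(colnames(x$X), collapse = ", "), "); df = ",
      x$df_residual, "\n", sep = "")
  invisible(x)
}

#' Fit the voxel-wise general linear model
#'
#' Ordinary least squares, solved once for all voxels:
#' `beta = (X'X)^-1 X' Y` with `Y` the scan-by-voxel map matrix. Residual
#' variance per voxel is `RSS / df_residual`.
#'
#' @param maps Numeric scan-by-voxel matrix, rows aligned with the design.
#' @param design An `ecm_design`.
#' @return An object of class `ecm_glm_fit`: `coefficients` (p x V),
#'   `sigma2` (length V), `xtx_inv`, `df_residual`, `design`.
#' @export
fit_glm <- function(maps, design) {
  stopifnot(inherits(design, "ecm_design"))
  maps <- as.matrix(maps)
  X <- design$X
  if (nrow(maps) != nrow(X))
    stop("fit_glm: maps have ", nrow(maps), " rows but design has ",
         nrow(X), " scans")
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- xtx_inv %*% crossprod(X, maps)
  rownames(beta) <- colnames(X)
  rss <- colSums((maps - X %*% beta)^2)
  # an exact fit leaves only rounding error; snap it to zero so downstream
  # contrasts report t = Inf rather than a rounding-driven finite value
  rss[rss <= 100 * nrow(X) * .Machine$double.eps^2 * colSums(maps^2)] <- 0
  structure(list(coefficients = beta, sigma2 = rss / design$df_residual,
                 xtx_inv = xtx_inv, df_residual = design$df_residual,
                 design = design),
            class = "ecm_glm_fit")
}

#' t-contrast over a fitted voxel-wise GLM
#'
#' For contrast weights `c`, computes `t = c'beta / sqrt(sigma2 c'(X'X)^-1 c)`
#' per voxel, the one-sided (or two-sided) p value from the t distribution
#' with the fit's residual degrees of freedom, and the equivalent Z score
#' (standard-normal quantile of the same tail probability, evaluated on the
#' log scale so extreme t values do not underflow). Voxels with zero residual
#' variance get `t = +/-Inf`; p values are floored at the smallest positive
#' double.
#'
#' @param fit An `ecm_glm_fit`.
#' @param weights Numeric contrast vector, one weight per design column, or a
#'   single design column name (weight 1 on that column).
#' @param alternative `"greater"` (default; positive correlation),
#'   `"less"`, or `"two.sided"`.
#' @return An object of class `stat_map`: list with `t`, `z`, `p`, `df`,
#'   `weights`, `alternative`.
#' @export
t_contrast <- function(fit, weights,
                       alternative = c("greater", "less", "two.sided")) {
  stopifnot(inherits(fit, "ecm_glm_fit"))
  alternative <- match.arg(alternative)
  X <- fit$design$X
  if (is.character(weights)) {
    nm <- weights
    if (!nm %in% colnames(X))
      stop("t_contrast: no design column named '", nm, "'")
    weights <- as.numeric(colnames(X) == nm)
  }
  if (length(weights) != ncol(X))
    stop("t_contrast: contrast length ", length(weights),
         " does not match ", ncol(X), " design columns")
  if (all(weights == 0))
    stop("t_contrast: contrast weights are all zero")
  cvar <- drop(t(weights) %*% fit$xtx_inv %*% weights)
  if (cvar <= 0) stop("t_contrast: contrast variance is not positive")
  eff <- drop(crossprod(weights, fit$coefficients))
  se <- sqrt(fit$sigma2 * cvar)
  tval <- ifelse(se > 0, eff / se, sign(eff) * Inf)
  tval[se == 0 & eff == 0] <- 0
  df <- fit$df_residual
  log_p <- switch(alternative,
    greater   = stats::pt(tval, df, lower.tail = FALSE, log.p = TRUE),
    less      = stats::pt(tval, df, lower.tail = TRUE, log.p = TRUE),
    two.sided = log(2) + stats::pt(abs(tval), df, lower.tail = FALSE,
                                   log.p = TRUE))
  log_p <- pmin(log_p, 0)
  z <- stats::qnorm(log_p, lower.tail = FALSE, log.p = TRUE)
  p <- pmax(exp(log_p), .Machine$double.xmin)
  structure(list(t = tval, z = z, p = p, df = df, weights = weights,
                 alternative = alternative),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", length(x$t), " voxels; df = ", x$df, "; max t = ",
      format(max(x$t)), "; ", x$alternative, " test\n", sep = "")
  invisible(x)
}

#' Family-wise error adjustment over resolution elements
#'
#' Adjusts uncorrected p values for `n_comparisons` effective tests (the
#' resel count): Bonferroni `min(1, n p)` or Sidak `1 - (1 - p)^n`.
#'
#' @param p Numeric vector of uncorrected p values in (0, 1].
#' @param n_comparisons Effective number of comparisons, >= 1.
#' @param method `"bonferroni"` (default) or `"sidak"`.
#' @return Adjusted p values, same length as `p`.
#' @export
fwe_adjust <- function(p, n_comparisons, method = c("bonferroni", "sidak")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("fwe_adjust: p values must lie in (0, 1]")
  if (!is.numeric(n_comparisons) || length(n_comparisons) != 1 ||
      n_comparisons < 1)
    stop("fwe_adjust: n_comparisons must be a single number >= 1")
  switch(method,
         bonferroni = pmin(1, n_comparisons * p),
         sidak = 1 - (1 - p)^n_comparisons)
}

#' Naive resel (resolution element) estimate
#'
#' Mask volume divided by the smoothing kernel volume:
#' `n_voxels * prod(voxel_size) / fwhm^3`. This is a deliberately crude
#' effective-comparison count that ignores data-driven smoothness estimation;
#' supply a resel count of your own (e.g. from the original analysis
#' software) when one is available.
#'
#' @param mask A `gm_mask`.
#' @param fwhm_mm Smoothing FWHM in mm.
#' @return A single number, at least 1.
#' @export
naive_resel_count <- function(mask, fwhm_mm) {
  stopifnot(inherits(mask, "gm_mask"), fwhm_mm > 0)
  vs <- sqrt(colSums(mask$affine[1:3, 1:3]^2))
  max(1, mask$n_voxels * prod(vs) / fwhm_mm^3)
}

# neighbor offsets for 6/18/26-connectivity
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  limit <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  off[nz >= 1 & nz <= limit, , drop = FALSE]
}

# label connected components of a logical 3D array; returns integer array
label_components <- function(mask_arr, connectivity) {
  d <- dim(mask_arr)
  off <- connectivity_offsets(connectivity)
  labels <- array(0L, dim = d)
  idx <- which(mask_arr)
  if (length(idx) == 0) return(labels)
  coords <- arrayInd(idx, d)
  lab <- 0L
  for (s in seq_along(idx)) {
    if (labels[idx[s]] != 0L) next
    lab <- lab + 1L
    queue <- matrix(coords[s, ], nrow = 1)
    labels[idx[s]] <- lab
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(off, 2, as.numeric(cur), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0) next
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      new <- lin[mask_arr[lin] & labels[lin] == 0L]
      if (length(new) > 0) {
        labels[new] <- lab
        queue <- rbind(queue, arrayInd(new, d))
      }
    }
  }
  labels
}

#' Threshold a stat map and form clusters
#'
#' Voxels with uncorrected p below `voxel_p_threshold` are labeled into
#' connected components under the chosen 3D connectivity; components whose
#' extent does not exceed `extent_threshold` voxels are dropped (an extent
#' filter of 20 keeps clusters with k > 20). Each surviving cluster is
#' reported with its extent, peak t / Z / p, the peak's world mm
#' coordinates, and (when a resel count is supplied) the FWE-adjusted peak
#' p value. Clusters are sorted by descending peak t.
#'
#' @param stat A `stat_map` over the in-mask voxels.
#' @param mask The `gm_mask` the stat map is aligned with.
#' @param voxel_p_threshold Cluster-forming uncorrected p (default 0.001).
#' @param extent_threshold Minimum exceeded extent in voxels (default 0:
#'   keep all).
#' @param connectivity 6, 18 (default) or 26.
#' @param fwe_n Optional resel count for peak-level FWE adjustment.
#' @param fwe_method `"bonferroni"` (default) or `"sidak"`.
#' @param fdr Add Benjamini-Hochberg adjusted peak p values (default
#'   `FALSE`).
#' @return A `data.frame` of class `cluster_table` with columns `cluster`,
#'   `k_e`, `peak_t`, `peak_z`, `peak_p_uncorr`, `peak_p_fwe`, `x_mm`,
#'   `y_mm`, `z_mm` (and `peak_p_fdr` if requested); attribute `voxels`
#'   holds each cluster's grid linear indices. Empty table when nothing
#'   survives.
#' @export
form_clusters <- function(stat, mask, voxel_p_threshold = 0.001,
                          extent_threshold = 0, connectivity = 18,
                          fwe_n = NULL, fwe_method = "bonferroni",
                          fdr = FALSE) {
  stopifnot(inherits(stat, "stat_map"), inherits(mask, "gm_mask"))
  if (length(stat$p) != mask$n_voxels)
    stop("form_clusters: stat map length does not match mask voxel count")
  if (voxel_p_threshold <= 0 || voxel_p_threshold > 1)
    stop("form_clusters: voxel_p_threshold must be in (0, 1]")
  supra <- array(FALSE, dim = mask$dim)
  supra[mask$ordering[stat$p < voxel_p_threshold]] <- TRUE
  labels <- label_components(supra, connectivity)
  n_lab <- max(labels)
  empty <- structure(
    data.frame(cluster = integer(0), k_e = integer(0), peak_t = numeric(0),
               peak_z = numeric(0), peak_p_uncorr = numeric(0),
               peak_p_fwe = numeric(0), x_mm = numeric(0), y_mm = numeric(0),
               z_mm = numeric(0)),
    voxels = list(), class = c("cluster_table", "data.frame"))
  if (n_lab == 0) return(empty)
  # per-voxel stats indexed by grid linear index
  t_grid <- array(NA_real_, dim = mask$dim)
  t_grid[mask$ordering] <- stat$t
  rows <- list()
  vox_list <- list()
  for (lab in seq_len(n_lab)) {
    vox <- which(labels == lab)
    if (length(vox) <= extent_threshold) next
    pk <- vox[which.max(t_grid[vox])]
    m <- match(pk, mask$ordering)
    mm <- voxel_to_world(arrayInd(pk, mask$dim), mask$affine)
    rows[[length(rows) + 1]] <- data.frame(
      cluster = NA_integer_, k_e = length(vox), peak_t = stat$t[m],
      peak_z = stat$z[m], peak_p_uncorr = stat$p[m],
      peak_p_fwe = if (is.null(fwe_n)) NA_real_ else
        fwe_adjust(stat$p[m], fwe_n, fwe_method),
      x_mm = mm[1], y_mm = mm[2], z_mm = mm[3])
    vox_list[[length(vox_list) + 1]] <- vox
  }
  if (length(rows) == 0) return(empty)
  tab <- do.call(rbind, rows)
  ord <- order(tab$peak_t, decreasing = TRUE)
  tab <- tab[ord, , drop = FALSE]
  vox_list <- vox_list[ord]
  tab$cluster <- seq_len(nrow(tab))
  if (fdr) tab$peak_p_fdr <- stats::p.adjust(tab$peak_p_uncorr, "BH")
  rownames(tab) <- NULL
  structure(tab, voxels = vox_list,
            class = c("cluster_table", "data.frame"))
}

#' Write a cluster table as TSV
#'
#' @param tab A `cluster_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
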