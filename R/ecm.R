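# Eigenvector centrality mapping: dense reference and matrix-free fast path.
#
# The voxel network is the N x N similarity matrix C = R + 1, where R holds
# pairwise Pearson correlations of the voxel time courses. All entries of C
# are positive (correlations exceed -1), so by Perron-Frobenius C has a
# unique real largest eigenvalue with a strictly positive eigenvector; its
# components are the voxel centralities.

#' Center and L2-normalize the rows of a time-series matrix
#'
#' After this transform the inner product of any two rows equals their
#' Pearson correlation, which is what makes the matrix-free centrality
#' iteration exact.
#'
#' @param ts Numeric voxel-by-time matrix; every row must have nonzero
#'   variance.
#' @return Matrix of the same shape with zero-mean, unit-norm rows.
#' @export
center_and_normalize_rows <- function(ts) {
  stopifnot(is.matrix(ts))
  if (!all(is.finite(ts)))
    stop("center_and_normalize_rows: non-finite values in input")
  z <- ts - rowMeans(ts)
  nrm <- sqrt(rowSums(z^2))
  bad <- which(nrm == 0)
  if (length(bad) > 0)
    stop("center_and_normalize_rows: zero-variance row(s) at voxel index ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  z / nrm
}

new_ec_map <- function(values, iterations, residual, eigenvalue) {
  structure(list(values = values, iterations = iterations,
                 residual = residual, eigenvalue = eigenvalue),
            class = "ec_map")
}

#' @export
print.ec_map <- function(x, ...) {
  cat("<ec_map> ", length(x$values), " voxels; lambda = ",
      format(x$eigenvalue), "; ", x$iterations, " iteration(s), residual ",
      format(x$residual), "\n", sep = "")
  invisible(x)
}

# positive sign convention for the Perron vector
fix_sign <- function(v) if (sum(v) < 0) -v else v

#' Eigenvector centrality by dense eigendecomposition (reference)
#'
#' Materializes the full N x N similarity matrix `C = R + 1` (R the Pearson
#' correlation matrix, so the diagonal of C is 2) and returns the unit-norm,
#' positive eigenvector of its largest eigenvalue. Intended as the exact
#' reference for small N; use [ec_fast()] for whole-brain masks.
#'
#' @param ts Voxel-by-time matrix, N >= 2 rows and >= 3 columns.
#' @return An `ec_map` with `values`, `eigenvalue`, `iterations = NA`.
#' @export
ec_dense <- function(ts) {
  stopifnot(is.matrix(ts))
  if (nrow(ts) < 2 || ncol(ts) < 3)
    stop("ec_dense: need at least 2 voxels and 3 frames")
  z <- center_and_normalize_rows(ts)
  C <- tcrossprod(z) + 1
  e <- eigen(C, symmetric = TRUE)
  v <- fix_sign(e$vectors[, 1])
  v <- v / sqrt(sum(v^2))
  new_ec_map(v, iterations = NA_integer_, residual = 0,
             eigenvalue = e$values[1])
}

#' Eigenvector centrality by matrix-free power iteration
#'
#' Computes the same Perron eigenvector as [ec_dense()] without ever forming
#' the N x N similarity matrix. With Z the row-normalized series
#' (`diag(Z Z') = 1` exactly), the matrix-vector product is
#' `C v = Z (Z' v) + sum(v) * 1`, costing O(N T) per iteration. Iteration
#' starts from the uniform positive vector (which guarantees convergence to
#' the Perron vector of the positive matrix C) and stops when the max-abs
#' componentwise change of the normalized iterate falls below `tol`.
#'
#' @param ts Voxel-by-time matrix; N may be large (1e4-1e5).
#' @param tol Convergence tolerance on the max-abs change (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @return An `ec_map`; `eigenvalue` is the final Rayleigh quotient,
#'   `iterations` and `residual` record convergence.
#' @export
ec_fast <- function(ts, tol = 1e-10, max_iter = 1000) {
  stopifnot(is.matrix(ts))
  if (nrow(ts) < 2 || ncol(ts) < 3)
    stop("ec_fast: need at least 2 voxels and 3 frames")
  z <- center_and_normalize_rows(ts)
  n <- nrow(z)
  v <- rep(1 / sqrt(n), n)
  lambda <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- drop(z %*% crossprod(z, v)) + sum(v)
    lambda <- sum(v * w)              # Rayleigh quotient (v has unit norm)
    v_new <- w / sqrt(sum(w^2))
    res <- max(abs(v_new - v))
    v <- v_new
    if (res < tol)
      return(new_ec_map(v, iterations = it, residual = res,
                        eigenvalue = lambda))
  }
  stop("ec_fast: power iteration did not converge within ", max_iter,
       " iterations (residual ", format(res), ", tol ", format(tol), ")")
}

#' Eigenvector centrality map for one scan
#'
#' Extracts the masked voxel-by-time matrix, runs [ec_fast()], and scatters
#' the centralities back into a volume (background exactly 0).
#'
#' @param vol4d BOLD series as a `volume4d`.
#' @param mask A `gm_mask`.
#' @param tol,max_iter Passed to [ec_fast()].
#' @param on_zero_variance `"error"` (default) stops on constant voxel time
#'   series; `"drop"` removes them from the mask for this computation and
#'   records them (their map value is 0).
#' @return List with `ec` (the `ec_map`), `volume` (a `volume3d`), and
#'   `dropped` (linear indices of dropped zero-variance voxels, if any).
#' @export
ec_map_volume <- function(vol4d, mask, tol = 1e-10, max_iter = 1000,
                          on_zero_variance = c("error", "drop")) {
  on_zero_variance <- match.arg(on_zero_variance)
  ts <- extract_timeseries(vol4d, mask)
  keep <- rep(TRUE, nrow(ts))
  if (on_zero_variance == "drop") {
    v <- rowSums((ts - rowMeans(ts))^2)
    keep <- v > 0
    if (!all(keep))
      message("ec_map_volume: dropping ", sum(!keep),
              " zero-variance voxel(s)")
  }
  ec <- ec_fast(ts[keep, , drop = FALSE], tol = tol, max_iter = max_iter)
  values <- numeric(mask$n_voxels)
  values[keep] <- ec$values
  list(ec = ec, volume = scatter_to_volume(values, mask),
       dropped = mask$ordering[!keep])
}
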