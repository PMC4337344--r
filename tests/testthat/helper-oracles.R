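# Shared fixtures and independent oracles for the test suite.

# full-grid mask (every voxel included) with a given affine
full_mask <- function(dim3, voxel_size = 3) {
  prob <- ecmcycle::volume3d(array(1, dim = dim3),
                             ecmcycle:::default_affine(dim3,
                                                       rep(voxel_size, 3)))
  ecmcycle::make_gm_mask(prob, smooth_fwhm_mm = 0, threshold = 0.5)
}

# fabricate a stat_map with prescribed per-voxel p values (df 28)
stat_from_p <- function(p, df = 28) {
  t <- stats::qt(p, df, lower.tail = FALSE)
  structure(list(t = t, z = stats::qnorm(p, lower.tail = FALSE), p = p,
                 df = df, weights = 1, alternative = "greater"),
            class = "stat_map")
}

# independent connected-components oracle: exhaustive pairwise adjacency
# fed to igraph (never the package's own flood fill)
oracle_components <- function(supra_arr, connectivity) {
  idx <- which(supra_arr)
  if (length(idx) == 0) return(list())
  co <- arrayInd(idx, dim(supra_arr))
  n <- length(idx)
  edges <- c()
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    d <- abs(co[a, ] - co[b, ])
    if (max(d) > 1) next
    s <- sum(d)
    ok <- switch(as.character(connectivity),
                 "6" = s == 1, "18" = s <= 2, "26" = TRUE)
    if (ok) edges <- c(edges, a, b)
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  lapply(split(seq_len(n), memb), function(ix) sort(idx[ix]))
}

# brute-force separable-kernel impulse response: outer product of the three
# 1D truncated kernels centred on the impulse, zero elsewhere
oracle_impulse_response <- function(dim3, center, fwhm_mm, voxel_size) {
  sig <- fwhm_mm / (voxel_size * 2 * sqrt(2 * log(2)))
  k1 <- function(sigma) {
    r <- ceiling(4 * sigma)
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    list(k = k / sum(k), r = r)
  }
  ks <- lapply(sig, k1)
  out <- array(0, dim = dim3)
  for (i in seq_len(dim3[1])) for (j in seq_len(dim3[2]))
    for (k in seq_len(dim3[3])) {
      d <- c(i, j, k) - center
      if (any(abs(d) > vapply(ks, `[[`, 0, "r"))) next
      out[i, j, k] <- ks[[1]]$k[d[1] + ks[[1]]$r + 1] *
        ks[[2]]$k[d[2] + ks[[2]]$r + 1] *
        ks[[3]]$k[d[3] + ks[[3]]$r + 1]
    }
  out
}

# grid linear indices of a ground-truth region
roi_lin <- function(truth, name) ecmcycle:::roi_linear_indices(truth, name)

# does any cluster's peak voxel fall inside the given region set?
peak_in_region <- function(stat, mask, region_lin, voxel_p = 0.001) {
  tab <- ecmcycle::form_clusters(stat, mask, voxel_p_threshold = voxel_p)
  if (nrow(tab) == 0) return(FALSE)
  vox <- attr(tab, "voxels")
  any(vapply(seq_len(nrow(tab)), function(i) {
    cl <- vox[[i]]
    pk <- cl[which.max(array(replace(rep(NA_real_, prod(mask$dim)),
                                     mask$ordering, stat$t), mask$dim)[cl])]
    pk %in% region_lin
  }, logical(1)))
}

# small deterministic AR(1)-free random time-series matrix
rand_ts <- function(n, t, seed) {
  set.seed(seed)
  matrix(rnorm(n * t), n, t)
}
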