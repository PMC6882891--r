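#' Voxel adjacency on a regular grid
#'
#' Neighbor structure among a masked set of voxels of a regular grid,
#' using 6-, 18- or 26-connectivity.
#'
#' @param grid A [voxel_grid()].
#' @param mask Logical vector over grid voxels, or a compartment label
#'   (default `"brain"`).
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners).
#' @return Object of class `grid_adjacency`: `neighbors` (list of integer
#'   vectors, indices into the masked voxel set), `vox_idx` (grid indices
#'   of the masked voxels), `connectivity`.
#' @export
grid_adjacency <- function(grid, mask = "brain", connectivity = 6) {
  m <- resolve_mask(grid, mask)
  vox_idx <- which(m)
  d <- grid$dims
  pos <- arrayInd(vox_idx, d)
  key <- integer(prod(d))
  key[vox_idx] <- seq_along(vox_idx)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
                 "26" = offs[nz >= 1, , drop = FALSE],
                 stop("connectivity must be 6, 18 or 26"))
  nb <- vector("list", length(vox_idx))
  for (k in seq_len(nrow(offs))) {
    q <- sweep(pos, 2, offs[k, ], "+")
    ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
      q[, 3] >= 1 & q[, 3] <= d[3]
    lin <- rep(0L, length(vox_idx))
    lin[ok] <- key[q[ok, 1] + (q[ok, 2] - 1L) * d[1] +
                     (q[ok, 3] - 1L) * d[1] * d[2]]
    hit <- which(lin > 0L)
    for (i in hit) nb[[i]] <- c(nb[[i]], lin[i])
  }
  structure(list(neighbors = nb, vox_idx = vox_idx,
                 connectivity = connectivity),
            class = "grid_adjacency")
}

# Connected components of a suprathreshold voxel subset; returns a list of
# integer vectors (indices into the masked voxel set).
connected_clusters <- function(above, neighbors) {
  idx <- which(above)
  if (length(idx) == 0) return(list())
  lab <- integer(length(above))
  out <- list()
  for (s in idx) {
    if (lab[s] > 0L) next
    id <- length(out) + 1L
    stack <- s
    lab[s] <- id
    members <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, v)
      for (w in neighbors[[v]]) {
        if (above[w] && lab[w] == 0L) {
          lab[w] <- id
          stack <- c(stack, w)
        }
      }
    }
    out[[id]] <- sort(members)
  }
  out
}

# Vectorized voxel-wise t statistics. maps: voxels x subjects.
voxel_t_unpaired <- function(maps, is_a) {
  n1 <- sum(is_a); n2 <- sum(!is_a)
  m1 <- rowMeans(maps[, is_a, drop = FALSE])
  m2 <- rowMeans(maps[, !is_a, drop = FALSE])
  v1 <- rowSums((maps[, is_a, drop = FALSE] - m1)^2)
  v2 <- rowSums((maps[, !is_a, drop = FALSE] - m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(pmax(sp2 * (1 / n1 + 1 / n2), 1e-300))
}

voxel_t_paired <- function(diffs) {
  n <- ncol(diffs)
  m <- rowMeans(diffs)
  s <- sqrt(rowSums((diffs - m)^2) / (n - 1))
  m / pmax(s / sqrt(n), 1e-300)
}

# Max cluster mass of a t-map, given threshold and tail.
max_cluster_mass <- function(tv, thr, neighbors, tail) {
  tt <- if (tail == "neg") -tv else tv
  cl <- connected_clusters(tt > thr, neighbors)
  if (length(cl) == 0) return(0)
  max(vapply(cl, function(ix) sum(tt[ix]), numeric(1)))
}

#' Cluster-based permutation t test on source maps
#'
#' Non-parametric cluster test: voxel-wise t statistics (two-sample pooled
#' or paired), thresholded at the `alpha_form` quantile of the t
#' distribution, connected components via the grid adjacency, cluster mass
#' = sum of t values, and a Monte-Carlo null distribution of the maximum
#' cluster mass obtained by permuting group labels (unpaired) or signs /
#' condition assignments (paired). Cluster p values are
#' `(1 + #null >= observed) / (1 + n_perm)`. When the number of distinct
#' relabelings does not exceed `n_perm`, they are enumerated exactly.
#'
#' @param maps_a Voxels x subjects matrix (group A, or the "post" /
#'   first-condition maps when `paired = TRUE`). Lists of `source_map`s are
#'   also accepted.
#' @param maps_b Second group / condition; for a paired one-sample test
#'   against zero (e.g. post-minus-pre against baseline) pass the
#'   difference maps as `maps_a` and leave `maps_b = NULL` with
#'   `paired = TRUE`.
#' @param adjacency A [grid_adjacency()] matching the map voxel set.
#' @param paired Paired (dependent-samples) test.
#' @param n_perm Number of random permutations (default 10000).
#' @param alpha_form Cluster-forming alpha level (voxel threshold).
#' @param tail `"pos"` (A > B, one-sided), `"neg"`, or `"both"`.
#' @param seed Integer seed for the permutation RNG.
#' @return Object of class `cluster_result`: `clusters` (list of grid-index
#'   vectors), `mass`, `p`, `t` (voxel t map), `threshold`, `n_perm`,
#'   `tail`, `null_max_mass`.
#' @export
cluster_perm_test <- function(maps_a, maps_b = NULL, adjacency,
                              paired = FALSE, n_perm = 10000,
                              alpha_form = 0.05, tail = "pos",
                              seed = 1L) {
  as_mat <- function(x) {
    if (is.list(x) && inherits(x[[1]], "source_map"))
      vapply(x, function(m) m$values, numeric(length(x[[1]]$values)))
    else as.matrix(x)
  }
  A <- as_mat(maps_a)
  nb <- adjacency$neighbors
  if (nrow(A) != length(nb)) stop("maps do not match the adjacency voxel set")
  tails <- if (tail == "both") c("pos", "neg") else tail
  if (paired) {
    D <- if (is.null(maps_b)) A else A - as_mat(maps_b)
    n <- ncol(D)
    if (n < 2) stop("paired test needs at least 2 subjects")
    df <- n - 1
    tv <- voxel_t_paired(D)
    thr <- stats::qt(1 - alpha_form, df)
    exact <- 2^n <= n_perm
    nper <- if (exact) 2^n else n_perm
    signs <- if (exact) {
      vapply(0:(nper - 1), function(b) 2 * ((b %/% 2^(0:(n - 1))) %% 2) - 1,
             numeric(n))
    } else {
      set.seed(seed)
      matrix(sample(c(-1, 1), n * nper, replace = TRUE), n, nper)
    }
    # all sign-flip t maps at once: the per-voxel sum of squares is
    # invariant under sign flips, so only the mean needs the product
    m_perm <- (D %*% signs) / n                      # voxels x nper
    ss <- rowSums(D^2)
    sd_perm <- sqrt(pmax((ss - n * m_perm^2) / (n - 1), 1e-300))
    t_perm <- m_perm / (sd_perm / sqrt(n))
  } else {
    B <- as_mat(maps_b)
    M <- cbind(A, B)
    is_a <- c(rep(TRUE, ncol(A)), rep(FALSE, ncol(B)))
    n <- ncol(M)
    n1 <- ncol(A); n2 <- ncol(B)
    if (n1 < 2 || n2 < 2) stop("unpaired test needs >= 2 per group")
    df <- n - 2
    tv <- voxel_t_unpaired(M, is_a)
    thr <- stats::qt(1 - alpha_form, df)
    n_distinct <- choose(n, n1)
    exact <- n_distinct <= n_perm
    nper <- if (exact) n_distinct else n_perm
    labs <- if (exact) {
      utils::combn(n, n1)
    } else {
      set.seed(seed)
      vapply(seq_len(nper), function(p) sample(n, n1), integer(n1))
    }
    P <- matrix(0, n, nper)
    P[labs + rep((seq_len(nper) - 1L) * n, each = n1)] <- 1
    s1 <- M %*% P                                    # group-A sums per perm
    stot <- rowSums(M)
    ss <- rowSums(M^2)
    m1 <- s1 / n1
    m2 <- (stot - s1) / n2
    sp2 <- pmax((ss - n1 * m1^2 - n2 * m2^2) / df, 1e-300)
    t_perm <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  null_max <- vapply(seq_len(nper), function(p) {
    tp <- t_perm[, p]
    max(vapply(tails, function(tl) max_cluster_mass(tp, thr, nb, tl),
               numeric(1)))
  }, numeric(1))
  clusters <- list(); mass <- numeric(0); pvals <- numeric(0); cl_tail <- character(0)
  for (tl in tails) {
    tt <- if (tl == "neg") -tv else tv
    cl <- connected_clusters(tt > thr, nb)
    for (ix in cl) {
      clusters[[length(clusters) + 1L]] <- adjacency$vox_idx[ix]
      m <- sum(tt[ix])
      mass <- c(mass, m)
      pvals <- c(pvals, (1 + sum(null_max >= m)) / (1 + length(null_max)))
      cl_tail <- c(cl_tail, tl)
    }
  }
  ord <- order(pvals, -mass)
  structure(list(clusters = clusters[ord], mass = mass[ord], p = pvals[ord],
                 cluster_tail = cl_tail[ord], t = tv, threshold = thr,
                 n_perm = length(null_max), exact = exists("exact") && exact,
                 tail = tail, alpha_form = alpha_form,
                 null_max_mass = null_max,
                 vox_idx = adjacency$vox_idx),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$clusters), " cluster(s), ",
      x$n_perm, " permutations, tail = ", x$tail, "\n", sep = "")
  if (length(x$clusters))
    for (i in seq_along(x$clusters))
      cat(sprintf("  cluster %d: %d voxels, mass %.2f, p = %.4g\n",
                  i, length(x$clusters[[i]]), x$mass[i], x$p[i]))
  invisible(x)
}

#' Individualized frequency bands
#'
#' Band definitions relative to the individual alpha frequency: alpha
#' IAF +/- 2 Hz, theta IAF - 5 to IAF - 3 Hz, beta IAF + 4 to IAF + 20 Hz.
#'
#' @param iaf Individual alpha frequency (Hz).
#' @return Named list of 2-vectors (Hz).
#' @export
band_definitions <- function(iaf) {
  list(alpha = iaf + c(-2, 2),
       theta = iaf + c(-5, -3),
       beta = iaf + c(4, 20))
}

#' Repeat a cluster test across frequency bands
#'
#' Runs the same cluster permutation test on band-specific difference maps
#' (e.g. alpha / theta / beta), as a frequency-specificity control.
#'
#' @param map_fn Function `(band_name) -> list(maps_a, maps_b)` returning
#'   the band-specific maps (matrices or `source_map` lists).
#' @param bands Named list of bands (only the names are passed through).
#' @param ... Passed to [cluster_perm_test()] (adjacency, paired, ...).
#' @return Named list of `cluster_result`s.
#' @export
band_sweep <- function(map_fn, bands, ...) {
  out <- lapply(names(bands), function(bn) {
    m <- map_fn(bn)
    cluster_perm_test(m$maps_a, m$maps_b, ...)
  })
  names(out) <- names(bands)
  out
}

#' Mean map value inside a cluster ROI
#'
#' Extracts each subject's average power change over a cluster mask, the
#' per-subject response used by the dose-response regression.
#'
#' @param map A `source_map` (or plain value vector over the map's voxel
#'   set).
#' @param cluster_mask Grid indices of the ROI (as stored in
#'   `cluster_result$clusters`), or a logical mask over grid voxels.
#' @return Scalar mean over the ROI.
#' @export
roi_mean <- function(map, cluster_mask) {
  if (is.logical(cluster_mask)) cluster_mask <- which(cluster_mask)
  if (length(cluster_mask) == 0) stop("empty ROI mask")
  sel <- match(cluster_mask, map$vox_idx)
  if (anyNA(sel)) stop("ROI contains voxels outside the map")
  mean(map$values[sel])
}

#' Export cluster results as a summary TSV
#'
#' @param result A [cluster_perm_test()] result.
#' @param path Output path.
#' @export
write_cluster_tsv <- function(result, path) {
  df <- data.frame(cluster = seq_along(result$clusters),
                   n_voxels = vapply(result$clusters, length, integer(1)),
                   mass = result$mass, p = result$p,
                   tail = result$cluster_tail)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a cluster mask to NIfTI-1
#'
#' @param result A [cluster_perm_test()] result.
#' @param grid The source [voxel_grid()].
#' @param path Output path.
#' @param which_cluster Cluster index (default 1, the most significant).
#' @export
write_cluster_nifti <- function(result, grid, path, which_cluster = 1L) {
  vol <- rep(0, prod(grid$dims))
  vol[result$clusters[[which_cluster]]] <- 1
  write_grid_nifti(vol, grid, path)
}
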