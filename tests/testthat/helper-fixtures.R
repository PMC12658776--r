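# Shared fixtures and independent oracles used across the suite.

# A small acquisition grid that still contains the seed and both target
# regions: 10 x 12 x 10 voxels at 18 mm, same mm origin as the full grids.
acq_tiny <- function(n_volumes = 60, n_dummy = 0) {
  acquisition_spec(tr_seconds = 2, n_volumes = n_volumes, n_dummy = n_dummy,
                   grid_dims = c(10L, 12L, 10L), voxel_mm = c(18, 18, 18))
}

# windowed seed-target Fisher z straight from a raw (undiscarded) run,
# bypassing heavy preprocessing; used where only the generator is under
# test. After the standardizing flip the planted regions sit at the
# *standard* coordinates, so the target mask is the cohort-level one.
mean_target_z <- function(cohort, subject_idx, window_len = 22L) {
  s <- cohort$subjects[[subject_idx]]
  run <- discard_initial(s$bold)
  masks <- cohort$masks
  masks$lesion <- s$lesion
  if (s$record$lesion_side == "right") {
    run <- flip_midsagittal(run, "right")
    masks <- lapply(masks, flip_midsagittal, lesion_side = "right")
  }
  dfc <- compute_dfc_series(run, masks, dfc_params(window_len_tr = window_len))
  tgt <- as.vector(cohort$masks$target) & dfc$valid
  mean(dfc$maps[tgt, ])
}

# brute-force dFC oracle: per window, per voxel, stats::cor
naive_dfc_maps <- function(run, masks, params) {
  mat <- t(matrix(run$data, prod(dim(run$data)[1:3]), dim(run$data)[4]))
  valid <- as.vector(masks$brain)
  if (!is.null(masks$lesion)) valid <- valid & !as.vector(masks$lesion)
  seed <- seed_timeseries(run, params, masks$brain)
  win <- sliding_windows(nrow(mat), params$window_len_tr, params$step_tr)
  out <- matrix(0, ncol(mat), nrow(win))
  for (w in seq_len(nrow(win))) {
    rows <- win[w, 1]:win[w, 2]
    for (v in which(valid)) {
      r <- suppressWarnings(stats::cor(mat[rows, v], seed[rows]))
      if (is.na(r)) r <- 0
      out[v, w] <- atanh(min(max(r, -(1 - 1e-7)), 1 - 1e-7))
    }
  }
  out
}

# independent connected-components oracle built on igraph
igraph_components <- function(mask, connectivity) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(array(0L, d))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0 &
                 rowSums(abs(offs)) <= c(`6` = 1, `18` = 2, `26` = 3)[
                   as.character(connectivity)], ]
  coord <- arrayInd(idx, d)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lookup <- setNames(seq_along(idx), key(coord))
  edges <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coord, 2, as.numeric(offs[o, ]), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    j <- lookup[key(nb[ok, , drop = FALSE])]
    i <- seq_along(idx)[ok]
    keep <- !is.na(j)
    edges <- c(edges, rbind(i[keep], j[keep]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- array(0L, d)
  out[idx] <- comp
  out
}

# do two component labelings define the same partition?
same_partition <- function(a, b) {
  fa <- as.vector(a); fb <- as.vector(b)
  if (!identical(fa > 0, fb > 0)) return(FALSE)
  on <- fa > 0
  length(unique(paste(fa[on], fb[on]))) == length(unique(fa[on])) &&
    length(unique(paste(fa[on], fb[on]))) == length(unique(fb[on]))
}

# quick builder for a bold_run with given (t x V) matrix on a spec
run_from_matrix <- function(mat, spec, subject_id = "sub-t") {
  bold_run(array(t(mat), dim = c(spec$grid_dims, nrow(mat))), spec,
           subject_id)
}

skip_if_no <- function(pkg) testthat::skip_if_not_installed(pkg)
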