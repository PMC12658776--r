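#' Acquisition geometry and timing of a resting-state BOLD run
#'
#' An `acquisition_spec` bundles everything the pipeline needs to know about
#' how a 4D BOLD series samples the brain: repetition time, number of volumes
#' (including the initial dummy volumes discarded before analysis), the voxel
#' grid, and the affine mapping voxel indices to MNI-like mm coordinates.
#'
#' Two presets are provided. [acq_canonical()] reproduces the acquisition the
#' pipeline is designed around: TR = 2 s, 240 volumes of which the first 10
#' are discarded, on the standard 61 x 73 x 61 grid at 3 mm resolution
#' (origin -90, -126, -72 mm). [acq_desk()] is a down-scaled grid
#' (20 x 24 x 20 at 9 mm, same mm origin) whose runs are long enough for 25
#' sliding windows; it exists so that the full pipeline, including network
#' training, runs in minutes on a single CPU.
#'
#' @param tr_seconds repetition time in seconds.
#' @param n_volumes total acquired volumes, dummies included.
#' @param n_dummy number of initial volumes to discard.
#' @param grid_dims integer triple, voxel grid dimensions.
#' @param voxel_mm numeric triple, voxel edge lengths in mm.
#' @param affine 4 x 4 matrix mapping 0-based voxel indices to mm; by default
#'   a diagonal scaling with origin `origin_mm`.
#' @param origin_mm mm coordinate of voxel (0, 0, 0) when `affine` is NULL.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(tr_seconds = 2,
                             n_volumes = 240,
                             n_dummy = 10,
                             grid_dims = c(61L, 73L, 61L),
                             voxel_mm = c(3, 3, 3),
                             affine = NULL,
                             origin_mm = c(-90, -126, -72)) {
  stopifnot(tr_seconds > 0, n_volumes >= 1, n_dummy >= 0,
            length(grid_dims) == 3, all(grid_dims >= 1),
            length(voxel_mm) == 3, all(voxel_mm > 0))
  if (n_dummy >= n_volumes)
    stop("n_dummy must be smaller than n_volumes")
  if (is.null(affine)) {
    affine <- diag(c(voxel_mm, 1))
    affine[1:3, 4] <- origin_mm
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4 x 4 matrix")
  structure(
    list(tr_seconds = tr_seconds,
         n_volumes = as.integer(n_volumes),
         n_dummy = as.integer(n_dummy),
         grid_dims = as.integer(grid_dims),
         voxel_mm = as.numeric(voxel_mm),
         affine = affine),
    class = "acquisition_spec")
}

#' @rdname acquisition_spec
#' @export
acq_canonical <- function() acquisition_spec()

#' @rdname acquisition_spec
#' @export
acq_desk <- function(n_volumes = 56, n_dummy = 10) {
  acquisition_spec(tr_seconds = 2, n_volumes = n_volumes, n_dummy = n_dummy,
                   grid_dims = c(20L, 24L, 20L), voxel_mm = c(9, 9, 9))
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("<acquisition_spec> %d volumes (TR %.3g s, %d dummy), grid %s at %s mm\n",
              x$n_volumes, x$tr_seconds, x$n_dummy,
              paste(x$grid_dims, collapse = "x"),
              paste(x$voxel_mm, collapse = "x")))
  invisible(x)
}

#' Voxel / mm coordinate conversion
#'
#' Voxel indices are 1-based on the R side; the affine follows the NIfTI
#' convention and acts on 0-based indices, so the conversion subtracts 1.
#'
#' @param spec an [acquisition_spec()].
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(spec, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  mm <- cbind(ijk - 1, 1) %*% t(spec$affine)
  mm[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_mm
#' @param mm n x 3 matrix of mm coordinates.
#' @return for [mm_to_voxel()], n x 3 matrix of fractional 1-based indices.
#' @export
mm_to_voxel <- function(spec, mm) {
  mm <- matrix(as.numeric(mm), ncol = 3)
  vox <- cbind(mm, 1) %*% t(solve(spec$affine))
  vox[, 1:3, drop = FALSE] + 1
}

#' mm coordinates of every voxel center
#'
#' @param spec an [acquisition_spec()].
#' @return a `prod(grid_dims)` x 3 matrix, rows in R array (column-major)
#'   voxel order.
#' @export
grid_mm_coords <- function(spec) {
  d <- spec$grid_dims
  ijk <- arrayInd(seq_len(prod(d)), d)
  voxel_to_mm(spec, ijk)
}

# mm^3 volume of one voxel
voxel_volume_mm3 <- function(spec) prod(spec$voxel_mm)
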