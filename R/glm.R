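#' GLM residualization of stimulus-evoked variance
#'
#' Fits the general linear model Y = X b + e voxelwise by ordinary least
#' squares and returns the residual series e, which carry the low-frequency
#' fluctuations of interest once the task response encoded in the design has
#' been projected out.  The data are expected to be spatially smoothed
#' beforehand (see [smooth_spatial()]); smoothing the spatially constant
#' design columns would be a no-op.
#'
#' @param run a (typically smoothed) [bold_run()].
#' @param design a `design_matrix` from [build_design()] with the same number
#'   of rows as the run has time steps.
#' @param mask optional logical 3D array restricting the fit; voxels outside
#'   the mask are zeroed in the output.
#' @return a [bold_run()] whose data are the residuals, with provenance
#'   attributes (`design_columns`, inherited `smoothing_fwhm_mm`).
#' @export
glm_residuals <- function(run, design, mask = NULL) {
  X <- design$values
  if (nrow(X) != n_time(run))
    stop(sprintf("design has %d rows but the run has %d time steps",
                 nrow(X), n_time(run)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(dropped, collapse = ", ")))
  }
  d <- dim(run$data)
  vox <- if (is.null(mask)) seq_len(prod(d[1:3])) else mask_flat(mask)
  if (!is.null(mask) && !all(dim(mask) == d[1:3]))
    stop("mask dims do not match the run grid")
  Y <- run_matrix(run, vox)                 # T x V
  E <- qr.resid(qrX, Y)
  out <- array(0, d)
  M <- matrix(out, prod(d[1:3]), d[4])
  M[vox, ] <- t(E)
  run$data <- array(M, d)
  attr(run, "design_columns") <- design$columns
  attr(run, "stage") <- "residual"
  run
}
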