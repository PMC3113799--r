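#' Voxelwise two-group test of Fisher z maps
#'
#' Per VOI voxel, a two-sample t statistic contrasting group A against group
#' B (pooled variance by default, df = nA + nB - 2; Welch by flag) is mapped
#' to a z-scale value by two-sided probability matching, signed positive
#' where A > B.
#'
#' @param zmaps_a,zmaps_b lists of `conn_map`s of type "z" for the two groups
#'   (each group needs at least 2 subjects).
#' @param var_equal pooled-variance t-test if TRUE (default); Welch otherwise.
#' @param labels character(2), display names for groups A and B.
#' @return object of class `stat_map`: `values` (3D z-scale array, NA outside
#'   the common VOI), group sizes, df, and the contrast orientation.
#' @export
voxelwise_group_test <- function(zmaps_a, zmaps_b, var_equal = TRUE,
                                 labels = c("A", "B")) {
  nA <- length(zmaps_a); nB <- length(zmaps_b)
  if (nA < 2 || nB < 2)
    stop("each group needs at least 2 subjects for a voxelwise t-test")
  seed <- zmaps_a[[1]]$seed
  dm <- dim(zmaps_a[[1]]$values)
  for (m in c(zmaps_a, zmaps_b)) {
    stopifnot(inherits(m, "conn_map"), m$type == "z")
    if (!identical(m$seed, seed) || !identical(dim(m$values), dm))
      stop("maps mix seeds or masks")
  }
  A <- vapply(zmaps_a, function(m) as.numeric(m$values), numeric(prod(dm)))
  B <- vapply(zmaps_b, function(m) as.numeric(m$values), numeric(prod(dm)))
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  if (var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, length(se))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  tstat <- (mA - mB) / se
  z <- t_to_z(tstat, df)
  vals <- array(z, dm)
  structure(list(values = vals, nA = nA, nB = nB,
                 df = if (var_equal) nA + nB - 2 else NA_real_,
                 contrast = sprintf("%s - %s", labels[1], labels[2]),
                 labels = labels, seed = seed),
            class = "stat_map")
}

# t -> z by matching tail probability (two-sided, sign preserved);
# log-scale to stay finite for extreme t
t_to_z <- function(tstat, df) {
  logp <- stats::pt(abs(tstat), df, lower.tail = FALSE, log.p = TRUE)
  sign(tstat) * stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
}

#' Estimate the spatial smoothness (FWHM) of statistical maps
#'
#' Assuming a Gaussian autocorrelation, the correlation of face-adjacent
#' in-mask voxels determines the FWHM of the equivalent Gaussian smoothing
#' kernel: rho = exp(-d^2 / (4 sigma^2)) for voxel spacing d.  Maps are
#' centered voxelwise across subjects first (when >= 2 maps are given) so
#' shared mean structure does not inflate the estimate; per-axis estimates
#' are combined by geometric mean and floored at the voxel size (the
#' effective resolution of an unsmoothed white-noise map).
#'
#' @param maps list of 3D arrays (or `conn_map`/`stat_map` objects).
#' @param mask logical 3D array.
#' @param voxel_mm numeric(3) voxel size in mm.
#' @return isotropic FWHM estimate in mm.
#' @export
estimate_smoothness <- function(maps, mask, voxel_mm = c(3, 3, 3)) {
  vals <- lapply(maps, function(m) if (is.list(m)) m$values else m)
  if (length(vals) < 2) stop("need at least 2 maps to estimate smoothness")
  dm <- dim(vals[[1]])
  stack <- vapply(vals, as.numeric, numeric(prod(dm)))
  mmean <- rowMeans(stack)
  stack <- stack - mmean
  inmask <- as.logical(mask)
  if (all(apply(stack[inmask, , drop = FALSE], 2, stats::sd) == 0))
    stop("constant map(s): smoothness undefined")
  fwhm <- numeric(3)
  for (a in 1:3) {
    sh <- shift_pairs(dm, a)
    ok <- inmask[sh$i] & inmask[sh$j]
    x1 <- as.numeric(stack[sh$i[ok], ])
    x2 <- as.numeric(stack[sh$j[ok], ])
    rho <- sum(x1 * x2) / sqrt(sum(x1^2) * sum(x2^2))
    if (!is.finite(rho) || rho <= 0) {
      fwhm[a] <- voxel_mm[a]
    } else {
      sigma <- voxel_mm[a] / (2 * sqrt(-log(rho)))
      fwhm[a] <- max(sigma_to_fwhm(sigma), voxel_mm[a])
    }
  }
  exp(mean(log(fwhm)))
}

# flat indices of face-adjacent voxel pairs along axis a
shift_pairs <- function(dm, a) {
  idx <- array(seq_len(prod(dm)), dm)
  if (a == 1) {
    i <- idx[-dm[1], , , drop = FALSE]; j <- idx[-1, , , drop = FALSE]
  } else if (a == 2) {
    i <- idx[, -dm[2], , drop = FALSE]; j <- idx[, -1, , drop = FALSE]
  } else {
    i <- idx[, , -dm[3], drop = FALSE]; j <- idx[, , -1, drop = FALSE]
  }
  list(i = as.integer(i), j = as.integer(j))
}

#' Monte Carlo null distribution for cluster-size correction
#'
#' Derives the small-volume-corrected minimum cluster size inside the VOI:
#' per iteration, white Gaussian noise on the grid is smoothed to the target
#' FWHM, restandardized within the mask, thresholded at |z| >=
#' `per_voxel_z`, and the maximum supra-threshold cluster size (and maximum
#' |z|) recorded.  The returned cutoff is the ceiling of the (1 - alpha)
#' quantile of the max-size null (floored at 1 voxel), so a cluster of
#' size >= cutoff has family-wise corrected p < alpha.
#'
#' @param mask logical 3D array (the VOI).
#' @param grid a [volume_grid].
#' @param fwhm_mm smoothness of the null fields in mm (use
#'   [estimate_smoothness()] on the data maps).
#' @param per_voxel_z cluster-forming threshold on the z scale (default
#'   2.576, two-sided p < 0.01).
#' @param alpha corrected significance level (default 0.05).
#' @param n_iter Monte Carlo iterations (>= 100).
#' @param seed RNG seed making the null reproducible.
#' @param connectivity 6 or 26 (default 26).
#' @return object of class `mc_null`: `min_cluster_vox` (the cutoff),
#'   `max_sizes`, `max_z`, plus the simulation parameters.
#' @export
mc_cluster_threshold <- function(mask, grid, fwhm_mm, per_voxel_z = 2.576,
                                 alpha = 0.05, n_iter = 1000, seed = 1,
                                 connectivity = 26) {
  inmask <- as.logical(mask)
  if (!any(inmask)) stop("empty mask")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (per_voxel_z <= 0) stop("per_voxel_z must be positive")
  if (n_iter < 100) stop("use at least 100 Monte Carlo iterations")
  dm <- grid$dims
  stopifnot(all(dim(mask) == dm))
  set.seed(seed)
  max_sizes <- integer(n_iter)
  max_z <- numeric(n_iter)
  supra <- array(FALSE, dm)
  for (it in seq_len(n_iter)) {
    noise <- array(stats::rnorm(prod(dm)), dm)
    sm <- smooth_array(noise, grid, fwhm_mm)
    v <- sm[inmask]
    v <- (v - mean(v)) / stats::sd(v)
    max_z[it] <- max(abs(v))
    supra[] <- FALSE
    supra[inmask] <- abs(v) >= per_voxel_z
    if (!any(supra)) { max_sizes[it] <- 0L; next }
    lab <- label_components_cpp(supra, as.integer(dm), as.integer(connectivity))
    max_sizes[it] <- max(tabulate(lab[lab > 0L]))
  }
  q <- stats::quantile(max_sizes, 1 - alpha, names = FALSE, type = 7)
  cutoff <- max(1L, as.integer(ceiling(q)))
  structure(list(min_cluster_vox = cutoff,
                 max_sizes = max_sizes, max_z = max_z,
                 per_voxel_z = per_voxel_z, alpha = alpha, n_iter = n_iter,
                 fwhm_mm = fwhm_mm, connectivity = connectivity, seed = seed,
                 peak_z_threshold = stats::quantile(max_z, 1 - alpha,
                                                    names = FALSE)),
            class = "mc_null")
}

#' Find supra-threshold clusters in a group statistic map
#'
#' Positive and negative excursions are clustered separately (signs are
#' preserved: negative maxima mark the B > A direction).  Components smaller
#' than the Monte Carlo corrected minimum size are dropped; surviving
#' components smaller than the report floor (conventionally 300 mm^3) are
#' dropped from the table.  The peak is the voxel of maximum |z|.
#'
#' @param stat a `stat_map` from [voxelwise_group_test()].
#' @param grid a [volume_grid].
#' @param per_voxel_z cluster-forming threshold (z scale, positive).
#' @param min_size_vox corrected minimum cluster size in voxels (from
#'   [mc_cluster_threshold()]).
#' @param report_floor_mm3 report floor in mm^3 (default 300; set 0 to keep
#'   every surviving cluster).
#' @param connectivity 6 or 26 (default 26).
#' @param labels optional label lookup: list(map = integer 3D array,
#'   names = character) such as a phantom's label map.
#' @param peak_z_threshold optional alternative accept rule: a cluster also
#'   survives if its peak |z| meets this simulated max-z quantile.
#' @return data.frame of cluster records: seed, region, contrast, x, y, z
#'   (peak, Talairach mm), max_z (signed), size_vox, size_mm3.
#' @export
find_clusters <- function(stat, grid, per_voxel_z = 2.576, min_size_vox = 1,
                          report_floor_mm3 = 300, connectivity = 26,
                          labels = NULL, peak_z_threshold = NULL) {
  stopifnot(per_voxel_z > 0, min_size_vox >= 1)
  vox_mm3 <- prod(grid$voxel_mm)
  recs <- list()
  for (sgn in c(1, -1)) {
    vals <- stat$values * sgn
    supra <- !is.na(vals) & vals >= per_voxel_z
    if (!any(supra)) next
    lab <- label_components_cpp(supra, as.integer(grid$dims),
                                as.integer(connectivity))
    for (comp in seq_len(max(lab))) {
      flat <- which(lab == comp)
      size <- length(flat)
      peak_ok <- !is.null(peak_z_threshold) &&
        max(vals[flat]) >= peak_z_threshold
      if (size < min_size_vox && !peak_ok) next
      if (size * vox_mm3 < report_floor_mm3) next
      pk <- flat[which.max(vals[flat])]
      pidx <- arrayInd(pk, grid$dims)
      pmm <- index_to_mm(as.integer(pidx), grid)
      region <- "n/a"
      if (!is.null(labels)) {
        li <- labels$map[pk]
        if (li > 0) region <- labels$names[li]
      }
      contrast <- if (sgn > 0)
        sprintf("%s > %s", stat$labels[1], stat$labels[2])
      else sprintf("%s > %s", stat$labels[2], stat$labels[1])
      recs[[length(recs) + 1]] <- data.frame(
        seed = stat$seed, region = region, contrast = contrast,
        x = pmm[1], y = pmm[2], z = pmm[3],
        max_z = sgn * max(vals[flat]),
        size_vox = size, size_mm3 = size * vox_mm3,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(seed = character(), region = character(),
                      contrast = character(), x = numeric(), y = numeric(),
                      z = numeric(), max_z = numeric(), size_vox = integer(),
                      size_mm3 = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Write a cluster table
#'
#' Formats cluster records in the conventional report layout: columns
#' Region, Contrast, Location (x y z), Maximum, Size (mm^3), sorted by seed,
#' then contrast, then size descending.
#'
#' @param records data.frame from [find_clusters()] (possibly several seeds
#'   row-bound together).
#' @param path optional file; when given, the table is written as CSV.
#' @return the formatted data.frame, invisibly when written to file.
#' @export
cluster_table <- function(records, path = NULL) {
  tab <- data.frame(Seed = records$seed,
                    Region = records$region,
                    Contrast = records$contrast,
                    Location = sprintf("%g %g %g", records$x, records$y,
                                       records$z),
                    Maximum = round(records$max_z, 2),
                    Size = records$size_mm3,
                    stringsAsFactors = FALSE)
  if (nrow(tab))
    tab <- tab[order(tab$Seed, tab$Contrast, -tab$Size), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Full two-group contrast with Monte Carlo small-volume correction
#'
#' Convenience wrapper chaining [voxelwise_group_test()],
#' [estimate_smoothness()], [mc_cluster_threshold()] and [find_clusters()].
#'
#' @inheritParams voxelwise_group_test
#' @param mask logical 3D VOI array.
#' @param grid a [volume_grid].
#' @param per_voxel_z,alpha,n_iter,connectivity,seed Monte Carlo correction
#'   parameters (see [mc_cluster_threshold()]).
#' @param report_floor_mm3 report floor passed to [find_clusters()].
#' @param labels optional label lookup for region names.
#' @param labels_ab character(2), display names of groups A and B.
#' @param rule "size" (default) requires the cluster-size cutoff; "size_or_peak"
#'   also accepts clusters whose peak exceeds the simulated max-z quantile.
#' @return list with `stat` (the `stat_map`), `mc` (the `mc_null`),
#'   `smoothness_mm` and `clusters` (data.frame).
#' @export
group_contrast <- function(zmaps_a, zmaps_b, mask, grid,
                           per_voxel_z = 2.576, alpha = 0.05, n_iter = 1000,
                           connectivity = 26, seed = 1,
                           report_floor_mm3 = 300, labels = NULL,
                           labels_ab = c("A", "B"), var_equal = TRUE,
                           rule = c("size", "size_or_peak")) {
  rule <- match.arg(rule)
  stat <- voxelwise_group_test(zmaps_a, zmaps_b, var_equal = var_equal,
                               labels = labels_ab)
  fwhm <- estimate_smoothness(c(zmaps_a, zmaps_b), mask, grid$voxel_mm)
  mc <- mc_cluster_threshold(mask, grid, fwhm, per_voxel_z = per_voxel_z,
                             alpha = alpha, n_iter = n_iter, seed = seed,
                             connectivity = connectivity)
  clusters <- find_clusters(stat, grid, per_voxel_z = per_voxel_z,
                            min_size_vox = mc$min_cluster_vox,
                            report_floor_mm3 = report_floor_mm3,
                            connectivity = connectivity, labels = labels,
                            peak_z_threshold = if (rule == "size_or_peak")
                              mc$peak_z_threshold else NULL)
  list(stat = stat, mc = mc, smoothness_mm = fwhm, clusters = clusters)
}
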