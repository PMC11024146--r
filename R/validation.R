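#' Surface error metrics between a predicted and a reference mesh
#'
#' Computes the set of absolute vertex-to-surface distances and summarizes
#' it as RMSE (root mean square), ASD (average surface distance) and HD
#' (Hausdorff distance, the maximum): `asd <= rmse <= hd` always.  No
#' vertex correspondence is assumed -- the reference plays the role of an
#' independent manual segmentation, so distances are nearest
#' point-to-triangle, not index-to-index.
#'
#' In `one_sided` mode the distance set is predicted-vertex to
#' reference-surface; `symmetric` (the default, standard in segmentation
#' evaluation) adds the reference-vertex to predicted-surface distances.
#'
#' @param predicted,reference nonempty [triangle_mesh()] objects.
#' @param direction `"symmetric"` or `"one_sided"`.
#' @return object of class `surface_error_report` with `rmse`, `asd`, `hd`
#'   (mm), `per_point_errors` (per predicted-mesh vertex) and `direction`.
#' @export
surface_error_report <- function(predicted, reference,
                                 direction = c("symmetric", "one_sided")) {
  direction <- match.arg(direction)
  stopifnot_mesh(predicted)
  stopifnot_mesh(reference)
  if (n_faces(predicted) == 0 || n_faces(reference) == 0)
    stop("empty mesh: both meshes need at least one face")
  d_pred <- surface_distance(predicted$vertices, reference)
  dset <- d_pred
  if (direction == "symmetric")
    dset <- c(dset, surface_distance(reference$vertices, predicted))
  structure(list(rmse = sqrt(mean(dset^2)),
                 asd = mean(abs(dset)),
                 hd = max(abs(dset)),
                 per_point_errors = d_pred,
                 direction = direction),
            class = "surface_error_report")
}

#' @export
print.surface_error_report <- function(x, ...) {
  cat(sprintf("surface_error_report (%s): RMSE %.3f, ASD %.3f, HD %.3f mm\n",
              x$direction, x$rmse, x$asd, x$hd))
  invisible(x)
}

#' Voxel-size accuracy criterion
#'
#' A prediction counts as accurate when its average surface distance lies
#' within the MRI voxel size, read as: ASD not exceeding the largest voxel
#' dimension (the slice thickness for an anisotropic protocol).
#'
#' @param report a [surface_error_report()].
#' @param voxel length-3 voxel dimensions in mm, e.g.
#'   `c(0.3571, 0.3571, 1.5)`.
#' @return list with `pass` (logical), `margin` (mm; largest voxel
#'   dimension minus ASD) and `threshold`.
#' @export
voxel_accuracy_check <- function(report, voxel) {
  if (!inherits(report, "surface_error_report"))
    stop("not a surface_error_report")
  voxel <- as.numeric(voxel)
  if (length(voxel) != 3 || any(voxel <= 0))
    stop("voxel must be three positive dimensions (mm)")
  thr <- max(voxel)
  list(pass = report$asd <= thr, margin = thr - report$asd, threshold = thr)
}

#' Mean point-dependent error map over subjects
#'
#' Arithmetic per-vertex mean of corresponded per-vertex error vectors
#' (all on the shared template topology); the result can be attached to
#' the template mesh as a color-mappable scalar via
#' `write_mesh(..., vertex_scalar = )`.
#'
#' @param per_subject_errors list of equal-length numeric vectors.
#' @return numeric vector of per-vertex mean errors (mm).
#' @export
mean_point_error_map <- function(per_subject_errors) {
  if (length(per_subject_errors) == 0) stop("no error vectors supplied")
  n <- length(per_subject_errors[[1]])
  if (any(vapply(per_subject_errors, length, 0L) != n))
    stop("error vectors differ in length: not on a shared topology")
  colMeans(do.call(rbind, per_subject_errors))
}

#' Shapiro-Wilk normality test of an error sample
#'
#' Thin wrapper around [stats::shapiro.test()] returning the W statistic,
#' p-value and the rejection decision at level `alpha`.  The null
#' hypothesis is that the sample originates from a normal distribution.
#'
#' @param values numeric sample, `3 <= n <= 5000`, not constant.
#' @param alpha significance level (default 0.05).
#' @return list with `W`, `p_value`, `reject`, `alpha`, `n`.
#' @export
shapiro_wilk <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("Shapiro-Wilk requires at least 3 values, got ", n)
  if (n > 5000) stop("Shapiro-Wilk is limited to 5000 values, got ", n)
  if (diff(range(values)) == 0) stop("constant sample: test undefined")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p_value = ht$p.value,
       reject = ht$p.value < alpha, alpha = alpha, n = n)
}

#' Median and range summary
#'
#' The summary used for all cohort error tables: standard median (mean of
#' the middle pair for even n) with the minimum and maximum.
#'
#' @param values nonempty numeric vector.
#' @return list with `median`, `min`, `max`.
#' @export
median_range_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty sample")
  list(median = stats::median(values), min = min(values), max = max(values))
}
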