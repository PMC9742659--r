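# Voxel-wise image-quality metrics against the reference ASC image, the
# structural similarity index, and the pooled joint-histogram analysis.

#' Evaluation mask
#'
#' The relative-error metrics divide by reference voxel values, so they are
#' only defined where the reference is positive; the same body mask is applied
#' to all metrics for consistency. Default rule: reference above a small
#' threshold (0.01 in normalized units).
#'
#' @param ref reference image.
#' @param tau threshold; voxels with `ref > tau` are evaluated. Use
#'   `tau = -Inf` for the whole image.
#' @return logical matrix (at least one voxel must be selected).
#' @export
eval_mask <- function(ref, tau = 0.01) {
  m <- ref > tau
  if (!any(m)) stop("evaluation mask is empty")
  m
}

#' Voxel-wise error metrics
#'
#' Over the masked voxels: mean error `ME = mean(pred - ref)`, mean absolute
#' error `MAE = mean(|pred - ref|)`, relative error
#' `RE% = 100 * mean((pred - ref) / ref)`, absolute relative error
#' `ARE% = 100 * mean(|pred - ref| / ref)`, and
#' `PSNR = 10 log10(Peak^2 / MSE)` with Peak the masked reference maximum
#' (configurable to a fixed value). `MSE = 0` yields `PSNR = Inf`.
#'
#' @param pred,ref conformable images (same units; SUV or normalized).
#' @param mask logical matrix, or `NULL` to build one via [eval_mask()].
#' @param tau threshold passed to [eval_mask()] when `mask` is `NULL`.
#' @param peak `"ref_max"` (default) or a fixed numeric Peak for PSNR.
#' @param study_id,strategy optional labels carried into the report.
#' @return one-row data frame (class `metrics_report`) with `ME`, `MAE`,
#'   `RE_pct`, `ARE_pct`, `PSNR_dB`, `peak`, `vxl`.
#' @export
voxel_metrics <- function(pred, ref, mask = NULL, tau = 0.01,
                          peak = "ref_max", study_id = NA_character_,
                          strategy = NA_character_) {
  stopifnot(all(dim(pred) == dim(ref)))
  if (is.null(mask)) mask <- eval_mask(ref, tau)
  stopifnot(all(dim(mask) == dim(ref)), any(mask))
  p <- pred[mask]; r <- ref[mask]
  if (any(r <= 0)) stop("masked reference voxels must be positive for RE/ARE")
  d <- p - r
  mse <- mean(d^2)
  pk <- if (identical(peak, "ref_max")) max(r) else as.numeric(peak)
  psnr <- if (mse == 0) Inf else 10 * log10(pk^2 / mse)
  out <- data.frame(study_id = study_id, strategy = strategy,
                    ME = mean(d), MAE = mean(abs(d)),
                    RE_pct = 100 * mean(d / r),
                    ARE_pct = 100 * mean(abs(d) / r),
                    PSNR_dB = psnr, peak = pk, vxl = sum(mask),
                    stringsAsFactors = FALSE)
  class(out) <- c("metrics_report", class(out))
  out
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sigma 1.5) and the
#' standard stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`. `L` is the
#' dynamic range: 5 for images in the normalized 0-5 range. Local statistics
#' use valid-region filtering (a 5-pixel border is excluded). Two identical
#' images give 1; a constant-zero pair gives 1 by the stabilized formula.
#'
#' @param pred,ref conformable matrices.
#' @param L dynamic range (default 5).
#' @param window_size odd window width (default 11).
#' @param sigma Gaussian window sigma (default 1.5).
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(pred, ref, L = 5, window_size = 11L, sigma = 1.5) {
  stopifnot(all(dim(pred) == dim(ref)), window_size %% 2 == 1,
            min(dim(pred)) >= window_size)
  r <- (window_size - 1L) %/% 2L
  g1 <- exp(-0.5 * ((-r:r) / sigma)^2)
  K <- outer(g1, g1); K <- K / sum(K)
  filt <- function(x) {
    f <- cpp_conv2d_fwd(as_chw(x), matrix(as.numeric(K), ncol = 1), 0,
                        window_size, window_size, 1L)
    matrix(f[, , 1], nrow(x), ncol(x))
  }
  valid <- function(x) x[(r + 1):(nrow(x) - r), (r + 1):(ncol(x) - r)]
  mu1 <- filt(pred); mu2 <- filt(ref)
  s11 <- filt(pred^2) - mu1^2
  s22 <- filt(ref^2) - mu2^2
  s12 <- filt(pred * ref) - mu1 * mu2
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(valid(num / den))
}

#' Pooled joint-histogram analysis with R-squared
#'
#' Pools masked voxels across studies, bins the (reference, predicted) pairs
#' into a 2D histogram, and reports the coefficient of determination of the
#' ordinary least-squares fit of predicted on reference values.
#'
#' @param pred_list,ref_list lists of conformable images.
#' @param tau mask threshold on the reference (see [eval_mask()]).
#' @param bins histogram bins per axis (default 128).
#' @param range intensity range covered by the histogram (default `c(0, 5)`).
#' @return list with `histogram` (bins x bins counts, reference on rows),
#'   `r_squared`, `slope`, `intercept`, `n_voxels`.
#' @export
joint_histogram_r2 <- function(pred_list, ref_list, tau = 0.01, bins = 128L,
                               range = c(0, 5)) {
  stopifnot(length(pred_list) == length(ref_list), length(pred_list) >= 1)
  pv <- c(); rv <- c()
  for (i in seq_along(pred_list)) {
    m <- ref_list[[i]] > tau
    pv <- c(pv, pred_list[[i]][m]); rv <- c(rv, ref_list[[i]][m])
  }
  if (length(rv) < 2) stop("need at least 2 pooled masked voxels")
  if (stats::var(rv) == 0) stop("reference has zero variance; R^2 undefined")
  fit <- stats::lm.fit(cbind(1, rv), pv)
  ssr <- sum(fit$residuals^2)
  sst <- sum((pv - mean(pv))^2)
  brk <- seq(range[1], range[2], length.out = bins + 1)
  bin_of <- function(x) pmin(pmax(findInterval(x, brk, all.inside = TRUE), 1L),
                             bins)
  h <- matrix(0L, bins, bins)
  tab <- table(factor(bin_of(rv), levels = seq_len(bins)),
               factor(bin_of(pv), levels = seq_len(bins)))
  h[] <- as.integer(tab)
  list(histogram = h, r_squared = 1 - ssr / sst,
       slope = fit$coefficients[2], intercept = fit$coefficients[1],
       n_voxels = length(rv))
}
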