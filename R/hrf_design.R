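#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peak at 6 s, undershoot peak
#' at 16 s, response:undershoot amplitude ratio 6), peak-normalized to 1.
#' The kernel is zero at t = 0, rises to a single positive peak, and shows a
#' later negative undershoot.
#'
#' @param t Time grid in seconds (non-negative).
#' @param peak_delay,undershoot_delay Gamma shape parameters (unit rate), i.e.
#'   the modes fall at `delay - 1` seconds.
#' @param ratio Response:undershoot amplitude ratio.
#' @return Numeric vector of kernel values, max = 1.
#' @examples
#' h <- hrf_double_gamma(seq(0, 32, 0.1))
#' @export
hrf_double_gamma <- function(t, peak_delay = 7, undershoot_delay = 16,
                             ratio = 6) {
  if (any(t < 0)) abort("HRF time grid must be non-negative")
  h <- dgamma(t, shape = peak_delay, rate = 1) -
    dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h / max(h)
}

# HRF-convolved regressor: events (onset, duration, amplitude) convolved on
# an oversampled grid then sampled at frame times 0, TR, 2TR, ...
convolve_events <- function(onset, duration, amplitude, n_frames, tr,
                            oversample = 16L, hrf = hrf_double_gamma) {
  dt <- tr / oversample
  n_fine <- n_frames * oversample + oversample
  x <- numeric(n_fine)
  for (i in seq_along(onset)) {
    i0 <- floor(onset[i] / dt) + 1L
    i1 <- ceiling((onset[i] + duration[i]) / dt)
    if (i1 > n_fine) abort("event extends past the end of the run")
    x[i0:i1] <- x[i0:i1] + amplitude[i]
  }
  k <- hrf(seq(0, 32, by = dt))
  y <- convolve(x, rev(k), type = "open")[seq_len(n_fine)] * dt
  y[seq(1L, by = oversample, length.out = n_frames)]
}

#' Build a first-level fMRI design matrix
#'
#' Condition regressors (expected, unexpected, no-go) are HRF-convolved
#' 0.5-s boxcars at the image onsets; each parametric modulator is the
#' unexpected-trial boxcar weighted by that trial's z-scored surprise; first
#' order temporal derivatives of task regressors are appended when requested;
#' nuisance columns are appended unmodified. Convolution runs on a 16x
#' oversampled grid before sampling at the TR.
#'
#' @param trials A `trial_table` from [generate_run()].
#' @param surprise Named list of `surprise` tibbles ([trial_surprise()]), one
#'   per feature model; may be empty.
#' @param nuisance Optional numeric matrix / tibble of nuisance regressors
#'   (timepoints x regressors).
#' @param tr Repetition time (seconds).
#' @param n_frames Number of volumes; defaults to covering the run plus a
#'   16-s tail.
#' @param add_derivatives Append temporal derivatives of task regressors?
#' @param check_rank Error on rank deficiency?
#' @return A `design_matrix`: numeric matrix (frames x regressors) with
#'   attributes `classes` (condition / modulator / derivative / nuisance) and
#'   `tr`.
#' @export
build_design <- function(trials, surprise = list(), nuisance = NULL, tr = 1,
                         n_frames = NULL, add_derivatives = TRUE,
                         check_rank = TRUE) {
  n_frames <- n_frames %||% default_frames(trials, tr)
  cols <- list(); classes <- character()
  for (cond in c("expected", "unexpected", "nogo")) {
    tt <- dplyr::filter(trials, .data$condition == cond)
    if (!nrow(tt)) next
    cols[[cond]] <- convolve_events(tt$onset, tt$duration,
                                    rep(1, nrow(tt)), n_frames, tr)
    classes <- c(classes, "condition")
  }
  un <- dplyr::filter(trials, .data$condition == "unexpected")
  if (length(surprise) && !nrow(un)) {
    warn("no unexpected trials: modulator columns dropped")
    surprise <- list()
  }
  for (m in names(surprise)) {
    sv <- surprise[[m]]
    z <- sv$z[match(un$trial, sv$trial)]
    if (anyNA(z)) abort(paste0("surprise vector '", m,
                               "' does not cover all unexpected trials"))
    cols[[m]] <- convolve_events(un$onset, un$duration, z, n_frames, tr)
    classes <- c(classes, "modulator")
  }
  if (add_derivatives) {
    task <- names(cols)
    for (nm in task) {
      cols[[paste0(nm, "_td")]] <- c(0, diff(cols[[nm]])) / tr
      classes <- c(classes, "derivative")
    }
  }
  if (!is.null(nuisance)) {
    nuis <- as.matrix(nuisance)
    if (nrow(nuis) != n_frames)
      abort("nuisance regressors must have one row per frame")
    nms <- colnames(nuis) %||% paste0("nuis", seq_len(ncol(nuis)))
    for (j in seq_len(ncol(nuis))) cols[[nms[j]]] <- nuis[, j]
    classes <- c(classes, rep("nuisance", ncol(nuis)))
  }
  X <- do.call(cbind, cols)
  if (any(colSums(abs(X)) == 0)) abort("design contains an all-zero column")
  if (check_rank) {
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1L) {
      drop <- setdiff(seq_len(ncol(X) + 1L), qrX$pivot[seq_len(qrX$rank)]) - 1L
      abort(paste0("design matrix is rank deficient; collinear column(s): ",
                   paste(colnames(X)[drop], collapse = ", ")))
    }
  }
  structure(X, classes = classes, tr = tr,
            class = c("design_matrix", "matrix", "array"))
}

#' Number of volumes needed to cover a trial table plus a 16-s tail
#' @param trials A `trial_table`.
#' @param tr Repetition time (seconds).
#' @return Integer frame count.
#' @export
default_frames <- function(trials, tr = 1) {
  as.integer(ceiling((max(trials$onset + trials$duration) + 16) / tr))
}

#' @export
tidy.design_matrix <- function(x, ...) {
  tibble(column = colnames(x), class = attr(x, "classes"))
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x), " frames x ", ncol(x), " regressors (TR ",
      attr(x, "tr"), " s)\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' High-pass filter by discrete-cosine projection
#'
#' Projects out a discrete cosine basis of all components with period longer
#' than `cutoff_s`, plus the mean. Operates column-wise on matrices.
#'
#' @param ts Numeric vector or matrix (timepoints x series).
#' @param tr Repetition time (seconds).
#' @param cutoff_s Filter cutoff period (seconds).
#' @return Filtered series (mean removed), same shape as `ts`.
#' @export
highpass <- function(ts, tr = 1, cutoff_s = 128) {
  x <- as.matrix(ts)
  n <- nrow(x)
  K <- dct_basis(n, tr, cutoff_s)
  res <- x - K %*% crossprod(K, x)
  if (is.null(dim(ts))) drop(res) else res
}

# orthonormal DCT-II columns with period > cutoff, mean column included
dct_basis <- function(n, tr, cutoff_s) {
  n_basis <- floor(2 * n * tr / cutoff_s)
  ks <- 0:max(n_basis, 0)
  K <- sapply(ks, function(k) cos(pi * k * (2 * seq_len(n) - 1) / (2 * n)))
  sweep(K, 2, sqrt(colSums(K^2)), "/")
}

#' Mask-aware Gaussian spatial smoothing
#'
#' Separable 3D Gaussian kernel with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis; the volume is renormalized by the smoothed mask so values near mask
#' edges are proper weighted averages of in-mask voxels only.
#'
#' @param vol 3D array (or 4D; smoothed volume-wise over the 4th axis).
#' @param fwhm_mm Full width at half maximum, mm (0 returns `vol`).
#' @param voxel_mm Voxel size, mm (scalar or length 3).
#' @param mask Optional logical/0-1 3D array.
#' @return Smoothed array, same shape; out-of-mask voxels set to 0.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_mm = 2, mask = NULL) {
  if (fwhm_mm <= 0) return(vol)
  if (length(dim(vol)) == 4L) {
    out <- vol
    for (t in seq_len(dim(vol)[4]))
      out[, , , t] <- smooth_volume(vol[, , , t], fwhm_mm, voxel_mm, mask)
    return(out)
  }
  voxel_mm <- rep(voxel_mm, length.out = 3)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  if (is.null(mask)) mask <- array(1, dim(vol))
  m <- mask * 1
  num <- gauss3d(vol * m, sigma)
  den <- gauss3d(m, sigma)
  out <- array(0, dim(vol))
  inm <- m > 0
  out[inm] <- num[inm] / den[inm]
  out
}

# separable 3D Gaussian convolution (zero-padded boundaries)
gauss3d <- function(a, sigma) {
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- exp(-((-r):r)^2 / (2 * sigma[ax]^2))
    k <- k / sum(k)
    a <- conv_axis(a, k, ax)
  }
  a
}

conv_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  m <- matrix(ap, nrow = n)
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    valid <- src >= 1L & src <= n
    out[valid, ] <- out[valid, ] + k[j] * m[src[valid], ]
  }
  aperm(array(out, dim(ap)), order(perm))
}

#' Variance inflation factors of a design matrix
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing (mean-removed) column j on all
#' other columns; perfect collinearity reports `Inf` and is flagged.
#'
#' @param X A `design_matrix` or numeric matrix.
#' @param classes Optional subset of column classes to report (the
#'   regression always uses all columns).
#' @return Tibble: `column`, `class`, `vif`, `flagged`.
#' @export
vif <- function(X, classes = NULL) {
  cls <- attr(X, "classes") %||% rep("condition", ncol(X))
  Xc <- scale(unclass(X), center = TRUE, scale = FALSE)
  out <- purrr::map_dbl(seq_len(ncol(Xc)), function(j) {
    fit <- lm.fit(Xc[, -j, drop = FALSE], Xc[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum(Xc[, j]^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
  res <- tibble(column = colnames(X), class = cls, vif = out,
                flagged = !is.finite(out))
  if (!is.null(classes)) res <- dplyr::filter(res, .data$class %in% classes)
  res
}
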