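#' Least-squares-separate single-trial estimation
#'
#' Fits one GLM per go trial: the design holds a regressor for the trial of
#' interest, one regressor per image identity for all remaining go trials
#' (the trial of interest is removed from its own image's regressor), a
#' no-go regressor, and any nuisance columns. The beta at the trial-of-
#' interest column is recorded, yielding one beta map per go trial.
#' Temporal derivatives are omitted by default.
#'
#' @param Y Numeric matrix (frames x voxels) or `bold_run`.
#' @param trials A `trial_table`.
#' @param nuisance Optional nuisance matrix (frames x regressors).
#' @param tr Repetition time (s).
#' @param n_frames Number of volumes (default from `Y`).
#' @return A `trial_betas` object: list with `betas` (go trials x voxels)
#'   and `meta` (the go-trial rows of `trials`).
#' @export
lss <- function(Y, trials, nuisance = NULL, tr = 1, n_frames = NULL) {
  if (inherits(Y, "bold_run")) { tr <- Y$tr; Y <- bold_matrix(Y) }
  Y <- as.matrix(Y)
  n_frames <- n_frames %||% nrow(Y)
  stopifnot(nrow(Y) == n_frames)
  go <- which(trials$condition != "nogo")
  # convolved unit regressor per trial (shared work across iterations)
  Xtr <- sapply(seq_len(nrow(trials)), function(i)
    convolve_events(trials$onset[i], trials$duration[i], 1, n_frames, tr))
  nogo_col <- if (any(trials$condition == "nogo"))
    rowSums(Xtr[, trials$condition == "nogo", drop = FALSE]) else NULL
  nuis <- if (!is.null(nuisance)) as.matrix(nuisance) else NULL
  betas <- matrix(NA_real_, length(go), ncol(Y))
  for (k in seq_along(go)) {
    i <- go[k]
    others <- setdiff(go, i)
    img <- trials$stimulus_id[others]
    other_cols <- sapply(split(others, img), function(idx)
      rowSums(Xtr[, idx, drop = FALSE]))
    X <- cbind(this_trial = Xtr[, i], other_cols, nogo = nogo_col, nuis, 1)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      abort(paste0("rank-deficient LSS design at trial ", i))
    betas[k, ] <- qr.coef(qrX, Y)[1, ]
  }
  structure(list(betas = betas, meta = trials[go, ]), class = "trial_betas")
}

#' @export
print.trial_betas <- function(x, ...) {
  cat("<trial_betas> ", nrow(x$betas), " trials x ", ncol(x$betas),
      " voxels\n", sep = "")
  invisible(x)
}

#' Restrict a trial-beta stack to a trial subset
#' @param x A `trial_betas` object.
#' @param which Logical or integer index over the rows of `x$meta`.
#' @return A `trial_betas` object.
#' @export
filter_betas <- function(x, which) {
  structure(list(betas = x$betas[which, , drop = FALSE],
                 meta = x$meta[which, ]), class = "trial_betas")
}
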