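#' Planted ground truth for synthetic BOLD data
#'
#' Describes, per voxel, the baseline response amplitude evoked by any image,
#' the modulation slope per feature model (in amplitude units per z-unit of
#' surprise), a population label, and optional per-stimulus additive pattern
#' amplitudes for stimulus-selective voxels. Slopes are zero outside the
#' population a model is planted in; the object is carried alongside every
#' synthetic run so analyses can be scored against it.
#'
#' @param dim Volume dimensions, e.g. `c(20, 20, 10)`.
#' @param baseline Scalar or 3D array of baseline amplitudes.
#' @param populations 3D character array of population labels
#'   (`high_scaling`, `low_scaling`, `null`, `non_selective`, ...); defaults
#'   to all `"null"`.
#' @param slopes Named list (one per feature model) of scalars or 3D arrays;
#'   a scalar is planted only in voxels whose population matches
#'   `slope_population[[model]]` (default `"high_scaling"`).
#' @param slope_population Named list mapping model to the population that
#'   carries its slope.
#' @param patterns Optional matrix (stimuli x voxels, rownames = stimulus
#'   ids) of additive per-stimulus amplitudes for selective voxels.
#' @param scrambled_gain Scalar or 3D array: multiplicative gain on the
#'   baseline for phase-scrambled localizer stimuli (< 1 in object-selective
#'   voxels yields the intact > scrambled contrast).
#' @param voxel_mm Isotropic voxel size in mm.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(dim, baseline = 1, populations = NULL,
                         slopes = list(), slope_population = list(),
                         patterns = NULL, scrambled_gain = 1, voxel_mm = 2) {
  as_vol <- function(x) if (length(x) == 1) array(x, dim) else {
    stopifnot(identical(base::dim(x), as.integer(dim))); x }
  populations <- populations %||% array("null", dim)
  slope_vols <- purrr::imap(slopes, function(s, m) {
    if (length(s) == 1) {
      pop <- slope_population[[m]] %||% "high_scaling"
      v <- array(0, dim)
      v[populations == pop] <- s
      v
    } else as_vol(s)
  })
  structure(list(dim = as.integer(dim), baseline = as_vol(baseline),
                 populations = populations, slopes = slope_vols,
                 patterns = patterns, scrambled_gain = as_vol(scrambled_gain),
                 voxel_mm = voxel_mm),
            class = "ground_truth")
}

#' 4D BOLD container
#'
#' @param data 4D array (x, y, z, time).
#' @param tr Repetition time in seconds.
#' @param mask Logical 3D array (defaults to all-TRUE).
#' @param truth Optional [ground_truth()] planted in the data.
#' @param voxel_mm Isotropic voxel size in mm.
#' @return A `bold_run` object.
#' @export
bold_run <- function(data, tr = 1, mask = NULL, truth = NULL, voxel_mm = 2) {
  stopifnot(length(dim(data)) == 4L, all(is.finite(data)))
  mask <- mask %||% array(TRUE, dim(data)[1:3])
  structure(list(data = data, tr = tr, mask = mask > 0, truth = truth,
                 voxel_mm = voxel_mm), class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_run> ", paste(d[1:3], collapse = "x"), " voxels x ", d[4],
      " frames (TR ", x$tr, " s), ", sum(x$mask), " in mask\n", sep = "")
  invisible(x)
}

#' In-mask time-by-voxel matrix of a BOLD run
#' @param run A `bold_run`.
#' @return Numeric matrix (frames x in-mask voxels, column order =
#'   `which(run$mask)`).
#' @export
bold_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4])[which(run$mask), , drop = FALSE])
}

# amplitude per trial per in-mask voxel implied by the ground truth
trial_amplitudes <- function(trials, surprise, truth, mask_idx) {
  n <- nrow(trials)
  amp <- matrix(rep(truth$baseline[mask_idx], each = n), n)
  un <- which(trials$condition == "unexpected")
  for (m in names(truth$slopes)) {
    if (all(truth$slopes[[m]] == 0)) next
    sv <- surprise[[m]]
    if (is.null(sv)) abort(paste0("no surprise vector supplied for planted model '", m, "'"))
    z <- sv$z[match(trials$trial[un], sv$trial)]
    if (anyNA(z)) abort("surprise vectors must cover all unexpected trials")
    amp[un, ] <- amp[un, ] + outer(z, truth$slopes[[m]][mask_idx])
  }
  amp
}

#' Simulate a main-task BOLD run with planted surprise scaling
#'
#' Voxel time-series are sums of HRF-convolved 0.5-s boxcars whose amplitude
#' on each trial is `baseline + sum_m slope_m * z_m(trial)` (slopes planted
#' per population in the ground truth), plus low-frequency cosine drift and
#' Gaussian (optionally AR(1)) noise.
#'
#' @param trials A `trial_table` from [generate_run()].
#' @param surprise Named list of `surprise` tibbles covering every model
#'   with a planted slope.
#' @param truth A [ground_truth()].
#' @param noise_sd SD of additive noise (0 = noiseless).
#' @param drift Drift spec: `list(n_basis, sd)` — random-amplitude cosines
#'   below the 1/128 Hz cutoff; `NULL` disables drift.
#' @param ar1 AR(1) coefficient for temporally correlated noise (0 = white).
#' @param tr Repetition time (s).
#' @param n_frames Number of volumes (default: run length plus 16-s tail).
#' @param mask Optional logical 3D array.
#' @param seed Optional integer seed.
#' @return A `bold_run` with the ground truth attached.
#' @export
synth_bold <- function(trials, surprise, truth, noise_sd = 1,
                       drift = list(n_basis = 3, sd = 0.5), ar1 = 0, tr = 1,
                       n_frames = NULL, mask = NULL, seed = NULL) {
  n_frames <- n_frames %||% default_frames(trials, tr)
  if (max(trials$onset + trials$duration) > n_frames * tr)
    abort("trial extends past the end of the run")
  mask <- (mask %||% array(TRUE, truth$dim)) > 0
  mask_idx <- which(mask)
  amp <- trial_amplitudes(trials, surprise, truth, mask_idx)
  # one convolved unit regressor per trial, shared across voxels
  Xtr <- sapply(seq_len(nrow(trials)), function(i)
    convolve_events(trials$onset[i], trials$duration[i], 1, n_frames, tr))
  sig <- Xtr %*% amp
  sig <- sig + with_seed(seed, noise_matrix(n_frames, length(mask_idx),
                                            noise_sd, drift, ar1, tr))
  vol <- array(0, c(truth$dim, n_frames))
  flat <- matrix(vol, prod(truth$dim), n_frames)
  flat[mask_idx, ] <- t(sig)
  bold_run(array(flat, c(truth$dim, n_frames)), tr = tr, mask = mask,
           truth = truth, voxel_mm = truth$voxel_mm)
}

noise_matrix <- function(n_frames, n_vox, noise_sd, drift, ar1, tr) {
  out <- matrix(0, n_frames, n_vox)
  if (!is.null(drift) && drift$n_basis > 0 && drift$sd > 0) {
    # low-order cosines with periods above 128 s (below the high-pass
    # cutoff frequency), so the 128-s filter removes them exactly
    B <- dct_basis(n_frames, tr, 128)[, -1, drop = FALSE]
    if (ncol(B) > 0) {
      B <- B[, seq_len(min(drift$n_basis, ncol(B))), drop = FALSE]
      out <- out + B %*% matrix(rnorm(ncol(B) * n_vox, sd = drift$sd),
                                ncol(B))
    }
  }
  if (noise_sd > 0) {
    e <- matrix(rnorm(n_frames * n_vox, sd = noise_sd), n_frames)
    if (ar1 != 0) {
      for (t in 2:n_frames) e[t, ] <- ar1 * e[t - 1, ] + e[t, ]
      e <- e * sqrt(1 - ar1^2) # stationary marginal sd = noise_sd
    }
    out <- out + e
  }
  out
}

#' Simulate a localizer BOLD run with stimulus-selective patterns
#'
#' Each 12-s miniblock evokes `baseline + pattern(stimulus)` in selective
#' voxels for intact images and `baseline * scrambled_gain` for
#' phase-scrambled images, convolved with the HRF, plus noise.
#'
#' @param trials A localizer `trial_table` ([generate_localizer()]).
#' @inheritParams synth_bold
#' @return A `bold_run`.
#' @export
synth_localizer_bold <- function(trials, truth, noise_sd = 1,
                                 drift = list(n_basis = 3, sd = 0.5),
                                 ar1 = 0, tr = 1, n_frames = NULL,
                                 mask = NULL, seed = NULL) {
  n_frames <- n_frames %||% default_frames(trials, tr)
  mask <- (mask %||% array(TRUE, truth$dim)) > 0
  mask_idx <- which(mask)
  n <- nrow(trials)
  amp <- matrix(rep(truth$baseline[mask_idx], each = n), n)
  scr <- trials$scrambled
  if (any(scr))
    amp[scr, ] <- amp[scr, ] * rep(truth$scrambled_gain[mask_idx],
                                   each = sum(scr))
  if (!is.null(truth$patterns)) {
    P <- truth$patterns[, mask_idx, drop = FALSE]
    ok <- !scr & trials$stimulus_id %in% rownames(P)
    amp[ok, ] <- amp[ok, ] + P[trials$stimulus_id[ok], , drop = FALSE]
  }
  Xtr <- sapply(seq_len(n), function(i)
    convolve_events(trials$onset[i], trials$duration[i], 1, n_frames, tr))
  sig <- Xtr %*% amp +
    with_seed(seed, noise_matrix(n_frames, length(mask_idx), noise_sd,
                                 drift, ar1, tr))
  vol <- matrix(0, prod(truth$dim), n_frames)
  vol[mask_idx, ] <- t(sig)
  bold_run(array(vol, c(truth$dim, n_frames)), tr = tr, mask = mask,
           truth = truth, voxel_mm = truth$voxel_mm)
}

#' Synthetic nuisance regressors for a run
#'
#' Emulates the standard confound set carried into first-level designs: six
#' rigid-body motion parameters (stationary AR(1) fluctuations — head motion
#' is bounded, not a random walk), framewise displacement (magnitude of the
#' motion derivative plus noise), and mean CSF and WM signals (slow AR(1)
#' plus measurement noise).
#'
#' @param n_frames Number of volumes.
#' @param seed Optional integer seed.
#' @return Numeric matrix `n_frames` x 9 with named columns.
#' @export
synth_nuisance <- function(n_frames, seed = NULL) {
  ar1 <- function(phi, sd) {
    e <- rnorm(n_frames, sd = sd)
    for (t in 2:n_frames) e[t] <- phi * e[t - 1] + e[t]
    e * sqrt(1 - phi^2)
  }
  with_seed(seed, {
    motion <- sapply(1:6, function(i) ar1(0.9, 0.05))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    fd <- c(0, rowSums(abs(diff(motion)))) + abs(rnorm(n_frames, sd = 0.01))
    csf <- ar1(0.8, 0.3) + rnorm(n_frames, sd = 0.2)
    wm <- ar1(0.8, 0.3) + rnorm(n_frames, sd = 0.2)
    cbind(motion, fd = fd, csf = csf, wm = wm)
  })
}

#' Simulate behavioural responses for a trial table
#'
#' Go-trial reaction times are Gaussian per condition (truncated at 0 by
#' resampling) with the three-condition means of the facilitation effect
#' (expected < unexpected-same < unexpected-different); correctness is
#' Bernoulli per condition; no-go trials receive no response except for
#' false alarms.
#'
#' @param trials A `trial_table`.
#' @param stimuli The [stimulus_set()] (for the animacy same/different split).
#' @param rt_means Named means in ms for `expected`, `unexpected_same`,
#'   `unexpected_diff`.
#' @param rt_sd RT standard deviation in ms.
#' @param error_rates Named error probabilities per condition.
#' @param false_alarm_rate Probability of responding on a no-go trial.
#' @param seed Optional integer seed.
#' @return Tibble: trial metadata plus `condition3`, `responded`, `correct`,
#'   `rt` (ms; `NA` when no response).
#' @export
synth_behavior <- function(trials, stimuli,
                           rt_means = c(expected = 501, unexpected_same = 509,
                                        unexpected_diff = 524),
                           rt_sd = 90,
                           error_rates = c(expected = 0.02,
                                           unexpected_same = 0.03,
                                           unexpected_diff = 0.06),
                           false_alarm_rate = 0.02, seed = NULL) {
  an <- setNames(stimuli$animacy, stimuli$stimulus_id)
  cond3 <- dplyr::case_when(
    trials$condition == "nogo" ~ "nogo",
    trials$condition == "expected" ~ "expected",
    an[trials$stimulus_id] == an[trials$expected_id] ~ "unexpected_same",
    TRUE ~ "unexpected_diff"
  )
  with_seed(seed, {
    n <- nrow(trials)
    rt <- rep(NA_real_, n)
    correct <- rep(NA, n)
    responded <- rep(FALSE, n)
    go <- cond3 != "nogo"
    responded[go] <- TRUE
    rt[go] <- rnorm(sum(go), rt_means[cond3[go]], rt_sd)
    while (any(bad <- go & !is.na(rt) & rt <= 0))
      rt[bad] <- rnorm(sum(bad), rt_means[cond3[bad]], rt_sd)
    correct[go] <- rbinom(sum(go), 1, 1 - error_rates[cond3[go]]) == 1
    fa <- !go & runif(n) < false_alarm_rate
    responded[fa] <- TRUE
    correct[!go] <- !fa[!go] # correct no-go = withheld response
    rt[fa] <- abs(rnorm(sum(fa), rt_means["expected"], rt_sd))
    dplyr::mutate(trials, condition3 = cond3, responded = responded,
                  correct = correct, rt = rt)
  })
}
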