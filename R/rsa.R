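#' Searchlight sphere definition
#'
#' One sphere per in-mask voxel: all in-mask voxels within `radius_mm`
#' Euclidean distance of the center. At 2-mm isotropic voxels a 6-mm radius
#' sphere deep inside the mask has 123 members.
#'
#' @param mask Logical 3D array.
#' @param radius_mm Sphere radius in mm.
#' @param voxel_mm Voxel size in mm (scalar or length 3).
#' @return A `searchlights` object: list with `centers` (indices into the
#'   in-mask voxel vector, i.e. columns of [bold_matrix()]) and `members`
#'   (list of in-mask indices per sphere, center included).
#' @export
make_searchlights <- function(mask, radius_mm = 6, voxel_mm = 2) {
  mask <- mask > 0
  dims <- dim(mask)
  voxel_mm <- rep(voxel_mm, length.out = 3)
  r <- floor(radius_mm / voxel_mm)
  off <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2],
                               dz = -r[3]:r[3]))
  dist <- sqrt(colSums((t(off) * voxel_mm)^2))
  off <- off[dist <= radius_mm, , drop = FALSE]
  vox_col <- array(NA_integer_, dims)
  vox_col[mask] <- seq_len(sum(mask))
  centers_lin <- which(mask)
  co <- arrayInd(centers_lin, dims)
  members <- purrr::map(seq_along(centers_lin), function(i) {
    cand <- sweep(off, 2, co[i, ], `+`)
    ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
      cand[, 2] >= 1 & cand[, 2] <= dims[2] &
      cand[, 3] >= 1 & cand[, 3] <= dims[3]
    cand <- cand[ok, , drop = FALSE]
    cols <- vox_col[cand]
    sort(cols[!is.na(cols)])
  })
  structure(list(centers = seq_len(sum(mask)), members = members,
                 radius_mm = radius_mm, mask = mask),
            class = "searchlights")
}

#' @export
print.searchlights <- function(x, ...) {
  cat("<searchlights> ", length(x$centers), " spheres, radius ",
      x$radius_mm, " mm\n", sep = "")
  invisible(x)
}

#' Per-stimulus GLM betas from a localizer run
#'
#' Fits one HRF-convolved regressor per stimulus (intact and scrambled
#' conditions separated) against baseline, the standard first-level model
#' whose per-stimulus parameter estimates feed the searchlight RSA.
#'
#' @param Y Frames x voxels matrix or `bold_run`.
#' @param trials A localizer `trial_table` ([generate_localizer()]).
#' @param tr Repetition time (s).
#' @param intact_only Return only intact-stimulus betas?
#' @return Matrix stimuli x voxels (rownames = stimulus ids).
#' @export
stimulus_glm <- function(Y, trials, tr = 1, intact_only = TRUE) {
  if (inherits(Y, "bold_run")) { tr <- Y$tr; Y <- bold_matrix(Y) }
  key <- ifelse(trials$scrambled, paste0(trials$stimulus_id, "_scr"),
                trials$stimulus_id)
  cols <- purrr::map(split(seq_len(nrow(trials)), key), function(idx)
    convolve_events(trials$onset[idx], trials$duration[idx],
                    rep(1, length(idx)), nrow(Y), tr))
  X <- do.call(cbind, cols)
  fit <- fit_glm(Y, structure(X, classes = rep("condition", ncol(X)),
                              tr = tr,
                              class = c("design_matrix", "matrix", "array")))
  b <- fit$beta[colnames(X), , drop = FALSE]
  if (intact_only) b <- b[!grepl("_scr$", rownames(b)), , drop = FALSE]
  b
}

#' Neural RDM from stimulus patterns
#'
#' Z-scores parameter estimates per voxel across stimuli, then computes
#' pairwise cosine distance (1 - cosine similarity) between the stimulus
#' pattern vectors. Voxels without variance across stimuli carry no pattern
#' information and are excluded.
#'
#' @param patterns Numeric matrix, stimuli x voxels (rownames = ids).
#' @return An `rdm`.
#' @export
neural_rdm <- function(patterns) {
  stopifnot(nrow(patterns) >= 3)
  v <- apply(patterns, 2, sd)
  z <- scale(patterns[, v > 0, drop = FALSE])
  if (ncol(z) < 2) abort("need >= 2 voxels with stimulus variance")
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) abort("zero-norm pattern after z-scoring")
  cs <- tcrossprod(z / nrm)
  d <- 1 - cs
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  new_rdm((d + t(d)) / 2, rownames(patterns))
}

#' Kendall tau-a between neural and model RDM lower triangles
#'
#' @param neural,model `rdm` objects over the same stimuli.
#' @return Tibble: `tau`, `fisher_z`.
#' @export
rsa_tau <- function(neural, model) {
  stopifnot(identical(rownames(neural), rownames(model)))
  mv <- rdm_ltv(model)
  if (sd(mv) == 0) abort("constant model RDM: tau undefined")
  tau <- kendall_tau_a(rdm_ltv(neural), mv)
  tibble(tau = tau, fisher_z = fisher_z(tau))
}

#' Searchlight RSA map for one subject
#'
#' For every searchlight sphere, builds the neural RDM from the stimulus
#' patterns restricted to the sphere and correlates its lower triangle with
#' each model RDM (Kendall tau-a, Fisher z transformed).
#'
#' @param patterns Stimulus patterns, stimuli x in-mask voxels.
#' @param searchlights A [make_searchlights()] object.
#' @param model_rdms Named list of model `rdm`s.
#' @return Matrix of Fisher-z values, spheres x models.
#' @export
searchlight_rsa <- function(patterns, searchlights, model_rdms) {
  labs <- rownames(model_rdms[[1]])
  for (m in model_rdms) stopifnot(identical(rownames(m), labs))
  if (!is.null(rownames(patterns))) {
    if (!setequal(rownames(patterns), labs))
      abort("pattern stimuli do not match model RDM labels")
    patterns <- patterns[labs, , drop = FALSE]
  }
  n <- nrow(patterns)
  npair <- n * (n - 1)
  lt <- lower.tri(matrix(0, n, n))
  model_sy <- purrr::map(model_rdms, function(m) {
    v <- m[lt]
    if (sd(v) == 0) abort("constant model RDM: tau undefined")
    sign(outer(v, v, `-`))
  })
  k <- length(rdm_ltv(model_rdms[[1]]))
  out <- matrix(NA_real_, length(searchlights$centers), length(model_rdms),
                dimnames = list(NULL, names(model_rdms)))
  for (i in seq_along(searchlights$centers)) {
    p <- patterns[, searchlights$members[[i]], drop = FALSE]
    v <- apply(p, 2, sd)
    p <- p[, v > 0, drop = FALSE]
    if (ncol(p) < 2) next
    z <- scale(p)
    nrm <- sqrt(rowSums(z^2))
    if (any(nrm == 0)) next
    d <- 1 - tcrossprod(z / nrm)
    nv <- d[lt]
    sx <- sign(outer(nv, nv, `-`))
    taus <- purrr::map_dbl(model_sy, ~ sum(sx * .x) / (k * (k - 1)))
    out[i, ] <- fisher_z(taus)
  }
  out
}

#' Group best-layer map from per-subject searchlight RSA
#'
#' Per sphere, the layer with the largest group-mean Fisher-z RSA
#' correlation (ties broken toward the earlier layer); spheres whose best
#' layer does not exceed the group one-sample z threshold stay unlabeled
#' (`NA`).
#'
#' @param subject_fz List over subjects of spheres x layers Fisher-z
#'   matrices ([searchlight_rsa()]).
#' @param threshold_z Group z threshold (3.1 = p < 0.001 uncorrected).
#' @return Tibble: `unit`, `best_layer` (integer index, `NA` below
#'   threshold), `mean_fisher_z`, `group_z`.
#' @export
best_layer_map <- function(subject_fz, threshold_z = 3.1) {
  arr <- simplify2array(subject_fz) # spheres x layers x subjects
  mean_fz <- apply(arr, c(1, 2), mean)
  best <- max.col(replace(mean_fz, is.na(mean_fz), -Inf), "first")
  stats <- purrr::map_dfr(seq_len(nrow(mean_fz)), function(i) {
    x <- arr[i, best[i], ]
    if (anyNA(x) || sd(x) == 0)
      return(tibble(group_z = NA_real_))
    tibble(group_z = t_to_z(mean(x) / (sd(x) / sqrt(length(x))),
                            length(x) - 1))
  })
  tibble(unit = seq_len(nrow(mean_fz)),
         best_layer = ifelse(!is.na(stats$group_z) &
                               stats$group_z >= threshold_z, best, NA_integer_),
         mean_fisher_z = mean_fz[cbind(seq_along(best), best)],
         group_z = stats$group_z)
}
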