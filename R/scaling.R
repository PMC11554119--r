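#' Build regions of interest with overlap arbitration and voxel selection
#'
#' Anatomical masks are dilated with a Gaussian kernel, overlapping voxels
#' are assigned to the smaller mask, and a voxel subset is selected per ROI:
#' the `k` most (or least) informative voxels of a localizer decoding map,
#' or all stimulus-driven voxels above a z threshold.
#'
#' @param masks Named list of logical 3D arrays (anatomical ROI masks).
#' @param score_map 3D array used for selection: decoding accuracy
#'   (`top_k_decoding` / `bottom_k_decoding`) or a localizer z map
#'   (`stimulus_driven`).
#' @param rule Selection rule.
#' @param k Voxels to select under the top/bottom-k rules.
#' @param dilate_fwhm_mm FWHM of the dilation kernel (0 = none).
#' @param voxel_mm Voxel size in mm.
#' @param driven_z Threshold for the `stimulus_driven` rule.
#' @return Named list of `roi_spec` objects: `name`, `anatomical` (linear
#'   voxel indices after arbitration), `selected`, `rule`, `k`.
#' @export
build_rois <- function(masks, score_map, rule = c("top_k_decoding",
                                                  "bottom_k_decoding",
                                                  "stimulus_driven"),
                       k = 200L, dilate_fwhm_mm = 3, voxel_mm = 2,
                       driven_z = 3.1) {
  rule <- match.arg(rule)
  dims <- dim(score_map)
  dil <- purrr::map(masks, function(m) {
    m <- (m > 0) * 1
    if (dilate_fwhm_mm > 0) {
      sigma <- dilate_fwhm_mm / (2 * sqrt(2 * log(2))) / rep(voxel_mm, 3)
      m <- (gauss3d(m, sigma) > 0.05) * 1
    }
    array(m > 0, dims)
  })
  # overlap arbitration: shared voxels go to the smaller mask
  sizes <- purrr::map_int(dil, ~ sum(.x))
  for (a in names(dil)) for (b in names(dil)) {
    if (a == b) next
    shared <- dil[[a]] & dil[[b]]
    if (!any(shared)) next
    loser <- if (sizes[a] <= sizes[b]) b else a
    dil[[loser]][shared] <- FALSE
  }
  purrr::imap(dil, function(m, nm) {
    anat <- which(m)
    sel <- switch(rule,
      top_k_decoding = anat[order(score_map[anat],
                                  decreasing = TRUE)][seq_len(min(k, length(anat)))],
      bottom_k_decoding = anat[order(score_map[anat])][seq_len(min(k, length(anat)))],
      stimulus_driven = anat[score_map[anat] >= driven_z])
    if (!length(sel)) abort(paste0("ROI '", nm, "' is empty after selection"))
    structure(list(name = nm, anatomical = anat, selected = sort(sel),
                   rule = rule, k = as.integer(k)), class = "roi_spec")
  })
}

#' Regress single-trial BOLD estimates onto surprise
#'
#' The core scaling analysis: per subject, ordinary least squares of the
#' unexpected-trial beta (ROI mean, or each voxel) on z-scored surprise
#' under one or more feature models. Slopes quantify how much the
#' prediction-error response grows per z-unit of surprise; per-model Pearson
#' r is reported alongside.
#'
#' @param betas A `trial_betas` stack (all trials or unexpected-only; the
#'   unexpected subset is taken via its metadata).
#' @param surprise A `surprise` tibble or named list of them.
#' @param voxels Optional voxel column indices (ROI); scope is the ROI mean
#'   when given, each voxel otherwise.
#' @return Scope `"roi"`: tibble `model_id`, `slope`, `intercept`, `r`,
#'   `n_trials`. Scope `"voxel"`: list with matrices `slope` and `r`
#'   (voxels x models).
#' @export
scaling_regression <- function(betas, surprise, voxels = NULL) {
  if (inherits(surprise, "surprise")) {
    surprise <- setNames(list(surprise), surprise$model_id[1])
  }
  un <- betas$meta$condition == "unexpected"
  meta <- betas$meta[un, ]
  if (nrow(meta) < 8) abort("need >= 8 unexpected trials for scaling regression")
  B <- betas$betas[un, , drop = FALSE]
  zs <- purrr::map(surprise, function(sv) {
    z <- sv$z[match(meta$trial, sv$trial)]
    if (anyNA(z)) abort("surprise vector does not cover all unexpected trials")
    if (sd(z) == 0) abort("degenerate surprise variance")
    z
  })
  if (!is.null(voxels)) {
    y <- rowMeans(B[, voxels, drop = FALSE])
    purrr::imap_dfr(zs, function(z, m) {
      fit <- lm.fit(cbind(1, z), y)
      tibble(model_id = m, slope = unname(fit$coefficients[2]),
             intercept = unname(fit$coefficients[1]),
             r = if (sd(y) > 0) cor(z, y) else NA_real_,
             n_trials = length(y))
    })
  } else {
    Z <- do.call(cbind, zs)
    Bc <- scale(B, scale = FALSE)
    Zc <- scale(Z, scale = FALSE)
    slope <- t(crossprod(Zc, Bc) / colSums(Zc^2)) # voxels x models
    sdB <- apply(B, 2, sd)
    r <- t(crossprod(scale(Z), scale(B))) / (nrow(B) - 1)
    r[sdB == 0, ] <- NA_real_
    colnames(slope) <- colnames(r) <- names(zs)
    list(slope = slope, r = r, n_trials = nrow(B))
  }
}

#' Group inference on subject-level scaling slopes
#'
#' @param subject_slopes Tibble with columns `subject`, `model_id`, `slope`
#'   (and optionally `r`), one row per subject x model (e.g., stacked
#'   ROI-scope results of [scaling_regression()]).
#' @param test Passed to [group_test()].
#' @return Tibble per model: group statistic, p, Cohen's dz / rank-biserial,
#'   mean slope, mean r, 95% CI of the mean slope.
#' @export
scaling_group <- function(subject_slopes, test = "t") {
  subject_slopes |>
    dplyr::group_by(.data$model_id) |>
    dplyr::group_modify(function(d, key) {
      gt <- group_test(d$slope, test = test)
      ci <- tryCatch(t.test(d$slope)$conf.int, error = function(e) c(NA, NA))
      dplyr::bind_cols(gt[, c("n", "statistic", "p", "effect_size")],
                       tibble(mean_slope = mean(d$slope),
                              mean_r = if ("r" %in% names(d)) mean(d$r) else NA_real_,
                              ci_low = ci[1], ci_high = ci[2]))
    }) |>
    dplyr::ungroup()
}

#' Per-voxel best-layer map of the prediction-error scaling
#'
#' For each voxel, single-layer regressions of the unexpected-trial betas on
#' each layer's surprise are compared by explained variance (squared
#' correlation); the label is the layer with the largest group-mean R^2
#' (ties to the earlier layer), masked to voxels where the best layer's
#' group one-sample z on subject slopes passes `threshold_z`.
#'
#' @param subject_fits List over subjects of voxel-scope
#'   [scaling_regression()] results (with layer models in column order).
#' @param threshold_z Group z threshold (1.96 = p < 0.05 two-sided).
#' @return Tibble: `unit`, `best_layer`, `mean_r2`, `group_z`.
#' @export
best_layer_effect_map <- function(subject_fits, threshold_z = 1.96) {
  r2 <- simplify2array(purrr::map(subject_fits, ~ .x$r^2))
  slopes <- simplify2array(purrr::map(subject_fits, ~ .x$slope))
  mean_r2 <- apply(r2, c(1, 2), mean)
  best <- max.col(replace(mean_r2, is.na(mean_r2), -Inf), "first")
  ns <- dim(slopes)[3]
  gz <- purrr::map_dbl(seq_along(best), function(i) {
    x <- slopes[i, best[i], ]
    if (anyNA(x) || sd(x) == 0) return(NA_real_)
    t_to_z(mean(x) / (sd(x) / sqrt(ns)), ns - 1)
  })
  tibble(unit = seq_along(best),
         best_layer = ifelse(!is.na(gz) & abs(gz) >= threshold_z, best,
                             NA_integer_),
         mean_r2 = mean_r2[cbind(seq_along(best), best)], group_z = gz)
}

#' ROI tests of parametric-modulator estimates
#'
#' One-sample tests of each modulator's subject-level contrast estimates
#' against zero per ROI, pairwise paired tests between modulators, and
#' Benjamini-Hochberg correction across ROIs x modulators (within each test
#' family). Cohen's dz (or rank-biserial) and, for the against-zero tests, a
#' default-prior JZS Bayes factor (Cauchy scale 0.707) are reported.
#'
#' @param estimates Tibble: `subject`, `roi`, `model_id`, `estimate`.
#' @param test `"t"`, `"wilcoxon"`, or `"auto"` (Shapiro-Wilk p < 0.05
#'   selects the Wilcoxon test).
#' @return List of tibbles `vs_zero` and `pairwise`.
#' @export
roi_modulator_tests <- function(estimates, test = "t") {
  pick_test <- function(x) {
    if (test != "auto") return(test)
    if (stats::shapiro.test(x)$p.value < 0.05) "wilcoxon" else "t"
  }
  vs_zero <- estimates |>
    dplyr::group_by(.data$roi, .data$model_id) |>
    dplyr::group_modify(function(d, key) {
      tst <- pick_test(d$estimate)
      gt <- group_test(d$estimate, test = tst)
      tval <- if (tst == "t") gt$statistic else
        mean(d$estimate) / (sd(d$estimate) / sqrt(nrow(d)))
      dplyr::bind_cols(gt[, c("n", "statistic", "p", "effect_size")],
                       tibble(test = tst,
                              bf10 = bf_one_sample(tval, nrow(d))))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(p_fdr = p.adjust(.data$p, method = "BH"))
  models <- unique(estimates$model_id)
  pairs <- if (length(models) >= 2) utils::combn(models, 2, simplify = FALSE) else list()
  pairwise <- purrr::map_dfr(unique(estimates$roi), function(rn) {
    purrr::map_dfr(pairs, function(pr) {
      wide <- estimates |>
        dplyr::filter(.data$roi == rn, .data$model_id %in% pr) |>
        tidyr::pivot_wider(id_cols = "subject", names_from = "model_id",
                           values_from = "estimate")
      d <- wide[[pr[1]]] - wide[[pr[2]]]
      tst <- pick_test(d)
      gt <- group_test(d, test = tst)
      tibble(roi = rn, model_a = pr[1], model_b = pr[2], n = gt$n,
             statistic = gt$statistic, p = gt$p,
             effect_size = gt$effect_size, test = tst)
    })
  })
  if (nrow(pairwise))
    pairwise$p_fdr <- p.adjust(pairwise$p, method = "BH")
  list(vs_zero = vs_zero, pairwise = pairwise)
}

#' Expectation-suppression contrast (unexpected minus expected)
#'
#' @param fit A `pe_glm` whose design has `expected` and `unexpected`
#'   condition columns.
#' @return A [glm_contrast()] tibble.
#' @export
expectation_suppression_contrast <- function(fit) {
  glm_contrast(fit, c(unexpected = 1, expected = -1))
}
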