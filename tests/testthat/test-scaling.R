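test_that("ROI construction arbitrates overlap toward the smaller mask", {
  dims <- c(12, 10, 5)
  small <- array(FALSE, dims); small[1:5, 1:6, ] <- TRUE    # 150 voxels
  large <- array(FALSE, dims); large[4:12, 1:6, ] <- TRUE   # 270 voxels
  score <- array(runif(prod(dims)), dims)
  rois <- build_rois(list(small = small, large = large), score,
                     k = 1000, dilate_fwhm_mm = 0)
  shared <- which(small & large)
  expect_true(all(shared %in% rois$small$anatomical))
  expect_false(any(shared %in% rois$large$anatomical))
  # k = available returns the whole (arbitrated) mask
  expect_setequal(rois$small$selected, rois$small$anatomical)
  # top-k rule keeps the k best-scoring voxels
  r200 <- build_rois(list(small = small), score, k = 100, dilate_fwhm_mm = 0)
  expect_length(r200$small$selected, 100)
  expect_gte(min(score[r200$small$selected]),
             max(score[setdiff(r200$small$anatomical,
                               r200$small$selected)]))
  # bottom-k selects the least informative voxels
  rb <- build_rois(list(small = small), score, rule = "bottom_k_decoding",
                   k = 100, dilate_fwhm_mm = 0)
  expect_lte(max(score[rb$small$selected]),
             min(score[setdiff(rb$small$anatomical, rb$small$selected)]))
  # k sweep (the 100..500 mask-size robustness analysis) is supported
  sweep_sizes <- purrr::map_int(c(50, 100, 150), function(k)
    length(build_rois(list(small = small), score, k = k,
                      dilate_fwhm_mm = 0)$small$selected))
  expect_equal(sweep_sizes, c(50L, 100L, 150L))
  expect_error(build_rois(list(a = array(FALSE, dims)), score,
                          dilate_fwhm_mm = 0), "empty")
})

test_that("scaling regression recovers planted slopes and honors invariances", {
  set.seed(1)
  n <- 56
  z <- as.numeric(scale(rnorm(n)))
  sv <- fx_surprise(1:n, z, "layer8")
  meta <- tibble::tibble(trial = 1:n, condition = "unexpected")
  B <- matrix(rep(0.5 + 2 * sv$z, 10), n, 10) # 10 voxels, identical slope
  tb <- structure(list(betas = B, meta = meta), class = "trial_betas")
  fit <- scaling_regression(tb, sv, voxels = 1:10)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  # adding a constant to all betas leaves the slope unchanged
  tb2 <- structure(list(betas = B + 100, meta = meta), class = "trial_betas")
  expect_equal(scaling_regression(tb2, sv, voxels = 1:10)$slope, 2,
               tolerance = 1e-12)
  # voxel-wise and ROI-mean slopes agree under a shared planted slope
  vox <- scaling_regression(tb, sv)
  expect_equal(unname(vox$slope[, 1]), rep(2, 10), tolerance = 1e-12)
  # permutation null centers at zero
  perm_slopes <- purrr::map_dbl(1:200, function(i) {
    svp <- sv; svp$z <- sample(svp$z)
    scaling_regression(tb, svp, voxels = 1:10)$slope
  })
  expect_lt(abs(mean(perm_slopes)), 0.15)
  expect_error(scaling_regression(filter_betas(tb, 1:6), sv, voxels = 1),
               ">= 8 unexpected")
})

test_that("group scaling inference separates planted and null models", {
  set.seed(2)
  subj <- purrr::map_dfr(1:20, function(s) {
    z8 <- as.numeric(scale(rnorm(56)))
    z2 <- as.numeric(scale(rnorm(56)))
    y <- 1 * z8 + rnorm(56, sd = 3)
    tibble::tibble(
      subject = s,
      model_id = c("layer8", "layer2"),
      slope = c(coef(lm(y ~ z8))[2], coef(lm(y ~ z2))[2]),
      r = c(cor(y, z8), cor(y, z2)))
  })
  grp <- scaling_group(subj)
  expect_lt(grp$p[grp$model_id == "layer8"], 0.001)
  l2 <- grp[grp$model_id == "layer2", ]
  expect_true(l2$ci_low <= 0 && l2$ci_high >= 0)
})

test_that("best-layer effect maps label planted layers with earlier-layer ties", {
  set.seed(3)
  n <- 56; nvox <- 30
  zs <- purrr::map(1:8, ~ as.numeric(scale(rnorm(n))))
  names(zs) <- paste0("layer", 1:8)
  svs <- purrr::imap(zs, ~ fx_surprise(1:n, .x, .y))
  meta <- tibble::tibble(trial = 1:n, condition = "unexpected")
  fits <- purrr::map(1:8, function(s) {
    B <- sapply(1:nvox, function(v) 1.5 * zs$layer8 + rnorm(n, sd = 1))
    tb <- structure(list(betas = B, meta = meta), class = "trial_betas")
    scaling_regression(tb, svs)
  })
  blm <- best_layer_effect_map(fits, threshold_z = 1.96)
  lab <- blm$best_layer[!is.na(blm$best_layer)]
  expect_gt(length(lab), 0)
  expect_gt(mean(lab == 8), 0.9)
  # identical surprise vectors for two layers tie toward the earlier layer
  svs2 <- svs; svs2$layer7 <- fx_surprise(1:n, zs$layer8, "layer7")
  fits2 <- purrr::map(1:8, function(s) {
    B <- sapply(1:nvox, function(v) 1.5 * zs$layer8 + rnorm(n, sd = 0.5))
    tb <- structure(list(betas = B, meta = meta), class = "trial_betas")
    scaling_regression(tb, svs2)
  })
  blm2 <- best_layer_effect_map(fits2, threshold_z = 1.96)
  lab2 <- blm2$best_layer[!is.na(blm2$best_layer)]
  expect_true(all(lab2 == 7)) # layer7 == layer8 by construction; earlier wins
  # pure-noise fits stay unlabeled at a high threshold
  fits0 <- purrr::map(1:8, function(s) {
    B <- sapply(1:nvox, function(v) rnorm(n))
    tb <- structure(list(betas = B, meta = meta), class = "trial_betas")
    scaling_regression(tb, svs)
  })
  blm0 <- best_layer_effect_map(fits0, threshold_z = 6)
  expect_true(all(is.na(blm0$best_layer)))
})

test_that("ROI modulator tests apply BH correction, effect sizes and Bayes factors", {
  set.seed(4)
  est <- tidyr::expand_grid(subject = 1:15, roi = c("V1", "LOC"),
                            model_id = c("layer8", "layer2")) |>
    dplyr::mutate(estimate = ifelse(.data$model_id == "layer8",
                                    rnorm(dplyr::n(), 1, 1),
                                    rnorm(dplyr::n(), 0, 1)))
  res <- roi_modulator_tests(est)
  expect_equal(res$vs_zero$p_fdr, p.adjust(res$vs_zero$p, "BH"))
  expect_true(all(res$vs_zero$p_fdr >= res$vs_zero$p))
  expect_true(all(res$pairwise$p_fdr >= res$pairwise$p))
  # planted effect detected; pairwise layer8 > layer2 present per ROI
  expect_true(all(res$vs_zero$p_fdr[res$vs_zero$model_id == "layer8"] < 0.05))
  expect_equal(nrow(res$pairwise), 2)
  # null estimates give BF10 < 1 (support for no modulation)
  null_est <- dplyr::mutate(est,
                            estimate = ifelse(.data$subject %% 2 == 0,
                                              0.01, -0.01))
  res0 <- roi_modulator_tests(null_est)
  expect_true(all(res0$vs_zero$bf10 < 1))
})

test_that("expectation-suppression contrast isolates the condition difference", {
  run <- fx_run(seed = 7)
  truth <- fx_truth(dim = c(4, 4, 2), slope = 0)
  # planted suppression: expected amplitude lower than unexpected
  amp_gain <- ifelse(run$condition == "expected", 0.5,
                     ifelse(run$condition == "unexpected", 1, 0.8))
  n <- default_frames(run, 1)
  Xtr <- sapply(seq_len(nrow(run)), function(i)
    pescale:::convolve_events(run$onset[i], run$duration[i], 1, n, 1))
  y <- Xtr %*% amp_gain
  X <- build_design(run, tr = 1, add_derivatives = FALSE)
  fit <- fit_glm(cbind(y, y), X)
  es <- expectation_suppression_contrast(fit)
  expect_equal(es$estimate, rep(0.5, 2), tolerance = 1e-6)
  # symmetric amplitudes -> zero contrast
  y0 <- Xtr %*% rep(1, nrow(run))
  es0 <- expectation_suppression_contrast(fit_glm(cbind(y0), X))
  expect_equal(es0$estimate, 0, tolerance = 1e-8)
})
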