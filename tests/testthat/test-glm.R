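test_that("double-gamma HRF has the canonical shape", {
  tg <- seq(0, 32, 0.01)
  h <- hrf_double_gamma(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  peak_t <- tg[which.max(h)]
  expect_gte(peak_t, 4); expect_lte(peak_t, 7)
  expect_lt(min(h), 0)                      # undershoot exists
  expect_lt(abs(min(h)), max(h))            # and is smaller than the peak
  expect_error(hrf_double_gamma(c(-1, 0, 1)), "non-negative")
})

test_that("design matrices carry conditions, modulators, derivatives, nuisance", {
  run <- fx_run(seed = 4)
  rd <- fx_rdms()
  sv <- list(layer8 = trial_surprise(rd$layer8, run, "layer8"),
             layer2 = trial_surprise(rd$layer2, run, "layer2"))
  nuis <- matrix(rnorm(default_frames(run, 1) * 3), ncol = 3,
                 dimnames = list(NULL, c("mot1", "mot2", "fd")))
  X <- build_design(run, sv, nuisance = nuis, tr = 1)
  cls <- table(attr(X, "classes"))
  expect_equal(unname(cls["condition"]), 3L)
  expect_equal(unname(cls["modulator"]), 2L)
  expect_equal(unname(cls["derivative"]), 5L)  # one per task regressor
  expect_equal(unname(cls["nuisance"]), 3L)
  # no unexpected trials: modulators dropped with a warning
  exp_only <- run[run$condition == "expected", ]
  expect_warning(X0 <- build_design(exp_only, sv["layer8"], tr = 1),
                 "no unexpected trials")
  expect_false("layer8" %in% colnames(X0))
})

test_that("modulators are near-orthogonal to the unexpected main effect", {
  st <- fx_stimuli()
  tpm <- build_tpm(st)
  rd <- fx_rdms()
  rs <- purrr::map_dbl(1:25, function(s) {
    run <- generate_run(tpm, st, seed = 1000 + s)
    sv <- trial_surprise(rd$layer8, run, "layer8")
    X <- build_design(run, list(layer8 = sv), tr = 1, add_derivatives = FALSE)
    cor(X[, "unexpected"], X[, "layer8"])
  })
  expect_lt(max(abs(rs)), 0.3)
})

test_that("high-pass filtering removes slow drift and spares fast signal", {
  n <- 400; tr <- 1
  expect_equal(highpass(rep(3, n), tr), rep(0, n))
  tg <- (seq_len(n) - 1) * tr
  slow <- cos(2 * pi * tg / 256)
  expect_lt(sd(highpass(slow, tr)) / sd(slow), 0.05)  # >95% attenuated
  fast <- cos(2 * pi * tg / 32)
  expect_gt(sd(highpass(fast, tr)) / sd(fast), 0.95)  # passband untouched
  # white-noise variance drops by at most basis-dim/n
  set.seed(1)
  e <- matrix(rnorm(n * 50), n)
  k <- floor(2 * n * tr / 128) + 1
  ratio <- sum(highpass(e, tr)^2) / sum(e^2)
  expect_gte(ratio, 1 - 2 * k / n)
  expect_lt(ratio, 1)
  # planted cosine drift from the generator is removed by the filter
  tt <- fx_spaced_trials(4)
  truth <- fx_truth(dim = c(4, 4, 2), slope = 0)
  bd <- synth_bold(tt, list(), truth, noise_sd = 0,
                   drift = list(n_basis = 3, sd = 1), seed = 2)
  b0 <- synth_bold(tt, list(), truth, noise_sd = 0, drift = NULL)
  y_drift <- highpass(bold_matrix(bd), tr)
  y_clean <- highpass(bold_matrix(b0), tr)
  expect_lt(max(abs(y_drift - y_clean)), 0.05 * diff(range(y_clean)))
})

test_that("Gaussian smoothing has the right kernel width and conserves mass", {
  d <- c(21, 21, 15)
  vol <- array(0, d)
  expect_identical(smooth_volume(vol + 1, 0), vol + 1)
  vol[11, 11, 8] <- 1
  sm <- smooth_volume(vol, fwhm_mm = 5, voxel_mm = 2)
  # delta response: fit sigma from the second moment along x
  x <- seq_len(d[1])
  w <- sm[, 11, 8] / sum(sm[, 11, 8])
  sigma_vox <- sqrt(sum(w * (x - 11)^2))
  expect_equal(sigma_vox, 5 / 2.3548 / 2, tolerance = 0.05)
  # total sum preserved when the kernel lies deep inside the mask
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # mask-aware renormalization: constant stays constant near edges
  smc <- smooth_volume(array(2, d), 5, 2, mask = array(TRUE, d))
  expect_equal(max(abs(smc - 2)), 0, tolerance = 1e-9)
})

test_that("OLS fit, contrasts, and diagnostics behave", {
  set.seed(2)
  run <- fx_spaced_trials(8)
  X <- build_design(run, tr = 1, add_derivatives = FALSE)
  n <- nrow(X)
  beta_true <- 2
  y <- X[, "expected"] * beta_true + rnorm(n, sd = 0.1)
  fit <- fit_glm(cbind(y), X)
  expect_equal(fit$dof, n - 2)
  ctr <- glm_contrast(fit, c(expected = 1))
  expect_equal(unname(ctr$estimate), beta_true, tolerance = 0.1)
  # residuals orthogonal to all design columns
  Xi <- cbind(1, unclass(X))
  res <- y - Xi %*% qr.coef(qr(Xi), y)
  expect_lt(max(abs(crossprod(Xi, res))), 1e-8)
  # zero contrast -> t = 0
  z0 <- glm_contrast(fit, c(expected = 0))
  expect_equal(unname(z0$t), 0)
  # duplicated regressor -> rank error
  Xdup <- cbind(unclass(X), dup = X[, 1])
  Xdup <- structure(Xdup, classes = rep("condition", ncol(Xdup)), tr = 1,
                    class = c("design_matrix", "matrix", "array"))
  expect_error(fit_glm(cbind(y), Xdup), "collinear")
})

test_that("filtering then fitting equals fitting with the cosine basis as nuisance", {
  set.seed(3)
  run <- fx_spaced_trials(8)
  X <- build_design(run, tr = 1, add_derivatives = FALSE)
  n <- nrow(X)
  y <- X[, "expected"] * 1.5 + cos(2 * pi * (1:n) / 300) + rnorm(n, 0.2)
  K <- pescale:::dct_basis(n, 1, 128)
  fit1 <- fit_glm(cbind(highpass(y, 1)),
                  structure(cbind(expected = highpass(X[, 1], 1)),
                            classes = "condition", tr = 1,
                            class = c("design_matrix", "matrix", "array")))
  Xk <- structure(cbind(expected = X[, 1], K[, -1]),
                  classes = c("condition", rep("nuisance", ncol(K) - 1)),
                  tr = 1, class = c("design_matrix", "matrix", "array"))
  fit2 <- fit_glm(cbind(y), Xk)
  expect_equal(unname(fit1$beta["expected", 1]),
               unname(fit2$beta["expected", 1]), tolerance = 1e-8)
})

test_that("temporal derivatives do not flip a noise-free planted effect", {
  run <- fx_run(seed = 5)
  rd <- fx_rdms()
  sv <- list(layer8 = trial_surprise(rd$layer8, run, "layer8"))
  truth <- fx_truth(dim = c(4, 4, 2), slope = 1)
  b <- synth_bold(run, sv, truth, noise_sd = 0, drift = NULL)
  for (deriv in c(FALSE, TRUE)) {
    X <- build_design(run, sv, tr = 1, n_frames = dim(b$data)[4],
                      add_derivatives = deriv)
    ctr <- glm_contrast(fit_glm(b, X), c(layer8 = 1))
    hs <- match(which(truth$populations == "high_scaling"), which(b$mask))
    expect_true(all(ctr$estimate[hs] > 0))
  }
})

test_that("fixed-effects combination is inverse-variance weighting", {
  one <- tibble::tibble(voxel = 1, estimate = 1, variance = 1)
  two <- tibble::tibble(voxel = 1, estimate = 3, variance = 1)
  fx <- fixed_effects(list(one, two))
  expect_equal(fx$estimate, 2)
  expect_equal(fx$variance, 0.5)
  expect_equal(fixed_effects(list(one)), one)
  same <- fixed_effects(list(one, one, one))
  expect_equal(same$estimate, 1)
  expect_equal(same$variance, 1 / 3)
})

test_that("variance inflation factors match closed forms", {
  set.seed(4)
  n <- 200
  A <- cbind(a = rnorm(n), b = rnorm(n))
  A <- qr.Q(qr(A)) # exactly orthogonal
  Xo <- structure(A, classes = c("condition", "condition"),
                  class = c("design_matrix", "matrix", "array"))
  expect_equal(vif(Xo)$vif, c(1, 1), tolerance = 1e-5)
  # two regressors with r = 0.8 -> VIF = 1/(1-0.64)
  u <- rnorm(n); v <- 0.8 * scale(u) + sqrt(1 - 0.64) * scale(rnorm(n))
  X2 <- structure(cbind(a = scale(u)[, 1], b = v[, 1]),
                  classes = c("condition", "condition"),
                  class = c("design_matrix", "matrix", "array"))
  r <- cor(X2[, 1], X2[, 2])
  expect_equal(vif(X2)$vif, rep(1 / (1 - r^2), 2), tolerance = 1e-8)
  # perfect collinearity flagged as infinite
  X3 <- structure(cbind(a = u, b = 2 * u, c = rnorm(n)),
                  classes = rep("condition", 3),
                  class = c("design_matrix", "matrix", "array"))
  v3 <- vif(X3)
  expect_true(all(v3$flagged[1:2]))
  expect_false(v3$flagged[3])
})

test_that("group tests report the right statistics and effect sizes", {
  # diffs [1,2,3]: dz = mean/sd = 2
  gt <- group_test(c(1, 2, 3))
  expect_equal(gt$effect_size, 2)
  # antisymmetric sample: t = 0, p = 1
  gt0 <- group_test(c(-2, -1, 1, 2))
  expect_equal(gt0$statistic, 0)
  expect_equal(gt0$p, 1)
  # zero variance flagged
  expect_true(group_test(rep(1, 5))$flagged)
  # Wilcoxon rank-biserial: all-positive sample -> r = 1
  gw <- group_test(c(1, 2, 3, 4, 5), test = "wilcoxon")
  expect_equal(gw$effect_size, 1)
})

test_that("sign-flip cluster inference controls family-wise error", {
  dims <- c(8, 8, 4); nvox <- prod(dims); nsub <- 12
  mask <- array(TRUE, dims)
  # planted blob is detected with the smallest attainable p
  set.seed(5)
  maps <- matrix(rnorm(nsub * nvox, sd = 0.5), nsub)
  blob <- array(FALSE, dims); blob[2:6, 2:6, 2:3] <- TRUE
  maps[, which(blob)] <- maps[, which(blob)] + 3
  tab <- cluster_inference(maps, mask, n_permutations = 199, seed = 6)
  expect_gte(nrow(tab), 1)
  expect_equal(min(tab$p_fwe), 1 / 200)
  big <- tab[which.max(tab$n_voxels), ]
  expect_gte(big$n_voxels, sum(blob) * 0.8)
  # empty suprathreshold set -> empty table
  null_maps <- matrix(rnorm(nsub * nvox, sd = 0.01), nsub)
  tab0 <- cluster_inference(null_maps * 0 + rnorm(nsub * nvox, sd = 1e-6),
                            mask, n_permutations = 19, seed = 7)
  expect_equal(nrow(tab0), 0)
  # empirical FWE under the null stays near nominal
  set.seed(8)
  rejections <- purrr::map_lgl(1:300, function(i) {
    m <- matrix(rnorm(8 * 250), 8)
    tb <- cluster_inference(m, array(TRUE, c(10, 5, 5)),
                            n_permutations = 49)
    nrow(tb) > 0 && any(tb$p_fwe <= 0.05)
  })
  expect_lte(mean(rejections), 0.07)
})
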