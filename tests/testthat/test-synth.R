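test_that("feature hierarchy mixes low and high latent geometry along layers", {
  st <- fx_stimuli()
  # degenerate mixing, zero noise: end layers reproduce the latent RDMs
  fh <- synth_feature_hierarchy(st, noise_sd = 0, latent_dim = 40,
                                n_features = 40, seed = 1)
  low_rdm <- correlation_rdm(
    `rownames<-`(attr(fh, "latent_low"), st$stimulus_id))
  high_rdm <- correlation_rdm(
    `rownames<-`(attr(fh, "latent_high"), st$stimulus_id))
  # projections rotate features; with latent_dim = n_features the geometry
  # is approximately preserved, so the end layers track their own latent
  r1 <- rdm_ltv(correlation_rdm(fh[[1]]))
  r8 <- rdm_ltv(correlation_rdm(fh[[8]]))
  expect_gt(cor(r1, rdm_ltv(low_rdm)), cor(r1, rdm_ltv(high_rdm)))
  expect_gt(cor(r8, rdm_ltv(high_rdm)), cor(r8, rdm_ltv(low_rdm)))
  expect_error(synth_feature_hierarchy(st, mixing = c(1, 0)), "monotone")
})

test_that("adjacent layers are representationally closer than distant ones", {
  ids <- sprintf("s%02d", 1:20)
  diffs <- purrr::map_dbl(1:10, function(s) {
    fh <- synth_feature_hierarchy(ids, seed = s)
    rd <- purrr::map(fh, correlation_rdm)
    adj <- mean(purrr::map_dbl(1:7, function(l)
      cor(rdm_ltv(rd[[l]]), rdm_ltv(rd[[l + 1]]))))
    far <- cor(rdm_ltv(rd[[1]]), rdm_ltv(rd[[8]]))
    adj - far
  })
  expect_true(all(diffs > 0))
})

test_that("instance averaging denoises layer RDMs", {
  ids <- sprintf("s%02d", 1:12)
  wins <- purrr::map_lgl(1:10, function(s) {
    # reference: the layer's latent geometry (the infinite-instance limit)
    fh0 <- synth_feature_hierarchy(ids, noise_sd = 0, seed = s)
    clean <- correlation_rdm(`rownames<-`(attr(fh0, "latent_high"), ids))
    noisy <- purrr::map(1:10, function(i)
      correlation_rdm(synth_feature_hierarchy(ids, noise_sd = 0.5,
                                              instance = i, seed = s)[[8]]))
    avg <- average_rdms(noisy)
    d_avg <- norm(unclass(avg) - unclass(clean), "F")
    d_single <- purrr::map_dbl(noisy, ~ norm(unclass(.x) - unclass(clean), "F"))
    d_avg < min(d_single)
  })
  expect_gte(sum(wins), 9)
})

test_that("synthetic BOLD realizes the planted linear surprise model", {
  st <- fx_stimuli()
  truth <- fx_truth(dim = c(6, 6, 3), slope = 0.5)
  # two isolated unexpected trials with known z difference
  tt <- tibble::tibble(trial = 1:2, cue = "q", stimulus_id = c("dog", "car"),
                       expected_id = "house", condition = "unexpected",
                       onset = c(10, 60), duration = 0.5, iti = 30)
  class(tt) <- c("trial_table", class(tt))
  sv <- fx_surprise(1:2, c(0.2, 1.0), "layer8")
  b <- synth_bold(tt, list(layer8 = sv), truth, noise_sd = 0, drift = NULL)
  vox <- which(truth$populations == "high_scaling")[1]
  col <- match(vox, which(b$mask))
  y <- bold_matrix(b)[, col]
  nfr <- length(y)
  peak1 <- max(y[1:40]); peak2 <- max(y[41:nfr])
  # unit response peak for this design
  unit <- max(convolve_events(10, 0.5, 1, nfr, 1))
  zs <- sv$z
  expect_equal(peak2 - peak1, 0.5 * (zs[2] - zs[1]) * unit, tolerance = 1e-6)
  # zero slopes: every unexpected trial evokes the identical response
  truth0 <- fx_truth(dim = c(6, 6, 3), slope = 0)
  b0 <- synth_bold(tt, list(layer8 = sv), truth0, noise_sd = 0, drift = NULL)
  y0 <- bold_matrix(b0)[, col]
  expect_equal(max(y0[1:40]), max(y0[41:nfr]), tolerance = 1e-9)
  # seeds only change the noise component
  s1 <- synth_bold(tt, list(layer8 = sv), truth, noise_sd = 0, drift = NULL,
                   seed = 1)
  s2 <- synth_bold(tt, list(layer8 = sv), truth, noise_sd = 0, drift = NULL,
                   seed = 2)
  expect_identical(s1$data, s2$data)
  n1 <- synth_bold(tt, list(layer8 = sv), truth, noise_sd = 1, seed = 1)
  expect_identical(n1$data,
                   synth_bold(tt, list(layer8 = sv), truth, noise_sd = 1,
                              seed = 1)$data)
  expect_error(synth_bold(dplyr::mutate(tt, onset = c(10, 98)),
                          list(layer8 = sv), truth, n_frames = 90),
               "past the end")
})

test_that("noise-free localizer patterns are exactly recoverable", {
  st <- fx_stimuli()
  truth <- fx_truth(dim = c(6, 6, 3))
  loc <- generate_localizer(st, seed = 7)
  b <- synth_localizer_bold(loc, truth, noise_sd = 0, drift = NULL)
  pat <- stimulus_glm(b, loc)
  sel <- which(truth$populations != "non_selective")
  cols <- match(sel, which(b$mask))
  # recovered betas reproduce baseline + planted pattern per stimulus
  expected <- truth$baseline[sel][1] + truth$patterns[rownames(pat), sel]
  expect_equal(pat[, cols], expected, tolerance = 1e-6, ignore_attr = TRUE)
  # intact > scrambled in selective voxels (object-selective contrast)
  pat_all <- stimulus_glm(b, loc, intact_only = FALSE)
  intact_mean <- colMeans(pat_all[!grepl("_scr$", rownames(pat_all)), cols])
  scr_mean <- colMeans(pat_all[grepl("_scr$", rownames(pat_all)), cols])
  expect_true(all(intact_mean > scr_mean))
})

test_that("synthetic behaviour realizes the planted facilitation ordering", {
  st <- fx_stimuli()
  blk <- generate_behavioral_block(st, seed = 8)
  # rt_sd = 0: condition means exact
  r0 <- synth_behavior(blk, st, rt_sd = 0, seed = 1)
  agg <- tapply(r0$rt[r0$condition3 != "nogo"],
                r0$condition3[r0$condition3 != "nogo"], mean)
  expect_equal(agg[["expected"]], 501)
  expect_equal(agg[["unexpected_same"]], 509)
  expect_equal(agg[["unexpected_diff"]], 524)
  # zero error rate -> perfect accuracy
  r1 <- synth_behavior(blk, st, error_rates = c(expected = 0,
                                                unexpected_same = 0,
                                                unexpected_diff = 0),
                       false_alarm_rate = 0, seed = 2)
  expect_true(all(r1$correct))
  # planted ordering holds in large samples
  big <- purrr::map_dfr(1:6, function(s)
    synth_behavior(generate_behavioral_block(st, seed = s), st,
                   seed = 50 + s))
  m <- tapply(big$rt[big$condition3 != "nogo"],
              big$condition3[big$condition3 != "nogo"], mean)
  expect_true(m[["expected"]] < m[["unexpected_same"]])
  expect_true(m[["unexpected_same"]] < m[["unexpected_diff"]])
})

test_that("the GLM recovers planted slopes from noise-free synthetic data", {
  st <- fx_stimuli()
  run <- fx_run(seed = 3)
  rd <- fx_rdms()
  sv <- list(layer8 = trial_surprise(rd$layer8, run, "layer8"),
             layer2 = trial_surprise(rd$layer2, run, "layer2"))
  truth <- fx_truth(dim = c(6, 6, 3), slope = 1.5)
  b <- synth_bold(run, sv["layer8"], truth, noise_sd = 0, drift = NULL)
  X <- build_design(run, sv, tr = 1, n_frames = dim(b$data)[4])
  fit <- fit_glm(b, X)
  ctr <- glm_contrast(fit, c(layer8 = 1))
  hs <- which(truth$populations == "high_scaling")
  expect_equal(max(abs(ctr$estimate[match(hs, which(b$mask))] - 1.5)) / 1.5, 0,
               tolerance = 1e-6)
  nullv <- which(truth$populations == "null")
  expect_lt(max(abs(ctr$estimate[match(nullv, which(b$mask))])), 1e-8)
})
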