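#' Canonical planted ground truth for a synthetic subject
#'
#' Splits the volume along x into a `high_scaling` region (stimulus
#' selective, BOLD amplitude scales with high-level surprise), a `null`
#' region (stimulus selective, no scaling — the type-I-error control), and a
#' `non_selective` remainder. Stimulus patterns for the selective regions
#' are projections of the supplied feature matrix, so their representational
#' geometry follows that layer.
#'
#' @param dim Volume dimensions.
#' @param features Stimulus feature matrix (stimuli x features) whose
#'   geometry the selective patterns inherit (e.g., layer 8 of
#'   [synth_feature_hierarchy()]).
#' @param slope Planted scaling slope (amplitude per z-unit of surprise).
#' @param model Feature model the slope is planted for.
#' @param baseline Baseline response amplitude.
#' @param pattern_sd SD of the planted per-stimulus pattern amplitudes.
#' @param seed Optional integer seed (pattern projection).
#' @return A [ground_truth()].
#' @export
default_truth <- function(dim, features, slope = 2, model = "layer8",
                          baseline = 1, pattern_sd = 0.5, seed = NULL) {
  nx <- dim[1]
  xidx <- slice.index(array(0, dim), 1)
  pop <- array("non_selective", dim)
  pop[xidx <= round(0.4 * nx)] <- "high_scaling"
  pop[xidx > round(0.4 * nx) & xidx <= round(0.7 * nx)] <- "null"
  sel <- which(pop %in% c("high_scaling", "null"))
  if (inherits(features, "feature_space")) features <- features$matrix
  pat <- with_seed(seed, {
    W <- matrix(rnorm(ncol(features) * length(sel)), ncol(features))
    P <- scale(t(scale(t(features))) %*% W) * pattern_sd
  })
  patterns <- matrix(0, nrow(features), prod(dim),
                     dimnames = list(rownames(features), NULL))
  patterns[, sel] <- pat
  scr <- array(1, dim)
  scr[sel] <- 0.5 # intact > scrambled in selective voxels
  slopes <- setNames(list(slope), model)
  ground_truth(dim, baseline = baseline, populations = pop, slopes = slopes,
               slope_population = setNames(list("high_scaling"), model),
               patterns = patterns, scrambled_gain = scr)
}

# deterministic per-subject/stage seed derived from a base seed
stage_seed <- function(base, subject, run = 0L) {
  (as.integer(base) * 499L + subject * 97L + run) %% .Machine$integer.max
}

#' Simulate a complete synthetic subject
#'
#' Generates, with planted ground truth: layer RDMs (instance-averaged
#' feature hierarchy), main-task runs (trial tables, surprise vectors, 4D
#' BOLD), localizer runs with stimulus-selective patterns, and behavioural
#' responses.
#'
#' @param cfg A [pipeline_config()].
#' @param subject Subject number (varies all stage seeds).
#' @param stimuli A [stimulus_set()].
#' @param n_localizers Localizer runs.
#' @return List: `stimuli`, `rdms`, `truth`, `runs` (each with `trials`,
#'   `surprise`, `bold`), `localizers` (each with `trials`, `bold`),
#'   `behavior`.
#' @export
simulate_subject <- function(cfg, subject = 1L, stimuli = stimulus_set(),
                             n_localizers = 2L) {
  fseed <- stage_seed(cfg$seeds$features, subject)
  rdms <- layer_rdms(stimuli, n_instances = 10L, seed = fseed)
  fh <- synth_feature_hierarchy(stimuli, seed = fseed)
  truth <- default_truth(cfg$dim, fh[[8]], slope = cfg$slope,
                         seed = stage_seed(cfg$seeds$features, subject, 1L))
  tpm <- build_tpm(stimuli)
  runs <- purrr::map(seq_len(cfg$n_runs), function(r) {
    trials <- generate_run(tpm, stimuli,
                           seed = stage_seed(cfg$seeds$design, subject, r))
    trials$run <- r
    surprise <- purrr::imap(rdms, ~ trial_surprise(.x, trials, .y))
    bold <- synth_bold(trials, surprise["layer8"], truth,
                       noise_sd = cfg$noise_sd, tr = cfg$tr,
                       seed = stage_seed(cfg$seeds$bold, subject, r))
    list(trials = trials, surprise = surprise, bold = bold)
  })
  localizers <- purrr::map(seq_len(n_localizers), function(r) {
    trials <- generate_localizer(stimuli,
                                 seed = stage_seed(cfg$seeds$design, subject,
                                                   100L + r))
    bold <- synth_localizer_bold(trials, truth, noise_sd = cfg$noise_sd,
                                 tr = cfg$tr,
                                 seed = stage_seed(cfg$seeds$bold, subject,
                                                   100L + r))
    list(trials = trials, bold = bold)
  })
  behavior <- purrr::map_dfr(seq_len(4L), function(b) {
    bt <- generate_behavioral_block(stimuli,
                                    seed = stage_seed(cfg$seeds$design,
                                                      subject, 200L + b))
    resp <- synth_behavior(bt, stimuli,
                           seed = stage_seed(cfg$seeds$behavior, subject, b))
    resp$block <- b
    resp
  })
  list(stimuli = stimuli, rdms = rdms, truth = truth, runs = runs,
       localizers = localizers, behavior = behavior)
}

#' Run the end-to-end synthetic pipeline
#'
#' simulate -> feature RDMs -> first-level parametric-modulation GLMs ->
#' fixed effects -> LSS -> localizer decoding + ROI selection -> surprise
#' scaling -> group statistics -> behavioural statistics, for
#' `cfg$n_subjects` synthetic subjects. When `out_dir` is given, events
#' TSVs, RDM TSVs, stats tables, the config, and a manifest with content
#' hashes are written.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List: `modulator_tests`, `scaling`, `behavior` (ANOVA + post-hoc
#'   + CIs), `subject` (per-subject tables), `manifest` (when written).
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  validate_config(cfg)
  stimuli <- stimulus_set()
  models <- c("layer2", "layer8")
  per_subject <- purrr::map(seq_len(cfg$n_subjects), function(s) {
    sub <- simulate_subject(cfg, s, stimuli)
    mods <- sub$rdms[models]
    run_fits <- purrr::map(sub$runs, function(rn) {
      Y <- highpass(bold_matrix(rn$bold), tr = cfg$tr,
                    cutoff_s = cfg$highpass_s)
      X <- build_design(rn$trials, rn$surprise[models], tr = cfg$tr,
                        n_frames = nrow(Y))
      fit <- fit_glm(Y, X)
      purrr::map(models, ~ glm_contrast(fit, setNames(1, .x))) |>
        setNames(models)
    })
    ffx <- purrr::map(models, function(m)
      fixed_effects(purrr::map(run_fits, m))) |> setNames(models)
    lss_stack <- purrr::map(sub$runs, ~ lss(.x$bold, .x$trials, tr = cfg$tr))
    betas <- structure(list(
      betas = do.call(rbind, purrr::map(lss_stack, "betas")),
      meta = dplyr::bind_rows(purrr::map2(
        lss_stack, seq_along(lss_stack),
        function(st, r) dplyr::mutate(st$meta,
                                      trial = .data$trial + (r - 1L) * 1000L)))
    ), class = "trial_betas")
    surprise_all <- purrr::map(setNames(models, models), function(m) {
      sv <- purrr::map2_dfr(sub$runs, seq_along(sub$runs),
                            function(rn, r) dplyr::mutate(
                              rn$surprise[[m]],
                              trial = .data$trial + (r - 1L) * 1000L))
      class(sv) <- c("surprise", class(sv))
      sv
    })
    # localizer decoding -> ROI selection in the selective region
    loc_lss <- purrr::map(sub$localizers, function(lc)
      lss(lc$bold,
          dplyr::mutate(lc$trials,
                        stimulus_id = ifelse(.data$scrambled,
                                             paste0(.data$stimulus_id, "_scr"),
                                             .data$stimulus_id)),
          tr = cfg$tr))
    loc_betas <- do.call(rbind, purrr::map(loc_lss, "betas"))
    loc_meta <- dplyr::bind_rows(purrr::map(loc_lss, "meta"))
    intact <- !loc_meta$scrambled
    mask <- array(TRUE, cfg$dim)
    sl <- make_searchlights(mask, radius_mm = cfg$radius_mm)
    acc <- searchlight_decode(
      filter_betas(structure(list(betas = loc_betas, meta = loc_meta),
                             class = "trial_betas"), intact),
      loc_meta$stimulus_id[intact], sl, seed = cfg$seeds$analysis)
    acc_map <- array(0, cfg$dim)
    acc_map[which(mask)[sl$centers]] <- acc
    anat <- list(selective = array(
      sub$truth$populations == "high_scaling", cfg$dim))
    rois <- build_rois(anat, acc_map, rule = "top_k_decoding", k = cfg$roi_k,
                       dilate_fwhm_mm = 0)
    scaling <- purrr::map_dfr(models, function(m)
      dplyr::mutate(scaling_regression(betas, surprise_all[[m]],
                                       voxels = rois$selective$selected),
                    subject = s))
    mod_est <- purrr::imap_dfr(ffx, function(fx, m)
      tibble(subject = s, roi = "selective", model_id = m,
             estimate = mean(fx$estimate[rois$selective$selected])))
    behav <- condition_split(filter_trials(dplyr::mutate(sub$behavior,
                                                         subject = s)))
    list(scaling = scaling, mod_est = mod_est, behavior = behav,
         trials = purrr::map(sub$runs, "trials"), rdms = sub$rdms)
  })
  scaling_tbl <- dplyr::bind_rows(purrr::map(per_subject, "scaling"))
  mod_tbl <- dplyr::bind_rows(purrr::map(per_subject, "mod_est"))
  behav_tbl <- dplyr::bind_rows(purrr::map(per_subject, "behavior"))
  res <- list(
    scaling = scaling_group(scaling_tbl),
    modulator_tests = if (cfg$n_subjects >= 3)
      roi_modulator_tests(mod_tbl) else NULL,
    behavior = list(
      rt_anova = if (cfg$n_subjects >= 3) rm_anova(behav_tbl) else NULL,
      posthoc = if (cfg$n_subjects >= 3) posthoc(behav_tbl) else NULL,
      cis = within_subject_ci(behav_tbl)),
    subject = list(scaling = scaling_tbl, modulators = mod_tbl,
                   behavior = behav_tbl)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(cfg, file.path(out_dir, "config.yaml"))
    for (s in seq_along(per_subject)) {
      for (r in seq_along(per_subject[[s]]$trials))
        write_events_tsv(per_subject[[s]]$trials[[r]],
                         file.path(out_dir, sprintf("sub-%02d_run-%02d_events.tsv",
                                                    s, r)))
    }
    purrr::iwalk(per_subject[[1]]$rdms, function(r, nm)
      write_rdm_tsv(r, file.path(out_dir, paste0("rdm_", nm, ".tsv"))))
    readr::write_tsv(scaling_tbl, file.path(out_dir, "scaling_subject.tsv"))
    readr::write_tsv(res$scaling, file.path(out_dir, "scaling_group.tsv"))
    files <- sort(list.files(out_dir, full.names = TRUE))
    files <- files[!grepl("manifest[.]json$", files)]
    manifest <- list(
      config = unclass(cfg),
      package_version = as.character(utils::packageVersion("pescale")),
      files = tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  }
  res
}
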