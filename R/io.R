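#' Read and write BIDS-style events TSV files
#'
#' Trial tables serialize with `onset`/`duration` in seconds, `trial_type`
#' (the condition), plus the cue/stimulus metadata columns; reading restores
#' a `trial_table` tibble.
#'
#' @param trials A `trial_table`.
#' @param path File path (`.tsv`).
#' @return `write_events_tsv()` returns `path` invisibly;
#'   `read_events_tsv()` returns a `trial_table`.
#' @export
write_events_tsv <- function(trials, path) {
  out <- dplyr::rename(as_tibble(trials), trial_type = "condition")
  first <- intersect(c("onset", "duration", "trial_type"), names(out))
  readr::write_tsv(out[, c(first, setdiff(names(out), first))], path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("onset", "duration", "trial_type")
  missing <- setdiff(required, names(out))
  if (length(missing))
    abort(paste0("events TSV is missing column(s): ",
                 paste(missing, collapse = ", ")))
  out <- dplyr::rename(out, condition = "trial_type")
  class(out) <- c("trial_table", class(out))
  out
}

#' Read and write RDMs as labelled TSV matrices
#' @param rdm An `rdm`.
#' @param path File path.
#' @export
write_rdm_tsv <- function(rdm, path) {
  df <- as.data.frame(unclass(rdm))
  readr::write_tsv(dplyr::bind_cols(tibble(stimulus = rownames(rdm)), df),
                   path)
  invisible(path)
}

#' @rdname write_rdm_tsv
#' @export
read_rdm_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  new_rdm(m, df$stimulus)
}

#' Read and write 4D BOLD runs as NIfTI
#'
#' @param run A `bold_run`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param tr Repetition time used when reading.
#' @export
write_bold_nifti <- function(run, path) {
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(rep(run$voxel_mm, 3), run$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param mask_path Optional NIfTI mask to read alongside.
#' @export
read_bold_nifti <- function(path, tr = NULL, mask_path = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  mask <- if (!is.null(mask_path)) {
    as.array(RNifti::readNifti(mask_path)) > 0
  } else NULL
  bold_run(as.array(img), tr = tr %||% pd[4], mask = mask,
           voxel_mm = pd[1])
}

#' Transition matrix JSON serialization
#' @param tpm A `tpm` matrix.
#' @param path File path.
#' @export
write_tpm_json <- function(tpm, path) {
  jsonlite::write_json(list(cues = rownames(tpm), images = colnames(tpm),
                            counts = unclass(tpm)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tpm_json
#' @export
read_tpm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.integer(x$counts), length(x$cues),
              dimnames = list(cue = x$cues, image = x$images))
  structure(m, class = c("tpm", "matrix", "array"))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end synthetic pipeline; all
#' stochastic stages require an explicit seed. Serializable to YAML.
#'
#' @param n_subjects,n_runs Subjects and main-task runs per subject.
#' @param dim Volume dimensions.
#' @param tr Repetition time (s).
#' @param noise_sd BOLD noise SD.
#' @param slope Planted high-level scaling slope.
#' @param fwhm_mm,highpass_s,radius_mm,roi_k Smoothing FWHM, high-pass
#'   cutoff, searchlight radius, ROI voxel count.
#' @param formation_z,rsa_z,liberal_z Statistical thresholds.
#' @param seeds Named list of integer seeds: `design`, `features`, `bold`,
#'   `behavior`, `analysis`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 2L, n_runs = 2L, dim = c(10, 10, 6),
                            tr = 1, noise_sd = 1, slope = 2, fwhm_mm = 5,
                            highpass_s = 128, radius_mm = 6, roi_k = 50L,
                            formation_z = 3.29, rsa_z = 3.1, liberal_z = 1.96,
                            seeds = list(design = 1L, features = 2L,
                                         bold = 3L, behavior = 4L,
                                         analysis = 5L)) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
              dim = as.integer(dim), tr = tr, noise_sd = noise_sd,
              slope = slope, fwhm_mm = fwhm_mm, highpass_s = highpass_s,
              radius_mm = radius_mm, roi_k = as.integer(roi_k),
              formation_z = formation_z, rsa_z = rsa_z, liberal_z = liberal_z,
              seeds = seeds)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  need <- c("design", "features", "bold", "behavior", "analysis")
  missing <- setdiff(need, names(cfg$seeds))
  if (length(missing) || any(purrr::map_lgl(cfg$seeds[need], is.null)))
    abort(paste0("missing seed(s): ", paste(missing, collapse = ", ")))
  if (any(c(cfg$formation_z, cfg$rsa_z, cfg$liberal_z) <= 0))
    abort("thresholds must be positive")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$dim <- as.integer(cfg$dim)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}
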