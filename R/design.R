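#' Build the transitional probability matrix of the cued design
#'
#' Each of the 8 letter cues predicts its paired image with 7:1 odds: per run
#' the paired (expected) image follows its cue `expected_reps` times, every
#' other image exactly once. All images therefore appear equally often and
#' cue reliability is `expected_reps / (expected_reps + 7)` (0.5 by default).
#'
#' @param stimuli A [stimulus_set()].
#' @param expected_reps Repetitions of each expected cue-image pair per run.
#' @return A `tpm` object: an 8 x 8 integer matrix (rows = cues, columns =
#'   images) of trial counts.
#' @examples
#' tpm <- build_tpm(stimulus_set())
#' sum(tpm) # 112 go trials
#' @export
build_tpm <- function(stimuli, expected_reps = 7L) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (anyDuplicated(stimuli$cue_letter) || anyDuplicated(stimuli$stimulus_id))
    abort("cue-image pairing must be one-to-one")
  expected_reps <- as.integer(expected_reps)
  if (expected_reps < 1L) abort("expected_reps must be >= 1")
  counts <- matrix(1L, 8L, 8L,
                   dimnames = list(cue = stimuli$cue_letter,
                                   image = stimuli$stimulus_id))
  diag(counts) <- expected_reps
  structure(counts, class = c("tpm", "matrix", "array"))
}

#' @export
print.tpm <- function(x, ...) {
  cat("<tpm> trials per run (cue x image)\n")
  print(matrix(x, nrow(x), dimnames = dimnames(x)), ...)
  invisible(x)
}

#' Truncated-exponential intertrial intervals
#'
#' Draws i.i.d. ITIs from an exponential distribution offset to `min` and
#' truncated at `max`, with the rate solved numerically so that the truncated
#' mean equals `mean`. Sampling uses the inverse CDF of the truncated law, so
#' every draw lies inside the range by construction (equivalent in
#' distribution to resampling out-of-range draws; no boundary atoms).
#'
#' @param n Number of draws.
#' @param spec List with elements `mean`, `min`, `max` (seconds).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` ITIs in seconds.
#' @examples
#' mean(sample_iti(1e4, seed = 1)) # close to 5
#' @export
sample_iti <- function(n, spec = iti_spec_run(), seed = NULL) {
  rate <- iti_rate(spec)
  u <- with_seed(seed, runif(n))
  width <- spec$max - spec$min
  spec$min - log(1 - u * (1 - exp(-rate * width))) / rate
}

#' @rdname sample_iti
#' @export
iti_spec_run <- function() list(mean = 5, min = 3, max = 12)

#' @rdname sample_iti
#' @export
iti_spec_block <- function() list(mean = 2.5, min = 1.5, max = 7.5)

# solve the exponential rate so the mean of Exp(rate) truncated to
# [0, max-min] equals mean-min
iti_rate <- function(spec) {
  target <- spec$mean - spec$min
  width <- spec$max - spec$min
  if (target <= 0 || target >= width / 2)
    abort("ITI mean must lie in (min, (min+max)/2) for a truncated exponential")
  f <- function(r) 1 / r - width / expm1(r * width) - target
  uniroot(f, c(1e-8, 1e3), tol = 1e-12)$root
}

# Random order of `keys` with no two consecutive equal entries. Tries plain
# shuffles first; if the multiset is too constrained for rejection alone
# (dense behavioural blocks), violating positions are repaired by swapping
# with admissible partners. Errors after `max_attempts` full restarts.
shuffle_no_adjacent <- function(keys, max_attempts = 10000L) {
  n <- length(keys)
  for (attempt in seq_len(max_attempts)) {
    ord <- sample.int(n)
    k <- keys[ord]
    ok <- FALSE
    for (pass in 1:50) {
      bad <- which(k[-1] == k[-n]) + 1L
      if (!length(bad)) { ok <- TRUE; break }
      for (i in bad) {
        if (k[i] != k[i - 1L]) next # fixed by an earlier swap this pass
        cand <- which(k != k[i])
        cand <- cand[cand != i]
        cand <- sample(cand)
        done <- FALSE
        for (j in cand) {
          # would swapping positions i and j create no violation at either?
          ki <- k[j]; kj <- k[i]
          ok_i <- (i == 1L || k[i - 1L] != ki) && (i == n || k[i + 1L] != ki || i + 1L == j)
          ok_j <- (j == 1L || k[j - 1L] != kj || j - 1L == i) && (j == n || k[j + 1L] != kj)
          if (ok_i && ok_j) {
            tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
            k <- keys[ord]
            done <- TRUE
            break
          }
        }
        if (!done) break
      }
    }
    if (ok) return(ord)
  }
  abort("could not order trials without adjacent repeats of the same cue-image pair")
}

#' Generate one main-task run of the cued design
#'
#' Realizes the transitional probability matrix exactly — 56 expected and 56
#' unexpected go trials by default — plus `nogo_count` no-go trials (a vowel
#' cue followed by a uniformly drawn image). Trial order is randomized under
#' the constraint that the same cue-image pair never occurs on two
#' consecutive trials. Each trial shows the cue for 0.5 s, then the image for
#' 0.5 s; `onset` is the image onset and ITIs follow the image.
#'
#' @param tpm A [build_tpm()] matrix.
#' @param stimuli The [stimulus_set()] the TPM was built from.
#' @param nogo_count Number of no-go trials.
#' @param iti_spec ITI specification, see [sample_iti()].
#' @param seed Optional integer seed.
#' @param t0 Time of the first cue onset (seconds).
#' @return A `trial_table` tibble: `trial`, `cue`, `stimulus_id`,
#'   `expected_id`, `condition` (expected / unexpected / nogo), `onset`,
#'   `duration`, `iti`.
#' @examples
#' run <- generate_run(build_tpm(stimulus_set()), stimulus_set(), seed = 1)
#' dplyr::count(run, condition)
#' @export
generate_run <- function(tpm, stimuli, nogo_count = 16L,
                         iti_spec = iti_spec_run(), seed = NULL, t0 = 4) {
  stopifnot(inherits(tpm, "tpm"))
  pairing <- cue_pairing(stimuli)
  with_seed(seed, {
    idx <- which(tpm > 0, arr.ind = TRUE)
    cues <- rep(rownames(tpm)[idx[, 1]], tpm[idx])
    imgs <- rep(colnames(tpm)[idx[, 2]], tpm[idx])
    if (nogo_count > 0) {
      vowels <- c("a", "e", "i", "o", "u")
      cues <- c(cues, sample(vowels, nogo_count, replace = TRUE))
      imgs <- c(imgs, sample(colnames(tpm), nogo_count, replace = TRUE))
    }
    ord <- shuffle_no_adjacent(paste(cues, imgs))
    cues <- cues[ord]; imgs <- imgs[ord]
    n <- length(cues)
    iti <- sample_iti(n, iti_spec)
    # cue (0.5 s) + image (0.5 s) + iti; onset marks the image
    image_onset <- t0 + 0.5 + c(0, cumsum(1 + iti))[seq_len(n)]
    expected_id <- unname(pairing[cues])
    condition <- dplyr::case_when(
      is.na(expected_id) ~ "nogo",
      imgs == expected_id ~ "expected",
      TRUE ~ "unexpected"
    )
    out <- tibble(
      trial = seq_len(n), cue = cues, stimulus_id = imgs,
      expected_id = expected_id, condition = condition,
      onset = image_onset, duration = 0.5, iti = iti
    )
    class(out) <- c("trial_table", class(out))
    out
  })
}

#' Generate one behavioural block
#'
#' Behavioural blocks triple the expected-pair repetitions (21 instead of 7),
#' double the no-go count (32), and use a faster ITI (mean 2.5 s, range
#' 1.5-7.5 s), for 256 trials total.
#'
#' @inheritParams generate_run
#' @return A `trial_table` tibble, see [generate_run()].
#' @export
generate_behavioral_block <- function(stimuli, seed = NULL, t0 = 4) {
  tpm <- build_tpm(stimuli, expected_reps = 21L)
  generate_run(tpm, stimuli, nogo_count = 32L, iti_spec = iti_spec_block(),
               seed = seed, t0 = t0)
}

#' Generate a localizer run of stimulus miniblocks
#'
#' Each intact image is shown in 4 miniblocks and each phase-scrambled
#' version in 2 (48 miniblocks total), with no immediate repetition of the
#' same stimulus. A miniblock flashes one stimulus for 15 cycles of 800 ms
#' (500 ms on / 300 ms off, 12 s total); one uniformly drawn cycle outside
#' the first 3 and last 2 shows a brightness target.
#'
#' @param stimuli A [stimulus_set()].
#' @param intact_reps,scrambled_reps Miniblocks per intact / scrambled image.
#' @param rest Seconds of fixation between miniblocks.
#' @param seed Optional integer seed.
#' @param t0 Onset of the first miniblock (seconds).
#' @return A `trial_table` tibble with one row per miniblock: `trial`,
#'   `stimulus_id`, `scrambled`, `condition`, `onset`, `duration` (12),
#'   `target_cycle` (1-based, in 4..13).
#' @export
generate_localizer <- function(stimuli, intact_reps = 4L, scrambled_reps = 2L,
                               rest = 4, seed = NULL, t0 = 4) {
  with_seed(seed, {
    ids <- c(rep(stimuli$stimulus_id, intact_reps),
             rep(paste0(stimuli$stimulus_id, "_scr"), scrambled_reps))
    ord <- shuffle_no_adjacent(ids)
    ids <- ids[ord]
    n <- length(ids)
    onset <- t0 + (seq_len(n) - 1) * (12 + rest)
    out <- tibble(
      trial = seq_len(n),
      stimulus_id = sub("_scr$", "", ids),
      scrambled = grepl("_scr$", ids),
      condition = ifelse(grepl("_scr$", ids), "scrambled", "intact"),
      onset = onset, duration = 12,
      target_cycle = sample(4:13, n, replace = TRUE)
    )
    class(out) <- c("trial_table", class(out))
    out
  })
}
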