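#' Filter behavioural trials for analysis
#'
#' Drops no-go trials, applies the reaction-time bounds (trials faster than
#' 100 ms or slower than 1,500 ms are excluded; boundary values are
#' retained), and marks the correct-response subset used for the RT
#' analysis.
#'
#' @param responses A response table ([synth_behavior()] output or
#'   equivalent) with `condition3`, `responded`, `correct`, `rt` (ms).
#' @param rt_min,rt_max RT bounds in ms.
#' @return The go-trial tibble with logical columns `include_acc` (RT in
#'   bounds) and `include_rt` (additionally correct), plus an attached
#'   `report` attribute of exclusion counts.
#' @export
filter_trials <- function(responses, rt_min = 100, rt_max = 1500) {
  go <- dplyr::filter(responses, .data$condition3 != "nogo")
  rt_ok <- go$responded & !is.na(go$rt) & go$rt >= rt_min & go$rt <= rt_max
  out <- dplyr::mutate(go, include_acc = rt_ok,
                       include_rt = rt_ok & .data$correct)
  attr(out, "report") <- tibble(
    n_go = nrow(go),
    n_rt_excluded = sum(!rt_ok),
    n_incorrect = sum(rt_ok & !go$correct)
  )
  out
}

#' Per-subject, per-condition behavioural summary
#'
#' Splits unexpected trials into those requiring the same button press as
#' the expected image (same animacy) and those requiring a different
#' response, then summarises mean RT (correct, in-bounds trials) and
#' accuracy per subject x condition.
#'
#' @param responses Filtered response table(s) ([filter_trials()]), with a
#'   `subject` column (added as `1` if absent). If `condition3` is missing
#'   it is derived from `condition`, `stimulus_id`, `expected_id` and
#'   `stimuli`.
#' @param stimuli Optional [stimulus_set()] for deriving the same/different
#'   split.
#' @return A `behavior_summary` tibble: `subject`, `condition3`, `mean_rt`,
#'   `accuracy`, `n_rt`, `n_acc`.
#' @export
condition_split <- function(responses, stimuli = NULL) {
  if (!"subject" %in% names(responses)) responses$subject <- 1L
  if (!"condition3" %in% names(responses)) {
    if (is.null(stimuli)) abort("need `stimuli` to derive the same/different split")
    an <- setNames(stimuli$animacy, stimuli$stimulus_id)
    responses$condition3 <- dplyr::case_when(
      responses$condition == "nogo" ~ "nogo",
      responses$condition == "expected" ~ "expected",
      an[responses$stimulus_id] == an[responses$expected_id] ~ "unexpected_same",
      TRUE ~ "unexpected_diff"
    )
  }
  out <- responses |>
    dplyr::filter(.data$condition3 != "nogo") |>
    dplyr::group_by(.data$subject, .data$condition3) |>
    dplyr::summarise(
      mean_rt = mean(.data$rt[.data$include_rt]),
      accuracy = mean(.data$correct[.data$include_acc]),
      n_rt = sum(.data$include_rt), n_acc = sum(.data$include_acc),
      .groups = "drop")
  class(out) <- c("behavior_summary", class(out))
  out
}

# subjects x conditions matrix of one measure
summary_wide <- function(summary, measure) {
  wide <- tidyr::pivot_wider(summary[, c("subject", "condition3", measure)],
                             names_from = "condition3",
                             values_from = dplyr::all_of(measure))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$subject
  lev <- intersect(c("expected", "unexpected_same", "unexpected_diff"),
                   colnames(m))
  m[, c(lev, setdiff(colnames(m), lev)), drop = FALSE]
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classic within-subject one-way ANOVA over the condition factor;
#' Greenhouse-Geisser epsilon is estimated from the condition covariance
#' matrix and applied to the degrees of freedom whenever epsilon < 1.
#' Partial eta squared = SS_effect / (SS_effect + SS_error).
#'
#' @param summary A [condition_split()] tibble.
#' @param measure `"mean_rt"` or `"accuracy"`.
#' @return A `pe_rm_anova` object (see [tidy.pe_rm_anova()]).
#' @export
rm_anova <- function(summary, measure = "mean_rt") {
  m <- summary_wide(summary, measure)
  stopifnot(ncol(m) >= 2, all(complete.cases(m)))
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - outer(rowMeans(m), colMeans(m), `+`) + grand)^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  # GG epsilon from the double-centered condition covariance matrix
  S <- stats::cov(m)
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  eps <- min(1, eps)
  df1c <- df1 * eps; df2c <- df2 * eps
  structure(list(F = f, df1 = df1c, df2 = df2c, df1_uncorrected = df1,
                 df2_uncorrected = df2, epsilon = eps,
                 p = stats::pf(f, df1c, df2c, lower.tail = FALSE),
                 eta_p2 = ss_cond / (ss_cond + ss_err),
                 n = n, k = k, measure = measure),
            class = "pe_rm_anova")
}

#' @export
print.pe_rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA (%s): F(%.1f, %.1f) = %.2f, p = %.4g, eta_p2 = %.2f (GG eps = %.2f)\n",
              x$measure, x$df1, x$df2, x$F, x$p, x$eta_p2, x$epsilon))
  invisible(x)
}

#' @export
tidy.pe_rm_anova <- function(x, ...) {
  tibble(term = "condition", statistic = x$F, df1 = x$df1, df2 = x$df2,
         p.value = x$p, eta_p2 = x$eta_p2, gg_epsilon = x$epsilon)
}

#' @export
glance.pe_rm_anova <- function(x, ...) {
  tibble(n_subjects = x$n, n_conditions = x$k, measure = x$measure)
}

#' Post-hoc pairwise paired t tests with Holm-Bonferroni correction
#'
#' @param summary A [condition_split()] tibble.
#' @param measure Column to test.
#' @return Tibble: `condition_a`, `condition_b`, `statistic`, `p`,
#'   `p_holm`, `dz`.
#' @export
posthoc <- function(summary, measure = "mean_rt") {
  m <- summary_wide(summary, measure)
  pairs <- utils::combn(colnames(m), 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    d <- m[, pr[1]] - m[, pr[2]]
    if (sd(d) == 0) {
      tibble(condition_a = pr[1], condition_b = pr[2],
             statistic = 0, p = 1, dz = NA_real_)
    } else {
      tt <- t.test(d)
      tibble(condition_a = pr[1], condition_b = pr[2],
             statistic = unname(tt$statistic), p = tt$p.value,
             dz = cohens_dz(d))
    }
  })
  out$p_holm <- p.adjust(out$p, method = "holm")
  out[, c("condition_a", "condition_b", "statistic", "p", "p_holm", "dz")]
}

#' Within-subject confidence intervals (Cousineau-Morey)
#'
#' Removes between-subject offsets (subtract the subject mean, add the grand
#' mean), rescales the condition variances by C/(C-1) to correct the
#' downward bias, and forms t-based intervals per condition.
#'
#' @param summary A [condition_split()] tibble.
#' @param measure Column to summarise.
#' @param level Confidence level.
#' @return Tibble: `condition3`, `mean`, `ci_half` (half-width).
#' @export
within_subject_ci <- function(summary, measure = "mean_rt", level = 0.95) {
  m <- summary_wide(summary, measure)
  n <- nrow(m); k <- ncol(m)
  if (k < 2) abort("Morey bias correction undefined for a single condition")
  norm <- m - rowMeans(m) + mean(m)
  v <- apply(norm, 2, var) * k / (k - 1)
  tibble(condition3 = colnames(m), mean = unname(colMeans(m)),
         ci_half = unname(qt(1 - (1 - level) / 2, n - 1) * sqrt(v / n)))
}

#' Directional 2-SD subject exclusion screen
#'
#' Flags subjects whose quality metrics fall more than 2 SD on the *worse*
#' side of the sample mean: higher-is-worse for head motion (mean FD, FD%),
#' DVARS and RT; lower-is-worse for tSNR and accuracy.
#'
#' @param metrics Tibble with `subject` plus metric columns.
#' @param higher_is_worse Named logical giving the bad direction per metric;
#'   defaults cover `fd`, `fd_perc`, `dvars`, `rt` (TRUE) and `tsnr`,
#'   `accuracy` (FALSE).
#' @param n_sd Threshold in SD units.
#' @return Tibble: `subject`, `excluded`, `reasons` (comma-separated
#'   offending metrics).
#' @export
exclusion_screen <- function(metrics,
                             higher_is_worse = c(fd = TRUE, fd_perc = TRUE,
                                                 dvars = TRUE, rt = TRUE,
                                                 tsnr = FALSE,
                                                 accuracy = FALSE),
                             n_sd = 2) {
  cols <- intersect(names(metrics), names(higher_is_worse))
  if (!length(cols)) abort("no recognised metric columns")
  flags <- purrr::map(cols, function(cl) {
    x <- metrics[[cl]]
    mu <- mean(x); s <- sd(x)
    if (s == 0) return(rep(FALSE, length(x)))
    if (higher_is_worse[[cl]]) x > mu + n_sd * s else x < mu - n_sd * s
  })
  names(flags) <- cols
  fm <- do.call(cbind, flags)
  tibble(subject = metrics$subject,
         excluded = rowSums(fm) > 0,
         reasons = purrr::map_chr(seq_len(nrow(fm)), function(i)
           paste(cols[fm[i, ]], collapse = ",")))
}
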