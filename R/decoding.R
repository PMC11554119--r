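#' Stratified cross-validation folds
#'
#' @param labels Factor/character vector of class labels.
#' @param k Number of folds.
#' @param seed Optional integer seed.
#' @return Integer fold assignment (1..k), each class spread across folds.
#' @export
stratified_folds <- function(labels, k = 4L, seed = NULL) {
  labels <- as.factor(labels)
  if (any(table(labels) < k))
    abort("stratification error: every class needs at least one trial per fold")
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# linear SVM with per-voxel standardization learned on the training set
fit_svm <- function(x, y, probability = FALSE) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  m <- e1071::svm(scale(x, mu, s), as.factor(y), kernel = "linear", cost = 1,
                  scale = FALSE, probability = probability)
  list(model = m, mu = mu, s = s, levels = levels(as.factor(y)))
}

predict_svm <- function(fit, x, probability = FALSE) {
  p <- stats::predict(fit$model, scale(x, fit$mu, fit$s),
                      probability = probability)
  if (probability) {
    pr <- attr(p, "probabilities")[, fit$levels, drop = FALSE]
    list(class = as.character(p), prob = pr)
  } else {
    list(class = as.character(p))
  }
}

#' Searchlight decoding of stimulus identity
#'
#' Per searchlight sphere, a linear SVM is trained and tested with
#' stratified k-fold cross-validation on single-trial patterns; the map of
#' mean held-out accuracies is used downstream to select the most
#' stimulus-informative ROI voxels.
#'
#' @param betas A `trial_betas` stack (e.g., localizer LSS estimates).
#' @param labels Class labels, one per trial row.
#' @param searchlights A [make_searchlights()] object.
#' @param folds Number of cross-validation folds.
#' @param seed Optional integer seed (fold assignment).
#' @return Numeric vector of cross-validated accuracies, one per sphere.
#' @export
searchlight_decode <- function(betas, labels, searchlights, folds = 4L,
                               seed = NULL) {
  B <- if (inherits(betas, "trial_betas")) betas$betas else as.matrix(betas)
  fold <- stratified_folds(labels, folds, seed)
  y <- as.factor(labels)
  acc <- numeric(length(searchlights$centers))
  for (i in seq_along(searchlights$centers)) {
    X <- B[, searchlights$members[[i]], drop = FALSE]
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- fit_svm(X[tr, , drop = FALSE], y[tr])
      pred <- predict_svm(m, X[!tr, , drop = FALSE])$class
      hits <- hits + sum(pred == as.character(y[!tr]))
    }
    acc[i] <- hits / length(y)
  }
  acc
}

#' True-class probabilities of a decoder output
#'
#' @param prob Matrix of class probabilities (trials x classes, named cols).
#' @param labels True class per trial.
#' @return Numeric vector: probability assigned to the true class.
#' @export
true_class_probability <- function(prob, labels) {
  stopifnot(all(labels %in% colnames(prob)))
  prob[cbind(seq_len(nrow(prob)), match(labels, colnames(prob)))]
}

#' Decoded true-class probability as a function of surprise
#'
#' Trains a multi-class linear SVM (pairwise-coupled probability
#' calibration) on prediction-free localizer patterns, extracts the
#' probability the decoder assigns to the true class on each unexpected
#' main-task trial, and regresses it on z-scored high-level surprise.
#'
#' @param train_betas,train_labels Localizer training patterns and labels.
#' @param test_betas A `trial_betas` stack of main-task trials (the
#'   unexpected subset is taken from its metadata).
#' @param surprise A `surprise` tibble (e.g., layer-8).
#' @param voxels Voxel column indices; must index the same voxel set in
#'   train and test.
#' @return List: `slope`, `intercept`, `r`, and `trials` tibble (`trial`,
#'   `true_class_prob`, `z`).
#' @export
probability_vs_surprise <- function(train_betas, train_labels, test_betas,
                                    surprise, voxels = NULL) {
  Btr <- if (inherits(train_betas, "trial_betas")) train_betas$betas else
    as.matrix(train_betas)
  un <- test_betas$meta$condition == "unexpected"
  meta <- test_betas$meta[un, ]
  Bte <- test_betas$betas[un, , drop = FALSE]
  if (ncol(Btr) != ncol(Bte))
    abort("train and test must share one voxel set")
  if (!is.null(voxels)) {
    Btr <- Btr[, voxels, drop = FALSE]
    Bte <- Bte[, voxels, drop = FALSE]
  }
  m <- fit_svm(Btr, train_labels, probability = TRUE)
  pr <- predict_svm(m, Bte, probability = TRUE)$prob
  tcp <- true_class_probability(pr, meta$stimulus_id)
  z <- surprise$z[match(meta$trial, surprise$trial)]
  if (anyNA(z)) abort("surprise vector does not cover all unexpected trials")
  fit <- lm.fit(cbind(1, z), tcp)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r = if (sd(tcp) > 0) cor(z, tcp) else 0,
       trials = tibble(trial = meta$trial, true_class_prob = tcp, z = z))
}

#' Identity decoding of expected vs unexpected main-task stimuli
#'
#' Trains on localizer patterns and tests on main-task single-trial
#' estimates averaged per object x expectation condition x run, yielding a
#' per-condition decoding accuracy.
#'
#' @param train_betas,train_labels Localizer training data.
#' @param test_betas Main-task `trial_betas` whose metadata includes a `run`
#'   column.
#' @param voxels Optional voxel subset (shared by train and test).
#' @return Tibble: `condition`, `n_tests`, `accuracy`.
#' @export
expectation_decoding <- function(train_betas, train_labels, test_betas,
                                 voxels = NULL) {
  Btr <- if (inherits(train_betas, "trial_betas")) train_betas$betas else
    as.matrix(train_betas)
  meta <- test_betas$meta
  if (!"run" %in% names(meta)) abort("test metadata needs a `run` column")
  keep <- meta$condition %in% c("expected", "unexpected")
  meta <- meta[keep, ]
  B <- test_betas$betas[keep, , drop = FALSE]
  if (!is.null(voxels)) {
    Btr <- Btr[, voxels, drop = FALSE]
    B <- B[, voxels, drop = FALSE]
  }
  key <- paste(meta$run, meta$condition, meta$stimulus_id, sep = "|")
  avg <- rowsum(B, key)
  avg <- avg / as.vector(table(key)[rownames(avg)])
  parts <- strsplit(rownames(avg), "|", fixed = TRUE)
  cond <- purrr::map_chr(parts, 2)
  stim <- purrr::map_chr(parts, 3)
  m <- fit_svm(Btr, train_labels)
  pred <- predict_svm(m, avg)$class
  tibble(condition = cond, correct = pred == stim) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_tests = dplyr::n(), accuracy = mean(.data$correct))
}
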