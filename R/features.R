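#' Representational dissimilarity matrices
#'
#' An `rdm` is a symmetric stimulus-by-stimulus dissimilarity matrix with a
#' zero diagonal and stimulus labels as dimnames. `new_rdm()` validates and
#' tags a matrix; `correlation_rdm()` computes correlation distance
#' (1 - Pearson) between the feature rows of a feature space;
#' `average_rdms()` takes the element-wise mean of RDMs that share labels.
#'
#' @param values Symmetric numeric matrix with zero diagonal.
#' @param labels Stimulus labels (defaults to rownames of `values`).
#' @return An `rdm` matrix.
#' @export
new_rdm <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) abort("an RDM needs stimulus labels")
  if (nrow(values) != ncol(values)) abort("RDM must be square")
  if (max(abs(values - t(values))) > 1e-8) abort("RDM must be symmetric")
  if (max(abs(diag(values))) > 1e-8) abort("RDM diagonal must be zero")
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("rdm", "matrix", "array"))
}

#' @rdname new_rdm
#' @param features Numeric matrix, stimuli in rows (rownames = stimulus ids),
#'   features in columns; or a `feature_space` from
#'   [synth_feature_hierarchy()].
#' @examples
#' f <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
#' correlation_rdm(f)
#' @export
correlation_rdm <- function(features) {
  if (inherits(features, "feature_space")) features <- features$matrix
  features <- as.matrix(features)
  if (ncol(features) < 2) abort("need at least 2 features per stimulus")
  v <- apply(features, 1, var)
  if (any(v == 0))
    abort(paste0("zero-variance feature row for stimulus: ",
                 paste(rownames(features)[v == 0], collapse = ", ")))
  d <- 1 - cor(t(features))
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  new_rdm((d + t(d)) / 2, rownames(features))
}

#' @rdname new_rdm
#' @param rdms List of `rdm` objects with identical labels in the same order.
#' @export
average_rdms <- function(rdms) {
  stopifnot(length(rdms) >= 1)
  labs <- rownames(rdms[[1]])
  for (r in rdms) {
    if (!identical(rownames(r), labs)) abort("RDM labels must match")
  }
  new_rdm(Reduce(`+`, lapply(rdms, unclass)) / length(rdms), labs)
}

# lower-triangle vector of an RDM (column-major, i > j)
rdm_ltv <- function(rdm) rdm[lower.tri(rdm)]

#' @export
print.rdm <- function(x, ...) {
  cat("<rdm> ", nrow(x), " stimuli\n", sep = "")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Turn an RDM into a long tibble of stimulus pairs
#'
#' @param x An `rdm`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `dissimilarity` (lower triangle only).
#' @export
tidy.rdm <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(lower.tri(x), arr.ind = TRUE)
  tibble(row = labs[idx[, 1]], col = labs[idx[, 2]],
         dissimilarity = x[idx])
}

#' @export
autoplot.rdm <- function(object, ...) {
  labs <- rownames(object)
  df <- tidyr::expand_grid(row = labs, col = labs) |>
    dplyr::mutate(dissimilarity = as.vector(t(unclass(object))))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$col, labs), y = factor(.data$row, rev(labs)),
    fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "dissim.") +
    ggplot2::coord_fixed()
}

#' Binary animacy-category RDM
#'
#' 0 for stimulus pairs of the same animacy category, 1 for pairs of
#' different categories: the task-relevant (response-category) control model.
#'
#' @param stimuli A [stimulus_set()].
#' @return An `rdm`.
#' @export
animacy_rdm <- function(stimuli) {
  a <- stimuli$animacy
  m <- outer(a, a, `!=`) * 1
  new_rdm(m, stimuli$stimulus_id)
}

#' Semantic RDM from word embeddings
#'
#' Correlation-distance RDM over supplied embedding vectors of the category
#' words (e.g., word2vec vectors); the semantic-surprise control model.
#'
#' @param embeddings Numeric matrix, one row per category word (rownames),
#'   or a named list of vectors.
#' @param stimuli Optional [stimulus_set()]; when given, rows are matched to
#'   `category_word` and labelled by `stimulus_id`.
#' @return An `rdm`.
#' @export
semantic_rdm <- function(embeddings, stimuli = NULL) {
  if (is.list(embeddings) && !is.matrix(embeddings))
    embeddings <- do.call(rbind, embeddings)
  if (!is.null(stimuli)) {
    missing <- setdiff(stimuli$category_word, rownames(embeddings))
    if (length(missing))
      abort(paste0("missing embedding for word(s): ",
                   paste(missing, collapse = ", ")))
    embeddings <- embeddings[stimuli$category_word, , drop = FALSE]
    rownames(embeddings) <- stimuli$stimulus_id
  }
  correlation_rdm(embeddings)
}

#' Trial-wise surprise under a feature model
#'
#' For every unexpected trial, looks up the model dissimilarity between the
#' image the cue predicted and the image actually seen, then z-scores these
#' values across the included trials (the form in which they enter the GLM
#' as a parametric modulator). Expected and no-go trials are excluded.
#'
#' @param rdm Feature-model `rdm`.
#' @param trials A `trial_table` (one run or several stacked runs).
#' @param model_id Label recorded in the output.
#' @return A `surprise` tibble: `trial`, `raw`, `z`, `model_id`.
#' @export
trial_surprise <- function(rdm, trials, model_id = "model") {
  un <- dplyr::filter(trials, .data$condition == "unexpected")
  if (!nrow(un)) abort("no unexpected trials to score")
  if (any(un$stimulus_id == un$expected_id))
    abort("trial marked unexpected but seen image equals expected image")
  raw <- rdm[cbind(un$expected_id, un$stimulus_id)]
  if (sd(raw) == 0)
    abort("degenerate feature model: constant dissimilarity across trials cannot be z-scored")
  out <- tibble(trial = un$trial, raw = raw,
                z = as.numeric(scale(raw)), model_id = model_id)
  class(out) <- c("surprise", class(out))
  out
}

#' Optimized selection of an 8-stimulus experimental set
#'
#' Searches random admissible subsets (4 animate + 4 inanimate) of a
#' stimulus pool for the one that maximizes within-layer RDM variance in the
#' low- and high-level feature spaces while minimizing the across-layer RDM
#' correlation: score = var(low ltv) + var(high ltv) - |r(low ltv, high ltv)|.
#'
#' @param features_low,features_high Pool feature matrices (stimuli x
#'   features, shared rownames), e.g., an early and a late network layer; or
#'   precomputed pool `rdm` objects (e.g., instance-averaged layer RDMs).
#' @param animacy Named character vector ("animate"/"inanimate") over the pool.
#' @param n_candidates Number of random subsets to score.
#' @param seed Optional integer seed.
#' @return List with `stimulus_id` (the 8 selected) and `diagnostics`
#'   (tibble: `var_low`, `var_high`, `cross_cor`, `score`).
#' @export
select_stimulus_set <- function(features_low, features_high, animacy,
                                n_candidates = 1000L, seed = NULL) {
  pool <- rownames(features_low)
  stopifnot(identical(pool, rownames(features_high)), !is.null(pool))
  animacy <- animacy[pool]
  an <- pool[animacy == "animate"]
  in_ <- pool[animacy == "inanimate"]
  if (length(an) < 4 || length(in_) < 4)
    abort("pool needs at least 4 stimuli per animacy class")
  # pool RDMs once; a subset's RDM is a submatrix of the pool RDM
  rdm_low <- if (inherits(features_low, "rdm")) features_low else
    correlation_rdm(features_low)
  rdm_high <- if (inherits(features_high, "rdm")) features_high else
    correlation_rdm(features_high)
  lt8 <- lower.tri(matrix(0, 8, 8))
  score_subset <- function(ids) {
    lo <- rdm_low[ids, ids][lt8]
    hi <- rdm_high[ids, ids][lt8]
    cc <- cor(lo, hi)
    c(var_low = var(lo), var_high = var(hi), cross_cor = cc,
      score = var(lo) + var(hi) - abs(cc))
  }
  with_seed(seed, {
    if (length(an) == 4 && length(in_) == 4) {
      cands <- list(c(an, in_))
    } else {
      cands <- replicate(n_candidates, c(sample(an, 4), sample(in_, 4)),
                         simplify = FALSE)
    }
    scores <- vapply(cands, score_subset, numeric(4))
    best <- which.max(scores["score", ])
    list(stimulus_id = cands[[best]],
         diagnostics = as_tibble(as.list(scores[, best])))
  })
}

#' Flag category outliers by agglomerative clustering
#'
#' Clusters pool stimuli on their high-level features (average linkage,
#' correlation distance, cut at the number of categories) and flags any
#' stimulus that is the sole member of its category outside that category's
#' modal cluster.
#'
#' @param features Feature matrix (stimuli x features, rownames = ids).
#' @param category Named character vector of category labels over the pool.
#' @return Character vector of flagged stimulus ids (possibly empty).
#' @export
flag_outliers <- function(features, category) {
  category <- category[rownames(features)]
  keep <- names(category)[!is.na(category)]
  counts <- table(category)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warn(paste0("skipping categories with <2 exemplars: ",
                paste(small, collapse = ", ")))
    keep <- keep[!category[keep] %in% small]
  }
  features <- features[keep, , drop = FALSE]
  category <- category[keep]
  k <- length(unique(category))
  d <- stats::as.dist(correlation_rdm(features))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  flagged <- character()
  for (cat in unique(category)) {
    members <- names(category)[category == cat]
    cl_cat <- cl[members]
    modal <- as.integer(names(which.max(table(cl_cat))))
    out <- members[cl_cat != modal]
    if (length(out) == 1L) flagged <- c(flagged, out)
  }
  sort(flagged)
}
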