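#' Fit an ordinary-least-squares GLM per voxel
#'
#' @param Y Numeric matrix (frames x voxels) or a `bold_run`.
#' @param X A `design_matrix` (an intercept column is appended).
#' @return A `pe_glm`: list with `beta` (regressors x voxels), `sigma2`,
#'   `dof`, `xtx_inv`, `columns`.
#' @export
fit_glm <- function(Y, X) {
  if (inherits(Y, "bold_run")) Y <- bold_matrix(Y)
  Y <- as.matrix(Y)
  Xi <- cbind(intercept = 1, unclass(X))
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi))
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(colnames(Xi)[setdiff(seq_len(ncol(Xi)),
                                            qrX$pivot[seq_len(qrX$rank)])],
                       collapse = ", ")))
  dof <- nrow(Xi) - qrX$rank
  if (dof <= 0) abort("non-positive residual degrees of freedom")
  beta <- qr.coef(qrX, Y)
  resid <- Y - Xi %*% beta
  structure(list(
    beta = beta,
    sigma2 = colSums(resid^2) / dof,
    dof = dof,
    xtx_inv = chol2inv(chol(crossprod(Xi))),
    columns = colnames(Xi)
  ), class = "pe_glm")
}

#' @export
print.pe_glm <- function(x, ...) {
  cat("<pe_glm> ", length(x$columns), " regressors x ", ncol(x$beta),
      " voxels, dof ", x$dof, "\n", sep = "")
  invisible(x)
}

#' Contrast estimate, variance, t and z per voxel
#'
#' @param fit A `pe_glm`.
#' @param contrast Named numeric vector (names matched to design columns) or
#'   full-length contrast vector including the intercept.
#' @return Tibble: `voxel`, `estimate`, `variance`, `t`, `z`, `dof`.
#' @export
glm_contrast <- function(fit, contrast) {
  cvec <- expand_contrast(fit, contrast)
  est <- unname(drop(crossprod(cvec, fit$beta)))
  cvar <- drop(crossprod(cvec, fit$xtx_inv %*% cvec))
  v <- unname(cvar * fit$sigma2)
  tval <- ifelse(v > 0, est / sqrt(v), 0)
  tibble(voxel = seq_along(est), estimate = est, variance = v,
         t = tval, z = t_to_z(tval, fit$dof), dof = fit$dof)
}

expand_contrast <- function(fit, contrast) {
  if (!is.null(names(contrast))) {
    cvec <- setNames(numeric(length(fit$columns)), fit$columns)
    bad <- setdiff(names(contrast), fit$columns)
    if (length(bad)) abort(paste0("unknown contrast column(s): ",
                                  paste(bad, collapse = ", ")))
    cvec[names(contrast)] <- contrast
  } else {
    stopifnot(length(contrast) == length(fit$columns))
    cvec <- as.numeric(contrast)
  }
  cvec
}

# two-sided-consistent monotone t -> z mapping at given dof
t_to_z <- function(t, dof) {
  z <- qnorm(pt(abs(t), dof, lower.tail = FALSE, log.p = TRUE),
             lower.tail = FALSE, log.p = TRUE)
  sign(t) * z
}

#' Fixed-effects combination of run-level contrasts
#'
#' Inverse-variance weighted average of run-level contrast estimates per
#' voxel; combined variance is `1 / sum(1 / v_i)`.
#'
#' @param contrasts List of [glm_contrast()] tibbles (one per run).
#' @return Tibble: `voxel`, `estimate`, `variance`.
#' @export
fixed_effects <- function(contrasts) {
  stopifnot(length(contrasts) >= 1)
  w <- purrr::map(contrasts, ~ 1 / .x$variance)
  wsum <- Reduce(`+`, w)
  est <- Reduce(`+`, purrr::map2(contrasts, w, ~ .x$estimate * .y)) / wsum
  tibble(voxel = contrasts[[1]]$voxel, estimate = est, variance = 1 / wsum)
}

#' Group-level one-sample test across subjects
#'
#' One-sample t test (with Cohen's dz) or Wilcoxon signed-rank test (with
#' matched-pairs rank-biserial correlation) of subject-level estimates
#' against zero. Two-sided.
#'
#' @param estimates Numeric vector (one unit) or matrix (subjects x units).
#' @param test `"t"` or `"wilcoxon"`.
#' @return Tibble: `unit`, `n`, `statistic`, `p`, `effect_size`, `z`,
#'   `flagged` (TRUE when the effect size is undefined, e.g. zero variance).
#' @export
group_test <- function(estimates, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  m <- as.matrix(estimates)
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    n <- sum(!is.na(x)); x <- x[!is.na(x)]
    if (test == "t") {
      s <- sd(x)
      if (s == 0) {
        return(tibble(unit = j, n = n, statistic = NA_real_, p = NA_real_,
                      effect_size = NA_real_, z = NA_real_, flagged = TRUE))
      }
      tt <- t.test(x)
      tibble(unit = j, n = n, statistic = unname(tt$statistic),
             p = tt$p.value, effect_size = mean(x) / s,
             z = t_to_z(unname(tt$statistic), n - 1), flagged = FALSE)
    } else {
      wt <- suppressWarnings(wilcox.test(x, exact = FALSE, correct = TRUE))
      tibble(unit = j, n = n, statistic = unname(wt$statistic),
             p = wt$p.value, effect_size = rank_biserial(x),
             z = qnorm(wt$p.value / 2, lower.tail = FALSE) *
               sign(rank_biserial(x)),
             flagged = all(x == 0))
    }
  })
}

# matched-pairs rank-biserial correlation: (W+ - W-) / (W+ + W-)
rank_biserial <- function(x) {
  x <- x[x != 0]
  if (!length(x)) return(0)
  r <- rank(abs(x))
  (sum(r[x > 0]) - sum(r[x < 0])) / sum(r)
}

#' Cluster-level inference by sign-flip permutation
#'
#' Forms 26-connectivity clusters of the group z map above the cluster
#' formation threshold (both signs) and assigns each a family-wise-error p
#' value from the maximum-cluster-extent null distribution obtained by
#' randomly sign-flipping subject maps.
#'
#' @param subject_maps Matrix (subjects x voxels) of subject-level estimates,
#'   voxels indexed over `mask`.
#' @param mask Logical 3D array; `sum(mask)` must equal `ncol(subject_maps)`.
#' @param formation_z Cluster-forming threshold on |z| (3.29 = p < 0.001
#'   two-sided).
#' @param n_permutations Number of sign-flip permutations.
#' @param seed Optional integer seed.
#' @return Tibble: `cluster`, `sign`, `n_voxels`, `peak_z`, `p_fwe`, plus a
#'   `label_map` attribute (3D integer array of cluster ids).
#' @export
cluster_inference <- function(subject_maps, mask, formation_z = 3.29,
                              n_permutations = 1000L, seed = NULL) {
  mask <- mask > 0
  stopifnot(sum(mask) == ncol(subject_maps))
  zmap_of <- function(m) {
    mu <- colMeans(m); s <- apply(m, 2, sd)
    tval <- ifelse(s > 0, mu / (s / sqrt(nrow(m))), 0)
    t_to_z(tval, nrow(m) - 1)
  }
  z <- zmap_of(subject_maps)
  comp <- suprathreshold_clusters(z, mask, formation_z)
  null_max <- with_seed(seed, {
    purrr::map_int(seq_len(n_permutations), function(p) {
      flips <- sample(c(-1, 1), nrow(subject_maps), replace = TRUE)
      zp <- zmap_of(subject_maps * flips)
      cp <- suprathreshold_clusters(zp, mask, formation_z)
      if (nrow(cp$table)) max(cp$table$n_voxels) else 0L
    })
  })
  tab <- comp$table
  tab$p_fwe <- purrr::map_dbl(tab$n_voxels, function(sz)
    (1 + sum(null_max >= sz)) / (n_permutations + 1))
  attr(tab, "label_map") <- comp$labels
  attr(tab, "zmap") <- z
  tab
}

# label 26-connected components of |z| >= thr within mask, split by sign
suprathreshold_clusters <- function(z, mask, thr) {
  dims <- dim(mask)
  vol <- array(0, dims)
  vol[mask] <- z
  labels <- array(0L, dims)
  supra <- which(abs(vol) >= thr & mask)
  tab <- tibble(cluster = integer(), sign = integer(),
                n_voxels = integer(), peak_z = numeric())
  if (!length(supra)) return(list(labels = labels, table = tab))
  remaining <- array(FALSE, dims); remaining[supra] <- TRUE
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cid <- 0L
  for (v in supra) {
    if (!remaining[v]) next
    cid <- cid + 1L
    sgn <- sign(vol[v])
    queue <- v; remaining[v] <- FALSE
    members <- integer()
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      co <- arrayInd(cur, dims)
      cand <- sweep(nb, 2, as.integer(co), `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
        cand[, 2] >= 1 & cand[, 2] <= dims[2] &
        cand[, 3] >= 1 & cand[, 3] <= dims[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + dims[1] * (cand[, 2] - 1L) +
        dims[1] * dims[2] * (cand[, 3] - 1L)
      lin <- lin[remaining[lin] & sign(vol[lin]) == sgn]
      if (length(lin)) {
        remaining[lin] <- FALSE
        queue <- c(queue, lin)
      }
    }
    labels[members] <- cid
    tab <- dplyr::bind_rows(tab, tibble(
      cluster = cid, sign = as.integer(sgn),
      n_voxels = length(members), peak_z = max(abs(vol[members])) * sgn))
  }
  list(labels = labels, table = tab)
}
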