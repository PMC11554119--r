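#' Synthetic layered feature hierarchy
#'
#' Stands in for the layer activations of a deep visual network: two
#' independent latent stimulus factor matrices ("low" and "high") are mixed
#' along a monotone per-layer schedule, so early layers express the low
#' factor, late layers the high factor, and adjacent layers are more similar
#' than distant ones. Instances share the latent factors and differ only in
#' their random feature projections (and feature noise), mirroring
#' independently initialized network instances whose RDMs are averaged.
#'
#' @param stimulus_id Stimulus labels (or a [stimulus_set()]).
#' @param n_layers Number of layers.
#' @param mixing Per-layer weight of the high factor, monotone non-decreasing
#'   in `[0, 1]`; defaults to an even ramp from 0 to 1.
#' @param latent_dim Dimension of each latent factor space.
#' @param n_features Feature dimension of every layer.
#' @param noise_sd SD of additive feature noise.
#' @param instance Instance number (projection seed offset).
#' @param layers Layer indices to realize (all by default; the mixing
#'   schedule still spans `n_layers`). Unrealized layers are `NULL`.
#' @param seed Base seed; latent factors depend only on `seed`, projections
#'   and noise also on `instance`.
#' @return A `feature_hierarchy`: list of `feature_space` objects (fields
#'   `layer_id`, `matrix`, `instance_id`), with the latent factors attached
#'   as attributes `latent_low` / `latent_high`.
#' @examples
#' fh <- synth_feature_hierarchy(stimulus_set(), seed = 1)
#' correlation_rdm(fh[[8]])
#' @export
synth_feature_hierarchy <- function(stimulus_id, n_layers = 8L,
                                    mixing = seq(0, 1, length.out = n_layers),
                                    latent_dim = 12L, n_features = 40L,
                                    noise_sd = 0.1, instance = 1L,
                                    layers = seq_len(n_layers), seed = NULL) {
  if (inherits(stimulus_id, "stimulus_set")) stimulus_id <- stimulus_id$stimulus_id
  n <- length(stimulus_id)
  if (is.unsorted(mixing)) abort("mixing schedule must be monotone non-decreasing")
  if (any(mixing < 0 | mixing > 1)) abort("mixing weights must lie in [0, 1]")
  latents <- with_seed(seed, list(
    low = matrix(rnorm(n * latent_dim), n, latent_dim),
    high = matrix(rnorm(n * latent_dim), n, latent_dim)
  ))
  proj_seed <- if (is.null(seed)) NULL else (seed %% 1000000L) * 1000L + instance
  out <- with_seed(proj_seed, {
    purrr::map(seq_len(n_layers), function(l) {
      P <- matrix(rnorm(latent_dim * n_features), latent_dim, n_features)
      Q <- matrix(rnorm(latent_dim * n_features), latent_dim, n_features)
      if (!l %in% layers) return(NULL)
      # sqrt weights: the layer's representational gram mixes the two latent
      # geometries linearly with weight w_l
      m <- sqrt(1 - mixing[l]) * (latents$low %*% P) +
        sqrt(mixing[l]) * (latents$high %*% Q)
      if (noise_sd > 0) m <- m + matrix(rnorm(n * n_features, sd = noise_sd), n)
      rownames(m) <- stimulus_id
      structure(list(layer_id = paste0("layer", l), matrix = m,
                     instance_id = as.integer(instance)),
                class = "feature_space")
    })
  })
  structure(out, latent_low = latents$low, latent_high = latents$high,
            class = "feature_hierarchy")
}

#' Layer RDMs of a feature hierarchy, averaged over instances
#'
#' Computes the correlation-distance RDM of each layer for `n_instances`
#' independent instances of the hierarchy and averages them element-wise, the
#' convention used to suppress instance-specific idiosyncrasies.
#'
#' @inheritParams synth_feature_hierarchy
#' @param n_instances Number of instances to average.
#' @param ... Passed to [synth_feature_hierarchy()].
#' @return Named list of `rdm` objects (`layer1` ... `layerN`).
#' @export
layer_rdms <- function(stimulus_id, n_instances = 10L, n_layers = 8L,
                       layers = seq_len(n_layers), seed = NULL, ...) {
  per_instance <- purrr::map(seq_len(n_instances), function(i) {
    fh <- synth_feature_hierarchy(stimulus_id, n_layers = n_layers,
                                  layers = layers, instance = i, seed = seed,
                                  ...)
    purrr::map(fh[layers], correlation_rdm)
  })
  out <- purrr::map(seq_along(layers), function(l) {
    average_rdms(purrr::map(per_instance, l))
  })
  names(out) <- paste0("layer", layers)
  out
}
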