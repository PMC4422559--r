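MOTIFS <- c("upstream", "downstream", "parallel", "unrelated")

#' Motif prototypes
#'
#' The expected pattern of feature values for each network motif, per
#' condition role: `MAX` means the feature should sit at the top of the
#' random-metabolite distribution, `R` means it should be indistinguishable
#' from random.  Downstream is MAX everywhere (the hub drives both its gene
#' targets and the metabolite in every condition); upstream is MAX in the
#' nutrient shifts but R under hub bypass (the drug cuts the metabolite off
#' from the transcriptome); parallel has MAX dynamic dependence in nutrient
#' shifts only and random hub-gene representation everywhere; unrelated is R
#' everywhere.
#'
#' @return A tibble with columns `motif`, `role`, `feature`, `proto`.
#' @export
motif_prototypes <- function() {
  tibble::tribble(
    ~motif,       ~role,            ~feature, ~proto,
    "upstream",   "nutrient_shift", "dd",     "MAX",
    "upstream",   "nutrient_shift", "rg",     "MAX",
    "upstream",   "hub_bypass",     "dd",     "R",
    "upstream",   "hub_bypass",     "rg",     "R",
    "downstream", "nutrient_shift", "dd",     "MAX",
    "downstream", "nutrient_shift", "rg",     "MAX",
    "downstream", "hub_bypass",     "dd",     "MAX",
    "downstream", "hub_bypass",     "rg",     "MAX",
    "parallel",   "nutrient_shift", "dd",     "MAX",
    "parallel",   "nutrient_shift", "rg",     "R",
    "parallel",   "hub_bypass",     "dd",     "R",
    "parallel",   "hub_bypass",     "rg",     "R",
    "unrelated",  "nutrient_shift", "dd",     "R",
    "unrelated",  "nutrient_shift", "rg",     "R",
    "unrelated",  "hub_bypass",     "dd",     "R",
    "unrelated",  "hub_bypass",     "rg",     "R"
  )
}

#' Enumerate dynamic-dependence method variants
#'
#' The cross product of metabolite interpolation method, assumed noise level
#' and replicate pairing: 2 x 4 x 3 = 24 ways of computing the dynamic
#' dependence with the defaults.
#'
#' @param interp Interpolation methods.
#' @param noise_cvs Noise coefficients of variation.
#' @param pairings Replicate pairing variants.
#' @return A tibble with columns `interp`, `noise_cv`, `pairing`,
#'   `variant_dd`.
#' @export
dd_variant_grid <- function(interp = c("linear", "smoothing_spline"),
                            noise_cvs = c(0.1, 0.2, 0.3, 0.4),
                            pairings = PAIRINGS) {
  g <- expand_grid(interp = interp, noise_cv = noise_cvs, pairing = pairings)
  g$variant_dd <- paste(g$interp, g$noise_cv, g$pairing, sep = "|")
  g
}

#' Enumerate full method variants
#'
#' Crosses the 24 dynamic-dependence variants with the two likelihood modes
#' (all three conditions, or hub bypass plus the best nutrient shift):
#' 48 probabilistic assignments with the defaults.
#'
#' @inheritParams dd_variant_grid
#' @param likelihood_modes One or both of `"all_three"`,
#'   `"bypass_plus_best_nutrient"`.
#' @return A tibble with one row per variant; column `variant` is a unique
#'   id.
#' @export
enumerate_variants <- function(interp = c("linear", "smoothing_spline"),
                               noise_cvs = c(0.1, 0.2, 0.3, 0.4),
                               pairings = PAIRINGS,
                               likelihood_modes = c("all_three", "bypass_plus_best_nutrient")) {
  likelihood_modes <- match.arg(likelihood_modes, several.ok = TRUE)
  g <- expand_grid(dd_variant_grid(interp, noise_cvs, pairings),
                   likelihood_mode = likelihood_modes)
  g$variant <- paste(g$variant_dd, g$likelihood_mode, sep = "|")
  g
}

# Mid-distribution eCDF of sorted null values:
# (#(v < x) + 0.5 * #(v = x)) / n.  For a draw exchangeable with the null
# sample this has expectation exactly 0.5 even when the feature is discrete
# (RG takes values on a 1/|SSG| grid); the plain right-continuous "<="
# count would be biased upward by half the tie probability, systematically
# over-penalizing R prototypes.
ecdf_value <- function(x, sorted_values) {
  n_le <- findInterval(x, sorted_values)
  n_lt <- findInterval(x, sorted_values, left.open = TRUE)
  (n_lt + 0.5 * (n_le - n_lt)) / length(sorted_values)
}

#' Likelihood of a feature value under a prototype
#'
#' Converts a feature value into a likelihood term via the empirical CDF of
#' the random-metabolite null ensemble.  The eCDF is the mid-distribution
#' function `(#(v < x) + 0.5 #(v = x)) / n`, which is exactly calibrated
#' (expectation 0.5 for a null-like draw) even for discrete features.  For
#' a `MAX` prototype the term is `eCDF(x)` (non-decreasing in the
#' feature).  For an `R` prototype the distance from the null median is
#' counted only above the median:
#' `1 - 2 * max(0, eCDF(x) - 0.5)` (the factor 2 rescales to `[0, 1]`;
#' with `rescale = FALSE` the term is `1 - max(0, eCDF(x) - 0.5)`).
#'
#' @param x Feature value(s).
#' @param proto `"MAX"` or `"R"`.
#' @param null_values Sorted (or unsorted) numeric null feature sample.
#' @param rescale Logical; rescale the R term to span `[0, 1]`.
#' @return Likelihood term(s) in `[0, 1]`.
#' @export
ecdf_likelihood <- function(x, proto = c("MAX", "R"), null_values, rescale = TRUE) {
  proto <- match.arg(proto)
  f <- ecdf_value(x, sort(null_values))
  if (proto == "MAX") return(f)
  s <- if (rescale) 2 else 1
  1 - s * pmax(0, f - 0.5)
}

#' Build the random-metabolite null ensemble
#'
#' Generates `n_random` artificial metabolites (a constant level with
#' multiplicative Gaussian noise at the dataset's empirical coefficient of
#' variation, on the experimental time grid), runs them through the
#' identical dynamic-dependence / hub-representation pipeline, and stores
#' the sorted feature values per (feature, condition) together with their
#' medians.  The mid-distribution empirical CDFs of these values are the
#' reference for the likelihood computation (see [ecdf_likelihood()]).
#'
#' @param x An [experiment_set()] (the ensemble is computed for `variant`),
#'   or a `dd_cache` from [compute_dd_features()] (the ensemble is
#'   extracted).
#' @param variant A one-row dd-variant tibble (see [dd_variant_grid()]);
#'   only used when `x` is an experiment set.
#' @param n_random Number of artificial metabolites (>= 20).
#' @param seed Integer seed.
#' @return A `null_ensemble`: tibble with columns `variant_dd`, `condition`,
#'   `feature`, `values` (sorted list column), `median`, plus attribute
#'   `n_random`.
#' @export
build_null_ensemble <- function(x, variant = dd_variant_grid()[1, ],
                                n_random = 100, seed = 1L) {
  cache <- if (inherits(x, "dd_cache")) {
    x
  } else if (inherits(x, "experiment_set")) {
    if (n_random < 20) abort("n_random must be at least 20")
    compute_dd_features(x, dd_variants = variant, n_random = n_random, seed = seed)
  } else {
    abort("x must be an experiment_set or a dd_cache")
  }
  nulls <- cache$features |>
    filter(.data$is_null) |>
    pivot_longer(c("dd", "rg"), names_to = "feature", values_to = "value") |>
    group_by(.data$variant_dd, .data$condition, .data$feature) |>
    summarise(values = list(sort(.data$value)), .groups = "drop") |>
    mutate(median = map_dbl(.data$values, median))
  structure(nulls, n_random = cache$n_random,
            class = c("null_ensemble", class(tibble())))
}

#' Motif likelihoods for one metabolite under one method variant
#'
#' The likelihood of each motif is the product of [ecdf_likelihood()] terms
#' over (condition, feature) pairs.  Mode `"all_three"` multiplies over all
#' conditions; `"bypass_plus_best_nutrient"` multiplies the hub-bypass terms
#' with, per motif, the terms of the nutrient shift whose per-condition
#' product is larger.
#'
#' @param features Data frame with columns `condition`, `feature`
#'   (`"dd"`/`"rg"`), `value`: one metabolite, one dd-variant, all
#'   conditions.
#' @param null A `null_ensemble` (or tibble with `condition`, `feature`,
#'   `values`) for the same dd-variant.
#' @param conditions A [condition_set()] tibble giving each condition's
#'   role.
#' @param mode `"all_three"` or `"bypass_plus_best_nutrient"`.
#' @param rescale Passed to [ecdf_likelihood()].
#' @return A tibble with columns `motif`, `likelihood`.
#' @export
motif_likelihood <- function(features, null, conditions,
                             mode = c("all_three", "bypass_plus_best_nutrient"),
                             rescale = TRUE) {
  mode <- match.arg(mode)
  features <- as_tibble(features)
  missing_cond <- setdiff(conditions$name, unique(features$condition))
  if (length(missing_cond) > 0) {
    abort(paste0("features missing for condition(s): ",
                 paste(missing_cond, collapse = ", ")))
  }
  terms <- features |>
    inner_join(conditions, by = c(condition = "name")) |>
    inner_join(tibble(condition = as.character(null$condition),
                      feature = null$feature, values = null$values),
               by = c("condition", "feature")) |>
    mutate(f = map2_dbl_(.data$value, .data$values,
                         function(x, v) ecdf_value(x, v))) |>
    cross_join(tibble(motif = MOTIFS)) |>
    inner_join(motif_prototypes(), by = c("motif", "role", "feature")) |>
    mutate(term = ifelse(.data$proto == "MAX", .data$f,
                         1 - (if (rescale) 2 else 1) * pmax(0, .data$f - 0.5)))
  cond_lik <- terms |>
    group_by(.data$motif, .data$condition, .data$role) |>
    summarise(lik = prod(.data$term), .groups = "drop")
  combine_condition_likelihoods(cond_lik, mode)
}

map2_dbl_ <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), 1.0)
}

combine_condition_likelihoods <- function(cond_lik, mode) {
  if (mode == "all_three") {
    out <- cond_lik |>
      group_by(.data$motif) |>
      summarise(likelihood = prod(.data$lik), .groups = "drop")
  } else {
    out <- cond_lik |>
      group_by(.data$motif) |>
      summarise(
        likelihood = prod(.data$lik[.data$role == "hub_bypass"]) *
          max(.data$lik[.data$role == "nutrient_shift"]),
        .groups = "drop")
  }
  out[match(MOTIFS, out$motif), ]
}

#' Posterior motif probabilities from likelihoods
#'
#' With uniform priors the posterior of motif i is `L_i / sum(L)`; the Bayes
#' factor between motifs is then the likelihood ratio.  When all
#' likelihoods vanish the posterior is uniform (0.25 each) and flagged
#' degenerate -- such variants support no motif in the majority vote.
#'
#' @param likelihoods Numeric vector of 4 non-negative likelihoods (named by
#'   motif, or in the order upstream, downstream, parallel, unrelated), or a
#'   tibble from [motif_likelihood()].
#' @return A tibble with columns `motif`, `likelihood`, `posterior`;
#'   attribute `degenerate`.
#' @export
motif_posterior <- function(likelihoods) {
  if (is.data.frame(likelihoods)) {
    l <- setNames(likelihoods$likelihood, likelihoods$motif)[MOTIFS]
  } else {
    l <- likelihoods
    if (is.null(names(l))) names(l) <- MOTIFS
    l <- l[MOTIFS]
  }
  if (any(l < 0)) abort("likelihoods must be non-negative")
  s <- sum(l)
  degenerate <- s == 0
  p <- if (degenerate) rep(0.25, 4) else l / s
  structure(tibble(motif = MOTIFS, likelihood = unname(l), posterior = unname(p)),
            degenerate = degenerate)
}

#' Bayes factor between two motifs
#'
#' @param posterior A tibble from [motif_posterior()].
#' @param i,j Motif names.
#' @return `P_i / P_j` (equals the likelihood ratio under uniform priors).
#' @export
bayes_factor <- function(posterior, i, j) {
  p <- setNames(posterior$posterior, posterior$motif)
  unname(p[i] / p[j])
}

#' Assignment frequencies and majority-vote call
#'
#' The frequency of a motif is the fraction of method variants assigning it
#' with posterior above `posterior_threshold`; a metabolite's final call is
#' the motif whose frequency exceeds `frequency_threshold`, or `"none"`.
#' Degenerate (all-equal) posteriors count toward no motif.
#'
#' @param posteriors Data frame with columns `metabolite`, `variant`,
#'   `motif`, `posterior` and (optionally) `degenerate`.
#' @param posterior_threshold Per-variant support threshold (default 0.5).
#' @param frequency_threshold Majority threshold on the frequency (default
#'   0.5, strict).
#' @return A tibble with one row per metabolite x motif: `frequency`, and
#'   the per-metabolite `call`.
#' @export
assignment_frequency <- function(posteriors, posterior_threshold = 0.5,
                                 frequency_threshold = 0.5) {
  posteriors <- as_tibble(posteriors)
  if (!"degenerate" %in% names(posteriors)) posteriors$degenerate <- FALSE
  freq <- posteriors |>
    group_by(.data$metabolite, .data$motif) |>
    summarise(frequency = mean(.data$posterior > posterior_threshold &
                                 !.data$degenerate),
              .groups = "drop_last") |>
    mutate(call = if (any(.data$frequency > frequency_threshold)) {
      .data$motif[which.max(.data$frequency)]
    } else {
      "none"
    }) |>
    ungroup()
  freq
}
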