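#' Compute DD and RG features for all metabolites and method variants
#'
#' The workhorse of the inference: for every condition it interpolates the
#' measured metabolites together with `n_random` artificial random
#' metabolites (the null ensemble, a constant with multiplicative Gaussian
#' noise at the dataset's empirical CV), computes the delayed distance
#' correlation of every metabolite against every transcript derivative for
#' each dynamic-dependence variant, selects each metabolite's significant
#' gene set (SSG), and derives the scalar features: DD (mean SSG distance
#' correlation) and RG (fraction of the SSG in the hub-TF target union).
#'
#' The returned cache keeps the SSGs, so hub-TF perturbation analyses can
#' recompute RG without redoing the (expensive, TF-independent) DD step.
#'
#' @param es A validated [experiment_set()].
#' @param dd_variants Tibble of dynamic-dependence variants, see
#'   [dd_variant_grid()].
#' @param n_random Size of the random-metabolite null ensemble (>= 20).
#' @param seed Integer seed (noise streams and null generation).
#' @param ssg_fraction Fraction of transcripts in the SSG (default 0.10).
#' @param smoothing Spline smoothing setting, see
#'   [interpolate_metabolite()].
#' @return A `dd_cache`: list with `features` (tibble: `variant_dd`,
#'   `interp`, `noise_cv`, `pairing`, `condition`, `metabolite`, `is_null`,
#'   `dd`, `rg`, `ssg` list column), plus bookkeeping fields.
#' @export
compute_dd_features <- function(es, dd_variants = dd_variant_grid(),
                                n_random = 100, seed = 1L,
                                ssg_fraction = 0.10, smoothing = "gcv") {
  diag <- validate_experiment_set(es)
  if (nrow(diag) > 0) {
    abort(paste0("invalid experiment set: ",
                 paste(diag$invariant, collapse = ", ")))
  }
  if (n_random < 20) abort("n_random must be at least 20")
  conds <- es$conditions$name
  tr_ids <- tc_features(es$transcripts[[conds[1]]])
  k <- ssg_size(length(tr_ids), ssg_fraction)
  null_ids <- sprintf("null_%04d", seq_len(n_random))
  out <- list()

  for (ci in seq_along(conds)) {
    cn <- conds[ci]
    met_tc <- es$metabolites[[cn]]
    cv_cond <- estimate_cv(met_tc)
    times <- tc_times(met_tc)
    n_rep <- length(tc_replicates(met_tc))
    null_rows <- list_rbind(lapply(seq_len(n_random), function(i) {
      tr <- generate_random_metabolite(times, level = 1, cv = cv_cond,
                                       seed = derive_seed(seed, ci, i),
                                       n_rep = n_rep)
      tr$feature_id <- null_ids[i]
      tr
    }))
    combined <- bind_rows(
      as_tibble(met_tc)[c("feature_id", "time", "replicate", "value")],
      null_rows[c("feature_id", "time", "replicate", "value")])
    comb_tc <- tc_matrix(combined, kind = "metabolite", condition = cn)
    trd <- prep_trd_matrix(es$transcripts[[cn]], smoothing = "gcv")

    for (ip in unique(dd_variants$interp)) {
      prep <- prep_met_channels(comb_tc, ip, smoothing)
      sub <- dd_variants[dd_variants$interp == ip, ]
      for (vi in seq_len(nrow(sub))) {
        v <- sub[vi, ]
        res <- dd_pairs_run(prep, trd, v$pairing, v$noise_cv, seed,
                            v$variant_dd, cn)
        mets <- rownames(res$dd_max)
        ssg_idx <- lapply(seq_along(mets), function(i) {
          ssg_top_idx(res$dd_max[i, ], tr_ids, k)
        })
        out[[length(out) + 1]] <- tibble(
          variant_dd = v$variant_dd, interp = v$interp,
          noise_cv = v$noise_cv, pairing = v$pairing, condition = cn,
          metabolite = mets, is_null = mets %in% null_ids,
          dd = vapply(seq_along(mets), function(i) {
            mean(res$dd_max[i, ssg_idx[[i]]])
          }, 1.0),
          ssg = lapply(ssg_idx, function(idx) tr_ids[idx]))
      }
    }
  }
  features <- list_rbind(out)
  features$rg <- rg_from_ssg(features$ssg, es$tf_map)
  structure(list(features = features, transcript_ids = tr_ids, k = k,
                 n_random = n_random, seed = seed,
                 conditions = es$conditions, dd_variants = dd_variants,
                 ssg_fraction = ssg_fraction, smoothing = smoothing),
            class = "dd_cache")
}

rg_from_ssg <- function(ssg_list, tf_map) {
  u <- hub_target_union(tf_map)
  vapply(ssg_list, function(g) mean(g %in% u), 1.0)
}

#' @export
print.dd_cache <- function(x, ...) {
  cat(sprintf("<dd_cache> %d dd-variants x %d conditions; %d metabolites + %d null; SSG size %d\n",
              nrow(x$dd_variants), nrow(x$conditions),
              length(unique(x$features$metabolite[!x$features$is_null])),
              x$n_random, x$k))
  invisible(x)
}

# Bayes-factor assignment from cached features.  The likelihood arithmetic
# lives here so that the TF-perturbation path can rerun it cheaply against a
# perturbed tf_map: RG is always recomputed from the cached SSGs (cheap),
# while the expensive, TF-independent DD features are reused as-is.
infer_from_cache <- function(cache, tf_map, variants = enumerate_variants(),
                             rescale = TRUE, posterior_threshold = 0.5,
                             frequency_threshold = 0.5) {
  feats <- cache$features
  feats$rg <- rg_from_ssg(feats$ssg, tf_map)
  long <- feats |>
    select(-"ssg", -"interp", -"noise_cv", -"pairing") |>
    pivot_longer(c("dd", "rg"), names_to = "feature", values_to = "value")
  nulls <- long |>
    filter(.data$is_null) |>
    group_by(.data$variant_dd, .data$condition, .data$feature) |>
    summarise(values = list(sort(.data$value)), .groups = "drop")
  real <- long |>
    filter(!.data$is_null) |>
    inner_join(nulls, by = c("variant_dd", "condition", "feature")) |>
    mutate(f = map2_dbl_(.data$value, .data$values, ecdf_value)) |>
    select(-"values")

  rs <- if (rescale) 2 else 1
  terms <- real |>
    inner_join(cache$conditions, by = c(condition = "name")) |>
    cross_join(tibble(motif = MOTIFS)) |>
    inner_join(motif_prototypes(), by = c("motif", "role", "feature")) |>
    mutate(term = ifelse(.data$proto == "MAX", .data$f,
                         1 - rs * pmax(0, .data$f - 0.5)))
  cond_lik <- terms |>
    group_by(.data$metabolite, .data$variant_dd, .data$motif,
             .data$condition, .data$role) |>
    summarise(lik = prod(.data$term), .groups = "drop")

  modes <- unique(variants$likelihood_mode)
  lik_by_mode <- list_rbind(lapply(modes, function(m) {
    if (m == "all_three") {
      l <- cond_lik |>
        group_by(.data$metabolite, .data$variant_dd, .data$motif) |>
        summarise(likelihood = prod(.data$lik), .groups = "drop")
    } else {
      l <- cond_lik |>
        group_by(.data$metabolite, .data$variant_dd, .data$motif) |>
        summarise(
          likelihood = prod(.data$lik[.data$role == "hub_bypass"]) *
            max(.data$lik[.data$role == "nutrient_shift"]),
          .groups = "drop")
    }
    l$likelihood_mode <- m
    l
  }))

  post <- variants |>
    select("variant", "variant_dd", "likelihood_mode") |>
    inner_join(lik_by_mode, by = c("variant_dd", "likelihood_mode"),
               relationship = "many-to-many") |>
    group_by(.data$metabolite, .data$variant) |>
    mutate(total = sum(.data$likelihood),
           degenerate = .data$total == 0,
           posterior = ifelse(.data$degenerate, 0.25,
                              .data$likelihood / .data$total)) |>
    ungroup() |>
    select("metabolite", "variant", "variant_dd", "likelihood_mode",
           "motif", "likelihood", "posterior", "degenerate")

  freq <- assignment_frequency(post, posterior_threshold, frequency_threshold)
  calls <- distinct(freq, .data$metabolite, .data$call)
  list(posteriors = post, frequencies = freq, calls = calls)
}

#' Assign metabolites to network motifs
#'
#' Runs the full probabilistic assignment: dynamic-dependence and hub-gene
#' representation features for every method variant, empirical-CDF
#' likelihoods against the random-metabolite null ensemble, Bayes-factor
#' posteriors per variant, and the majority vote over variants.
#'
#' @inheritParams compute_dd_features
#' @param variants Method variants from [enumerate_variants()] (48 by
#'   default).
#' @param rescale Rescale R-prototype likelihood terms to `[0, 1]`, see
#'   [ecdf_likelihood()].
#' @param posterior_threshold Per-variant support threshold.
#' @param frequency_threshold Majority threshold on assignment frequency.
#' @param cache Optionally, a precomputed `dd_cache` (its variants must
#'   cover `variants`); with a cache, `es` may be `NULL` if `tf_map` is
#'   given.
#' @param tf_map TF prior; defaults to the experiment set's map.
#' @return A `motif_assignment` object with elements `calls`,
#'   `frequencies`, `posteriors`, `cache`, `variants`, `tf_map`,
#'   `conditions`, `params`.
#' @export
assign_motifs <- function(es, variants = enumerate_variants(), n_random = 100,
                          seed = 1L, ssg_fraction = 0.10, smoothing = "gcv",
                          rescale = TRUE, posterior_threshold = 0.5,
                          frequency_threshold = 0.5, cache = NULL,
                          tf_map = NULL) {
  dd_vars <- distinct(variants[c("interp", "noise_cv", "pairing", "variant_dd")])
  if (is.null(cache)) {
    cache <- compute_dd_features(es, dd_vars, n_random = n_random, seed = seed,
                                 ssg_fraction = ssg_fraction,
                                 smoothing = smoothing)
  }
  tf_map <- tf_map %||% es$tf_map
  if (is.null(tf_map)) abort("need an experiment set or an explicit tf_map")
  inf <- infer_from_cache(cache, tf_map, variants, rescale,
                          posterior_threshold, frequency_threshold)
  structure(list(calls = inf$calls, frequencies = inf$frequencies,
                 posteriors = inf$posteriors, cache = cache,
                 variants = variants, tf_map = tf_map,
                 conditions = es$conditions,
                 params = list(seed = seed, n_random = cache$n_random,
                               ssg_fraction = ssg_fraction,
                               rescale = rescale,
                               posterior_threshold = posterior_threshold,
                               frequency_threshold = frequency_threshold)),
            class = "motif_assignment")
}

#' @export
print.motif_assignment <- function(x, ...) {
  cat(sprintf("<motif_assignment> %d metabolites, %d method variants\n",
              nrow(x$calls), length(unique(x$posteriors$variant))))
  print(x$calls, n = Inf)
  invisible(x)
}

#' @rdname assign_motifs
#' @param x A `motif_assignment`.
#' @param ... Unused.
#' @export
tidy.motif_assignment <- function(x, ...) {
  x$frequencies
}

#' @rdname assign_motifs
#' @export
glance.motif_assignment <- function(x, ...) {
  calls <- x$calls$call
  tibble(n_metabolites = nrow(x$calls),
         n_variants = length(unique(x$posteriors$variant)),
         n_upstream = sum(calls == "upstream"),
         n_downstream = sum(calls == "downstream"),
         n_parallel = sum(calls == "parallel"),
         n_unrelated = sum(calls == "unrelated"),
         n_none = sum(calls == "none"))
}
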