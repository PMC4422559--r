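#' Enumerate hub-TF removal sets
#'
#' All possible reduced hub-TF sets after removing `r` TFs: `C(|hub|, r)`
#' sets in deterministic (combination) order.
#'
#' @param hub_tfs Character vector of hub TFs.
#' @param r Number of TFs to remove (`1 <= r < length(hub_tfs)`).
#' @return List of character vectors (the reduced sets).
#' @export
enumerate_removals <- function(hub_tfs, r) {
  if (r < 1 || r >= length(hub_tfs)) {
    abort("r must satisfy 1 <= r < length(hub_tfs)")
  }
  drop_sets <- combn(hub_tfs, r, simplify = FALSE)
  lapply(drop_sets, function(d) setdiff(hub_tfs, d))
}

#' Sample augmented hub-TF sets
#'
#' Adds `a` distinct non-hub TFs to the hub set, `n_samples` times,
#' reproducibly per seed.  If the pool has exactly `a` members all draws
#' are identical (warned).
#'
#' @param tf_pool All TF names (hub and non-hub).
#' @param hub_tfs Current hub TFs.
#' @param a Number of TFs to add per draw.
#' @param n_samples Number of random draws (default 100).
#' @param seed Integer seed.
#' @return List of character vectors (augmented hub sets).
#' @export
sample_additions <- function(tf_pool, hub_tfs, a, n_samples = 100, seed = 1L) {
  pool <- setdiff(tf_pool, hub_tfs)
  if (length(pool) < a) {
    abort(sprintf("pool of non-hub TFs (%d) smaller than a = %d",
                  length(pool), a))
  }
  if (length(pool) == a) {
    warn("pool of non-hub TFs has exactly 'a' members: all draws are identical")
  }
  with_rng_seed(seed, {
    lapply(seq_len(n_samples), function(i) c(hub_tfs, sample(pool, a)))
  })
}

#' Recompute motif calls under a perturbed hub-TF set
#'
#' The dynamic-dependence features and their null eCDFs do not depend on
#' the TF prior, so only the RG features (real and null), likelihoods,
#' posteriors, frequencies and final calls are recomputed from the cached
#' SSGs.
#'
#' @param ma A [assign_motifs()] result (its `cache` is required).
#' @param hub_tfs The perturbed hub-TF set (subset of the map's TFs).
#' @return A tibble with columns `metabolite`, `call` (and the perturbed
#'   frequencies as attribute `frequencies`).
#' @export
reassign_under_perturbation <- function(ma, hub_tfs) {
  if (is.null(ma$cache)) abort("motif_assignment carries no dd_cache")
  tf_map <- set_hub_tfs(ma$tf_map, hub_tfs)
  inf <- infer_from_cache(ma$cache, tf_map, ma$variants,
                          rescale = ma$params$rescale,
                          posterior_threshold = ma$params$posterior_threshold,
                          frequency_threshold = ma$params$frequency_threshold)
  out <- inf$calls
  attr(out, "frequencies") <- inf$frequencies
  out
}

#' Robustness report over a set of TF perturbations
#'
#' Per metabolite, the assignment robustness is the fraction of
#' perturbation sets yielding the same final call as the unperturbed
#' analysis.  Per bin of the unperturbed maximal assignment frequency, the
#' error taxonomy is: false negative = an unperturbed motif call became
#' "none"; false positive = the perturbed call is a motif that differs from
#' the unperturbed call (including none -> motif); total = fn + fp.
#'
#' @param ma The unperturbed [assign_motifs()] result.
#' @param perturbed_calls List of call tibbles from
#'   [reassign_under_perturbation()] (>= 1).
#' @param bin_width Width of the maximal-frequency bins in percent
#'   (default 10).
#' @return A `robustness_report`: list with `per_metabolite` and `binned`
#'   tibbles.
#' @export
robustness_report <- function(ma, perturbed_calls, bin_width = 10) {
  if (length(perturbed_calls) < 1) abort("need at least one perturbation set")
  unpert <- ma$calls
  max_freq <- ma$frequencies |>
    group_by(.data$metabolite) |>
    summarise(max_frequency = 100 * max(.data$frequency), .groups = "drop")

  pert <- imap(perturbed_calls, function(calls, i) {
    tibble(set = i, metabolite = calls$metabolite, perturbed = calls$call)
  }) |>
    list_rbind() |>
    inner_join(rename(unpert, unperturbed = "call"), by = "metabolite") |>
    mutate(
      same = .data$perturbed == .data$unperturbed,
      fn = .data$unperturbed != "none" & .data$perturbed == "none",
      fp = .data$perturbed != "none" & .data$perturbed != .data$unperturbed)

  per_met <- pert |>
    group_by(.data$metabolite) |>
    summarise(unperturbed_call = .data$unperturbed[1],
              assignment_robustness = mean(.data$same),
              .groups = "drop")

  breaks <- seq(0, 100, by = bin_width)
  binned <- pert |>
    inner_join(max_freq, by = "metabolite") |>
    mutate(bin = cut(.data$max_frequency, breaks = breaks,
                     include.lowest = TRUE, right = TRUE)) |>
    group_by(.data$bin) |>
    summarise(n = dplyr::n(),
              fn_rate = mean(.data$fn),
              fp_rate = mean(.data$fp),
              total_error_rate = mean(.data$fn) + mean(.data$fp),
              .groups = "drop")

  structure(list(per_metabolite = per_met, binned = binned,
                 n_sets = length(perturbed_calls)),
            class = "robustness_report")
}

#' Full hub-TF robustness analysis
#'
#' Convenience wrapper running the exhaustive removal plans (-1 ... -r TFs)
#' and random addition plans (+1 ... +a TFs, `n_samples` draws each) and
#' reporting one [robustness_report()] per plan.
#'
#' @param ma A [assign_motifs()] result.
#' @param remove_sizes Removal sizes (e.g. `1:3`); `NULL` to skip.
#' @param add_sizes Addition sizes; `NULL` to skip.
#' @param n_samples Draws per addition size.
#' @param seed Integer seed for the additions.
#' @return A tibble with columns `kind`, `size`, `n_sets`, and a `report`
#'   list column of `robustness_report` objects.
#' @export
hub_tf_robustness <- function(ma, remove_sizes = 1:3, add_sizes = 1:3,
                              n_samples = 100, seed = 1L) {
  hub <- ma$tf_map$hub_tfs
  pool <- ma$tf_map$tf_ids
  plans <- list()
  for (r in remove_sizes %||% integer()) {
    plans[[length(plans) + 1]] <- list(kind = "remove", size = r,
                                       sets = enumerate_removals(hub, r))
  }
  for (a in add_sizes %||% integer()) {
    plans[[length(plans) + 1]] <- list(
      kind = "add", size = a,
      sets = sample_additions(pool, hub, a, n_samples,
                              seed = derive_seed(seed, a)))
  }
  rows <- lapply(plans, function(pl) {
    calls <- lapply(pl$sets, function(s) reassign_under_perturbation(ma, s))
    tibble(kind = pl$kind, size = pl$size, n_sets = length(pl$sets),
           report = list(robustness_report(ma, calls)))
  })
  list_rbind(rows)
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> %d perturbation sets\n", x$n_sets))
  print(x$per_metabolite, n = Inf)
  invisible(x)
}

#' @rdname robustness_report
#' @param x A `robustness_report`.
#' @param ... Unused.
#' @export
tidy.robustness_report <- function(x, ...) {
  x$per_metabolite
}

#' @rdname robustness_report
#' @export
glance.robustness_report <- function(x, ...) {
  tibble(n_sets = x$n_sets,
         mean_robustness = mean(x$per_metabolite$assignment_robustness),
         total_error_rate = sum(x$binned$n * x$binned$total_error_rate) /
           sum(x$binned$n))
}
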