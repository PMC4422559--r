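#' Sample distance correlation
#'
#' Szekely's sampled distance correlation between two paired samples, in
#' `[0, 1]`.  Points may be univariate (numeric vectors) or multivariate
#' (matrices with one sample per row, Euclidean distances).  When either
#' sample has zero distance variance (a constant signal) the value is 0:
#' a constant carries no dependence.
#'
#' @param x,y Numeric vectors, or matrices with the same number of rows.
#' @return A number in `[0, 1]`.
#' @examples
#' distance_correlation(1:5, 1:5)      # 1
#' distance_correlation(1:5, rep(2, 5)) # 0
#' @export
distance_correlation <- function(x, y) {
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  y <- if (is.matrix(y)) y else matrix(as.numeric(y), ncol = 1)
  if (nrow(x) != nrow(y)) abort("x and y must have the same number of samples")
  if (nrow(x) < 2) abort("need at least 2 paired samples")
  dcor_cpp(x, y)
}

#' Inject multiplicative Gaussian measurement noise
#'
#' Replaces each sample s by s + eps with eps ~ Normal(0, (cv * |s|)^2).
#' Draws come from a counter-based stream keyed by the seed and the supplied
#' string keys (typically metabolite id, transcript id, condition, method
#' variant), so results are reproducible and independent of evaluation
#' order.
#'
#' @param samples Numeric vector.
#' @param cv Coefficient of variation (> 0; 0 returns the input unchanged).
#' @param seed Integer seed.
#' @param keys Character vector identifying the stream.
#' @return Numeric vector of the same length.
#' @export
inject_noise <- function(samples, cv, seed = 1L, keys = character()) {
  stopifnot(cv >= 0)
  if (cv == 0) return(as.numeric(samples))
  as.numeric(noise_inject_cpp(as.numeric(samples), cv, as.double(seed),
                              as.character(keys)))
}

PAIRINGS <- c("average", "concat_replicates", "replicates_3d")

pairing_code <- function(pairing) {
  match(match.arg(pairing, PAIRINGS), PAIRINGS) - 1L
}

# sampled trajectory tibble -> channel matrices
traj_channels <- function(traj, grid) {
  stopifnot(setequal(unique(traj$time), grid))
  wide <- pivot_wider(traj, names_from = "time", values_from = "value")
  chan <- wide$channel
  m <- as.matrix(wide[as.character(grid)])
  rownames(m) <- chan
  m
}

#' Delayed dynamic dependence of one metabolite-transcript pair
#'
#' Pairs the metabolite samples at minutes 0..10 with the transcript
#' derivative samples at minutes d..d+10, for every delay d in 0..10, and
#' computes the distance correlation for each delay after injecting
#' multiplicative Gaussian noise on both sides.  Three pairing variants are
#' supported: `average` (replicate-averaged 11-point samples),
#' `concat_replicates` (metabolite replicates concatenated into one
#' 11R-point sample, transcript window tiled R times), and `replicates_3d`
#' (11 samples of R-dimensional points on both sides).
#'
#' @param met Interpolated metabolite trajectory from
#'   [interpolate_metabolite()] (needs per-replicate channels for the
#'   replicate pairings).
#' @param trd Transcript-derivative trajectory from
#'   [transcript_derivative()].
#' @param pairing One of `"average"`, `"concat_replicates"`,
#'   `"replicates_3d"`.  With a single replicate, `replicates_3d` falls back
#'   to `average` with a warning.
#' @param cv Noise coefficient of variation (0 disables noise).
#' @param seed Integer seed for the noise stream.
#' @param metabolite,transcript,condition,variant Strings keying the noise
#'   stream and labelling the record.
#' @return A one-row tibble: `metabolite`, `transcript`, `condition`,
#'   `dd_by_delay` (list column of 11 values named by delay), `dd_max`,
#'   `argmax_delay`.
#' @export
delayed_dd <- function(met, trd, pairing = "average", cv = 0, seed = 1L,
                       metabolite = "met", transcript = "tr",
                       condition = "", variant = "") {
  pairing <- match.arg(pairing, PAIRINGS)
  met_m <- traj_channels(met, MET_GRID)
  trd_m <- traj_channels(trd, TR_GRID)
  if (nrow(trd_m) > 1) trd_m <- matrix(colMeans(trd_m), nrow = 1)
  rep_rows <- grep("^r[0-9]+$", rownames(met_m))
  n_rep <- length(rep_rows)
  if (pairing != "average" && n_rep == 0) {
    abort(paste0("pairing '", pairing, "' needs per-replicate metabolite channels"))
  }
  if (pairing == "replicates_3d" && n_rep == 1) {
    warn("replicates_3d with a single replicate: falling back to 'average'")
    pairing <- "average"
  }
  met_avg <- if ("avg" %in% rownames(met_m)) {
    met_m["avg", , drop = FALSE]
  } else {
    matrix(colMeans(met_m[rep_rows, , drop = FALSE]), nrow = 1)
  }
  met_rep <- if (n_rep > 0) {
    matrix(t(met_m[rep_rows, , drop = FALSE]), nrow = 1) # replicate-major blocks
  } else {
    met_avg
  }
  res <- dd_matrix_cpp(met_avg, met_rep, max(n_rep, 1L), trd_m,
                       metabolite, transcript, pairing_code(pairing), cv,
                       as.double(seed), variant, condition,
                       return_delays = TRUE)
  dd <- as.numeric(res$dd_by_delay)
  names(dd) <- 0:10
  tibble(metabolite = metabolite, transcript = transcript,
         condition = condition, dd_by_delay = list(dd),
         dd_max = res$dd_max[1, 1], argmax_delay = as.numeric(res$argmax[1, 1]))
}

#' All-pairs dynamic dependence for one condition and one method variant
#'
#' @param es An [experiment_set()].
#' @param condition Condition name.
#' @param interp Metabolite interpolation method (`"linear"` or
#'   `"smoothing_spline"`).
#' @param pairing Pairing variant, see [delayed_dd()].
#' @param cv Noise coefficient of variation.
#' @param seed Integer seed.
#' @param smoothing Spline smoothing setting, see [interpolate_metabolite()].
#' @return A tibble with one row per metabolite x transcript pair:
#'   `metabolite`, `transcript`, `condition`, `dd_max`, `argmax_delay`.
#' @export
build_dd_matrix <- function(es, condition, interp = "linear",
                            pairing = "average", cv = 0, seed = 1L,
                            smoothing = "gcv") {
  met_tc <- es$metabolites[[condition]]
  tr_tc <- es$transcripts[[condition]]
  if (is.null(met_tc) || is.null(tr_tc)) {
    abort(paste0("condition not present in experiment set: ", condition))
  }
  prep <- prep_met_channels(met_tc, interp, smoothing)
  trd <- prep_trd_matrix(tr_tc, smoothing = "gcv")
  variant <- paste(interp, cv, pairing, sep = "|")
  res <- dd_pairs_run(prep, trd, pairing, cv, seed, variant, condition)
  tibble(metabolite = rep(rownames(res$dd_max), ncol(res$dd_max)),
         transcript = rep(colnames(res$dd_max), each = nrow(res$dd_max)),
         condition = condition,
         dd_max = as.numeric(res$dd_max),
         argmax_delay = as.numeric(res$argmax))
}

# interpolate every metabolite of a tc_matrix; returns avg and replicate
# matrices ready for dd_matrix_cpp
prep_met_channels <- function(met_tc, interp, smoothing) {
  a <- tc_array(met_tc)
  feats <- dimnames(a)[[1]]
  times <- as.numeric(dimnames(a)[[2]])
  n_rep <- dim(a)[3]
  avg <- matrix(NA_real_, length(feats), length(MET_GRID), dimnames = list(feats, MET_GRID))
  rep_m <- matrix(NA_real_, length(feats), n_rep * length(MET_GRID))
  rownames(rep_m) <- feats
  for (i in seq_along(feats)) {
    mean_vals <- rowMeans(matrix(a[i, , ], nrow = length(times)), na.rm = TRUE)
    avg[i, ] <- interp_channel(times, mean_vals, interp, smoothing, MET_GRID)
    for (r in seq_len(n_rep)) {
      v <- a[i, , r]
      keep <- !is.na(v)
      rep_m[i, ((r - 1) * length(MET_GRID) + 1):(r * length(MET_GRID))] <-
        interp_channel(times[keep], v[keep], interp, smoothing, MET_GRID)
    }
  }
  list(avg = avg, rep = rep_m, n_rep = n_rep)
}

# transcript-derivative matrix: one row per transcript, 25 columns
prep_trd_matrix <- function(tr_tc, smoothing = "gcv") {
  a <- tc_array(tr_tc)
  feats <- dimnames(a)[[1]]
  times <- as.numeric(dimnames(a)[[2]])
  out <- matrix(NA_real_, length(feats), length(TR_GRID), dimnames = list(feats, TR_GRID))
  for (i in seq_along(feats)) {
    v <- rowMeans(matrix(a[i, , ], nrow = length(times)), na.rm = TRUE)
    out[i, ] <- interp_channel(times, v, "smoothing_spline", smoothing, TR_GRID, deriv = 1L)
  }
  out
}

dd_pairs_run <- function(prep, trd, pairing, cv, seed, variant, condition) {
  eff_pairing <- pairing
  if (pairing == "replicates_3d" && prep$n_rep == 1) {
    warn("replicates_3d with a single replicate: falling back to 'average'")
    eff_pairing <- "average"
  }
  res <- dd_matrix_cpp(prep$avg, prep$rep, prep$n_rep, trd,
                       rownames(prep$avg), rownames(trd),
                       pairing_code(eff_pairing), cv, as.double(seed),
                       variant, condition, return_delays = FALSE)
  rownames(res$dd_max) <- rownames(prep$avg)
  colnames(res$dd_max) <- rownames(trd)
  dimnames(res$argmax) <- dimnames(res$dd_max)
  res
}

# significant-set size: round-half-up of fraction*G, at least 1
ssg_size <- function(n_transcripts, fraction = 0.10) {
  if (!(fraction > 0 && fraction <= 1)) abort("SSG fraction must be in (0, 1]")
  max(1L, as.integer(floor(fraction * n_transcripts + 0.5)))
}

#' Select the significant set of genes (SSG) for one metabolite
#'
#' The top `fraction` (default 10%) of transcripts by maximum delayed
#' dynamic dependence.  The set size is `round(fraction * G)` (half up,
#' minimum 1); ties at the cutoff are broken by lexicographic transcript id
#' so the selection is deterministic.
#'
#' @param records Data frame with columns `transcript` and `dd_max` (one
#'   metabolite, one condition; at least 10 transcripts).
#' @param fraction Fraction of the transcript universe to select.
#' @return A one-row tibble with list columns `gene_set` and `dd_values`
#'   plus `n_genes`.
#' @export
select_ssg <- function(records, fraction = 0.10) {
  records <- as_tibble(records)
  g <- nrow(records)
  if (g < 10) abort("need at least 10 transcripts to select an SSG")
  k <- ssg_size(g, fraction)
  ord <- order(-records$dd_max, records$transcript, method = "radix")
  top <- records[ord[seq_len(k)], ]
  tibble(gene_set = list(top$transcript), dd_values = list(top$dd_max), n_genes = k)
}

# fast path used by the pipeline: indices of the SSG in a named dd vector
ssg_top_idx <- function(dd, ids, k) {
  ord <- order(-dd, ids, method = "radix")
  ord[seq_len(k)]
}

#' Dynamic-dependence feature of an SSG
#'
#' The mean of the SSG members' maximum distance-correlation values; the
#' scalar "dynamic dependence" feature used for motif assignment.
#'
#' @param ssg A one-row tibble from [select_ssg()] (or any list with a
#'   `dd_values` element).
#' @return A number in `[0, 1]`.
#' @export
dd_feature <- function(ssg) {
  v <- if (is.data.frame(ssg)) ssg$dd_values[[1]] else ssg$dd_values
  if (length(v) == 0) abort("empty SSG")
  mean(v)
}

#' Hub-gene representation feature of an SSG
#'
#' The fraction of SSG members that are documented targets of at least one
#' hub-controlled TF.  With `mode = "enrichment"` the fraction is divided by
#' the genome-wide background fraction of hub targets and clipped to 1
#' (off by default).
#'
#' @param ssg A one-row tibble from [select_ssg()].
#' @param tf_map A [tf_target_map()] with non-empty `hub_tfs`.
#' @param mode `"fraction"` (default) or `"enrichment"`.
#' @param universe Transcript universe (required for `"enrichment"`).
#' @return A number in `[0, 1]`.
#' @export
rg_feature <- function(ssg, tf_map, mode = c("fraction", "enrichment"),
                       universe = NULL) {
  mode <- match.arg(mode)
  if (length(tf_map$hub_tfs) == 0) abort("tf_map has no hub-controlled TFs")
  genes <- if (is.data.frame(ssg)) ssg$gene_set[[1]] else ssg$gene_set
  if (length(genes) == 0) abort("empty SSG")
  u <- hub_target_union(tf_map)
  frac <- mean(genes %in% u)
  if (mode == "fraction") return(frac)
  if (is.null(universe)) abort("enrichment mode needs the transcript universe")
  bg <- mean(universe %in% u)
  if (bg == 0) return(0)
  min(1, frac / bg)
}

# Empirical replicate CV of a tc_matrix: root mean square over
# (feature, time) cells of sd/|mean| across replicates.  The RMS is used
# rather than the median because with few replicates each per-cell sd is a
# low-df estimate whose median sits well below the true sigma; averaging on
# the variance scale is unbiased, so the null ensemble is generated at the
# same noise level as a flat measured metabolite.
estimate_cv <- function(tc, fallback = 0.1) {
  a <- tc_array(tc)
  if (dim(a)[3] < 2) return(fallback)
  m <- apply(a, c(1, 2), mean, na.rm = TRUE)
  s <- apply(a, c(1, 2), sd, na.rm = TRUE)
  cvs <- s / abs(m)
  cvs <- cvs[is.finite(cvs)]
  if (length(cvs) == 0) return(fallback)
  sqrt(mean(cvs^2))
}
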