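# The generator realizes the conceptual model in which metabolite
# concentrations control transcript dynamics through an unknown network:
# gene expression follows linear relaxation d[Tr]/dt = alpha (D(t - tau) -
# [Tr]) toward a driver-dependent target D, where the driver is the hub
# activity (hub-controlled genes), a planted parallel metabolite (parallel
# genes), or a slow autonomous drift (background genes).

# run expr with a locally seeded RNG, restoring the caller's stream
with_rng_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a sub-seed below 2^31 from a base seed and integer tags
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 69069 + as.numeric(t) + 1) %% 2147483647
  as.integer(h)
}

#' Configuration for a synthetic three-condition experiment
#'
#' Defaults emulate the study design: metabolites sampled every minute over
#' 0-10 min in 3 replicates, transcripts at 9 time points over 0-24 min,
#' multiplicative measurement noise with CV 0.15, per-gene transcriptional
#' response delays of 1-6 min, and a TF prior in which 11 of 30 TFs are
#' hub-controlled and jointly cover the hub-driven gene set.
#'
#' @param n_genes Transcript universe size.
#' @param n_tor_genes Number of hub-driven genes.
#' @param n_parallel_genes Number of genes driven by the parallel
#'   metabolite.
#' @param n_tfs Total number of TFs (hub TFs plus decoys).
#' @param n_hub_tfs Number of hub-controlled TFs.
#' @param metabolites Tibble with columns `name`, `class` (planted motif,
#'   one of upstream / downstream / parallel / unrelated).
#' @param n_replicates Metabolite replicate count.
#' @param cv Metabolite measurement noise coefficient of variation
#'   (mass-spectrometry precision).
#' @param transcript_cv Transcript measurement noise CV; arrays after
#'   normalization are considerably more precise than MS metabolomics.
#' @param delay_range Range (min) of per-gene response delays.
#' @param amplitude Activation gain of planted metabolite responses: a full
#'   activation swing changes the level by a factor
#'   `(0.5 + amplitude) / 0.5` (4-fold with the default 1.5), symmetrically
#'   for up- and down-shifts on the fold-change scale.
#' @param alpha Gene relaxation rate (1/min).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 200, n_tor_genes = 40,
                             n_parallel_genes = 20, n_tfs = 30,
                             n_hub_tfs = 11,
                             metabolites = default_planted_metabolites(),
                             n_replicates = 3, cv = 0.15, transcript_cv = 0.08,
                             delay_range = c(1, 6), amplitude = 1.5,
                             alpha = 0.15, seed = 1L) {
  metabolites <- as_tibble(metabolites)
  stopifnot(all(c("name", "class") %in% names(metabolites)),
            all(metabolites$class %in% MOTIFS))
  if (n_tor_genes + n_parallel_genes > n_genes) {
    abort("n_tor_genes + n_parallel_genes must not exceed n_genes")
  }
  if (n_hub_tfs >= n_tfs) abort("need decoy TFs: n_hub_tfs < n_tfs")
  structure(list(n_genes = n_genes, n_tor_genes = n_tor_genes,
                 n_parallel_genes = n_parallel_genes, n_tfs = n_tfs,
                 n_hub_tfs = n_hub_tfs, metabolites = metabolites,
                 n_replicates = n_replicates, cv = cv,
                 transcript_cv = transcript_cv,
                 delay_range = delay_range, amplitude = amplitude,
                 alpha = alpha, seed = as.integer(seed)),
            class = "synthetic_config")
}

default_planted_metabolites <- function() {
  tibble(name = c("met_upstream", "met_downstream", "met_parallel",
                  "met_unrelated_1", "met_unrelated_2", "met_unrelated_3"),
         class = c("upstream", "downstream", "parallel",
                   "unrelated", "unrelated", "unrelated"))
}

#' Generate an artificial random metabolite trajectory
#'
#' The null construction: a constant level with i.i.d. multiplicative
#' Gaussian noise on every (time, replicate) cell.
#'
#' @param times Sampling times (minutes).
#' @param level Constant level.
#' @param cv Noise coefficient of variation (> 0; 0 gives the constant).
#' @param seed Integer seed.
#' @param n_rep Replicate count.
#' @return Tibble with columns `time`, `replicate`, `value`.
#' @export
generate_random_metabolite <- function(times, level = 1, cv = 0.1, seed = 1L,
                                       n_rep = 1L) {
  stopifnot(cv >= 0)
  with_rng_seed(seed, {
    g <- expand_grid(time = times, replicate = seq_len(n_rep))
    g$value <- level * (1 + cv * rnorm(nrow(g)))
    arrange(g, .data$time, .data$replicate)
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# hub activity in [0, 1]: gradual step at t = 2 min, up or down
hub_activity <- function(t, direction) {
  s <- sigmoid(0.8 * (t - 2))
  if (direction > 0) s else 1 - s
}

# Parallel-metabolite activation in [0, 1]: a late secondary program (rise
# centered at 8.5 min, partial adaptation after ~17 min).  The late onset is
# what decouples it from the hub regulon: the delay grid can only align
# transcript events occurring at or after a metabolite's change, so genes
# responding to the early hub step cannot be aligned with this metabolite,
# while its own (still later) target genes can.
parallel_activation <- function(t) {
  sigmoid(1.5 * (t - 8.5)) * (0.35 + 0.65 * sigmoid(-0.4 * (t - 17)))
}

# Metabolite level proportional to an activation a(t) in [0, 1], normalized
# to 1 at t = 0: with the default amplitude 1.5 (and floor 0.5) a full
# activation swing gives a 4-fold change, symmetric between up- and
# downshifts on the fold-change scale.
activation_to_level <- function(a, a0, amplitude, floor = 0.5) {
  (floor + amplitude * a) / (floor + amplitude * a0)
}

# noiseless metabolite trajectories per planted class; baseline 1
planted_metabolite_curve <- function(class, t, condition_role, shift_dir, amplitude) {
  flat <- rep(1, length(t))
  if (class == "unrelated") return(flat)
  if (condition_role == "hub_bypass" && class %in% c("upstream", "parallel")) {
    return(flat) # the drug does not touch the metabolite
  }
  if (class == "upstream") {
    # sustained shift starting at t ~ 0, preceding the hub response by ~1.5 min
    k <- 1.5; t0 <- 0.75
    s <- sigmoid(k * (t - t0))
    a <- if (shift_dir > 0) s else 1 - s
    a0 <- if (shift_dir > 0) sigmoid(-k * t0) else 1 - sigmoid(-k * t0)
    return(activation_to_level(a, a0, amplitude))
  }
  if (class == "parallel") {
    # late secondary program, see parallel_activation()
    pulse <- parallel_activation(t)
    a <- if (shift_dir > 0) pulse else 1 - pulse
    a0 <- if (shift_dir > 0) pulse[1] else 1 - pulse[1]
    return(activation_to_level(a, a0, amplitude))
  }
  if (class == "downstream") {
    # relaxation toward a level proportional to hub activity, every condition
    dir <- if (condition_role == "hub_bypass") -1 else shift_dir
    a0 <- hub_activity(0, dir)
    target <- function(tt) activation_to_level(hub_activity(tt, dir), a0, amplitude)
    return(relax_ode(t, target, rate = 0.5))
  }
  abort(paste0("unknown planted class: ", class))
}

# Euler integration of dx/dt = rate * (target(t) - x), x(0) = 1
relax_ode <- function(t_out, target, rate, lag = 0, t_max = max(t_out), dt = 0.05) {
  grid <- seq(0, t_max, by = dt)
  x <- numeric(length(grid))
  x[1] <- 1
  for (i in seq_along(grid)[-1]) {
    tt <- max(grid[i - 1] - lag, 0)
    x[i] <- x[i - 1] + dt * rate * (target(tt) - x[i - 1])
  }
  approx(grid, x, xout = t_out)$y
}

#' Generate a synthetic three-condition experiment with planted motifs
#'
#' Builds metabolite and transcript time courses for a nutrient upshift, a
#' nutrient downshift and a drug-induced hub-bypass condition, with planted
#' upstream / downstream / parallel / unrelated metabolites, hub-driven and
#' parallel-driven gene sets, decoy TFs, and multiplicative measurement
#' noise; returns the experiment set together with the ground truth.
#'
#' @param cfg A [synthetic_config()].
#' @return List with elements `experiment` (an [experiment_set()]) and
#'   `truth` (list of `metabolites` and `genes` tibbles).
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_rng_seed(cfg$seed, generate_experiment_impl(cfg))
}

generate_experiment_impl <- function(cfg) {
  conds <- condition_set()
  met_times <- 0:10
  tr_times <- c(0, 1, 3, 5, 7, 11, 15, 19, 24)
  genes <- sprintf("g%03d", seq_len(cfg$n_genes))
  n_hub_g <- cfg$n_tor_genes
  n_par_g <- cfg$n_parallel_genes
  driver <- c(rep("hub", n_hub_g), rep("parallel_metabolite", n_par_g),
              rep("none", cfg$n_genes - n_hub_g - n_par_g))
  gene_truth <- tibble(
    gene = genes, driver = driver,
    delay = runif(cfg$n_genes, cfg$delay_range[1], cfg$delay_range[2]),
    sign = sample(c(-1, 1), cfg$n_genes, replace = TRUE),
    drift = rnorm(cfg$n_genes, 0, 0.01))

  metabolites <- list()
  transcripts <- list()
  for (ci in seq_len(nrow(conds))) {
    cn <- conds$name[ci]
    role <- conds$role[ci]
    shift_dir <- if (cn == "downshift") -1 else 1
    hub_dir <- if (cn == "upshift") 1 else -1

    # --- metabolites ---
    rows <- list()
    for (mi in seq_len(nrow(cfg$metabolites))) {
      m <- cfg$metabolites[mi, ]
      curve <- planted_metabolite_curve(m$class, met_times, role, shift_dir,
                                        cfg$amplitude)
      for (r in seq_len(cfg$n_replicates)) {
        rows[[length(rows) + 1]] <- tibble(
          feature_id = m$name, time = met_times, replicate = r,
          value = curve * (1 + cfg$cv * rnorm(length(curve))))
      }
    }
    metabolites[[cn]] <- tc_matrix(list_rbind(rows), "metabolite", cn)

    # --- driver activations in [0, 1] for gene targets ---
    par_act <- if (role == "hub_bypass") {
      function(tt) rep(0, length(tt)) # parallel metabolite untouched by the drug
    } else {
      function(tt) parallel_activation(tt)
    }
    hub_act <- function(tt) hub_activity(tt, hub_dir)
    # signed gene target: 3-fold induction or repression across a full swing
    gene_target <- function(act_fun, sgn) {
      function(tt) {
        a <- act_fun(tt)
        a <- if (sgn > 0) a else 1 - a
        a0 <- if (sgn > 0) act_fun(0) else 1 - act_fun(0)
        activation_to_level(a, a0, amplitude = 1)
      }
    }

    # --- transcripts ---
    trs <- matrix(NA_real_, cfg$n_genes, length(tr_times),
                  dimnames = list(genes, tr_times))
    for (gi in seq_len(cfg$n_genes)) {
      g <- gene_truth[gi, ]
      lvl <- switch(
        g$driver,
        hub = relax_ode(tr_times, gene_target(hub_act, g$sign),
                        rate = cfg$alpha, lag = g$delay),
        parallel_metabolite = relax_ode(tr_times, gene_target(par_act, g$sign),
                                        rate = cfg$alpha, lag = g$delay),
        none = 1 + g$drift * tr_times)
      trs[gi, ] <- lvl * (1 + cfg$transcript_cv * rnorm(length(lvl)))
    }
    tr_long <- tibble(feature_id = rep(genes, each = length(tr_times)),
                      time = rep(tr_times, cfg$n_genes),
                      replicate = 1L,
                      value = as.numeric(t(trs)))
    transcripts[[cn]] <- tc_matrix(tr_long, "transcript", cn)
  }

  # --- TF map: hub TFs jointly cover the hub gene set; decoys are random ---
  hub_tf_names <- if (cfg$n_hub_tfs == 11) default_hub_tfs() else
    sprintf("HubTF%02d", seq_len(cfg$n_hub_tfs))
  decoy_names <- sprintf("DecoyTF%02d", seq_len(cfg$n_tfs - cfg$n_hub_tfs))
  hub_genes <- genes[driver == "hub"]
  targets <- setNames(vector("list", cfg$n_tfs), c(hub_tf_names, decoy_names))
  # each hub gene is covered by 1-3 hub TFs
  for (tf in hub_tf_names) targets[[tf]] <- character()
  for (g in hub_genes) {
    owners <- sample(hub_tf_names, sample(1:3, 1))
    for (tf in owners) targets[[tf]] <- c(targets[[tf]], g)
  }
  # guard against an empty hub TF (possible for tiny hub gene sets)
  for (tf in hub_tf_names) {
    if (length(targets[[tf]]) == 0) targets[[tf]] <- sample(hub_genes, 1)
  }
  for (tf in decoy_names) {
    targets[[tf]] <- sample(genes, min(15, cfg$n_genes))
  }
  tf_map <- tf_target_map(targets, hub_tfs = hub_tf_names)

  es <- experiment_set(metabolites, transcripts, tf_map, conds)
  truth <- list(
    metabolites = select(cfg$metabolites, "name", planted_class = "class"),
    genes = select(gene_truth, "gene", "driver", "delay", "sign"))
  list(experiment = es, truth = truth)
}
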