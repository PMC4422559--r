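test_that("variant enumeration reproduces the method combinatorics", {
  expect_equal(nrow(enumerate_variants()), 48)
  expect_equal(nrow(dd_variant_grid()), 24)
  expect_equal(nrow(enumerate_variants(noise_cvs = 0.1)), 12)
  expect_equal(anyDuplicated(enumerate_variants()$variant), 0)
  # 24 distinct DD methods inside the 48
  expect_equal(length(unique(enumerate_variants()$variant_dd)), 24)
})

test_that("motif prototypes encode the expected patterns", {
  p <- motif_prototypes()
  get <- function(m, r, f) p$proto[p$motif == m & p$role == r & p$feature == f]
  expect_true(all(p$proto[p$motif == "downstream"] == "MAX"))
  expect_true(all(p$proto[p$motif == "unrelated"] == "R"))
  expect_equal(get("upstream", "nutrient_shift", "dd"), "MAX")
  expect_equal(get("upstream", "hub_bypass", "rg"), "R")
  expect_equal(get("parallel", "nutrient_shift", "dd"), "MAX")
  expect_equal(get("parallel", "nutrient_shift", "rg"), "R")
  expect_equal(get("parallel", "hub_bypass", "dd"), "R")
})

test_that("eCDF likelihood terms satisfy the boundary cases", {
  nulls <- 1:20 / 20 # even n, interpolated median -> eCDF(median) = 0.5
  med <- median(nulls)
  expect_equal(ecdf_likelihood(med, "MAX", nulls), 0.5)
  expect_equal(ecdf_likelihood(med, "R", nulls), 1)
  expect_equal(ecdf_likelihood(2, "MAX", nulls), 1)
  expect_equal(ecdf_likelihood(2, "R", nulls), 0)
  expect_equal(ecdf_likelihood(-1, "MAX", nulls), 0)
  expect_equal(ecdf_likelihood(-1, "R", nulls), 1)
  # without rescaling the R term spans [0.5, 1]
  expect_equal(ecdf_likelihood(2, "R", nulls, rescale = FALSE), 0.5)
})

test_that("eCDF likelihoods are monotone in the feature value", {
  set.seed(31)
  nulls <- runif(50)
  xs <- seq(-0.1, 1.1, length.out = 200)
  lmax <- ecdf_likelihood(xs, "MAX", nulls)
  lr <- ecdf_likelihood(xs, "R", nulls)
  expect_true(all(diff(lmax) >= 0))
  expect_true(all(diff(lr) <= 0))
})

test_that("motif likelihood is the product of per-term eCDF distances", {
  conds <- condition_set()
  set.seed(32)
  null_tbl <- tidyr::expand_grid(condition = conds$name,
                                 feature = c("dd", "rg"))
  null_tbl$values <- lapply(1:6, function(i) sort(runif(20)))
  feats <- tidyr::expand_grid(condition = conds$name, feature = c("dd", "rg"))
  feats$value <- runif(6)

  lik <- motif_likelihood(feats, null_tbl, conds, mode = "all_three")
  # hand-computed oracle: product over the 6 (condition, feature) terms
  proto <- motif_prototypes()
  for (m in c("upstream", "downstream", "parallel", "unrelated")) {
    terms <- sapply(1:6, function(i) {
      role <- conds$role[conds$name == feats$condition[i]]
      pr <- proto$proto[proto$motif == m & proto$role == role &
                          proto$feature == feats$feature[i]]
      ecdf_likelihood(feats$value[i], pr, null_tbl$values[[i]])
    })
    expect_equal(lik$likelihood[lik$motif == m], prod(terms),
                 tolerance = 1e-12)
  }

  # bypass + best nutrient: bypass product times the better shift product
  lik2 <- motif_likelihood(feats, null_tbl, conds,
                           mode = "bypass_plus_best_nutrient")
  for (m in c("upstream", "downstream", "parallel", "unrelated")) {
    per_cond <- sapply(conds$name, function(cn) {
      idx <- which(feats$condition == cn)
      prod(sapply(idx, function(i) {
        role <- conds$role[conds$name == cn]
        pr <- proto$proto[proto$motif == m & proto$role == role &
                            proto$feature == feats$feature[i]]
        ecdf_likelihood(feats$value[i], pr, null_tbl$values[[i]])
      }))
    })
    byp <- conds$name[conds$role == "hub_bypass"]
    nut <- conds$name[conds$role == "nutrient_shift"]
    expect_equal(lik2$likelihood[lik2$motif == m],
                 unname(per_cond[byp] * max(per_cond[nut])),
                 tolerance = 1e-12)
  }

  expect_error(motif_likelihood(feats[feats$condition != "upshift", ],
                                null_tbl, conds), "missing")
})

test_that("posteriors normalize, flag degeneracy, and expose Bayes factors", {
  p <- motif_posterior(c(upstream = 0.4, downstream = 0.1,
                         parallel = 0.1, unrelated = 0.4))
  expect_equal(p$posterior, c(0.4, 0.1, 0.1, 0.4))
  expect_false(attr(p, "degenerate"))

  pe <- motif_posterior(rep(2, 4))
  expect_equal(pe$posterior, rep(0.25, 4))

  pz <- motif_posterior(rep(0, 4))
  expect_equal(pz$posterior, rep(0.25, 4))
  expect_true(attr(pz, "degenerate"))

  expect_error(motif_posterior(c(-1, 1, 1, 1)), "non-negative")
  expect_equal(bayes_factor(p, "upstream", "downstream"), 4)
})

test_that("posterior and frequency invariants hold on randomized inputs", {
  set.seed(33)
  for (i in 1:1000) {
    l <- rexp(4) * rbinom(4, 1, 0.8)
    p <- motif_posterior(l)
    expect_equal(sum(p$posterior), 1, tolerance = 1e-12)
    if (all(l > 0)) {
      # Bayes-factor transitivity B_ij * B_jk = B_ik
      b12 <- bayes_factor(p, "upstream", "downstream")
      b23 <- bayes_factor(p, "downstream", "parallel")
      b13 <- bayes_factor(p, "upstream", "parallel")
      expect_equal(b12 * b23, b13, tolerance = 1e-9)
    }
  }

  # at most one motif can exceed 50% frequency
  set.seed(34)
  for (i in 1:50) {
    n_var <- sample(c(4, 16, 48), 1)
    post <- tidyr::expand_grid(metabolite = "m", variant = seq_len(n_var),
                               motif = c("upstream", "downstream",
                                         "parallel", "unrelated"))
    post <- dplyr::group_by(post, variant) |>
      dplyr::mutate(posterior = {
        l <- rexp(4)
        l / sum(l)
      }) |>
      dplyr::ungroup()
    freq <- assignment_frequency(post)
    expect_lte(sum(freq$frequency > 0.5), 1)
    expect_true(all(freq$frequency >= 0 & freq$frequency <= 1))
  }
})

test_that("assignment frequency implements the majority-vote rules", {
  mk_post <- function(p_up) {
    tidyr::expand_grid(metabolite = "m", variant = seq_along(p_up)) |>
      dplyr::rowwise() |>
      dplyr::mutate(post = list(tibble::tibble(
        motif = c("upstream", "downstream", "parallel", "unrelated"),
        posterior = c(p_up[variant], rep((1 - p_up[variant]) / 3, 3))))) |>
      tidyr::unnest(post) |>
      dplyr::ungroup()
  }
  # 48 variants, 30 supporting upstream above 50%
  freq <- assignment_frequency(mk_post(c(rep(0.9, 30), rep(0.2, 18))))
  expect_equal(freq$frequency[freq$motif == "upstream"], 30 / 48)
  expect_equal(unique(freq$call), "upstream")

  # every variant degenerate -> all frequencies 0, call none
  post <- mk_post(rep(0.25, 10))
  post$posterior <- 0.25
  post$degenerate <- TRUE
  freq2 <- assignment_frequency(post)
  expect_true(all(freq2$frequency == 0))
  expect_equal(unique(freq2$call), "none")

  # plurality without strict majority -> none
  freq3 <- assignment_frequency(mk_post(c(rep(0.9, 24), rep(0.2, 26))))
  expect_equal(freq3$frequency[freq3$motif == "upstream"], 0.48)
  expect_equal(unique(freq3$call), "none")
})

test_that("null ensemble eCDFs honour the order-statistic conventions", {
  sim <- small_synthetic()
  v <- dd_variant_grid(interp = "linear", noise_cvs = 0.2,
                       pairings = "average")
  ne <- build_null_ensemble(sim$experiment, variant = v, n_random = 20,
                            seed = 5)
  expect_s3_class(ne, "null_ensemble")
  expect_equal(nrow(ne), 6) # 3 conditions x 2 features
  for (i in seq_len(nrow(ne))) {
    vals <- ne$values[[i]]
    expect_equal(hubmotif:::ecdf_value(-Inf, vals), 0)
    expect_equal(hubmotif:::ecdf_value(Inf, vals), 1)
    expect_true(all(diff(vals) >= 0))
  }
  # the continuous DD feature has distinct values: eCDF(median) = 0.5 (even n)
  dd_rows <- which(ne$feature == "dd")
  for (i in dd_rows) {
    if (!anyDuplicated(ne$values[[i]])) {
      expect_equal(hubmotif:::ecdf_value(ne$median[i], ne$values[[i]]), 0.5)
    }
  }
  expect_error(build_null_ensemble(sim$experiment, variant = v,
                                   n_random = 5), "at least 20")
})
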