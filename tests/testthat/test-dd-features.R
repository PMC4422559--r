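test_that("noise injection honours its contracts", {
  x <- c(1, 2, -3, 0.5)
  expect_equal(inject_noise(x, cv = 0), x)
  a <- inject_noise(x, cv = 0.2, seed = 5, keys = c("m1", "g1"))
  b <- inject_noise(x, cv = 0.2, seed = 5, keys = c("m1", "g1"))
  expect_identical(a, b)
  c <- inject_noise(x, cv = 0.2, seed = 5, keys = c("m1", "g2"))
  expect_false(identical(a, c))
  # sd of s + cv*|s|*z at s = 1, cv = 0.2 over 1e4 draws
  draws <- inject_noise(rep(1, 1e4), cv = 0.2, seed = 9)
  expect_gt(sd(draws), 0.19)
  expect_lt(sd(draws), 0.21)
  expect_lt(abs(mean(draws) - 1), 0.01)
})

test_that("delayed_dd yields 11 delay values and finds planted delays", {
  met_vals <- sin(0:10) + 2
  met <- make_met_traj(met_vals)
  # zero derivative everywhere -> all 11 values are 0
  r0 <- delayed_dd(met, make_trd_traj(rep(0, 25)), cv = 0)
  expect_length(r0$dd_by_delay[[1]], 11)
  expect_true(all(r0$dd_by_delay[[1]] == 0))

  # planted copy at every delay d = 0..10 (noise off): dd = 1 at d
  for (d in 0:10) {
    trd_vals <- rep(0, 25)
    trd_vals[(d + 1):(d + 11)] <- met_vals
    r <- delayed_dd(met, make_trd_traj(trd_vals), cv = 0)
    expect_equal(r$argmax_delay, d)
    expect_equal(r$dd_max, 1, tolerance = 1e-12)
    expect_equal(max(r$dd_by_delay[[1]]), r$dd_max)
  }
})

test_that("replicates_3d with one replicate falls back to average", {
  met <- make_met_traj(sin(0:10) + 2, channel = "r1")
  trd_vals <- rep(0, 25); trd_vals[1:11] <- sin(0:10) + 2
  expect_warning(r <- delayed_dd(met, make_trd_traj(trd_vals),
                                 pairing = "replicates_3d", cv = 0),
                 "falling back")
  expect_equal(r$dd_max, 1, tolerance = 1e-12)
})

test_that("build_dd_matrix covers all pairs and ignores row order", {
  sim <- small_synthetic()
  es <- sim$experiment
  rec <- build_dd_matrix(es, "upshift", cv = 0.1, seed = 3)
  n_met <- length(tc_features(es$metabolites$upshift))
  n_tr <- length(tc_features(es$transcripts$upshift))
  expect_equal(nrow(rec), n_met * n_tr)

  # permute transcript rows: per-pair values unchanged (id-keyed noise)
  es2 <- es
  tr <- as.data.frame(es2$transcripts$upshift)
  ids <- unique(tr$feature_id)
  tr$feature_id <- factor(tr$feature_id, levels = rev(ids))
  tr <- dplyr::arrange(tr, feature_id)
  tr$feature_id <- as.character(tr$feature_id)
  es2$transcripts$upshift <- tc_matrix(tr, "transcript", "upshift")
  rec2 <- build_dd_matrix(es2, "upshift", cv = 0.1, seed = 3)
  j <- dplyr::inner_join(rec, rec2, by = c("metabolite", "transcript"))
  expect_equal(nrow(j), nrow(rec))
  expect_equal(j$dd_max.x, j$dd_max.y, tolerance = 1e-14)
})

test_that("SSG selection implements round-half-up with id tie-breaks", {
  recs <- tibble::tibble(transcript = sprintf("g%03d", 1:100),
                         dd_max = seq(0.01, 1, length.out = 100))
  ssg <- select_ssg(recs, 0.1)
  expect_equal(ssg$n_genes, 10)
  expect_setequal(ssg$gene_set[[1]], sprintf("g%03d", 91:100))

  expect_equal(hubmotif:::ssg_size(5716, 0.1), 572)
  expect_equal(hubmotif:::ssg_size(14, 0.1), 1)
  expect_error(select_ssg(recs, 1.5), "fraction")
  expect_error(select_ssg(recs[1:5, ], 0.1), "at least 10")

  # all-equal dd: deterministic first-by-id selection
  ties <- tibble::tibble(transcript = sprintf("g%03d", 100:1),
                         dd_max = rep(0.5, 100))
  ssg2 <- select_ssg(ties, 0.1)
  expect_equal(sort(ssg2$gene_set[[1]]), sprintf("g%03d", 1:10))
})

test_that("DD feature is the mean of the SSG and matches a sort oracle", {
  ssg <- tibble::tibble(gene_set = list(c("a", "b")),
                        dd_values = list(c(0.8, 0.6)), n_genes = 2)
  expect_equal(dd_feature(ssg), 0.7)
  expect_equal(dd_feature(list(dd_values = rep(1, 5))), 1)

  set.seed(21)
  dd <- runif(1000)
  recs <- tibble::tibble(transcript = sprintf("g%04d", 1:1000), dd_max = dd)
  got <- dd_feature(select_ssg(recs, 0.1))
  oracle <- mean(sort(dd, decreasing = TRUE)[1:100])
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("RG feature counts the hub-target fraction of the SSG", {
  map <- tf_target_map(list(TF1 = c("g1", "g2"), TF2 = c("g3", "g4")),
                       hub_tfs = c("TF1", "TF2"))
  ssg <- tibble::tibble(gene_set = list(paste0("g", 1:10)),
                        dd_values = list(rep(0.5, 10)), n_genes = 10)
  expect_equal(rg_feature(ssg, map), 0.4)

  empty_map <- tf_target_map(list(TF1 = character(), TF2 = "g3"),
                             hub_tfs = "TF1")
  expect_equal(rg_feature(ssg, empty_map), 0)

  sub <- tibble::tibble(gene_set = list(c("g1", "g3")),
                        dd_values = list(c(1, 1)), n_genes = 2)
  expect_equal(rg_feature(sub, map), 1)
  expect_error(rg_feature(ssg, set_hub_tfs(map, character())), "no hub")
})

test_that("dd_max grows monotonically with the delay grid", {
  # max over a superset of delays can only increase
  met <- make_met_traj(cos(0:10) + 2)
  trd_vals <- rep(0.1, 25); trd_vals[8:18] <- cos(0:10) + 2
  r <- delayed_dd(met, make_trd_traj(trd_vals), cv = 0)
  dd <- r$dd_by_delay[[1]]
  for (k in 2:11) expect_gte(max(dd[1:k]), max(dd[1:(k - 1)]))
})
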