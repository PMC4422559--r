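test_that("removal enumeration matches the binomial counts", {
  hub <- default_hub_tfs()
  expect_length(enumerate_removals(hub, 1), 11)
  expect_length(enumerate_removals(hub, 2), 55)
  expect_length(enumerate_removals(hub, 3), 165) # C(11, 3)
  expect_true(all(lengths(enumerate_removals(hub, 2)) == 9))
  expect_error(enumerate_removals(hub, 11), "1 <= r")
  expect_error(enumerate_removals(hub, 0), "1 <= r")
})

test_that("addition sampling is sized, seeded, and warns on a tight pool", {
  pool <- c(default_hub_tfs(), sprintf("X%02d", 1:19))
  hub <- default_hub_tfs()
  sets <- sample_additions(pool, hub, a = 1, n_samples = 100, seed = 4)
  expect_length(sets, 100)
  expect_true(all(lengths(sets) == 12))
  expect_true(all(vapply(sets, function(s) all(hub %in% s), TRUE)))
  sets2 <- sample_additions(pool, hub, a = 1, n_samples = 100, seed = 4)
  expect_identical(sets, sets2)

  tight <- c(hub, "only_one")
  expect_warning(s3 <- sample_additions(tight, hub, a = 1, n_samples = 5,
                                        seed = 1),
                 "identical")
  expect_length(unique(lapply(s3, sort)), 1)
  expect_error(sample_additions(hub, hub, a = 1), "smaller")
})

test_that("identity perturbation reproduces the unperturbed calls exactly", {
  ma <- small_assignment()
  same <- reassign_under_perturbation(ma, ma$tf_map$hub_tfs)
  expect_equal(same$metabolite, ma$calls$metabolite)
  expect_equal(same$call, ma$calls$call)
  rep <- robustness_report(ma, list(same))
  expect_true(all(rep$per_metabolite$assignment_robustness == 1))
  expect_true(all(rep$binned$total_error_rate == 0))
})

test_that("removals leaving the target union intact do not change calls", {
  ma <- small_assignment()
  map <- ma$tf_map
  # add a TF whose targets are all covered by the remaining hub TFs
  u <- unique(unlist(map$targets[map$hub_tfs]))
  targets2 <- c(map$targets, list(Shadow = u[seq_len(min(3, length(u)))]))
  map2 <- tf_target_map(targets2, hub_tfs = c(map$hub_tfs, "Shadow"))
  ma2 <- ma
  ma2$tf_map <- map2
  with_shadow <- reassign_under_perturbation(ma2, map2$hub_tfs)
  without_shadow <- reassign_under_perturbation(ma2, map$hub_tfs)
  expect_equal(as.data.frame(with_shadow), as.data.frame(without_shadow))
})

test_that("error rates follow the fn/fp taxonomy and sum per bin", {
  ma <- small_assignment()
  mets <- ma$calls$metabolite
  # construct perturbed call sets by hand around the real unperturbed calls
  unpert <- ma$calls$call
  flip_to <- function(call) ifelse(call == "downstream", "parallel", "downstream")
  same <- ma$calls
  to_none <- ma$calls |> dplyr::mutate(call = "none")
  flipped <- ma$calls |> dplyr::mutate(call = flip_to(call))
  rep <- robustness_report(ma, c(replicate(8, same, simplify = FALSE),
                                 replicate(1, to_none, simplify = FALSE),
                                 replicate(1, flipped, simplify = FALSE)))
  pm <- rep$per_metabolite
  # metabolites with an unperturbed "none" call are unchanged by the to_none
  # set, so their robustness is 9/10 rather than 8/10
  expected <- ifelse(pm$unperturbed_call == "none", 0.9, 0.8)
  expect_equal(pm$assignment_robustness, expected)
  binned <- rep$binned
  expect_equal(binned$total_error_rate, binned$fn_rate + binned$fp_rate,
               tolerance = 1e-12)
  # a metabolite whose unperturbed call is none: motif in perturbed = fp
  none_mets <- mets[unpert == "none"]
  if (length(none_mets) > 0) {
    # for those, the to_none set is not an error, the flip set is an fp
    expect_true(all(binned$fp_rate >= 0))
  }
  # global rates: 1 none-set (fn for motif calls) + 1 flip-set (fp)
  motif_share <- mean(unpert != "none")
  overall_fn <- sum(binned$n * binned$fn_rate) / sum(binned$n)
  expect_equal(overall_fn, 0.1 * motif_share, tolerance = 1e-12)
})

test_that("DD features are bitwise invariant under TF perturbations", {
  ma <- small_assignment()
  cache <- ma$cache
  dd_before <- cache$features$dd
  invisible(reassign_under_perturbation(ma, ma$tf_map$hub_tfs[-1]))
  expect_identical(ma$cache$features$dd, dd_before)
})

test_that("hub_tf_robustness assembles plans of the right size", {
  ma <- small_assignment()
  plan <- hub_tf_robustness(ma, remove_sizes = 1, add_sizes = 1,
                            n_samples = 5, seed = 2)
  expect_equal(plan$n_sets, c(length(ma$tf_map$hub_tfs), 5))
  expect_true(all(vapply(plan$report, inherits, TRUE, "robustness_report")))
})
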