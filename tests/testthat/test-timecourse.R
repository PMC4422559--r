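test_that("a well-formed TSV parses into the expected cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tt0_r1\tt5_r1\tt10_r1",
               "GLN\t1.0\t1.5\t2.0",
               "T6P\t1.0\t0.8\t0.5"), path)
  tc <- read_timecourse_tsv(path, "metabolite", "upshift")
  expect_s3_class(tc, "tc_matrix")
  expect_equal(nrow(tc), 6)
  expect_equal(tc_features(tc), c("GLN", "T6P"))
  expect_equal(tc_times(tc), c(0, 5, 10))
  expect_equal(tc$value[tc$feature_id == "T6P" & tc$time == 5], 0.8)
})

test_that("malformed files raise named format errors", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tt0_r1\tt5_r1\tt10_r1",
               "GLN\t1\t1\t1",
               "GLN\t2\t2\t2"), dup)
  expect_error(read_timecourse_tsv(dup, "metabolite", "upshift"), "GLN")

  bad_hdr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ttime0\tt5_r1", "GLN\t1\t1"), bad_hdr)
  expect_error(read_timecourse_tsv(bad_hdr, "metabolite", "upshift"),
               "unparseable")

  non_mono <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tt5_r1\tt0_r1", "GLN\t1\t1"), non_mono)
  expect_error(read_timecourse_tsv(non_mono, "metabolite", "upshift"),
               "non-monotone")
})

test_that("write/read round trip is the identity, including NA cells", {
  df <- tidyr::expand_grid(feature_id = c("A", "B"), time = c(0, 2.5, 10),
                           replicate = 1:2)
  df$value <- seq_len(nrow(df)) / 7
  df$value[4] <- NA
  tc <- tc_matrix(df, "metabolite", "upshift")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timecourse_tsv(tc, path)
  expect_true(any(grepl("\tNA", readLines(path))))
  back <- read_timecourse_tsv(path, "metabolite", "upshift")
  expect_equal(as.data.frame(back), as.data.frame(tc))

  # empty feature list -> header-only file, still round trips
  empty <- tc_matrix(df[0, ], "metabolite", "upshift")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_timecourse_tsv(empty, path2)
  expect_equal(nrow(read_timecourse_tsv(path2, "metabolite", "upshift")), 0)
})

test_that("parsing is invariant to data row order up to feature order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tt0_r1\tt5_r1\tt10_r1",
               "B\t1\t2\t3", "A\t4\t5\t6"), path)
  tc <- read_timecourse_tsv(path, "metabolite", "upshift")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tt0_r1\tt5_r1\tt10_r1",
               "A\t4\t5\t6", "B\t1\t2\t3"), path2)
  tc2 <- read_timecourse_tsv(path2, "metabolite", "upshift")
  a <- dplyr::arrange(as.data.frame(tc), feature_id, time, replicate)
  b <- dplyr::arrange(as.data.frame(tc2), feature_id, time, replicate)
  expect_equal(a, b)
})

test_that("GMT parsing merges duplicates and validates structure", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("TF1\tna\tg1\tg2\tg3",
               "TF2\tna\tg2\tg4",
               "TF3\tna\tg1\tg4\tg5"), path)
  map <- read_tf_targets_gmt(path)
  expect_equal(length(map$tf_ids), 3)
  expect_setequal(unique(unlist(map$targets)), paste0("g", 1:5))

  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("TF1\tna\tg1\tg2", "TF1\tna\tg2\tg3"), dup)
  expect_warning(map2 <- read_tf_targets_gmt(dup), "TF1")
  expect_setequal(map2$targets$TF1, c("g1", "g2", "g3"))

  short <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("TF1\tna\tg1", "LONESOME"), short)
  expect_error(read_tf_targets_gmt(short), "fewer than 2")
})

test_that("GMT round trip preserves the map and hub list has 11 TFs", {
  expect_length(default_hub_tfs(), 11)
  map <- tf_target_map(list(TF1 = c("g1", "g2"), TF2 = "g3"), hub_tfs = "TF1")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_tf_targets_gmt(map, path)
  back <- read_tf_targets_gmt(path)
  expect_equal(back$targets, map$targets)
  expect_error(set_hub_tfs(map, "TFX"), "not present")
})

test_that("experiment-set validation reports structural violations", {
  sim <- small_synthetic()
  es <- sim$experiment
  expect_equal(nrow(validate_experiment_set(es)), 0)

  # transcript universes differ between conditions
  es2 <- es
  tr <- as.data.frame(es2$transcripts$upshift)
  tr$feature_id[tr$feature_id == tr$feature_id[1]] <- "rogue_gene"
  es2$transcripts$upshift <- tc_matrix(tr, "transcript", "upshift")
  d2 <- validate_experiment_set(es2)
  expect_true(any(grepl("shared_transcripts_universe", d2$invariant)))

  # no hub_bypass condition
  es3 <- es
  es3$conditions$role <- c("nutrient_shift", "nutrient_shift", "nutrient_shift")
  d3 <- validate_experiment_set(es3)
  expect_true(any(grepl("hub_bypass", d3$invariant)))
})
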