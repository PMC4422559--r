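#' Experimental conditions
#'
#' A condition is a labelled perturbation with a causal role: either a
#' `nutrient_shift` (the hub responds to its natural metabolic inputs) or a
#' `hub_bypass` (chemical inhibition, e.g. rapamycin, inactivates the hub
#' directly and so decouples it from upstream metabolic signals).  The motif
#' prototypes differ between the two roles, which is what makes the upstream /
#' downstream / parallel motifs distinguishable at all.
#'
#' @param name Character vector of condition labels.
#' @param role Character vector, one of `"nutrient_shift"` or `"hub_bypass"`.
#' @return A tibble with columns `name` and `role`.
#' @examples
#' condition_set()
#' @export
condition_set <- function(name = c("upshift", "downshift", "rapamycin"),
                          role = c("nutrient_shift", "nutrient_shift", "hub_bypass")) {
  stopifnot(length(name) == length(role))
  bad <- setdiff(role, c("nutrient_shift", "hub_bypass"))
  if (length(bad) > 0) {
    abort(paste0("unknown condition role(s): ", paste(bad, collapse = ", ")))
  }
  tibble(name = as.character(name), role = as.character(role))
}

#' Construct a replicated time-course matrix
#'
#' The canonical container for one molecular layer (metabolites or
#' transcripts) in one condition: a long tibble with one row per
#' (feature, time, replicate) cell.  Time is in minutes relative to the shift;
#' time 0 is the pre-shift steady state.  Values are fold changes or
#' normalized intensities; missing cells are `NA`.
#'
#' @param data A data frame with columns `feature_id`, `time`, `replicate`,
#'   `value`.
#' @param kind `"metabolite"` or `"transcript"`.
#' @param condition Condition label (character scalar).
#' @return A `tc_matrix`: the validated long tibble with `kind` and
#'   `condition` attributes.
#' @export
tc_matrix <- function(data, kind = c("metabolite", "transcript"), condition) {
  kind <- match.arg(kind)
  stopifnot(is.character(condition), length(condition) == 1)
  data <- as_tibble(data)
  need <- c("feature_id", "time", "replicate", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("tc_matrix data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  data <- data[need]
  data$feature_id <- as.character(data$feature_id)
  data$time <- as.numeric(data$time)
  data$replicate <- as.integer(data$replicate)
  data$value <- as.numeric(data$value)
  if (any(data$time < 0)) abort("times must be non-negative (pre-shift samples map to t = 0)")

  feats <- unique(data$feature_id)
  times <- sort(unique(data$time))
  reps <- sort(unique(data$replicate))
  if (nrow(data) > 0 && !0 %in% times) {
    abort("time grid must include 0 (the pre-shift steady state)")
  }
  # every (feature, time, replicate) cell present exactly once
  if (nrow(data) != length(feats) * length(times) * length(reps)) {
    counts <- dplyr::count(data, .data$feature_id, .data$time, .data$replicate)
    dup <- counts$feature_id[counts$n > 1]
    if (length(dup) > 0) {
      abort(paste0("duplicate cells for feature id(s): ",
                   paste(unique(dup), collapse = ", ")))
    }
    abort("incomplete grid: every (feature, time, replicate) cell must be present (use NA for missing values)")
  }
  structure(
    dplyr::arrange(data, match(.data$feature_id, feats), .data$time, .data$replicate),
    kind = kind, condition = condition,
    class = c("tc_matrix", class(tibble())))
}

#' @export
print.tc_matrix <- function(x, ...) {
  cat(sprintf("<tc_matrix> %s, condition '%s': %d features x %d times x %d replicates\n",
              attr(x, "kind"), attr(x, "condition"),
              length(unique(x$feature_id)), length(unique(x$time)),
              length(unique(x$replicate))))
  NextMethod()
}

tc_kind <- function(tc) attr(tc, "kind")
tc_condition <- function(tc) attr(tc, "condition")

#' Accessors for time-course matrices
#'
#' @param tc A [tc_matrix()].
#' @return Feature ids (input order), sorted times, or sorted replicate
#'   indices.
#' @export
tc_features <- function(tc) unique(tc$feature_id)

#' @rdname tc_features
#' @export
tc_times <- function(tc) sort(unique(tc$time))

#' @rdname tc_features
#' @export
tc_replicates <- function(tc) sort(unique(tc$replicate))

# features x times x replicates array, dimnames set
tc_array <- function(tc) {
  feats <- tc_features(tc)
  times <- tc_times(tc)
  reps <- tc_replicates(tc)
  a <- array(NA_real_, dim = c(length(feats), length(times), length(reps)),
             dimnames = list(feats, times, reps))
  a[cbind(match(tc$feature_id, feats), match(tc$time, times),
          match(tc$replicate, reps))] <- tc$value
  a
}

parse_tc_headers <- function(headers) {
  m <- regmatches(headers, regexec("^t([0-9]+(?:\\.[0-9]+)?)_r([0-9]+)$", headers))
  bad <- headers[vapply(m, length, 1L) != 3L]
  if (length(bad) > 0) {
    abort(paste0("unparseable column header(s), expected 't<minutes>_r<replicate>': ",
                 paste(bad, collapse = ", ")))
  }
  tibble(
    time = vapply(m, function(x) as.numeric(x[2]), 1.0),
    replicate = vapply(m, function(x) as.integer(x[3]), 1L)
  )
}

#' Read a time-course matrix from TSV
#'
#' Expects a first column of feature ids and remaining columns named
#' `t<minutes>_r<replicate>` (minutes may be fractional), ordered by time
#' ascending then replicate ascending.  Missing cells are the literal `NA`.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams tc_matrix
#' @return A [tc_matrix()].
#' @export
read_timecourse_tsv <- function(path, kind = c("metabolite", "transcript"), condition) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    feature_id = readr::col_character()
  ), na = "NA", progress = FALSE)
  if (names(df)[1] != "feature_id") names(df)[1] <- "feature_id"
  if (ncol(df) == 1) {
    return(tc_matrix(tibble(feature_id = character(), time = numeric(),
                            replicate = integer(), value = numeric()),
                     kind = kind, condition = condition))
  }
  hdr <- parse_tc_headers(names(df)[-1])
  ord <- order(hdr$time, hdr$replicate)
  if (!identical(ord, seq_len(nrow(hdr)))) {
    abort("non-monotone time grid: columns must be ordered by time, then replicate")
  }
  dup <- df$feature_id[duplicated(df$feature_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate feature id(s): ", paste(unique(dup), collapse = ", ")))
  }
  long <- df |>
    pivot_longer(-"feature_id", names_to = "cell", values_to = "value") |>
    mutate(time = hdr$time[match(.data$cell, names(df)[-1])],
           replicate = hdr$replicate[match(.data$cell, names(df)[-1])]) |>
    select("feature_id", "time", "replicate", "value")
  tc_matrix(long, kind = kind, condition = condition)
}

#' Write a time-course matrix to TSV
#'
#' Inverse of [read_timecourse_tsv()]: feature ids in input order, columns by
#' time ascending then replicate ascending, missing cells written as `NA`.
#'
#' @param tc A [tc_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_tsv <- function(tc, path) {
  stopifnot(inherits(tc, "tc_matrix"))
  wide <- tc |>
    mutate(cell = sprintf("t%s_r%d", as.character(.data$time), .data$replicate)) |>
    select("feature_id", "cell", "value") |>
    pivot_wider(names_from = "cell", values_from = "value")
  # enforce deterministic column order: time asc, replicate asc
  hdr <- parse_tc_headers(names(wide)[-1])
  wide <- wide[c(1L, 1L + order(hdr$time, hdr$replicate))]
  readr::write_tsv(wide, path, na = "NA", progress = FALSE)
  invisible(path)
}
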