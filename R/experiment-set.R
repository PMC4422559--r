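#' Bundle a multi-condition experiment
#'
#' An experiment set holds, for every condition, one metabolite and one
#' transcript time-course matrix, plus the TF-target prior.  All conditions
#' must share the same metabolite and transcript id universes.
#'
#' @param metabolites Named list of metabolite [tc_matrix()] objects, one per
#'   condition name.
#' @param transcripts Named list of transcript [tc_matrix()] objects, same
#'   names.
#' @param tf_map A [tf_target_map()].
#' @param conditions A [condition_set()] tibble; defaults to the standard
#'   upshift / downshift / rapamycin design.
#' @return An `experiment_set` object.
#' @export
experiment_set <- function(metabolites, transcripts, tf_map,
                           conditions = condition_set()) {
  stopifnot(is.list(metabolites), is.list(transcripts),
            inherits(tf_map, "tf_target_map"))
  structure(list(metabolites = metabolites, transcripts = transcripts,
                 tf_map = tf_map, conditions = as_tibble(conditions)),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("<experiment_set> %d conditions (%s)\n",
              nrow(x$conditions),
              paste(x$conditions$name, collapse = ", ")))
  nm <- tryCatch(length(tc_features(x$metabolites[[1]])), error = function(e) NA)
  ng <- tryCatch(length(tc_features(x$transcripts[[1]])), error = function(e) NA)
  cat(sprintf("  %s metabolites, %s transcripts; %d TFs (%d hub)\n",
              nm, ng, length(x$tf_map$tf_ids), length(x$tf_map$hub_tfs)))
  invisible(x)
}

#' Validate an experiment set
#'
#' Checks the structural invariants and returns diagnostics rather than
#' raising: an empty tibble means the set is valid.
#'
#' @param es An [experiment_set()].
#' @return A tibble with columns `invariant` and `detail`, one row per
#'   violation.
#' @export
validate_experiment_set <- function(es) {
  d <- list()
  add <- function(invariant, detail) {
    d[[length(d) + 1]] <<- tibble(invariant = invariant, detail = detail)
  }
  cond_names <- es$conditions$name
  if (sum(es$conditions$role == "hub_bypass") != 1) {
    add("one_hub_bypass_condition",
        paste0("found ", sum(es$conditions$role == "hub_bypass"),
               " hub_bypass conditions, need exactly 1"))
  }
  if (!any(es$conditions$role == "nutrient_shift")) {
    add("at_least_one_nutrient_shift", "no condition has role nutrient_shift")
  }
  for (layer in c("metabolites", "transcripts")) {
    missing <- setdiff(cond_names, names(es[[layer]]))
    if (length(missing) > 0) {
      add(paste0(layer, "_present_per_condition"),
          paste0("missing for condition(s): ", paste(missing, collapse = ", ")))
    }
  }
  have <- intersect(cond_names, intersect(names(es$metabolites), names(es$transcripts)))
  if (length(have) >= 2) {
    ref <- have[1]
    for (layer in c("metabolites", "transcripts")) {
      ref_ids <- tc_features(es[[layer]][[ref]])
      for (cn in have[-1]) {
        ids <- tc_features(es[[layer]][[cn]])
        if (!setequal(ids, ref_ids)) {
          off <- c(setdiff(ids, ref_ids), setdiff(ref_ids, ids))
          add(paste0("shared_", layer, "_universe"),
              paste0("conditions '", ref, "' and '", cn, "' differ: ",
                     paste(head(off, 5), collapse = ", ")))
        }
      }
    }
  }
  if (length(have) >= 1) {
    g <- length(tc_features(es$transcripts[[have[1]]]))
    if (g < 10) add("transcript_universe_size", paste0("G = ", g, " < 10"))
  }
  if (length(es$tf_map$hub_tfs) < 1) {
    add("hub_tfs_nonempty", "no hub-controlled TFs designated")
  }
  if (length(d) == 0) {
    tibble(invariant = character(), detail = character())
  } else {
    list_rbind(d)
  }
}

es_condition_names <- function(es) es$conditions$name

es_bypass_condition <- function(es) {
  es$conditions$name[es$conditions$role == "hub_bypass"][1]
}

es_nutrient_conditions <- function(es) {
  es$conditions$name[es$conditions$role == "nutrient_shift"]
}
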