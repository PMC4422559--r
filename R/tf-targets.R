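#' Default hub-controlled transcription factors
#'
#' The eleven yeast transcription factors documented as direct targets of
#' TORC1, used as the default hub-TF prior for the "representation of hub
#' genes" feature.
#'
#' @return Character vector of length 11.
#' @export
default_hub_tfs <- function() {
  c("Gcn4", "Rtg1", "Rtg3", "Gln3", "Sfp1", "Fhl1",
    "Ifh1", "Msn2", "Msn4", "Gis1", "Sko1")
}

#' Construct a TF-to-target map
#'
#' @param targets Named list: one character vector of target gene ids per TF.
#' @param hub_tfs Character vector of TF names designated hub-controlled
#'   (must be a subset of `names(targets)` when non-empty).
#' @return A `tf_target_map` object: list with elements `tf_ids`, `targets`
#'   (deduplicated), `hub_tfs`.
#' @export
tf_target_map <- function(targets, hub_tfs = character()) {
  stopifnot(is.list(targets), !is.null(names(targets)))
  targets <- lapply(targets, function(g) unique(as.character(g)))
  tf_ids <- names(targets)
  bad <- setdiff(hub_tfs, tf_ids)
  if (length(bad) > 0) {
    abort(paste0("hub TF(s) not present in the map: ", paste(bad, collapse = ", ")))
  }
  structure(list(tf_ids = tf_ids, targets = targets,
                 hub_tfs = as.character(hub_tfs)),
            class = "tf_target_map")
}

#' @export
print.tf_target_map <- function(x, ...) {
  cat(sprintf("<tf_target_map> %d TFs (%d hub-controlled), %d distinct target genes\n",
              length(x$tf_ids), length(x$hub_tfs),
              length(unique(unlist(x$targets)))))
  invisible(x)
}

#' Set the hub-controlled TFs on a map
#'
#' Hub membership lives in run configuration, not in the GMT file, so the
#' same gene-set file can serve perturbed analyses.
#'
#' @param map A [tf_target_map()].
#' @param hub_tfs Character vector of TF names.
#' @return The map with `hub_tfs` replaced.
#' @export
set_hub_tfs <- function(map, hub_tfs) {
  tf_target_map(map$targets, hub_tfs = hub_tfs)
}

# union of target sets of the hub TFs
hub_target_union <- function(map) {
  unique(unlist(map$targets[map$hub_tfs], use.names = FALSE))
}

#' Read TF target sets from a GMT file
#'
#' One line per TF: name, description, then tab-separated target gene ids
#' (Broad gene-set format).  A TF listed twice has its target sets merged
#' with a warning.  Hub TFs are initially empty; set them with
#' [set_hub_tfs()].
#'
#' @param path Path to a GMT file.
#' @return A [tf_target_map()].
#' @export
read_tf_targets_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 2L
  if (any(short)) {
    abort(paste0("GMT line(s) with fewer than 2 fields: line ",
                 paste(which(short), collapse = ", ")))
  }
  tfs <- vapply(fields, `[[`, "", 1L)
  gene_lists <- lapply(fields, function(f) if (length(f) > 2) f[-(1:2)] else character())
  if (anyDuplicated(tfs)) {
    warn(paste0("TF(s) listed more than once, targets merged: ",
                paste(unique(tfs[duplicated(tfs)]), collapse = ", ")))
  }
  targets <- tapply(gene_lists, tfs, function(gl) unique(unlist(gl)), simplify = FALSE)
  targets <- targets[unique(tfs)] # preserve first-appearance order
  tf_target_map(as.list(targets))
}

#' Write TF target sets to a GMT file
#'
#' @param map A [tf_target_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tf_targets_gmt <- function(map, path) {
  lines <- vapply(map$tf_ids, function(tf) {
    paste(c(tf, "na", map$targets[[tf]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
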