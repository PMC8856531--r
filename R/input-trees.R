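#' Assemble an input-tree collection
#'
#' An input-tree collection is a tibble with one row per published tree and
#' columns `tree_id`, `study_id`, `year`, `data_types` (list of character
#' tags such as `"COI"` or `"morphology"`), `n_taxa`, `weight_num` /
#' `weight_den` (the analysis weight as an exact rational, default 1), and
#' `tree` (list of `ape::phylo`).  All curation, encoding and support
#' functions consume and return this shape.
#'
#' @param trees list of `ape::phylo` trees.
#' @param tree_id,study_id character vectors (recycled if length 1).
#' @param year integer publication years.
#' @param data_types list of character vectors (or a single character vector
#'   recycled), one set of data-type tags per tree.
#' @return a tibble of class `input_tree_set`.
#' @export
input_tree_set <- function(trees, tree_id = NULL, study_id = NULL,
                           year = NA_integer_, data_types = list(character(0))) {
  stopifnot(is.list(trees), all(vapply(trees, inherits, TRUE, "phylo")))
  n <- length(trees)
  tree_id <- tree_id %||% sprintf("tree%02d", seq_len(n))
  study_id <- study_id %||% sprintf("S%03d", seq_len(n))
  if (length(study_id) == 1L) study_id <- rep(study_id, n)
  if (length(year) == 1L) year <- rep(year, n)
  if (!is.list(data_types)) data_types <- list(data_types)
  if (length(data_types) == 1L) data_types <- rep(data_types, n)
  if (anyDuplicated(paste(study_id, tree_id)))
    stop("(study_id, tree_id) pairs must be unique")
  out <- tibble::tibble(
    tree_id = as.character(tree_id),
    study_id = as.character(study_id),
    year = as.integer(year),
    data_types = data_types,
    n_taxa = vapply(trees, function(t) length(t$tip.label), 0L),
    weight_num = 1L,
    weight_den = 1L,
    tree = trees
  )
  class(out) <- c("input_tree_set", class(out))
  out
}

#' @export
print.input_tree_set <- function(x, ...) {
  cat(sprintf("Input-tree collection: %d trees, %d taxa\n",
              nrow(x), length(all_taxa(x))))
  NextMethod()
}

#' Union of taxon labels over an input-tree collection
#' @param trees an `input_tree_set` tibble.
#' @return sorted character vector of taxon labels.
#' @export
all_taxa <- function(trees) {
  sort(unique(unlist(lapply(trees$tree, function(t) t$tip.label))))
}

#' Weights of an input-tree collection as numerics
#' @param trees an `input_tree_set` tibble.
#' @return numeric vector of weights (`weight_num / weight_den`).
#' @export
tree_weights <- function(trees) trees$weight_num / trees$weight_den

#' Write an input-tree bundle to disk
#'
#' The bundle layout (consumed by [read_tree_bundle()] and
#' [run_pipeline()]): `trees/<tree_id>.nwk`, a `metadata.csv` table
#' (tree_id, study_id, year, data_type, n_taxa; tags joined with `;`)
#' and optionally `model.nwk` with the generating tree.
#'
#' @param trees an `input_tree_set` tibble.
#' @param dir output directory (created if missing).
#' @param model optional `ape::phylo` model tree to include.
#' @return `dir`, invisibly.
#' @export
write_tree_bundle <- function(trees, dir, model = NULL) {
  dir.create(file.path(dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(trees)))
    write_newick(trees$tree[[i]],
                 file.path(dir, "trees", paste0(trees$tree_id[i], ".nwk")))
  meta <- tibble::tibble(
    tree_id = trees$tree_id,
    study_id = trees$study_id,
    year = trees$year,
    data_type = vapply(trees$data_types, paste, "", collapse = ";"),
    n_taxa = trees$n_taxa
  )
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  if (!is.null(model)) write_newick(model, file.path(dir, "model.nwk"))
  invisible(dir)
}

#' Read an input-tree bundle from disk
#'
#' @param dir directory written by [write_tree_bundle()] (or laid out the
#'   same way by hand).
#' @return an `input_tree_set` tibble; if `model.nwk` is present the model
#'   tree is attached as attribute `"model"`.
#' @export
read_tree_bundle <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  trees <- lapply(meta$tree_id, function(id) {
    read_newick(file.path(dir, "trees", paste0(id, ".nwk")))[[1]]
  })
  out <- input_tree_set(trees,
                        tree_id = meta$tree_id,
                        study_id = meta$study_id,
                        year = meta$year,
                        data_types = strsplit(meta$data_type, ";", fixed = TRUE))
  model_path <- file.path(dir, "model.nwk")
  if (file.exists(model_path))
    attr(out, "model") <- read_newick(model_path)[[1]]
  out
}
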