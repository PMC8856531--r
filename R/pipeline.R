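#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end supertree analysis.  The
#' configuration round-trips through YAML unchanged
#' ([save_config()] / [load_config()]).
#'
#' @param input directory containing an input-tree bundle
#'   (see [read_tree_bundle()]); may be `NULL` when trees are passed to
#'   [run_pipeline()] directly.
#' @param output directory for stage artifacts.
#' @param overlap_max maximum tolerated taxon-overlap fraction between
#'   same-data trees (fixed at 0.5 by the curation protocol; exposed for
#'   transparency).
#' @param min_trees,min_cells representation-filter thresholds, see
#'   [representation_filter()].
#' @param n_reps,swap,max_trees,seed search settings, see
#'   [search_config()].
#' @param consensus_threshold majority-rule threshold.
#' @param partitions `NULL` or a named list of taxon vectors
#'   (innermost first), see [partition_spec()].
#' @param rename_table `NULL` or path to a CSV with columns `from`,`to`
#'   applied to taxon labels at ingestion (cross-study synonymy).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output = NULL,
                            overlap_max = 0.5, min_trees = 2, min_cells = 2,
                            n_reps = 1000, swap = "TBR", max_trees = 10000,
                            seed = NULL, consensus_threshold = 0.5,
                            partitions = NULL, rename_table = NULL) {
  stopifnot(overlap_max > 0, overlap_max <= 1, min_trees >= 1, min_cells >= 1,
            consensus_threshold >= 0.5, consensus_threshold < 1)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message(sprintf("pipeline_config: no seed supplied, drew seed = %d", seed))
  }
  structure(list(input = input, output = output, overlap_max = overlap_max,
                 min_trees = as.integer(min_trees),
                 min_cells = as.integer(min_cells),
                 n_reps = as.integer(n_reps), swap = swap,
                 max_trees = as.integer(max_trees), seed = as.integer(seed),
                 consensus_threshold = consensus_threshold,
                 partitions = partitions, rename_table = rename_table),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

apply_rename_table <- function(trees, path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(tab)))
  from <- normalize_taxon_labels(tab$from)
  to <- normalize_taxon_labels(tab$to)
  for (i in seq_len(nrow(trees))) {
    t <- trees$tree[[i]]
    hit <- match(t$tip.label, from)
    t$tip.label[!is.na(hit)] <- to[hit[!is.na(hit)]]
    if (anyDuplicated(t$tip.label))
      stop(sprintf("rename table creates duplicate labels in tree %s",
                   trees$tree_id[i]))
    trees$tree[[i]] <- t
  }
  trees
}

#' Run the full supertree pipeline
#'
#' Curation (pseudoreplication resolution, singleton removal,
#' connectivity check), MRP encoding with the representation filter
#' applied to a fixed point, heuristic parsimony search (partitioned if
#' partitions are configured), strict and majority-rule consensus, V/V+
#' support scoring, and collapse of novel clades.  When an output
#' directory is configured, every stage artifact is written together
#' with a manifest (seed, stage counts, warnings, and an MD5 hash of
#' every output file) that makes reruns byte-verifiable.
#'
#' @param config a [pipeline_config()].
#' @param trees optionally, an `input_tree_set` tibble (otherwise read
#'   from `config$input`).
#' @return (invisibly) a list: curated trees, curation report, matrix,
#'   fill statistics, search/partition results, consensus trees, support
#'   table, and `final_supertree` (novel clades collapsed).
#' @export
run_pipeline <- function(config, trees = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  note_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  if (is.null(trees)) {
    if (is.null(config$input)) stop("run_pipeline: no input trees (stage: ingest)")
    trees <- read_tree_bundle(config$input)
  }
  if (!is.null(config$rename_table))
    trees <- apply_rename_table(trees, config$rename_table)

  # --- curation ---
  cur <- withCallingHandlers(curate(trees), warning = note_warning)

  # --- encoding + representation filter to a fixed point ---
  curated <- cur$trees
  removed_underrep <- character(0)
  repeat {
    if (nrow(curated) == 0L) stop("no trees retained after curation (stage: curation)")
    m <- encode_matrix(curated)
    fs <- withCallingHandlers(matrix_fill_stats(m), warning = note_warning)
    drop_taxa <- representation_filter(fs, config$min_trees, config$min_cells)
    if (length(drop_taxa) == 0L) break
    removed_underrep <- c(removed_underrep, drop_taxa)
    keep <- rep(TRUE, nrow(curated))
    for (i in seq_len(nrow(curated))) {
      t <- prune_to(curated$tree[[i]],
                    setdiff(curated$tree[[i]]$tip.label, drop_taxa))
      if (is.null(t) || length(t$tip.label) < 3L) keep[i] <- FALSE
      else {
        curated$tree[[i]] <- t
        curated$n_taxa[i] <- length(t$tip.label)
      }
    }
    curated <- curated[keep, , drop = FALSE]
  }
  if (length(removed_underrep) > 0)
    cur$report$taxa <- dplyr::bind_rows(cur$report$taxa,
      tibble::tibble(taxon = removed_underrep, reason = "under_represented"))

  # --- search + consensus (+ partitions) ---
  scfg <- search_config(n_reps = config$n_reps, swap = config$swap,
                        seed = config$seed, max_trees = config$max_trees)
  if (!is.null(config$partitions)) {
    spec <- do.call(partition_spec, config$partitions)
    part <- withCallingHandlers(
      run_partitioned(curated, spec, scfg,
                      consensus_threshold = config$consensus_threshold),
      warning = note_warning)
    supertree <- part$supertree
    search <- lapply(part$partitions, `[[`, "search")
    strict <- lapply(part$partitions, `[[`, "strict")
    majority <- lapply(part$partitions, `[[`, "majority")
  } else {
    part <- NULL
    m_final <- encode_matrix(curated)
    search <- heuristic_search(m_final, scfg)
    strict <- strict_consensus(search)
    majority <- majority_consensus(search, config$consensus_threshold)
    supertree <- majority$tree
  }

  # --- support + collapse of novel clades ---
  support <- score_supertree(supertree, curated)
  if (!is.null(config$partitions)) {
    # constrained partition clades get no V score
    constrained <- lapply(config$partitions, function(s)
      sort(intersect(s, supertree$tip.label)))
    ckeys <- vapply(constrained, cluster_key, "")
    skeys <- vapply(support$clade, cluster_key, "")
    support$V[skeys %in% ckeys] <- NA_real_
    support$V_plus[skeys %in% ckeys] <- NA_real_
    support$novel[skeys %in% ckeys] <- FALSE
  }
  final <- collapse_novel(supertree, support)

  search_list <- if (inherits(search, "search_result")) list(search) else search
  if (any(vapply(search_list, function(s) isTRUE(s$hit_max_trees), TRUE)))
    warnings_log <- c(warnings_log, "max_trees cap reached during search")

  result <- list(trees = curated, curation_report = cur$report,
                 components = cur$components,
                 fill_stats = fs, search = search,
                 strict = strict, majority = majority,
                 support = support, supertree = supertree,
                 final_supertree = final, warnings = warnings_log,
                 seed = config$seed)

  if (!is.null(config$output))
    write_pipeline_artifacts(result, config, m_latest = m)
  invisible(result)
}

write_pipeline_artifacts <- function(result, config, m_latest) {
  out <- config$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(name) { files <<- c(files, file.path(out, name)); file.path(out, name) }

  rep_df <- result$curation_report$trees
  utils::write.csv(rep_df, p("curation_trees.csv"), row.names = FALSE)
  utils::write.csv(result$curation_report$taxa, p("curation_taxa.csv"),
                   row.names = FALSE)
  write_nexus(m_latest, p("matrix.nex"), constraints = config$partitions)
  write_matrix_csv(m_latest, p("matrix.csv"))
  if (inherits(result$search, "search_result")) {
    writeLines(vapply(result$search$trees, write_newick, ""), p("mpts.nwk"))
    write_consensus(result$strict, p("strict.nwk"))
    write_consensus(result$majority, p("majority.nwk"), annotate = TRUE)
  } else {
    for (nm in names(result$search)) {
      writeLines(vapply(result$search[[nm]]$trees, write_newick, ""),
                 p(sprintf("mpts_%s.nwk", nm)))
      write_consensus(result$strict[[nm]], p(sprintf("strict_%s.nwk", nm)))
      write_consensus(result$majority[[nm]], p(sprintf("majority_%s.nwk", nm)),
                      annotate = TRUE)
    }
  }
  write_support_csv(result$support, p("support.csv"))
  write_newick(result$supertree, p("supertree.nwk"))
  write_newick(result$final_supertree, p("final_supertree.nwk"))

  manifest <- list(
    seed = config$seed,
    n_trees_retained = nrow(result$trees),
    n_taxa = length(all_taxa(result$trees)),
    n_characters = ncol(m_latest$matrix),
    n_components = length(result$components),
    warnings = as.list(result$warnings),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f)))
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yml"))
  invisible(out)
}

#' Taxon-coverage report
#'
#' Turns counts of taxa (per taxonomic rank) into the percentage of the
#' regional fauna represented in a supertree, rounding half-up to whole
#' percent.
#'
#' @param counts a data frame with columns `rank`, `numerator`
#'   (taxa represented) and `denominator` (taxa in the region); extra
#'   columns are preserved.
#' @return a tibble with an added integer `percent` column.
#' @examples
#' coverage_report(data.frame(rank = "Genus", numerator = 114,
#'                            denominator = 325))
#' @export
coverage_report <- function(counts) {
  stopifnot(all(c("rank", "numerator", "denominator") %in% names(counts)))
  if (any(counts$denominator == 0)) stop("zero denominator in coverage counts")
  if (any(counts$numerator > counts$denominator))
    stop("represented taxa exceed the regional total")
  if (any(counts$numerator < 0 | counts$denominator < 0))
    stop("coverage counts must be non-negative")
  out <- tibble::as_tibble(counts)
  out$percent <- as.integer(floor(100 * out$numerator / out$denominator + 0.5))
  out
}
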