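#' Baum-Ragan matrix representation of an input-tree collection
#'
#' Each internal node (except the root) of each input tree becomes one
#' binary character: taxa inside the clade are coded 1, taxa present in
#' that tree but outside the clade 0, and taxa absent from the tree `?`
#' (missing).  A synthetic all-zero outgroup row `MRP_OUTGROUP` roots the
#' parsimony analysis (clade-based coding is only meaningful on rooted
#' trees); it is stripped from all reported trees.  Character weights are
#' copied from the source tree's curation weight and carried as exact
#' rationals.
#'
#' @param trees an `input_tree_set` tibble (curated).
#' @param taxa optional ordered character vector of taxa; defaults to the
#'   sorted union of the trees' leaves.
#' @return an object of class `mrp_matrix`: a list with `matrix`
#'   (character matrix taxa x characters with entries `"0"`, `"1"`, `"?"`),
#'   `char_tree_id`, `char_cluster`, `weight_num`, `weight_den`.
#' @export
encode_matrix <- function(trees, taxa = NULL) {
  taxa <- taxa %||% all_taxa(trees)
  if ("MRP_OUTGROUP" %in% taxa)
    stop("'MRP_OUTGROUP' is a reserved taxon label")
  rows <- c(taxa, "MRP_OUTGROUP")
  cols <- list()
  char_tree <- character(0)
  char_cluster <- list()
  wnum <- integer(0)
  wden <- integer(0)
  for (i in seq_len(nrow(trees))) {
    t <- trees$tree[[i]]
    leaves <- t$tip.label
    for (cl in tree_clusters(t)) {
      col <- rep("?", length(rows))
      names(col) <- rows
      col[leaves] <- "0"
      col[cl] <- "1"
      col["MRP_OUTGROUP"] <- "0"
      cols[[length(cols) + 1L]] <- col
      char_tree <- c(char_tree, trees$tree_id[i])
      char_cluster[[length(char_cluster) + 1L]] <- cl
      wnum <- c(wnum, trees$weight_num[i])
      wden <- c(wden, trees$weight_den[i])
    }
  }
  if (length(cols) == 0L)
    stop(paste0("no characters could be encoded: every input tree is an ",
                "unresolved star, so no supertree resolution is possible"))
  m <- do.call(cbind, cols)
  dimnames(m) <- list(rows, sprintf("c%04d", seq_along(cols)))
  structure(list(matrix = m, char_tree_id = char_tree,
                 char_cluster = char_cluster,
                 weight_num = wnum, weight_den = wden),
            class = "mrp_matrix")
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat(sprintf("MRP matrix: %d taxa (incl. outgroup) x %d characters from %d trees\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$char_tree_id))))
  fr <- mean(x$matrix == "?")
  cat(sprintf("missing cells: %.1f%%\n", 100 * fr))
  invisible(x)
}

# scaled integer weights with the common denominator (LCM of denominators)
scaled_weights <- function(m) {
  L <- lcm_all(unique(m$weight_den))
  list(weights = as.numeric(m$weight_num) * (L / as.numeric(m$weight_den)),
       denom = L)
}

#' Missing-data statistics of an MRP matrix
#'
#' Reports the overall fraction of `?` cells and, per taxon, the number of
#' non-missing cells and of source trees.  Feeds
#' [representation_filter()].  Very sparse matrices (default: more than
#' 90% missing) trigger a warning, since heuristic parsimony searches can
#' stall on such data.
#'
#' @param m an `mrp_matrix`.
#' @param warn_threshold overall missing fraction above which to warn.
#' @return list with `overall_missing` (fraction) and `per_taxon`
#'   (tibble: taxon, n_nonmissing, n_missing, n_trees).
#' @export
matrix_fill_stats <- function(m, warn_threshold = 0.9) {
  mm <- m$matrix
  miss <- mm == "?"
  per_tree <- split(seq_len(ncol(mm)), m$char_tree_id)
  n_trees <- vapply(rownames(mm), function(tx) {
    sum(vapply(per_tree, function(cols) any(!miss[tx, cols]), TRUE))
  }, 0L)
  out <- list(
    overall_missing = mean(miss),
    per_taxon = tibble::tibble(
      taxon = rownames(mm),
      n_nonmissing = as.integer(rowSums(!miss)),
      n_missing = as.integer(rowSums(miss)),
      n_trees = as.integer(n_trees)
    )
  )
  if (out$overall_missing > warn_threshold)
    warning(sprintf("MRP matrix is %.1f%% missing data; the parsimony search may struggle",
                    100 * out$overall_missing))
  out
}

# quote NEXUS labels that contain characters outside the safe set
nexus_label <- function(x) {
  bad <- grepl("[^A-Za-z0-9_.]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Write an MRP matrix as a NEXUS file
#'
#' Emits a DATA block (symbols 0/1, missing `?`), an ASSUMPTIONS block
#' with a weight set, and optionally PAUP-dialect monophyly constraint
#' commands, so the matrix can be analysed in PAUP* as well as with
#' [heuristic_search()].  Rational weights are scaled by the least common
#' multiple of their denominators to integers, preserving relative
#' weights exactly.  Output is byte-stable for a fixed matrix.
#'
#' @param m an `mrp_matrix`.
#' @param file output path.
#' @param constraints optional named list of character vectors (taxon
#'   sets to hold monophyletic).
#' @return `file`, invisibly.
#' @export
write_nexus <- function(m, file, constraints = NULL) {
  mm <- m$matrix
  sw <- scaled_weights(m)
  labs <- nexus_label(rownames(mm))
  if (any(labs != rownames(mm)))
    message("write_nexus: quoted taxon labels containing special characters")
  pad <- max(nchar(labs))
  lines <- c(
    "#NEXUS",
    "",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(mm), ncol(mm)),
    "  FORMAT SYMBOLS=\"01\" MISSING=?;",
    "  MATRIX"
  )
  for (i in seq_len(nrow(mm)))
    lines <- c(lines, sprintf("    %-*s %s", pad, labs[i],
                              paste(mm[i, ], collapse = "")))
  lines <- c(lines, "  ;", "END;", "", "BEGIN ASSUMPTIONS;",
             sprintf("  WTSET * mrp_weights = %s;",
                     paste(sprintf("%d: %d", as.integer(sw$weights),
                                   seq_len(ncol(mm))), collapse = ", ")),
             "END;")
  if (!is.null(constraints) && length(constraints) > 0) {
    nm <- names(constraints) %||% sprintf("clade%d", seq_along(constraints))
    cl <- vapply(seq_along(constraints), function(i) {
      sprintf("  CONSTRAINTS %s (MONOPHYLY) = ((%s));", nm[i],
              paste(nexus_label(constraints[[i]]), collapse = ","))
    }, "")
    lines <- c(lines, "", "BEGIN PAUP;", cl, "END;")
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read back a NEXUS MRP matrix
#'
#' Minimal reader for the dialect written by [write_nexus()], used for
#' round-trip verification.  Weights are recovered from the weight set;
#' character provenance (source tree, cluster) is not stored in NEXUS and
#' is left empty.
#'
#' @param file path to a NEXUS file written by [write_nexus()].
#' @return an `mrp_matrix` (with empty provenance fields).
#' @export
read_nexus <- function(file) {
  lines <- readLines(file, warn = FALSE)
  i0 <- grep("^\\s*MATRIX\\s*$", lines)[1]
  i1 <- grep("^\\s*;\\s*$", lines)
  i1 <- i1[i1 > i0][1]
  rows <- trimws(lines[(i0 + 1):(i1 - 1)])
  rows <- rows[nzchar(rows)]
  parts <- regmatches(rows, regexec("^('[^']*'|\\S+)\\s+(\\S+)$", rows))
  labs <- gsub("^'|'$", "", vapply(parts, `[`, "", 2))
  dat <- vapply(parts, `[`, "", 3)
  mm <- do.call(rbind, strsplit(dat, ""))
  dimnames(mm) <- list(labs, sprintf("c%04d", seq_len(ncol(mm))))
  wline <- grep("WTSET", lines, value = TRUE)
  wnum <- rep(1L, ncol(mm))
  if (length(wline) == 1) {
    spec <- sub(";\\s*$", "", sub(".*=", "", wline))
    for (term in strsplit(spec, ",")[[1]]) {
      kv <- as.integer(strsplit(trimws(term), ":")[[1]])
      wnum[kv[2]] <- kv[1]
    }
  }
  structure(list(matrix = mm, char_tree_id = rep(NA_character_, ncol(mm)),
                 char_cluster = vector("list", ncol(mm)),
                 weight_num = wnum, weight_den = rep(1L, ncol(mm))),
            class = "mrp_matrix")
}

#' Tidy an MRP matrix into a long tibble
#'
#' @param x an `mrp_matrix`.
#' @param ... unused.
#' @return tibble with columns taxon, character, state, tree_id, weight.
#' @method tidy mrp_matrix
#' @export
tidy.mrp_matrix <- function(x, ...) {
  mm <- x$matrix
  tibble::tibble(
    taxon = rep(rownames(mm), times = ncol(mm)),
    character = rep(colnames(mm), each = nrow(mm)),
    state = as.vector(mm),
    tree_id = rep(x$char_tree_id, each = nrow(mm)),
    weight = rep(x$weight_num / x$weight_den, each = nrow(mm))
  )
}

#' Export an MRP matrix as CSV for inspection
#'
#' @param m an `mrp_matrix`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_matrix_csv <- function(m, file) {
  df <- as.data.frame(m$matrix)
  df <- cbind(taxon = rownames(m$matrix), df)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
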