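# Run artefacts: NEXUS tree trace (translate-block dialect), tab-separated
# parameter log, JSON run manifest.

#' Write a NEXUS tree trace
#'
#' Writes the retained trees of a trace as a NEXUS trees block with a
#' translate table and one numbered tree per sample (`tree STATE_<gen>`), the
#' dialect emitted by mainstream Bayesian phylogenetics software, so external
#' summarisation tools can consume the trace.
#'
#' @param trace An `hp_trace`.
#' @param path Destination path (conventionally `.t`).
#' @return The path, invisibly.
#' @export
write_tree_trace <- function(trace, path) {
  stopifnot(inherits(trace, "hp_trace"))
  labels <- trace$labels
  n <- length(labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines(c("begin trees;", "   translate"), con)
  tr_lines <- paste0("      ", seq_len(n), " ", labels,
                     ifelse(seq_len(n) < n, ",", ";"))
  writeLines(tr_lines, con)
  idx_labels <- as.character(seq_len(n))
  for (k in seq_along(trace$trees)) {
    tr <- .build_phylo(trace$trees[[k]]$edge, trace$trees[[k]]$len, idx_labels)
    writeLines(paste0("   tree STATE_", trace$samples$generation[k],
                      " = [&U] ", .newick_string(tr)), con)
  }
  writeLines("end;", con)
  invisible(path)
}

#' Write a tab-separated parameter log
#'
#' Columns: generation, unnormalised log joint, total tree length.
#'
#' @param trace An `hp_trace`.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_param_log <- function(trace, path) {
  stopifnot(inherits(trace, "hp_trace"))
  df <- as.data.frame(trace$samples)
  df$log_joint <- formatC(df$log_joint, digits = 10, format = "g")
  df$tree_length <- formatC(df$tree_length, digits = 10, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to re-run a sampling job bit-identically: the
#' full configuration (including the seed), input digests, package version and
#' timing.
#'
#' @param trace An `hp_trace`.
#' @param path Destination path.
#' @param inputs Named character vector of input file paths to digest
#'   (optional).
#' @param elapsed Elapsed seconds (optional).
#' @return The path, invisibly.
#' @export
write_manifest <- function(trace, path, inputs = NULL, elapsed = NA_real_) {
  stopifnot(inherits(trace, "hp_trace"))
  cfg <- trace$config
  cfg$prior <- unclass(cfg$prior)
  manifest <- list(
    package = "hyperphylo",
    version = as.character(utils::packageVersion("hyperphylo")),
    config = unclass(cfg),
    n_taxa = length(trace$labels),
    taxa = trace$labels,
    retained_samples = nrow(trace$samples),
    elapsed_seconds = elapsed,
    topology_distance = "robinson_foulds"
  )
  if (!is.null(inputs)) {
    manifest$inputs <- lapply(inputs, function(p) {
      list(path = p, size = file.size(p),
           digest = as.numeric(sum(utf8ToInt(paste(readLines(p, warn = FALSE),
                                                   collapse = "\n")))))
    })
  }
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and write square distance matrices
#'
#' Plain-text square matrices with a header row (and first column) of taxon
#' labels; the separator defaults on the file extension (`.csv` = comma,
#' otherwise tab).
#'
#' @param path File path.
#' @param D Symmetric distance matrix with dimnames.
#' @param sep Field separator; `NULL` picks by extension.
#' @return `read_distance_matrix` returns a symmetric named matrix;
#'   `write_distance_matrix` returns the path, invisibly.
#' @export
read_distance_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  D <- as.matrix(df)
  if (nrow(D) != ncol(D)) stop("read_distance_matrix: matrix is not square")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("read_distance_matrix: matrix is not symmetric")
  }
  dimnames(D) <- list(rownames(df), colnames(df))
  D
}

#' @rdname read_distance_matrix
#' @export
write_distance_matrix <- function(D, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  D <- as.matrix(D)
  if (is.null(rownames(D))) {
    dimnames(D) <- rep(list(paste0("t", seq_len(nrow(D)))), 2)
  }
  utils::write.table(D, path, sep = sep, quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Write a diagnostics grid as TSV, or a summary list as JSON
#'
#' Companions for [landscape_scan()] / [neighborhood_sample()] outputs (TSV
#' with the lattice coordinates in columns) and for summary objects such as
#' [tree_length_summary()] or [glance()] rows (JSON).
#'
#' @param grid A data frame (e.g. a scan tibble).
#' @param x A list or one-row data frame of summary values.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
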