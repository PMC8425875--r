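#' Read metabolite-protein interaction edges from TSV
#'
#' Reads a tab-separated edge list with header columns `metabolite_id`,
#' `protein_id` and `role` (one of `substrate`, `product`, `both`). Every row
#' becomes one edge tagged with `source_tag` as its provenance. Malformed rows
#' are reported with their line numbers.
#'
#' @param path Path to a TSV file.
#' @param source_tag Character scalar naming the source database for all rows.
#' @return A data frame of class `mpi_edges` with columns `metabolite_id`,
#'   `protein_id`, `role`, `sources`.
#' @export
read_mpi_edges <- function(path, source_tag) {
  if (!is.character(source_tag) || length(source_tag) != 1L || !nzchar(source_tag))
    stop_mpinet("source_tag must be a non-empty string",
                class = "mpinet_parameter_error")
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "protein_id", "role")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop_mpinet("MPI edge file ", path, " is missing required column(s): ",
                paste(missing_cols, collapse = ", "),
                class = "mpinet_format_error")
  if (nrow(df) > 0) {
    bad_role <- which(!df$role %in% c("substrate", "product", "both"))
    if (length(bad_role) > 0) {
      # +1 for the header: report physical file line numbers
      stop_mpinet("unknown role value(s) ",
                  paste(unique(df$role[bad_role]), collapse = ", "),
                  " at line(s) ", paste(bad_role + 1L, collapse = ", "),
                  " of ", path, class = "mpinet_format_error")
    }
    bad_id <- which(!nzchar(df$metabolite_id) | !nzchar(df$protein_id))
    if (length(bad_id) > 0)
      stop_mpinet("empty identifier at line(s) ",
                  paste(bad_id + 1L, collapse = ", "), " of ", path,
                  class = "mpinet_format_error")
  }
  mpi_edges(df$metabolite_id, df$protein_id, df$role, source_tag)
}

#' Construct an MPI edge table
#'
#' @param metabolite_id,protein_id,role Character vectors of equal length.
#' @param sources Character scalar or vector of source tags (stored
#'   semicolon-joined, sorted, unique).
#' @return Data frame of class `mpi_edges`.
#' @export
mpi_edges <- function(metabolite_id, protein_id, role, sources) {
  if (length(role) == 1L) role <- rep(role, length(metabolite_id))
  stopifnot(length(metabolite_id) == length(protein_id),
            length(role) == length(metabolite_id))
  if (!all(role %in% c("substrate", "product", "both")))
    stop_mpinet("role values must be substrate/product/both",
                class = "mpinet_format_error")
  src <- vapply(sources, function(s)
    paste(sort(unique(strsplit(s, ";", fixed = TRUE)[[1]])), collapse = ";"),
    character(1), USE.NAMES = FALSE)
  if (length(src) == 1L) src <- rep(src, length(metabolite_id))
  df <- data.frame(metabolite_id = as.character(metabolite_id),
                   protein_id = as.character(protein_id),
                   role = as.character(role),
                   sources = src,
                   stringsAsFactors = FALSE)
  class(df) <- c("mpi_edges", "data.frame")
  df
}

#' Write an MPI network (or edge table) as TSV
#'
#' Emits the same dialect `read_mpi_edges()` consumes, with a `source` column
#' carrying the semicolon-joined source tags. Edges are sorted by
#' (metabolite_id, protein_id) so output is deterministic.
#'
#' @param net An `mpi_network` or `mpi_edges` object.
#' @param path Output path.
#' @export
write_mpi_network <- function(net, path) {
  edges <- if (inherits(net, "mpi_network")) net$edges else net
  edges <- edges[order(edges$metabolite_id, edges$protein_id), , drop = FALSE]
  out <- data.frame(metabolite_id = edges$metabolite_id,
                    protein_id = edges$protein_id,
                    role = edges$role,
                    source = edges$sources)
  write_tsv_stable(out, path)
}

#' Read an undirected PPI edge list (two-column TSV)
#'
#' @param path TSV with header columns `protein_a`, `protein_b`.
#' @return Data frame with columns `protein_a`, `protein_b`.
#' @export
read_ppi_edges <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (!all(c("protein_a", "protein_b") %in% names(df)))
    stop_mpinet("PPI edge file must have columns protein_a, protein_b",
                class = "mpinet_format_error")
  df[, c("protein_a", "protein_b")]
}

#' Read a GMT gene-set / metabolite-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. The description field is
#' kept as the set category.
#'
#' @param path GMT file path.
#' @return A `pathway_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_mpinet("GMT line with fewer than 3 fields: ", substr(l, 1, 60),
                  class = "mpinet_format_error")
    list(name = f[1], category = f[2], members = unique(f[-(1:2)]))
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  pathway_collection(sets)
}

#' Write a pathway collection to GMT
#' @param pathways A `pathway_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(s)
    paste(c(s$name, s$category, s$members), collapse = "\t"), character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Construct a pathway collection
#'
#' @param sets Named list; each element a list with `name`, `category` and a
#'   non-empty character vector `members`.
#' @return Object of class `pathway_collection` (a named list).
#' @export
pathway_collection <- function(sets) {
  if (length(sets) > 0 && is.null(names(sets)))
    names(sets) <- vapply(sets, `[[`, character(1), "name")
  for (s in sets) {
    if (is.null(s$members) || length(s$members) == 0)
      stop_mpinet("pathway ", s$name %||% "<unnamed>", " has no members",
                  class = "mpinet_format_error")
  }
  structure(sets, class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection with", length(x), "sets\n")
  invisible(x)
}

#' Read an expression matrix TSV (first column gene id, then samples)
#' @param path TSV path.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Write an expression matrix TSV
#' @param mat Numeric matrix, genes x samples.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  write_tsv_stable(df, path)
}

#' Read a clinical table TSV
#'
#' Expected columns: `sample_id` (required) and any of `group`, `subtype`,
#' `pair_id`, `time`, `event`, plus free covariate columns.
#' @param path TSV path.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop_mpinet("clinical table must have a sample_id column",
                class = "mpinet_format_error")
  if (anyDuplicated(df$sample_id))
    stop_mpinet("duplicate sample_id in clinical table",
                class = "mpinet_format_error")
  df
}

#' Read a two-column log2 fold-change table (protein_id, log2fc)
#' @param path TSV path.
#' @return Named numeric vector.
#' @export
read_log2fc <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "log2fc") %in% names(df)))
    stop_mpinet("log2FC table must have columns protein_id, log2fc",
                class = "mpinet_format_error")
  setNames(as.numeric(df$log2fc), df$protein_id)
}
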