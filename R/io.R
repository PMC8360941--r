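#' Read a bipartite edge list
#'
#' Reads a delimited edge list into a [bipartite_network()] (two columns:
#' `source,target`) or, with `temporal = TRUE`, a
#' [temporal_bipartite_network()] (three columns: `source,target,date`).
#' Column 1 defines V1, column 2 defines V2; a node appearing in both columns
#' is a bipartiteness error. Duplicate rows collapse to one link (temporal:
#' the earliest date wins). Only nodes appearing in at least one row are kept;
#' isolated nodes can be added via `v1`/`v2`.
#'
#' @param path file path
#' @param delimiter field separator (default tab; `","` for CSV)
#' @param temporal logical; expect a third date column
#' @param date_format date parsing format (default ISO-8601 `%Y-%m-%d`)
#' @param header logical; whether the first row is a header
#' @param v1,v2 optional extra node identifiers (isolated-node sidecar)
#' @return a `bipartite_network` or `temporal_bipartite_network`
#' @export
read_bipartite_edgelist <- function(path, delimiter = "\t", temporal = FALSE,
                                    date_format = "%Y-%m-%d", header = FALSE,
                                    v1 = NULL, v2 = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (header && length(raw) > 0) raw <- raw[-1]
  want <- if (temporal) 3L else 2L
  fields <- strsplit(raw, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < want)
  if (length(bad) > 0) {
    stop("malformed row at line ", bad[1] + as.integer(header),
         ": expected ", want, " fields, found ", nf[bad[1]])
  }
  cols <- lapply(seq_len(want), function(k) trimws(vapply(fields, `[[`, "", k)))
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  names(df) <- c("v1", "v2", "date")[seq_len(want)]
  net <- if (temporal) {
    temporal_bipartite_network(df, v1 = v1, v2 = v2, date_format = date_format)
  } else {
    bipartite_network(df, v1 = v1, v2 = v2)
  }
  bp_info("read %d rows from %s: %d V1 nodes, %d V2 nodes, %d links (%d duplicate rows collapsed)",
          length(raw), path, length(net$v1), length(net$v2), n_links(net),
          length(raw) - n_links(net))
  net
}

#' Read a labelled binary adjacency matrix (drug-target benchmark dialect)
#'
#' Reads the dense labelled 0/1 TSV dialect used by the classical drug-target
#' interaction benchmarks: the first row holds the V1 (drug) labels, the first
#' column the V2 (target) labels, and every cell is 0 or 1.
#'
#' @param path file path to the TSV
#' @return a `bipartite_network` with a link for every 1-cell; label rows and
#'   columns with no links are kept as isolated nodes.
#' @export
read_bipartite_adjacency <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                         check.names = FALSE, stringsAsFactors = FALSE)
  v2_labels <- as.character(m[[1]])
  v1_labels <- colnames(m)[-1]
  cells <- as.matrix(m[, -1, drop = FALSE])
  if (anyDuplicated(v1_labels)) stop("duplicate column label(s) in ", path)
  if (anyDuplicated(v2_labels)) stop("duplicate row label(s) in ", path)
  suppressWarnings(storage.mode(cells) <- "numeric")
  if (anyNA(cells) || !all(cells %in% c(0, 1))) {
    stop("non-binary cell(s): adjacency matrices must contain only 0 and 1")
  }
  idx <- which(cells == 1, arr.ind = TRUE)
  links <- data.frame(v1 = v1_labels[idx[, 2]], v2 = v2_labels[idx[, 1]],
                      stringsAsFactors = FALSE)
  net <- bipartite_network(links, v1 = v1_labels, v2 = v2_labels)
  bp_info("read %d x %d adjacency from %s: %d links",
          length(v2_labels), length(v1_labels), path, n_links(net))
  net
}

#' Write a network as an edge-list TSV
#' @param net a `bipartite_network` (temporal networks include the date column)
#' @param path output path
#' @param delimiter field separator
#' @return `path`, invisibly
#' @export
write_bipartite_edgelist <- function(net, path, delimiter = "\t") {
  df <- links_df(net)
  if ("date" %in% names(df)) df$date <- format(df$date, "%Y-%m-%d")
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
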