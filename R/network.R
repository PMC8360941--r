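#' Construct a bipartite network
#'
#' A bipartite network G = (V1, V2, E) has two disjoint node sets with links
#' allowed only across the sets. Internally the network is stored as a sparse
#' 0/1 biadjacency matrix B of shape |V1| x |V2|, the representation on which
#' all similarity indices operate (e.g. B Bt B counts length-3 walks between
#' the two sides).
#'
#' @param links two-column data frame (or matrix) of links; column 1 holds V1
#'   node identifiers, column 2 holds V2 node identifiers. Identifiers are
#'   opaque strings; side membership is positional, never inferred from names.
#' @param v1,v2 optional explicit node sets (character). When given they must
#'   contain every node used by `links`; extra entries become isolated nodes.
#'   When omitted the node sets are the distinct values of each column.
#' @return an object of class `bipartite_network`: a list with sorted
#'   character vectors `v1`, `v2` and the sparse biadjacency matrix `B`.
#' @examples
#' net <- bipartite_network(data.frame(p = c("a", "a", "b"), d = c("1", "2", "1")))
#' n_links(net)
#' @export
bipartite_network <- function(links = NULL, v1 = NULL, v2 = NULL) {
  if (is.null(links)) {
    links <- data.frame(v1 = character(0), v2 = character(0))
  }
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (ncol(links) < 2) stop("`links` must have two columns (V1 node, V2 node)")
  lu <- as.character(links[[1]])
  lv <- as.character(links[[2]])
  if (anyNA(lu) || anyNA(lv) || any(lu == "") || any(lv == "")) {
    stop("links contain missing or empty node identifiers")
  }
  v1 <- sort(unique(c(as.character(v1), lu)))
  v2 <- sort(unique(c(as.character(v2), lv)))
  both <- intersect(v1, v2)
  if (length(both) > 0) {
    stop("bipartiteness violated: node(s) appear on both sides: ",
         paste(utils::head(both, 5), collapse = ", "))
  }
  keep <- if (length(lu) > 0) !duplicated(paste0(lu, "\r", lv)) else logical(0)
  B <- Matrix::sparseMatrix(
    i = match(lu[keep], v1), j = match(lv[keep], v2),
    x = 1, dims = c(length(v1), length(v2)),
    dimnames = list(v1, v2)
  )
  structure(list(v1 = v1, v2 = v2, B = B), class = "bipartite_network")
}

#' Construct a temporal bipartite network
#'
#' A bipartite network whose every link carries a calendar date (e.g. the
#' diagnosis date of a patient-disease link). The network is interpreted as
#' evolving by link addition: a link exists from its date onward, so duplicate
#' (patient, disease) records collapse to the earliest date.
#'
#' @param links three-column data frame: V1 node (patient), V2 node (disease),
#'   date (`Date`, or character parseable via `date_format`).
#' @param v1,v2 optional explicit node sets, as in [bipartite_network()].
#' @param date_format format string for character dates (default ISO-8601).
#' @return an object of class `temporal_bipartite_network` (which also
#'   inherits `bipartite_network`), with an extra `edges` data frame holding
#'   one row per link: `v1`, `v2`, `date`.
#' @export
temporal_bipartite_network <- function(links, v1 = NULL, v2 = NULL,
                                       date_format = "%Y-%m-%d") {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (ncol(links) < 3) stop("temporal links need three columns (V1, V2, date)")
  dts <- links[[3]]
  if (!inherits(dts, "Date")) {
    parsed <- as.Date(as.character(dts), format = date_format)
    bad <- which(is.na(parsed) & !is.na(dts))
    if (length(bad) > 0) {
      stop("unparseable date(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           " (expected format ", date_format, ")")
    }
    dts <- parsed
  }
  if (anyNA(dts)) stop("missing timestamp on ", sum(is.na(dts)), " link(s)")
  edges <- data.frame(
    v1 = as.character(links[[1]]), v2 = as.character(links[[2]]),
    date = dts, stringsAsFactors = FALSE
  )
  # duplicate (patient, disease) rows keep the earliest date (first diagnosis)
  edges <- edges[order(edges$v1, edges$v2, edges$date), , drop = FALSE]
  edges <- edges[!duplicated(edges[c("v1", "v2")]), , drop = FALSE]
  base <- bipartite_network(edges[c("v1", "v2")], v1 = v1, v2 = v2)
  edges <- edges[order(edges$v1, edges$v2), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    c(unclass(base), list(edges = edges)),
    class = c("temporal_bipartite_network", "bipartite_network")
  )
}

#' Number of links in a network
#' @param net a `bipartite_network`
#' @return integer link count |E|
#' @export
n_links <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  as.integer(sum(net$B))
}

#' Links of a network as a data frame
#' @param net a `bipartite_network`
#' @return data frame with character columns `v1`, `v2`, sorted by (v1, v2);
#'   for temporal networks a `date` column is included.
#' @export
links_df <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (inherits(net, "temporal_bipartite_network")) return(net$edges)
  Bt <- methods::as(net$B, "TsparseMatrix")
  out <- data.frame(
    v1 = net$v1[Bt@i + 1L], v2 = net$v2[Bt@j + 1L],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$v1, out$v2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
node_side <- function(net, v) {
  v <- as.character(v)
  if (length(v) != 1) stop("one node at a time")
  if (v %in% net$v1) "v1" else if (v %in% net$v2) "v2"
  else stop("unknown node: ", v)
}

#' Neighbours of a node
#'
#' Returns Gamma(v), the set of nodes linked to `v`; always a subset of the
#' opposite side of the bipartition.
#'
#' @param net a `bipartite_network`
#' @param v a node identifier present in the network
#' @return sorted character vector of neighbour identifiers
#' @examples
#' neighbors(make_fig1_fixture(), "e")
#' @export
neighbors <- function(net, v) {
  side <- node_side(net, v)
  if (side == "v1") {
    net$v2[which(as.numeric(net$B[v, ]) > 0)]
  } else {
    net$v1[which(as.numeric(net$B[, v]) > 0)]
  }
}

#' Second neighbourhood of a node
#'
#' Returns Gamma-hat(v), the union of the neighbour sets of v's neighbours: a
#' subset of v's own side, possibly containing v itself.
#'
#' @inheritParams neighbors
#' @return sorted character vector
#' @export
second_neighbors <- function(net, v) {
  nb <- neighbors(net, v)
  if (length(nb) == 0) return(character(0))
  sort(unique(unlist(lapply(nb, function(z) neighbors(net, z)))))
}

#' Degree of a node
#' @inheritParams neighbors
#' @return |Gamma(v)|, a non-negative integer
#' @export
degree <- function(net, v) {
  side <- node_side(net, v)
  if (side == "v1") as.integer(sum(net$B[v, ])) else as.integer(sum(net$B[, v]))
}

#' Degrees of all nodes on one side
#' @param net a `bipartite_network`
#' @param side `"v1"` or `"v2"`
#' @return named integer vector of degrees
#' @export
degrees <- function(net, side = c("v1", "v2")) {
  side <- match.arg(side)
  d <- if (side == "v1") Matrix::rowSums(net$B) else Matrix::colSums(net$B)
  stats::setNames(as.integer(d), if (side == "v1") net$v1 else net$v2)
}

#' Add a link to a network
#'
#' @param net a `bipartite_network`
#' @param x a V1 node, `y` a V2 node; new nodes are added to their side
#'   provided bipartiteness is preserved.
#' @param y see `x`
#' @return a new `bipartite_network` with the link present
#' @export
add_link <- function(net, x, y) {
  stopifnot(inherits(net, "bipartite_network"))
  if (inherits(net, "temporal_bipartite_network")) {
    stop("add_link() operates on static networks; rebuild temporal networks from edges")
  }
  x <- as.character(x); y <- as.character(y)
  if (x %in% net$v2) stop("bipartiteness violated: ", x, " is a V2 node")
  if (y %in% net$v1) stop("bipartiteness violated: ", y, " is a V1 node")
  bipartite_network(rbind(links_df(net), data.frame(v1 = x, v2 = y)),
                    v1 = union(net$v1, x), v2 = union(net$v2, y))
}

#' Summary statistics of a bipartite network
#'
#' The quantities conventionally tabulated for bipartite benchmark networks:
#' node and link counts and the mean degree on each side.
#'
#' @param net a `bipartite_network`
#' @return data frame with one row: `n_nodes`, `n_v1`, `n_v2`, `n_links`,
#'   `mean_degree_v1`, `mean_degree_v2`
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  m <- n_links(net)
  n1 <- length(net$v1); n2 <- length(net$v2)
  data.frame(
    n_nodes = n1 + n2, n_v1 = n1, n_v2 = n2, n_links = m,
    mean_degree_v1 = if (n1 > 0) m / n1 else NA_real_,
    mean_degree_v2 = if (n2 > 0) m / n2 else NA_real_
  )
}

#' Filter a temporal cohort to patients with at least k conditions
#'
#' Retains exactly the V1 (patient) nodes with degree >= k and their links;
#' V2 (disease) nodes left isolated are dropped. This mirrors the usual
#' multimorbidity preprocessing step of keeping only patients diagnosed with
#' at least `k` distinct conditions.
#'
#' @param net a `temporal_bipartite_network`
#' @param k minimum number of distinct diagnoses (>= 1)
#' @return a filtered `temporal_bipartite_network`
#' @export
filter_min_conditions <- function(net, k = 4) {
  stopifnot(inherits(net, "temporal_bipartite_network"), k >= 1)
  deg <- degrees(net, "v1")
  keep <- names(deg)[deg >= k]
  edges <- net$edges[net$edges$v1 %in% keep, , drop = FALSE]
  bp_info("min-conditions filter (k=%d): kept %d of %d patients, %d links",
          k, length(keep), length(net$v1), nrow(edges))
  temporal_bipartite_network(edges)
}

#' @exportS3Method base::print
print.bipartite_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf("<%s> |V1| = %d, |V2| = %d, |E| = %d\n",
              paste(class(x)[1]), s$n_v1, s$n_v2, s$n_links))
  cat(sprintf("  mean degree: V1 %.3f, V2 %.3f\n",
              s$mean_degree_v1, s$mean_degree_v2))
  invisible(x)
}
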