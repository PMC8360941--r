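#' Supported similarity indices
#'
#' The closed vocabulary of index names: the one-sided common-neighbour
#' counts (`CN1`, `CN2`), the bipartite common-neighbour index `CN` and its
#' classical variants (`JC`, `AA`, `RA`, `PA`), the local-community-paradigm
#' family (`LCL`, `CAR`, `CJC`, `CAA`, `CRA`, `CPA`), the path-based resource
#' allocation index `PRA`, and `RANDOM`, a uniform-score null used to
#' calibrate evaluation machinery (its AUC should be about 0.5).
#'
#' @return character vector of index names
#' @export
index_names <- function() {
  c("CN1", "CN2", "CN", "JC", "AA", "RA", "PA",
    "LCL", "CAR", "CJC", "CAA", "CRA", "CPA", "PRA", "RANDOM")
}

#' @noRd
check_index <- function(index) {
  if (length(index) != 1 || !index %in% c(index_names(), "TPRA")) {
    stop("unknown index name: ", paste(index, collapse = ","),
         " (choose from ", paste(c(index_names(), "TPRA"), collapse = ", "), ")")
  }
  index
}

#' Common-neighbour sets of a cross-set pair
#'
#' The nodes "touched by quadrangles" through x in V1 and y in V2, split by
#' side: `side1` = Gamma-hat(x) intersect Gamma(y) (V1 nodes) and `side2` =
#' Gamma(x) intersect Gamma-hat(y) (V2 nodes). The bipartite CN score is
#' |side1| + |side2|; the two sets are disjoint by construction since they
#' live on different sides.
#'
#' @param net a `bipartite_network`
#' @param x a V1 node
#' @param y a V2 node
#' @return list with character vectors `side1` and `side2`
#' @examples
#' cn_sets(make_fig1_fixture(), "e", "1")
#' @export
cn_sets <- function(net, x, y) {
  x <- as.character(x); y <- as.character(y)
  if (!(x %in% net$v1)) stop("side error: ", x, " is not a V1 node")
  if (!(y %in% net$v2)) stop("side error: ", y, " is not a V2 node")
  list(
    side1 = intersect(second_neighbors(net, x), neighbors(net, y)),
    side2 = intersect(neighbors(net, x), second_neighbors(net, y))
  )
}

#' @noRd
lcl_links <- function(net, x, y) {
  # links (p', d') with p' in Gamma(y), d' in Gamma(x): the local community
  gy <- neighbors(net, y)  # V1 side
  gx <- neighbors(net, x)  # V2 side
  if (length(gy) == 0 || length(gx) == 0) {
    return(data.frame(v1 = character(0), v2 = character(0)))
  }
  sub <- net$B[gy, gx, drop = FALSE]
  idx <- which(as.matrix(sub) > 0, arr.ind = TRUE)
  data.frame(v1 = gy[idx[, 1]], v2 = gx[idx[, 2]], stringsAsFactors = FALSE)
}

#' Similarity score of a single cross-set pair
#'
#' Computes one similarity index for one (x, y) pair from the literal
#' set-based definitions. This is the readable reference route; [score_all()]
#' computes the same scores for many pairs at once via sparse matrix algebra,
#' and the two routes agree (this identity is exercised in the test suite).
#'
#' Definitions, for x in V1, y in V2, with CN set as in [cn_sets()] and the
#' local community links L(x, y) = all links between Gamma(y) and Gamma(x):
#' \itemize{
#'   \item `CN1`/`CN2`/`CN`: |side1|, |side2|, and their sum.
#'   \item `JC`: CN / (|Gamma-hat(x) union Gamma(y)| + |Gamma(x) union Gamma-hat(y)|).
#'   \item `AA`: sum over CN-set nodes z of 1/log2 |Gamma(z)|.
#'   \item `RA`: sum over CN-set nodes z of 1/|Gamma(z)|.
#'   \item `PA`: |Gamma(x)| * |Gamma(y)|.
#'   \item `LCL`: |L(x, y)|; equals the unique length-3 path count for
#'     non-adjacent pairs.
#'   \item `PRA`: sum over links (p', d') in L(x, y) of
#'     1 / (|Gamma(p')| * |Gamma(d')|) — each length-3 path weighted by the
#'     inverse degrees of its internal nodes.
#'   \item `CAR`: CN * LCL.
#'   \item `CAA`/`CRA`: sum over CN-set nodes z of gamma(z)/log2 |Gamma(z)|
#'     (resp. gamma(z)/|Gamma(z)|), where gamma(z) counts local-community
#'     links incident to z.
#'   \item `CJC`: CAR divided by the JC denominator.
#'   \item `CPA`: ex*ey + ex*CAR + ey*CAR + CAR^2 with ex, ey the numbers of
#'     links of x resp. y leaving the local community.
#'   \item `RANDOM`: a uniform draw in [0, 1) (requires `seed` for
#'     reproducibility).
#' }
#'
#' @param net a `bipartite_network`
#' @param index an index name from [index_names()]
#' @param x a V1 node
#' @param y a V2 node
#' @param seed integer seed, used only by `RANDOM`
#' @return a single non-negative numeric score
#' @examples
#' net <- make_fig1_fixture()
#' score_pair(net, "CN", "e", "1")   # 5
#' score_pair(net, "PRA", "e", "1")  # 5/12
#' @export
score_pair <- function(net, index, x, y, seed = NULL) {
  check_index(index)
  if (index == "TPRA") stop("TPRA needs a conditional-probability matrix; use score_tpra()")
  if (index == "RANDOM") {
    if (!is.null(seed)) set.seed(seed)
    return(stats::runif(1))
  }
  if (index == "PA") {
    return(as.numeric(degree(net, x) * degree(net, y)))
  }
  cs <- cn_sets(net, x, y)
  cn1 <- length(cs$side1); cn2 <- length(cs$side2); cn <- cn1 + cn2
  if (index == "CN1") return(as.numeric(cn1))
  if (index == "CN2") return(as.numeric(cn2))
  if (index == "CN") return(as.numeric(cn))
  deg_of <- function(zs) vapply(zs, function(z) degree(net, z), 0L)
  if (index == "AA") {
    zs <- c(cs$side1, cs$side2)
    return(sum(1 / log2(deg_of(zs))))
  }
  if (index == "RA") {
    zs <- c(cs$side1, cs$side2)
    return(sum(1 / deg_of(zs)))
  }
  jc_denom <- function() {
    length(union(second_neighbors(net, x), neighbors(net, y))) +
      length(union(neighbors(net, x), second_neighbors(net, y)))
  }
  if (index == "JC") {
    d <- jc_denom()
    return(if (d > 0) cn / d else 0)
  }
  ll <- lcl_links(net, x, y)
  lcl <- nrow(ll)
  if (index == "LCL") return(as.numeric(lcl))
  if (index == "PRA") {
    if (lcl == 0) return(0)
    return(sum(1 / (deg_of(ll$v1) * deg_of(ll$v2))))
  }
  car <- cn * lcl
  if (index == "CAR") return(as.numeric(car))
  if (index == "CJC") {
    d <- jc_denom()
    return(if (d > 0) car / d else 0)
  }
  gamma_of <- function(z) sum(ll$v1 == z) + sum(ll$v2 == z)
  if (index %in% c("CAA", "CRA")) {
    zs <- c(cs$side1, cs$side2)
    if (length(zs) == 0) return(0)
    g <- vapply(zs, gamma_of, 0)
    w <- if (index == "CAA") 1 / log2(deg_of(zs)) else 1 / deg_of(zs)
    return(sum(g * w))
  }
  if (index == "CPA") {
    ex <- degree(net, x) - cn2
    ey <- degree(net, y) - cn1
    return(ex * ey + ex * car + ey * car + car^2)
  }
  stop("unhandled index: ", index)  # nocov
}

#' Score matrix over the full pair universe
#'
#' Computes the chosen index for every (V1, V2) pair at once using sparse
#' matrix algebra on the biadjacency matrix B. Entries for pairs that are
#' links of `net` are computed from the same formulas (they are meaningful
#' only for the non-adjacent pairs scored during evaluation, where they agree
#' with [score_pair()]).
#'
#' @param net a `bipartite_network`
#' @param index index name; `"TPRA"` additionally requires `M`
#' @param M a [cond_prob_matrix()] covering all V2 nodes (TPRA only)
#' @param seed integer seed (RANDOM only)
#' @return dense |V1| x |V2| numeric matrix with node-name dimnames
#' @export
score_matrix <- function(net, index, M = NULL, seed = NULL) {
  check_index(index)
  B <- net$B
  n1 <- length(net$v1); n2 <- length(net$v2)
  dv1 <- as.numeric(Matrix::rowSums(B))
  dv2 <- as.numeric(Matrix::colSums(B))
  finish <- function(S) {
    out <- as.matrix(S)
    dimnames(out) <- list(net$v1, net$v2)
    out
  }
  if (index == "RANDOM") {
    if (!is.null(seed)) set.seed(seed)
    return(finish(matrix(stats::runif(n1 * n2), n1, n2)))
  }
  if (index == "PA") return(finish(outer(dv1, dv2)))
  N1 <- methods::as(Matrix::tcrossprod(B), "generalMatrix")  # V1 x V1 shared-neighbour counts
  N2 <- methods::as(Matrix::crossprod(B), "generalMatrix")   # V2 x V2
  A1 <- 1 * (N1 > 0)                 # A1[x, p'] = 1 iff p' in Gamma-hat(x)
  A2 <- 1 * (N2 > 0)
  S1 <- A1 %*% B                     # |side1| counts
  S2 <- B %*% A2                     # |side2| counts
  if (index == "CN1") return(finish(S1))
  if (index == "CN2") return(finish(S2))
  CN <- S1 + S2
  if (index == "CN") return(finish(CN))
  # degree weights; a CN-set node always has degree >= 1, and degree >= 2
  # unless the pair is adjacent, so the guards only affect link entries
  inv1 <- ifelse(dv1 > 0, 1 / dv1, 0)
  inv2 <- ifelse(dv2 > 0, 1 / dv2, 0)
  log1 <- ifelse(dv1 > 1, 1 / log2(dv1), 0)
  log2w <- ifelse(dv2 > 1, 1 / log2(dv2), 0)
  if (index == "AA") return(finish(A1 %*% (B * log1) + B %*% (A2 * log2w)))
  if (index == "RA") return(finish(A1 %*% (B * inv1) + B %*% (A2 * inv2)))
  jc_denominator <- function() {
    g1 <- as.numeric(Matrix::rowSums(A1))   # |Gamma-hat(x)|
    g2 <- as.numeric(Matrix::rowSums(A2))   # |Gamma-hat(y)|
    outer(g1, dv2, "+") - as.matrix(S1) + outer(dv1, g2, "+") - as.matrix(S2)
  }
  if (index == "JC") {
    D <- jc_denominator()
    return(finish(ifelse(D > 0, as.matrix(CN) / D, 0)))
  }
  LCL <- B %*% Matrix::t(B) %*% B
  if (index == "LCL") return(finish(LCL))
  if (index == "PRA") {
    Bn <- (B * inv1) %*% Matrix::Diagonal(n2, inv2)  # B[p,d]/(deg p * deg d)
    return(finish(B %*% Matrix::t(Bn) %*% B))
  }
  if (index == "TPRA") {
    if (is.null(M)) stop("TPRA requires a conditional-probability matrix M")
    Mm <- align_condprob(M, net$v2)
    Bn <- (B * inv1) %*% Matrix::Diagonal(n2, inv2)
    C <- as.matrix(Matrix::t(Bn) %*% B) * Mm   # C[d', y] weighted by M(d', y)
    return(finish(B %*% C))
  }
  CAR <- as.matrix(CN) * as.matrix(LCL)
  if (index == "CAR") return(finish(CAR))
  if (index == "CJC") {
    D <- jc_denominator()
    return(finish(ifelse(D > 0, CAR / D, 0)))
  }
  if (index == "CAA") return(finish(N1 %*% (B * log1) + B %*% (N2 * log2w)))
  if (index == "CRA") return(finish(N1 %*% (B * inv1) + B %*% (N2 * inv2)))
  if (index == "CPA") {
    EX <- outer(dv1, rep(1, n2)) - as.matrix(S2)  # links of x outside the community
    EY <- outer(rep(1, n1), dv2) - as.matrix(S1)
    return(finish(EX * EY + (EX + EY) * CAR + CAR^2))
  }
  stop("unhandled index: ", index)  # nocov
}

#' Score a set of candidate pairs
#'
#' Scores candidate cross-set pairs with one index and returns a ranked
#' score table. With `candidates = "nonexistent"` (the default) the
#' candidates are E' = U \ E, all pairs of the |V1| x |V2| universe that are
#' not links — the usual missing-link candidate set.
#'
#' @param net a `bipartite_network`
#' @param index index name (see [index_names()]; `"TPRA"` requires `M`)
#' @param candidates `"nonexistent"`, `"all"`, or a two-column data frame of
#'   (V1, V2) pairs
#' @param missing_only when a data frame of candidates is supplied, error if
#'   any candidate is already a link (default TRUE)
#' @param M conditional-probability matrix for TPRA
#' @param seed seed for RANDOM
#' @return data frame `source`, `target`, `score`, `index`, `rank`, ordered
#'   by rank; ranking is score-descending with ties broken by pair id
#' @examples
#' score_all(make_fig1_fixture(), "PRA")
#' @export
score_all <- function(net, index, candidates = "nonexistent",
                      missing_only = TRUE, M = NULL, seed = NULL) {
  check_index(index)
  S <- score_matrix(net, index, M = M, seed = seed)
  if (is.character(candidates) && length(candidates) == 1) {
    mode <- match.arg(candidates, c("nonexistent", "all"))
    keep <- if (mode == "nonexistent") as.matrix(net$B) == 0 else
      matrix(TRUE, length(net$v1), length(net$v2))
    idx <- which(keep, arr.ind = TRUE)
    pairs <- data.frame(source = net$v1[idx[, 1]], target = net$v2[idx[, 2]],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(candidates, stringsAsFactors = FALSE)
    if (nrow(pairs) > 0) {
      names(pairs)[1:2] <- c("source", "target")
      pairs$source <- as.character(pairs$source)
      pairs$target <- as.character(pairs$target)
      miss1 <- setdiff(pairs$source, net$v1)
      miss2 <- setdiff(pairs$target, net$v2)
      if (length(miss1) || length(miss2)) {
        stop("unknown candidate node(s): ",
             paste(utils::head(c(miss1, miss2), 5), collapse = ", "))
      }
      if (missing_only) {
        is_link <- as.matrix(net$B)[cbind(pairs$source, pairs$target)] > 0
        if (any(is_link)) {
          stop("candidate pair(s) already present as links: ",
               paste(utils::head(paste0("(", pairs$source[is_link], ",",
                                        pairs$target[is_link], ")"), 5),
                     collapse = ", "))
        }
      }
    } else {
      pairs <- data.frame(source = character(0), target = character(0))
    }
  }
  if (nrow(pairs) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      score = numeric(0), index = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  sc <- S[cbind(pairs$source, pairs$target)]
  ord <- order(-sc, pairs$source, pairs$target)
  out <- data.frame(source = pairs$source, target = pairs$target, score = sc,
                    index = index, stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a score table to CSV
#' @param scores a score table from [score_all()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(scores[c("source", "target", "score", "index", "rank")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
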