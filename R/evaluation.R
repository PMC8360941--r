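#' @noRd
new_link_split <- function(net, probe, protocol, seed) {
  all_links <- links_df(net)[c("v1", "v2")]
  key <- function(df) paste0(df$v1, "\r", df$v2)
  in_probe <- key(all_links) %in% key(probe)
  train <- all_links[!in_probe, , drop = FALSE]
  rownames(train) <- rownames(probe) <- NULL
  # E' = U \ E: negatives never include observed links, probe included
  Bm <- as.matrix(net$B)
  idx <- which(Bm == 0, arr.ind = TRUE)
  nonexistent <- data.frame(v1 = net$v1[idx[, 1]], v2 = net$v2[idx[, 2]],
                            stringsAsFactors = FALSE)
  nonexistent <- nonexistent[order(nonexistent$v1, nonexistent$v2), , drop = FALSE]
  rownames(nonexistent) <- NULL
  stopifnot(nrow(train) + nrow(probe) == nrow(all_links))
  structure(
    list(train = train, probe = probe[c("v1", "v2")], nonexistent = nonexistent,
         v1 = net$v1, v2 = net$v2, protocol = protocol, seed = seed),
    class = "link_split"
  )
}

#' Random train/probe split of a static network
#'
#' Partitions the observed links E uniformly at random into a training set
#' and a probe set with |probe| = round(probe_fraction * |E|); every link has
#' the same probability of landing in the probe set. The nonexistent set
#' E' = U \ E (negatives for evaluation) is attached.
#'
#' @param net a `bipartite_network`
#' @param probe_fraction fraction of links held out (0 < f < 1); default 0.1,
#'   the conventional 90/10 protocol
#' @param seed integer seed; identical seeds give identical splits
#' @return a `link_split`: list with data frames `train`, `probe`,
#'   `nonexistent`, plus the node sets, `protocol` and `seed`
#' @export
split_static <- function(net, probe_fraction = 0.1, seed = 1) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!(probe_fraction > 0 && probe_fraction < 1)) {
    stop("parameter error: probe_fraction must lie in (0, 1)")
  }
  links <- links_df(net)[c("v1", "v2")]
  m <- nrow(links)
  np <- round(probe_fraction * m)
  if (np < 1 || np >= m) {
    stop("parameter error: probe size ", np, " infeasible for ", m, " links")
  }
  set.seed(seed)
  probe <- links[sort(sample.int(m, np)), , drop = FALSE]
  new_link_split(net, probe, "static_random", seed)
}

#' Temporal leave-latest-out train/probe split
#'
#' Emulates future-link prediction: patients are sampled at random (without
#' replacement, among patients with at least two links) and for each sampled
#' patient exactly the latest-dated link goes to the probe set, all of that
#' patient's other links and all links of unsampled patients to the training
#' set. Sampling stops when the probe holds round(probe_fraction * |E|)
#' links. A patient's latest-date tie is broken by lexicographically smallest
#' disease id.
#'
#' @param net a `temporal_bipartite_network`
#' @param probe_fraction fraction of links held out (default 0.1)
#' @param seed integer seed
#' @return a `link_split` with `protocol = "temporal_leave_latest"`
#' @export
split_temporal <- function(net, probe_fraction = 0.1, seed = 1) {
  if (!inherits(net, "temporal_bipartite_network")) {
    stop("split_temporal() needs a temporal network")
  }
  if (!(probe_fraction > 0 && probe_fraction < 1)) {
    stop("parameter error: probe_fraction must lie in (0, 1)")
  }
  edges <- net$edges
  m <- nrow(edges)
  np <- round(probe_fraction * m)
  if (np < 1) stop("parameter error: probe size rounds to 0")
  deg <- degrees(net, "v1")
  eligible <- names(deg)[deg >= 2]
  if (length(eligible) < np) {
    stop("parameter error: need ", np, " patients with >= 2 links, have ",
         length(eligible))
  }
  set.seed(seed)
  chosen <- sample(eligible, np)
  # latest link per chosen patient; date ties -> smallest disease id
  sub <- edges[edges$v1 %in% chosen, , drop = FALSE]
  sub <- sub[order(sub$v1, -as.numeric(sub$date), sub$v2), , drop = FALSE]
  probe <- sub[!duplicated(sub$v1), c("v1", "v2"), drop = FALSE]
  new_link_split(net, probe, "temporal_leave_latest", seed)
}

#' Training network of a split
#'
#' Rebuilds the network from the training links only, keeping the full node
#' sets (probe endpoints stay as nodes so the held-out pairs can be scored).
#'
#' @param net the original network
#' @param split a `link_split` of `net`
#' @return a `bipartite_network` (temporal input yields a temporal network
#'   restricted to training links)
#' @export
training_network <- function(net, split) {
  stopifnot(inherits(split, "link_split"))
  if (inherits(net, "temporal_bipartite_network")) {
    key <- paste0(net$edges$v1, "\r", net$edges$v2)
    keep <- key %in% paste0(split$train$v1, "\r", split$train$v2)
    temporal_bipartite_network(net$edges[keep, , drop = FALSE],
                               v1 = net$v1, v2 = net$v2)
  } else {
    bipartite_network(split$train, v1 = net$v1, v2 = net$v2)
  }
}

#' Pairwise-comparison AUC
#'
#' The comparison estimator of the area under the ROC curve: among n
#' comparisons of a probe-link score against a nonexistent-link score, count
#' n' wins and n'' ties and report (n' + 0.5 n'') / n. `n_comparisons =
#' "exhaustive"` compares every (probe, nonexistent) pair; an integer draws
#' that many independent uniform comparisons. A scorer assigning i.i.d.
#' random scores has AUC about 0.5.
#'
#' @param probe_scores numeric scores of the held-out (positive) links
#' @param nonexistent_scores numeric scores of the nonexistent (negative) pairs
#' @param n_comparisons `"exhaustive"` or a positive integer
#' @param seed seed for sampled comparisons
#' @return list of class `auc_result`: `n`, `n_higher`, `n_tied`, `auc`
#' @export
auc_pairwise <- function(probe_scores, nonexistent_scores,
                         n_comparisons = "exhaustive", seed = 1) {
  sp <- as.numeric(probe_scores); sn <- as.numeric(nonexistent_scores)
  if (length(sp) == 0 || length(sn) == 0) {
    stop("evaluation error: both score sets must be non-empty")
  }
  if (identical(n_comparisons, "exhaustive")) {
    sns <- sort(sn)
    n_le <- findInterval(sp, sns)                      # #{sn <= sp}
    n_lt <- findInterval(sp, sns, left.open = TRUE)    # #{sn <  sp}
    n_higher <- sum(n_lt)
    n_tied <- sum(n_le - n_lt)
    n <- as.numeric(length(sp)) * length(sn)
  } else {
    n <- as.numeric(n_comparisons)
    if (is.na(n) || n < 1) stop("n_comparisons must be 'exhaustive' or a positive integer")
    set.seed(seed)
    i <- sample.int(length(sp), n, replace = TRUE)
    j <- sample.int(length(sn), n, replace = TRUE)
    n_higher <- sum(sp[i] > sn[j])
    n_tied <- sum(sp[i] == sn[j])
  }
  structure(list(n = n, n_higher = n_higher, n_tied = n_tied,
                 auc = (n_higher + 0.5 * n_tied) / n),
            class = "auc_result")
}

#' @exportS3Method base::print
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f  (n = %g, higher = %g, tied = %g)\n",
              x$auc, x$n, x$n_higher, x$n_tied))
  invisible(x)
}

#' Rank-based AUROC
#'
#' Area under the ROC curve computed from the full ranking via midranks
#' (the Mann-Whitney statistic). Equals the exhaustive pairwise-comparison
#' AUC; the two are implemented independently (comparison counting vs rank
#' sums) and cross-checked in the test suite.
#'
#' @param scores numeric scores of all candidates
#' @param labels logical (or 0/1) vector: TRUE for probe (positive) pairs
#' @return AUROC in [0, 1]
#' @export
auroc_full <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  m <- sum(labels); nn <- sum(!labels)
  if (m == 0 || nn == 0) stop("evaluation error: need both positive and negative labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - m * (m + 1) / 2) / (as.numeric(m) * nn)
}

#' Precision, recall and F-score at a cut-off
#'
#' Ranks candidates by score (descending, ties broken by pair id ascending
#' when `pair_ids` is given, else by position) and takes the top k. Precision
#' is the fraction of selected items that are relevant, recall the fraction
#' of relevant items selected, and F = 2pr / (p + r) (0 when p + r = 0).
#'
#' @param scores numeric candidate scores
#' @param labels logical relevance labels (probe membership)
#' @param k cut-off, 1 <= k <= number of candidates (conventionally the probe
#'   size)
#' @param pair_ids optional character ids for deterministic tie-breaking
#' @return named numeric vector `precision`, `recall`, `f_score`
#' @export
precision_recall_f <- function(scores, labels, k, pair_ids = NULL) {
  labels <- as.logical(labels)
  if (k < 1) stop("parameter error: k must be >= 1")
  if (k > length(scores)) {
    stop("parameter error: k = ", k, " exceeds ", length(scores), " candidates")
  }
  ord <- if (is.null(pair_ids)) order(-scores) else order(-scores, pair_ids)
  tp <- sum(labels[ord][seq_len(k)])
  p <- tp / k
  r <- if (sum(labels) > 0) tp / sum(labels) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f_score = f)
}
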