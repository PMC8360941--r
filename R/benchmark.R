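#' Score and evaluate one train/probe split with one index
#'
#' Builds the candidate table (probe links as positives, nonexistent pairs as
#' negatives), scores every candidate on the training network, and computes
#' the evaluation metrics. The comparison AUC is exhaustive when
#' |probe| * |nonexistent| <= `auc_max_exhaustive`, otherwise estimated from
#' `auc_samples` sampled comparisons.
#'
#' @param train_net the training [bipartite_network()] (see
#'   [training_network()])
#' @param split the `link_split` being evaluated
#' @param index index name (`"TPRA"` requires `M`)
#' @param M `cond_prob_matrix` for TPRA, estimated from training links
#' @param k precision cut-off; default the probe size
#' @param auc_max_exhaustive,auc_samples exhaustive/sampled AUC switch
#' @param seed seed used for sampled AUC comparisons and the RANDOM index
#' @return list with `metrics` (named numeric: auc, auroc, precision, recall,
#'   f_score) and `table` (ranked candidate data frame with logical `label`)
#' @export
evaluate_split <- function(train_net, split, index, M = NULL, k = NULL,
                           auc_max_exhaustive = 1e7, auc_samples = 1e6,
                           seed = 1) {
  stopifnot(inherits(split, "link_split"))
  probe <- split$probe
  nonex <- split$nonexistent
  # scoring and comparison sampling get seeds distinct from the split's seed,
  # so a random scorer is independent of which links were held out
  S <- score_matrix(train_net, index, M = M, seed = seed + 131071L)
  sp <- S[cbind(probe$v1, probe$v2)]
  sn <- S[cbind(nonex$v1, nonex$v2)]
  exhaustive <- as.numeric(length(sp)) * length(sn) <= auc_max_exhaustive
  auc <- auc_pairwise(sp, sn,
                      n_comparisons = if (exhaustive) "exhaustive" else auc_samples,
                      seed = seed + 262143L)
  scores <- c(sp, sn)
  labels <- c(rep(TRUE, length(sp)), rep(FALSE, length(sn)))
  ids <- c(paste0(probe$v1, "\r", probe$v2), paste0(nonex$v1, "\r", nonex$v2))
  if (is.null(k)) k <- length(sp)
  prf <- precision_recall_f(scores, labels, k, pair_ids = ids)
  ord <- order(-scores, ids)
  table <- data.frame(
    source = c(probe$v1, nonex$v1)[ord], target = c(probe$v2, nonex$v2)[ord],
    score = scores[ord], label = labels[ord], index = index,
    stringsAsFactors = FALSE
  )
  table$rank <- seq_len(nrow(table))
  rownames(table) <- NULL
  list(
    metrics = c(auc = auc$auc, auroc = auroc_full(scores, labels), prf),
    table = table,
    auc_detail = auc, k = k, exhaustive_auc = exhaustive
  )
}

#' Repeated-run benchmark of similarity indices
#'
#' The standard evaluation protocol: in each run the observed links are split
#' afresh into training and probe sets (90/10 by default), every index is
#' evaluated on the same split, and for the temporal index the
#' conditional-probability matrix is re-estimated from that run's training
#' links only. Means and standard deviations over runs are reported per
#' index.
#'
#' @param net a `bipartite_network`; a `temporal_bipartite_network` enables
#'   the temporal split protocol and the `"TPRA"` index
#' @param indices character vector of index names ([index_names()], plus
#'   `"TPRA"` for temporal networks)
#' @param probe_fraction held-out fraction per run (default 0.1)
#' @param runs number of repetitions (default 100)
#' @param seed base seed; run r uses seed + r for its split
#' @param k precision cut-off (default: probe size)
#' @param condprob_mode,condprob_ties estimator settings for TPRA
#' @param keep_tables keep each run's ranked candidate table (memory-heavy;
#'   default keeps only the first run's tables for downstream diagnostics)
#' @inheritParams evaluate_split
#' @return an `eval_report`: list with `summary` (data frame index x metric
#'   mean/sd), `runs` (per-run long data frame), `config`, and `tables` (per
#'   index, ranked tables of the kept runs)
#' @export
run_benchmark <- function(net, indices, probe_fraction = 0.1, runs = 100,
                          seed = 1, k = NULL,
                          condprob_mode = "all_patients",
                          condprob_ties = "strict",
                          auc_max_exhaustive = 1e7, auc_samples = 1e6,
                          keep_tables = FALSE) {
  stopifnot(runs >= 1)
  temporal <- inherits(net, "temporal_bipartite_network")
  for (ix in indices) check_index(ix)
  if ("TPRA" %in% indices && !temporal) {
    stop("TPRA requires a temporal network (conditional probabilities need dates)")
  }
  detail <- list()
  tables <- list()
  for (r in seq_len(runs)) {
    sr <- seed + r
    split <- if (temporal) split_temporal(net, probe_fraction, seed = sr)
             else split_static(net, probe_fraction, seed = sr)
    tnet <- training_network(net, split)
    M <- if ("TPRA" %in% indices) {
      estimate_condprob(tnet, mode = condprob_mode, ties = condprob_ties)
    } else NULL
    for (ix in indices) {
      ev <- evaluate_split(tnet, split, ix, M = M, k = k,
                           auc_max_exhaustive = auc_max_exhaustive,
                           auc_samples = auc_samples, seed = sr)
      detail[[length(detail) + 1L]] <- data.frame(
        run = r, seed = sr, index = ix, t(ev$metrics),
        stringsAsFactors = FALSE
      )
      if (r == 1 || keep_tables) {
        tables[[ix]] <- c(tables[[ix]], list(ev$table))
      }
    }
  }
  runs_df <- do.call(rbind, detail)
  metrics <- c("auc", "auroc", "precision", "recall", "f_score")
  summary <- do.call(rbind, lapply(unique(runs_df$index), function(ix) {
    sub <- runs_df[runs_df$index == ix, , drop = FALSE]
    data.frame(
      index = ix,
      metric = metrics,
      mean = vapply(metrics, function(m) mean(sub[[m]]), 0),
      sd = vapply(metrics, function(m) if (nrow(sub) > 1) stats::sd(sub[[m]]) else 0, 0),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))
  structure(
    list(summary = summary, runs = runs_df,
         config = list(indices = indices, probe_fraction = probe_fraction,
                       runs = runs, seed = seed, k = k,
                       condprob_mode = condprob_mode,
                       condprob_ties = condprob_ties,
                       temporal = temporal,
                       auc_max_exhaustive = auc_max_exhaustive,
                       auc_samples = auc_samples),
         tables = tables),
    class = "eval_report"
  )
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d run(s), probe fraction %.2f, seed %d\n",
              x$config$runs, x$config$probe_fraction, x$config$seed))
  wide <- x$summary[x$summary$metric == "auc", ]
  for (i in seq_len(nrow(wide))) {
    cat(sprintf("  %-6s AUC %.4f +/- %.4f\n",
                wide$index[i], wide$mean[i], wide$sd[i]))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes `summary.csv` (index x metric mean/sd), `runs.csv` (per-run
#' metrics) and `report.json` (full detail including the configuration, so
#' the output is self-describing: run count, seeds, k, tie policies).
#'
#' @param report an `eval_report`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(report$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(config = report$config, summary = report$summary, runs = report$runs),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(dir)
}

#' Degree-bias diagnostic of a ranked prediction table
#'
#' Classical similarity indices tend to surface high-degree diseases first.
#' This diagnostic walks the score-ranked candidate list, keeps the correct
#' predictions (probe links), and reports for each disease the position of
#' its first correct prediction together with the disease's degree rank
#' (diseases sorted ascending by degree; rank 1 = lowest degree). A
#' degree-biased index fills the top orders with high degree ranks.
#'
#' @param table a ranked candidate table with logical `label` column, as
#'   produced by [evaluate_split()]
#' @param net the network supplying disease degrees (conventionally the full
#'   observed network)
#' @return data frame `disease`, `first_correct_order`, `degree`,
#'   `degree_rank`, ordered by `first_correct_order`; empty when nothing was
#'   predicted correctly
#' @export
degree_bias_analysis <- function(table, net) {
  correct <- table[table$label, , drop = FALSE]
  correct <- correct[order(correct$rank), , drop = FALSE]
  deg <- degrees(net, "v2")
  deg_rank <- stats::setNames(rank(deg, ties.method = "first"), names(deg))
  if (nrow(correct) == 0) {
    return(data.frame(disease = character(0), first_correct_order = integer(0),
                      degree = integer(0), degree_rank = integer(0)))
  }
  correct$order <- seq_len(nrow(correct))
  first <- correct[!duplicated(correct$target), , drop = FALSE]
  out <- data.frame(
    disease = first$target,
    first_correct_order = first$order,
    degree = as.integer(deg[first$target]),
    degree_rank = as.integer(deg_rank[first$target]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Unique-disease coverage of the top correct predictions
#'
#' Sorts the correctly predicted links of one run by score rank, keeps the
#' top `ceiling(top_fraction * C)` of the C correct predictions, and reports
#' how many distinct diseases they cover, plus how deep into the
#' degree-sorted disease list (descending; rank 1 = highest degree) the
#' covered diseases reach. Indices that only recover high-degree diseases
#' yield small counts and shallow reach.
#'
#' @inheritParams degree_bias_analysis
#' @param top_fraction fraction of correct predictions kept (0 < f <= 1;
#'   default 0.5)
#' @return list `n_unique_diseases`, `lowest_degree_rank`, `n_correct`;
#'   zero counts (with a warning) when nothing was predicted correctly
#' @export
unique_disease_coverage <- function(table, net, top_fraction = 0.5) {
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stop("parameter error: top_fraction must lie in (0, 1]")
  }
  correct <- table[table$label, , drop = FALSE]
  correct <- correct[order(correct$rank), , drop = FALSE]
  if (nrow(correct) == 0) {
    warning("no correct predictions in this run")
    return(list(n_unique_diseases = 0L, lowest_degree_rank = NA_integer_,
                n_correct = 0L))
  }
  top <- correct[seq_len(ceiling(top_fraction * nrow(correct))), , drop = FALSE]
  deg <- degrees(net, "v2")
  desc_rank <- stats::setNames(rank(-as.numeric(deg), ties.method = "first"),
                               names(deg))
  list(
    n_unique_diseases = length(unique(top$target)),
    lowest_degree_rank = as.integer(max(desc_rank[unique(top$target)])),
    n_correct = nrow(correct)
  )
}
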