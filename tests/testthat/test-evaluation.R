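test_that("static splits partition the links at the requested fraction", {
  net <- random_bipartite(20, 10, 0.5, seed = 2)
  m <- n_links(net)
  sp <- split_static(net, 0.1, seed = 4)
  expect_equal(nrow(sp$probe), round(0.1 * m))
  expect_equal(nrow(sp$train) + nrow(sp$probe), m)
  key <- function(df) paste(df$v1, df$v2)
  expect_length(intersect(key(sp$train), key(sp$probe)), 0)
  expect_length(intersect(key(sp$nonexistent), key(links_df(net))), 0)
  expect_equal(nrow(sp$nonexistent), 20 * 10 - m)
  # same seed, same split; tiny fractions are rejected
  expect_identical(split_static(net, 0.1, seed = 4), sp)
  expect_error(split_static(net, 1e-4, seed = 1), "parameter error")
  expect_error(split_static(net, 1.2, seed = 1), "parameter error")
})

test_that("temporal splits hold out each sampled patient's latest diagnosis", {
  coh <- simulate_cohort(cohort_spec(n_patients = 120, seed = 14))
  m <- n_links(coh)
  sp <- split_temporal(coh, 0.1, seed = 3)
  expect_equal(nrow(sp$probe), round(0.1 * m))
  expect_equal(length(unique(sp$probe$v1)), nrow(sp$probe))  # one link per patient
  edges <- coh$edges
  for (i in seq_len(nrow(sp$probe))) {
    pat <- sp$probe$v1[i]
    own <- edges[edges$v1 == pat, ]
    expect_equal(max(own$date), own$date[own$v2 == sp$probe$v2[i]])
  }
  # probe dates never precede the same patient's training dates
  tr <- merge(sp$train, edges)
  pr <- merge(sp$probe, edges)
  for (pat in pr$v1) {
    expect_gte(as.numeric(pr$date[pr$v1 == pat]),
               max(as.numeric(tr$date[tr$v1 == pat])))
  }
  # explicit three-year patient: the 2003 link is the probe
  toy <- temporal_bipartite_network(data.frame(
    p = c("p1", "p1", "p1", rep("p2", 4), rep("p3", 3)),
    d = c("A", "B", "C", "A", "B", "C", "D", "A", "B", "D"),
    t = c("2001-01-01", "2002-01-01", "2003-01-01",
          "2001-01-01", "2001-02-01", "2001-03-01", "2001-04-01",
          "2001-01-01", "2001-02-01", "2001-03-01")
  ))
  spt <- split_temporal(toy, 0.1, seed = 1)  # one probe link
  expect_equal(nrow(spt$probe), 1)
  pat <- spt$probe$v1
  own <- toy$edges[toy$edges$v1 == pat, ]
  expect_equal(spt$probe$v2, own$v2[which.max(as.numeric(own$date))])
})

test_that("partition and disjointness hold across many random temporal splits", {
  coh <- simulate_cohort(cohort_spec(n_patients = 80, seed = 21))
  m <- n_links(coh)
  all_key <- paste(coh$edges$v1, coh$edges$v2)
  key <- function(df) paste(df$v1, df$v2)
  for (s in 1:100) {
    sp <- split_temporal(coh, 0.1, seed = s)
    expect_setequal(c(key(sp$train), key(sp$probe)), all_key)
    expect_length(intersect(key(sp$train), key(sp$probe)), 0)
    expect_length(intersect(key(sp$nonexistent), all_key), 0)
  }
})

test_that("training networks keep all nodes but only training links", {
  coh <- simulate_cohort(cohort_spec(n_patients = 60, seed = 33))
  sp <- split_temporal(coh, 0.1, seed = 2)
  tnet <- training_network(coh, sp)
  expect_identical(tnet$v1, coh$v1)
  expect_identical(tnet$v2, coh$v2)
  expect_equal(n_links(tnet), nrow(sp$train))
  expect_true(all(as.matrix(tnet$B)[cbind(sp$probe$v1, sp$probe$v2)] == 0))
})

test_that("pairwise AUC handles perfect, tied and hand-computed configurations", {
  expect_equal(auc_pairwise(2, 1)$auc, 1)
  expect_equal(auc_pairwise(1, 2)$auc, 0)
  r <- auc_pairwise(rep(1, 5), rep(1, 7))
  expect_equal(r$auc, 0.5)
  expect_equal(r$n_tied, 35)
  expect_equal(r$n_higher, 0)
  r2 <- auc_pairwise(c(3, 1), c(2, 2, 0))
  # wins: 3>2,3>2,3>0,1>0 = 4 of 6; no ties
  expect_equal(r2$auc, 4 / 6)
  expect_error(auc_pairwise(numeric(0), 1), "evaluation error")
})

test_that("exhaustive comparison AUC equals the brute-force oracle and the rank AUROC", {
  set.seed(55)
  for (rep in 1:50) {
    mp <- sample(2:30, 1); mn <- sample(2:40, 1)
    # integer scores force plenty of ties
    sp <- sample(0:5, mp, replace = TRUE)
    sn <- sample(0:5, mn, replace = TRUE)
    a <- auc_pairwise(sp, sn)$auc
    expect_equal(a, brute_auc(sp, sn))
    expect_equal(a, auroc_full(c(sp, sn), c(rep(TRUE, mp), rep(FALSE, mn))))
  }
})

test_that("rank AUROC matches pROC and respects score reversal", {
  skip_if_not_installed("pROC")
  set.seed(77)
  scores <- runif(120)
  labels <- rbinom(120, 1, 0.3) == 1
  mine <- auroc_full(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
  expect_equal(auroc_full(-scores, labels), 1 - mine, tolerance = 1e-12)
  expect_error(auroc_full(scores, rep(TRUE, 120)), "evaluation error")
})

test_that("sampled AUC converges to the exhaustive value", {
  set.seed(91)
  sp <- runif(40); sn <- runif(300)
  exact <- auc_pairwise(sp, sn)$auc
  est <- auc_pairwise(sp, sn, n_comparisons = 2e5, seed = 10)$auc
  expect_lt(abs(est - exact), 3 * sqrt(0.25 / 2e5) + 0.01)
})

test_that("a random scorer is calibrated at AUC one half", {
  net <- random_bipartite(40, 40, 0.15, seed = 12)
  sp <- split_static(net, 0.1, seed = 12)
  S <- score_matrix(net, "RANDOM", seed = 987)  # independent of the split
  a <- auc_pairwise(S[cbind(sp$probe$v1, sp$probe$v2)],
                    S[cbind(sp$nonexistent$v1, sp$nonexistent$v2)])
  mp <- nrow(sp$probe); mn <- nrow(sp$nonexistent)
  se <- sqrt((mp + mn + 1) / (12 * mp * mn))  # Mann-Whitney null SE
  expect_lt(abs(a$auc - 0.5), 3 * se)
})

test_that("precision/recall/F behave per definition, including the tie algebra", {
  # 10 candidates, 3 positives ranked 1, 2, 4; k = 3
  scores <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, rep(FALSE, 6))
  prf <- precision_recall_f(scores, labels, k = 3)
  expect_equal(unname(prf["precision"]), 2 / 3)
  expect_equal(unname(prf["recall"]), 2 / 3)
  expect_equal(unname(prf["f_score"]), 2 / 3)  # p = r implies F = p
  # perfect ranking at k = |positives|
  perfect <- precision_recall_f(scores, c(TRUE, TRUE, TRUE, rep(FALSE, 7)), k = 3)
  expect_equal(unname(perfect), c(1, 1, 1))
  expect_error(precision_recall_f(scores, labels, k = 0), "parameter error")
  expect_error(precision_recall_f(scores, labels, k = 11), "parameter error")
  # all scores tied and no positives selected: F falls back to 0
  none <- precision_recall_f(c(1, 1), c(FALSE, TRUE), k = 1,
                             pair_ids = c("a", "b"))
  expect_equal(unname(none["f_score"]), 0)
})

test_that("benchmarks are reproducible and a single run reports zero spread", {
  coh <- simulate_cohort(cohort_spec(n_patients = 60, seed = 44))
  r1 <- run_benchmark(coh, c("CN", "PA"), runs = 1, seed = 5)
  expect_true(all(r1$summary$sd == 0))
  expect_true(all(r1$summary$mean >= 0 & r1$summary$mean <= 1))
  r2 <- run_benchmark(coh, c("CN", "PA"), runs = 3, seed = 5)
  r3 <- run_benchmark(coh, c("CN", "PA"), runs = 3, seed = 5)
  expect_identical(r2$summary, r3$summary)
  expect_true(all(r2$summary$sd >= 0))
  # every index is evaluated on the same split within a run
  expect_equal(unique(table(r2$runs$run)), 2L)
})

test_that("evaluation reports serialize with their configuration", {
  coh <- simulate_cohort(cohort_spec(n_patients = 60, seed = 44))
  rep <- run_benchmark(coh, c("CN", "TPRA"), runs = 2, seed = 5)
  d <- withr::local_tempdir()
  write_eval_report(rep, d)
  expect_true(all(file.exists(file.path(d, c("summary.csv", "runs.csv", "report.json")))))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(js$config$runs, 2)
  expect_equal(js$config$condprob_ties, "strict")
})

test_that("degree-bias and coverage diagnostics read a ranked run correctly", {
  coh <- simulate_cohort(cohort_spec(n_patients = 80, seed = 52))
  sp <- split_temporal(coh, 0.1, seed = 9)
  tnet <- training_network(coh, sp)
  ev <- evaluate_split(tnet, sp, "PRA")
  db <- degree_bias_analysis(ev$table, coh)
  expect_true(all(db$first_correct_order >= 1))
  expect_false(any(duplicated(db$disease)))
  expect_true(all(db$disease %in% coh$v2))
  # orders are positions in the correct-prediction sequence
  correct <- ev$table[ev$table$label, ]
  expect_equal(db$first_correct_order[db$disease == correct$target[1]], 1)
  cov <- unique_disease_coverage(ev$table, coh, 0.5)
  expect_lte(cov$n_unique_diseases, length(unique(correct$target)))
  expect_gte(cov$n_unique_diseases, 1)
  expect_lte(cov$lowest_degree_rank, length(coh$v2))
  # degenerate runs: a single correct prediction sits at order one
  single <- data.frame(source = "p", target = coh$v2[1], score = 1,
                       label = TRUE, rank = 1)
  expect_equal(degree_bias_analysis(single, coh)$first_correct_order, 1)
  none <- data.frame(source = "p", target = coh$v2[1], score = 1,
                     label = FALSE, rank = 1)
  expect_equal(nrow(degree_bias_analysis(none, coh)), 0)
  expect_warning(cov0 <- unique_disease_coverage(none, coh), "no correct")
  expect_equal(cov0$n_unique_diseases, 0)
})
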