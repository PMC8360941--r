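#' Estimate the disease-transition conditional-probability matrix
#'
#' From a time-stamped patient-disease network, estimates M(i, j) = Pr(a
#' patient is later diagnosed with disease j | diagnosed with disease i).
#' Two denominators are supported:
#' \describe{
#'   \item{`all_patients`}{M(i, j) = #\{patients with i at t_i and j at
#'     t_j > t_i\} / #\{patients with i\}. Low values may reflect incomplete
#'     follow-up rather than true rarity.}
#'   \item{`both_diagnosed`}{M(i, j) = #\{patients with both, t_i < t_j\} /
#'     #\{patients with both i and j\} — the probability that i preceded j
#'     among co-diagnosed patients. Without same-date ties,
#'     M(i, j) + M(j, i) = 1 whenever the denominator is positive.}
#' }
#' Same-date pairs (t_i = t_j) carry no ordering evidence; under the default
#' `ties = "strict"` they count in the denominator but not the numerator,
#' under `ties = "half"` they add 0.5 to both numerators. The diagonal is 0.
#'
#' @param net a `temporal_bipartite_network` (typically the training network
#'   of a split: estimate from training links only, never the full network)
#' @param mode `"all_patients"` or `"both_diagnosed"`
#' @param ties `"strict"` or `"half"`
#' @param smoothing additive smoothing constant added to every numerator,
#'   with the number of diseases times the constant added to denominators
#'   (default 0 = none)
#' @return an object of class `cond_prob_matrix`: list with `diseases`,
#'   `values` (|D| x |D| matrix, rows = given disease i, columns = later
#'   disease j), `numerator` and `denominator` count matrices, `mode`, `ties`
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_patients = 50, seed = 1))
#' M <- estimate_condprob(coh)
#' @export
estimate_condprob <- function(net, mode = c("all_patients", "both_diagnosed"),
                              ties = c("strict", "half"), smoothing = 0) {
  mode <- match.arg(mode)
  ties <- match.arg(ties)
  if (!inherits(net, "temporal_bipartite_network")) {
    stop("temporal error: estimate_condprob() needs a time-stamped network")
  }
  edges <- net$edges
  dis <- net$v2
  pats <- net$v1
  nd <- length(dis)
  # patient x disease matrix of diagnosis dates (NA where undiagnosed)
  Td <- matrix(NA_real_, length(pats), nd, dimnames = list(pats, dis))
  Td[cbind(edges$v1, edges$v2)] <- as.numeric(edges$date)
  num <- matrix(0, nd, nd, dimnames = list(dis, dis))
  den <- matrix(0, nd, nd, dimnames = list(dis, dis))
  for (i in seq_len(nd)) {
    ti <- Td[, i]
    has_i <- !is.na(ti)
    if (!any(has_i)) next
    Tj <- Td[has_i, , drop = FALSE]
    later <- Tj > ti[has_i]            # strictly after i
    same <- Tj == ti[has_i]
    both <- !is.na(Tj)
    n_later <- colSums(later, na.rm = TRUE)
    n_same <- colSums(same, na.rm = TRUE)
    n_both <- colSums(both)
    numer <- n_later + if (ties == "half") 0.5 * n_same else 0
    num[i, ] <- numer
    den[i, ] <- if (mode == "all_patients") sum(has_i) else n_both
  }
  diag(num) <- 0
  vals_den <- den + nd * smoothing
  vals <- ifelse(vals_den > 0, (num + smoothing) / vals_den, 0)
  diag(vals) <- 0
  structure(
    list(diseases = dis, values = vals, numerator = num, denominator = den,
         mode = mode, ties = ties, smoothing = smoothing),
    class = "cond_prob_matrix"
  )
}

#' Build a conditional-probability matrix from explicit values
#'
#' Mostly useful for tests and worked examples (e.g. an all-ones matrix
#' reduces the temporal index to the static path-based one).
#'
#' @param values square numeric matrix with entries in [0, 1] and dimnames
#'   giving the disease identifiers (or supply `diseases`)
#' @param diseases optional disease identifiers
#' @return a `cond_prob_matrix`
#' @export
cond_prob_matrix <- function(values, diseases = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("values must be square")
  if (is.null(diseases)) diseases <- rownames(values)
  if (is.null(diseases)) stop("disease identifiers required (dimnames or `diseases`)")
  diseases <- as.character(diseases)
  dimnames(values) <- list(diseases, diseases)
  if (any(values < 0 | values > 1)) stop("probabilities must lie in [0, 1]")
  structure(
    list(diseases = diseases, values = values, numerator = NULL,
         denominator = NULL, mode = "explicit", ties = NA_character_,
         smoothing = 0),
    class = "cond_prob_matrix"
  )
}

#' @noRd
align_condprob <- function(M, diseases) {
  if (!inherits(M, "cond_prob_matrix")) stop("M must be a cond_prob_matrix")
  missing <- setdiff(diseases, M$diseases)
  if (length(missing) > 0) {
    stop("coverage error: disease(s) absent from the probability matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  M$values[diseases, diseases, drop = FALSE]
}

#' Temporal path-based similarity score of one patient-disease pair
#'
#' The temporal extension of the path-based resource-allocation index: each
#' unique length-3 path p - d' - p' - d is weighted by the inverse degrees of
#' its internal nodes and by the estimated probability that disease d follows
#' disease d',
#' \deqn{S_{pd} = \sum_{paths} M(d', d) / (|\Gamma(p')| |\Gamma(d')|).}
#' With an all-ones M this reduces exactly to the static PRA index; scores
#' scale linearly in M.
#'
#' @param net a `bipartite_network` of training links (degrees and paths are
#'   taken from it)
#' @param M a `cond_prob_matrix` covering all diseases of `net` (estimated
#'   from training links)
#' @param p a patient (V1) node
#' @param d a disease (V2) node
#' @return non-negative numeric score
#' @export
score_tpra <- function(net, M, p, d) {
  p <- as.character(p); d <- as.character(d)
  if (!(p %in% net$v1)) stop("side error: ", p, " is not a V1 node")
  if (!(d %in% net$v2)) stop("side error: ", d, " is not a V2 node")
  Mm <- align_condprob(M, net$v2)
  ll <- lcl_links(net, p, d)   # rows: (p', d') links of the local community
  if (nrow(ll) == 0) return(0)
  dp <- vapply(ll$v1, function(z) degree(net, z), 0L)
  dd <- vapply(ll$v2, function(z) degree(net, z), 0L)
  sum(Mm[cbind(ll$v2, rep(d, nrow(ll)))] / (dp * dd))
}

#' Score candidate pairs with the temporal index
#'
#' Vectorised [score_tpra()] over a candidate set, mirroring [score_all()].
#'
#' @inheritParams score_all
#' @param net a `bipartite_network` of training links
#' @param M a `cond_prob_matrix` covering all diseases of `net`
#' @return data frame `source`, `target`, `score`, `index` (= "TPRA"),
#'   `rank`, plus attribute `condprob_mode` recording the matrix identity used
#' @export
score_all_temporal <- function(net, M, candidates = "nonexistent",
                               missing_only = TRUE) {
  out <- score_all(net, "TPRA", candidates = candidates,
                   missing_only = missing_only, M = M)
  attr(out, "condprob_mode") <- M$mode
  out
}

#' Write a conditional-probability matrix as CSV plus JSON sidecar
#'
#' Writes the disease-by-disease probability matrix as a labelled CSV and a
#' `<path>.meta.json` sidecar recording the estimation mode, tie policy,
#' smoothing, and the integer count matrices.
#'
#' @param M a `cond_prob_matrix`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_condprob <- function(M, path) {
  utils::write.csv(as.data.frame(M$values), path, row.names = TRUE, quote = FALSE)
  meta <- list(mode = M$mode, ties = M$ties, smoothing = M$smoothing,
               diseases = M$diseases,
               numerator = M$numerator, denominator = M$denominator)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @exportS3Method base::print
print.cond_prob_matrix <- function(x, ...) {
  cat(sprintf("<cond_prob_matrix> %d diseases, mode = %s, ties = %s\n",
              length(x$diseases), x$mode, x$ties))
  invisible(x)
}
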