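---
title: "Path-based link prediction in static and temporal bipartite networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-based link prediction in static and temporal bipartite networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biplink)
options(biplink.quiet = TRUE)
```

## The problem

Many biomedical systems are naturally bipartite: drugs interact with protein
targets, patients are diagnosed with diseases. Both kinds of data pose the
same question — given the interactions we have observed, which of the absent
pairs are most likely to be real (a missed drug–target interaction) or to
appear in the future (a patient's next diagnosis)?

`biplink` treats this as *link prediction on a bipartite network*
G = (V1, V2, E). Every candidate pair (x ∈ V1, y ∈ V2) receives a similarity
score; candidates are then ranked and the top of the ranking is read as the
prediction. Because a bipartite network has no odd cycles, two nodes on
opposite sides never share a direct common neighbour, so the unipartite
common-neighbour machinery must be rebuilt on *quadrangles*: 4-cycles
x–d′–p′–y, equivalently paths of length 3.

## The indices

Write Γ(v) for the neighbour set of v, and Γ̂(v) = ∪_{z∈Γ(v)} Γ(z) for the
two-hop (same-side) reach. The package implements three families, all local
(they look only at the neighbourhoods of the query pair, so they scale to
large sparse networks):

**Classical common-neighbour family.** The one-sided counts
CN1 = |Γ̂(x) ∩ Γ(y)| and CN2 = |Γ(x) ∩ Γ̂(y)| each count the nodes of one
side touched by quadrangles through (x, y); since the two sets live on
different sides, the bipartite common-neighbour score is their sum,
CN = CN1 + CN2. Weighted variants down-weight promiscuous intermediates:
AA divides each common neighbour z by log2 |Γ(z)|, RA by |Γ(z)| itself.
JC normalises CN by the union of the neighbourhoods, and PA = |Γ(x)|·|Γ(y)|
is the pure degree-product baseline.

**Local-community (CAR/LCL) family.** LCL counts the links *among* the
common neighbours — for a non-adjacent pair this is exactly the number of
distinct length-3 paths between x and y. CAR = CN · LCL rewards pairs whose
common neighbours are themselves interconnected; CAA and CRA weight each
common neighbour by its number of community links γ(z); CJC and CPA are the
corresponding normalised and degree-augmented forms. (CPA retains the
external-degree product ex·ey, so unlike the rest of the family it is
non-zero even when the community is empty.)

**Path-based resource allocation (PRA).** Instead of counting paths, PRA
lets every length-3 path x–d′–p′–y carry flow inversely proportional to the
degrees of its *internal* nodes:

    S_PRA(x, y) = Σ_paths 1 / (|Γ(p′)| · |Γ(d′)|).

Counting the same evidence as LCL but discounting hub-mediated routes makes
PRA both more accurate and less biased toward high-degree targets — the
degree-bias diagnostics (`degree_bias_analysis()`,
`unique_disease_coverage()`) make that bias measurable.

All indices exist in two independent implementations: literal set-based
per-pair functions (`score_pair()`) and sparse-matrix algebra over all pairs
at once (`score_matrix()`, built on the biadjacency matrix B, e.g. the
length-3 walk counts B·Bᵀ·B). The test suite asserts their agreement on
random graph batteries; scoring in bulk uses the matrix route.

### The temporal index (TPRA)

For patient–disease data with diagnosis dates, order matters: gout rarely
precedes the hypertension that predicts it. Let M(d′, d) estimate
Pr(a patient is later diagnosed with d | diagnosed with d′). The temporal
index weights every path by the transition probability of its intermediate
disease:

    S_TPRA(p, d) = Σ_paths M(d′, d) / (|Γ(p′)| · |Γ(d′)|).

Two exact reductions pin the definition down: M ≡ 1 recovers PRA, and TPRA
is linear in M. Both are asserted in the tests.

`estimate_condprob()` estimates M by counting, per ordered disease pair,
patients diagnosed with d′ strictly before d. Two denominators are offered:
`all_patients` (all carriers of d′; conservative, deflated by incomplete
follow-up) and `both_diagnosed` (only co-diagnosed patients; without
same-date ties the matrix then satisfies M(i,j) + M(j,i) = 1). Same-date
pairs carry no ordering evidence, so by default they count in denominators
only (`ties = "strict"`); `ties = "half"` splits them. The diagonal is zero,
and no path can use d′ = d for a non-adjacent candidate anyway. M is always
estimated from *training* links only — estimating it from the full network
would leak the very links being predicted.

## Evaluation protocol

`split_static()` partitions the observed links uniformly into 90% training /
10% probe (both configurable); `split_temporal()` emulates forecasting by
sampling patients and holding out each sampled patient's *latest* diagnosis
(so no probe link predates a training link of the same patient; ties on the
latest date are broken by smallest disease id, and only patients with at
least two links are sampled so nobody becomes untrainable). Negatives are
always E′ = U \ E, the pairs absent from the *full* network.

Two AUC routes are implemented independently and cross-checked: the
comparison estimator AUC = (n′ + 0.5 n″)/n over probe-vs-nonexistent score
comparisons (exhaustive when |E^P|·|E′| ≤ 10⁷, else 10⁶ sampled
comparisons), and the rank-based AUROC with midrank ties, which the tests
also verify against `pROC`. With midrank ties the exhaustive comparison AUC
and the AUROC are the same number; reported tables carry both columns.
Precision, recall and F = 2pr/(p+r) are computed at a cut-off k defaulting
to the probe size. `run_benchmark()` repeats the whole procedure (fresh
split per run, same split shared by all indices, M re-estimated per run) and
reports mean ± sd per index.

Determinism: every stochastic step takes a seed; run r of a benchmark uses
seed + r. Within a run, the scorer and the sampled-comparison stream use
sub-seeds offset from the split's seed — a random scorer sharing the split's
exact seed turns out to be correlated with the probe selection through the
shared RNG stream, which would break the AUC ≈ 0.5 null calibration.
Ranking ties are broken by pair id, so reports are bit-reproducible.

## The synthetic cohort generator

Real multimorbidity registries are access-restricted, so the package ships a
generative stand-in, `simulate_cohort()`. Per patient and time step, each
undiagnosed disease j is acquired with probability
1 − (1 − b_j) · Π_{i∈current} (1 − T(i, j)): a per-step baseline prevalence
b_j plus independent planted transition hazards from the diseases already
present. Acquisitions are dated on a per-patient counter (same-step
acquisitions get consecutive dates in disease-id order; a `same_day` mode
produces genuine ties to exercise the tie policy). Patients with fewer than
`min_conditions = 4` diagnoses are dropped, mirroring the standard
multimorbidity filter.

Defaults were chosen once to resemble reported registry cohort shapes: 20 diseases,
10 steps, baseline prevalence declining geometrically from 0.02 to 0.0025
(heterogeneous prevalence, as in real registries), chain transitions
T(i, i+1) = 0.3 (0.5 in `strong_transition_spec()`), giving a mean filtered
patient degree near 6 — comparable to the 5–5.6 of large registries. The
generator logs the *realized* conditional frequencies of the retained
cohort, computed from its own event sequence in the emitted ordering, and
`estimate_condprob()` recovers them from the written dates; at 5000 patients
the two agree to well within 0.05.

What the generator does *not* emulate: demographic covariates, mortality and
censoring, calendar-time effects, coding noise, and the heavy-tailed disease
prevalence of ICD-coded data. Passing benchmarks on synthetic cohorts
therefore demonstrates correctness of the machinery and the expected
*ordering* of methods under planted signal (e.g. TPRA above the degree-only
PA baseline), not clinical performance on any real registry.

## A worked example

The package ships the small illustration network used throughout the
documentation — five patients a–e, three diseases 1–3, eleven links:

```{r}
net <- make_fig1_fixture()
net
cn_sets(net, "e", "1")
enumerate_paths3(net, "e", "1")
score_pair(net, "CN", "e", "1")
score_pair(net, "PRA", "e", "1")   # (1/8 + 1/12 + 1/12 + 1/8) = 5/12
```

Adding the link (a, 3) creates a fifth e–1 path while leaving the CN score
untouched — path counts see structure that neighbour counts miss:

```{r}
plus <- add_link(net, "a", "3")
nrow(enumerate_paths3(plus, "e", "1"))
score_pair(plus, "CN", "e", "1")
```

And a small end-to-end temporal benchmark:

```{r}
coh <- simulate_cohort(strong_transition_spec(n_patients = 300, seed = 7))
run_benchmark(coh, c("CN", "PA", "PRA", "TPRA"), runs = 5, seed = 7)
```

## Numerical and design notes

* **Zero-degree guards.** A common neighbour always has degree ≥ 2 for a
  non-adjacent pair (it touches one endpoint and an internal path node), so
  1/log2|Γ(z)| is finite wherever it is used; the matrix route guards the
  degree-1 case anyway because it also fills entries for adjacent pairs,
  which evaluation never consumes.
* **Adjacent pairs and walk counts.** B·Bᵀ·B counts walks; for adjacent
  pairs walks may revisit an endpoint, so the path/walk identity is stated
  (and tested) for non-adjacent pairs only — exactly the pairs scored during
  evaluation.
* **Bipartite CAR-family forms.** The bipartite JC/RA/CAR/CAA/CRA/CJC/CPA
  variants follow the local-community conventions of the drug–target
  link-prediction literature; each formula lives in one small documented
  branch of `score_pair()`, so swapping a convention is a one-line change.
* **Problem sizes.** The shipped tests run on graphs of ≤ 30 nodes for
  exhaustive identities, 100-split protocol checks, a 5000-patient cohort
  for parameter recovery, and a 500-patient / 20-run benchmark for the
  ordering experiment — sizes at which every check is exact or
  Monte-Carlo-stable while the whole suite stays fast.
* **Known limitations.** No global indices (Katz, SimRank), no embeddings,
  no weighted or multi-edge networks, no unipartite projections. The
  temporal model conditions on single intermediate diseases (pairwise
  transitions), not on full disease histories.
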