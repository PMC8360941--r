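# biplink

Link prediction for static and temporal **bipartite networks**, aimed at
biomedical screens: which absent drug–target pairs are probably real
interactions, and which disease will a multimorbid patient be diagnosed with
next?

A bipartite network G = (V1, V2, E) links two disjoint node sets (drugs and
targets; patients and diseases). Opposite-side nodes never share a direct
common neighbour, so `biplink` scores a candidate pair (x, y) from the
**quadrangles** (length-3 paths x–d′–p′–y) around it:

* classical bipartite local indices — one-sided counts CN1 = |Γ̂(x)∩Γ(y)|
  and CN2 = |Γ(x)∩Γ̂(y)|, their sum CN, plus JC, AA, RA and the degree
  baseline PA = |Γ(x)|·|Γ(y)| (Γ̂ is the two-hop same-side reach);
* the local-community family — LCL (links among the common neighbours,
  equal to the number of distinct length-3 paths for a non-adjacent pair),
  CAR = CN·LCL, CAA, CRA, CJC, CPA;
* **PRA**, path-based resource allocation, which lets each path carry flow
  inversely proportional to its internal-node degrees,
  `S_PRA(x,y) = Σ_paths 1 / (|Γ(p′)|·|Γ(d′)|)`;
* **TPRA**, the temporal extension for time-stamped diagnoses: each path is
  additionally weighted by the estimated conditional probability
  M(d′, d) = Pr(diagnosed with d later | diagnosed with d′),
  `S_TPRA(p,d) = Σ_paths M(d′,d) / (|Γ(p′)|·|Γ(d′)|)`,
  with M estimated from training links only (`estimate_condprob()`).

Around the indices sits the standard evaluation stack: random 90/10
train/probe splits, a leave-latest-diagnosis-out temporal split, the
comparison AUC `(n′ + 0.5 n″)/n`, rank-based AUROC, precision/recall/F at a
cut-off, repeated-run benchmarking with mean ± sd, degree-bias diagnostics,
and a synthetic multimorbidity cohort generator with planted
disease-transition structure.

## Worked example

The package ships a small illustration network (five patients a–e, three
diseases 1–3, eleven links) whose scores can be checked by hand:

```r
library(biplink)
net <- make_fig1_fixture()
enumerate_paths3(net, "e", "1")
#>   source via_v2 via_v1 target
#> 1      e      2      a      1
#> 2      e      2      b      1
#> 3      e      3      b      1
#> 4      e      3      d      1
score_pair(net, "CN", "e", "1")   # 3 V1-side + 2 V2-side common neighbours
#> [1] 5
score_pair(net, "PRA", "e", "1")  # 1/8 + 1/12 + 1/12 + 1/8
#> [1] 0.4166667
score_all(net, "PRA")             # rank all four missing pairs
#>   source target     score index rank
#> 1      a      3 0.6111111   PRA    1
#> 2      d      2 0.6111111   PRA    2
#> 3      c      1 0.4166667   PRA    3
#> 4      e      1 0.4166667   PRA    4
```

Four length-3 paths connect e and 1; PRA discounts the two paths through
the degree-3 hub b, giving 5/12. Adding the link (a, 3) creates a fifth
path while CN stays at 5 — path counts see structure that neighbour counts
miss.

A temporal benchmark on a synthetic cohort with strong planted transitions:

```r
coh <- simulate_cohort(strong_transition_spec(n_patients = 300, seed = 7))
run_benchmark(coh, c("CN", "PA", "PRA", "TPRA"), runs = 5, seed = 7)
#> <eval_report> 5 run(s), probe fraction 0.10, seed 7
#>   CN     AUC 0.7090 +/- 0.0051
#>   PA     AUC 0.5858 +/- 0.0065
#>   PRA    AUC 0.7747 +/- 0.0053
#>   TPRA   AUC 0.9046 +/- 0.0082
```

The degree-only baseline PA barely beats chance, the path-based PRA uses the
quadrangle structure, and TPRA adds the planted temporal signal on top. Each
run draws a fresh leave-latest-out split, evaluates every index on the same
split, and re-estimates the conditional probabilities from that run's
training links.

## Command line

A thin CLI wraps the same functions (installed at
`system.file("cli", "biplink", package = "biplink")`):

```sh
biplink stats    --network edges.tsv
biplink score    --network edges.tsv --index PRA --out scores.csv
biplink condprob --network diagnoses.tsv --mode both_diagnosed --out M.csv
biplink evaluate --network diagnoses.tsv --temporal \
                 --indices CN,PA,PRA,TPRA --runs 100 --probe 0.1 --seed 7 --out report/
biplink simulate --patients 500 --seed 7 --out diagnoses.tsv
```

Inputs are two-column (static) or three-column `source,target,date`
(temporal) edge lists, or the labelled dense 0/1 adjacency TSV used by the
classical drug–target benchmarks (`read_bipartite_adjacency()`).

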