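# specdiv

Entropy-based analysis of **annotated directed networks** — networks whose
nodes carry categorical labels, such as synapse-level connectomes annotated
with cell classes, cell types or developmental lineages. The package is
aimed at network neuroscientists and, more generally, at anyone asking
which nodes of a labeled directed network sit next to *diversely
specialized* connectivity channels.

## The measure

Each node gets an annotation connectivity vector: the proportion of its
incoming (or outgoing) edge weight landing on each label,

ν<sub>ij</sub> = Σ<sub>z</sub> a<sub>iz</sub> b<sub>zj</sub>,  ρ<sub>ij</sub> = ν<sub>ij</sub> / Σ<sub>j'</sub> ν<sub>ij'</sub>,

whose Shannon entropy S<sub>i</sub> = −Σ<sub>j</sub> ρ<sub>ij</sub> ln ρ<sub>ij</sub>
(nats) measures specialization: 0 when all connectivity hits one label,
ln M when it is spread over all M labels. For a set of N such vectors the
**specialization-diversity** is

ΔS = S(p̄) − S̄,

the entropy of the mean vector minus the mean entropy. Jensen's inequality
guarantees ΔS ≥ 0, and ΔS is large only when the vectors are individually
specialized *in diverse labels*. Two directed two-hop motifs give per-node
scores: the **distributive** ΔS<sup>D,out</sup> over the out-vectors of a
node's downstream partners, and the **integrative** ΔS<sup>U,in</sup> over
the in-vectors of its upstream partners. Nodes ranking highest by their sum
are **entropic hubs** — which are generally *not* the highest-degree nodes.

The package also provides:

* pairwise **entropic distances** in the (ΔS<sup>D,out</sup>, ΔS<sup>U,in</sup>)
  plane with three randomized null models (side-preserving pairs,
  stratum-preserving groups, all-by-all) and two-sample Kolmogorov–Smirnov
  tests aggregated over seeded realizations;
* a seeded **synthetic generator** of annotated networks with planted
  diverse hubs, planted same-specialization controls and mirrored
  left–right pairs, used as the package's fixture source and
  parameter-recovery testbed;
* TSV input/output for edge lists, annotation tables, score tables and
  test results, plus a thin command-line interface
  (`inst/cli/specdiv.R` with subcommands `compute`, `hubs`, `nulltest`,
  `simulate`, `plot`).

## Worked example

```r
library(specdiv)

sim    <- generate_network(synthetic_spec(n_nodes = 80,
                                          mirror_fraction = 0.2,
                                          seed = 11))
scores <- specdiv(sim$network)
rank_entropic_hubs(scores, k = 5)
#>   rank   node_id   ds_u_in ds_d_out   ds_sum degree normalized_degree
#> 1    1     hub02 1.5043346 1.834306 3.338641     14         0.8235294
#> 2    2     hub01 1.6244887 1.258904 2.883393     17         1.0000000
#> 3    3     hub03 1.4241897 1.296990 2.721179     15         0.8823529
#> 4    4     bg059 1.0863522 1.349480 2.435833      7         0.4117647
#> 5    5 hub01_d02 0.9814452 1.098612 2.080058      6         0.3529412

run_null_test(scores, group_col = "pair_id",
              null_kind = "side_preserving", side_col = "side",
              realizations = 10, seed = 17)
#> Entropic-distance null-model test
#>   grouping: pair_id   null: side_preserving
#>   observed pairs: 9   null sample: 90 (10 realizations, pooled)
#>   KS statistic: 0.9778   p-value: 3.212e-07
#>   seed: 17
```

The three planted diverse hubs (`hub01`–`hub03`) take the top ranks: each
is surrounded by partners individually specialized in six distinct labels,
so both motif scores approach ln 6 ≈ 1.79 nats. The null test shows that
mirrored left–right pairs are far more similar in their score vectors than
random cross-side pairs (KS statistic 0.98, p ≈ 3×10⁻⁷).

For real data, load a `source,target,weight` edge table and a
`node_id,label,…` annotation table with `read_annotated_network()`, then
call `specdiv()` on the result. See the vignette
(`vignettes/specialization-diversity.Rmd`) for the model, conventions,
null-model details and limitations.

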