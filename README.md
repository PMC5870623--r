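# domctx

Directional domain-context scoring and optimal selection for protein
domain prediction.

## What problem this solves, and for whom

Profile-HMM domain searches (HMMER3 `hmmscan` against a Pfam-style family
library) score every candidate domain independently, and curated bit-score
thresholds then accept or reject each match on its own. But domains
co-occur in proteins with strong *order* preferences, and a borderline
match sitting in a familiar ordered combination is far more believable
than the same match in isolation. `domctx` is for anyone annotating
protein sequences with Pfam-style domains who wants to rescue weak-but-
consistent matches and suppress implausible combinations, without giving
up exactness or reproducibility.

Given a permissive `hmmscan --domtblout` run, per-family thresholds and a
directed family-pair count network, the package selects, for each protein,
the conflict-free candidate subset `D'` maximizing

    sum_{i in D'} (H_i - T^d_{F_i})  +  sum_{i<j in D'} S_{F_i,F_j}  -  sum_{F in D'} Ttilde_F

where `H_i` is the per-domain bit score, `T^d` the family's gathering
threshold, `Ttilde_F = T^s_F - T^d_F` the sequence-threshold surcharge,
and `S_{i,j} = log2( p(F_i,F_j) / (p(F_i) p(F_j)) )` the *directional*
context score of family `F_i` occurring before `F_j`, estimated from the
count network with a symmetric Dirichlet prior (`alpha = 1e-3`) over all
`n^2` ordered pairs. Every ordered pair contributes, not just adjacent
ones. Candidates conflict when they overlap by more than 40 residues or
half the shorter range (nesting-whitelisted family pairs excepted).

The optimum is found exactly: iterative **positive elimination** prunes
candidates that cannot help any solution, a provably-safe **trivial
shortcut** returns clean survivor sets directly, and remaining cases are
solved as an **integer linear program** (tight AND-constraint
linearization, greedy clique-cover conflict rows) by a built-in exact
branch-and-bound. A brute-force oracle, a first-order Markov scorer, the
Standard Pfam baseline filter, a macro-averaged FDR estimator with
reversed-sequence decoy labeling, and a seeded synthetic-instance
generator round out the toolkit.

## Worked example

```r
library(domctx)

# context scores from a directed count network: 2 families, c(A,B) = 8
cc <- load_context_counts(c("A\tB\t8"))
m  <- context_model(cc, families = c("A", "B"), alpha = 1)
pair_score(m, "A", "B")   # 1.584963  = log2(3): A-before-B is rewarded
pair_score(m, "B", "A")   # -1.584963 = the unobserved-pair penalty

# a seeded synthetic instance: 6 candidates, 6 families
inst <- generate_instance(k = 6, seed = 11)
sol  <- predict_domains(inst$candidates, inst$meta, inst$model)
sol
#> domain_solution: 3 domain(s), objective = 13.600705 bits, status = optimal
#>   family_id ali_start ali_end bitscore
#> 4    FAM006         6     120     34.8
#> 2    FAM006       130     196     34.9
#> 5    FAM006       197     285     27.4
sol$diagnostics[c("k_in", "k_survivors", "nodes")]
#> $k_in        [1] 6
#> $k_survivors [1] 4
#> $nodes       [1] 10
```

Positive elimination cut 6 candidates to 4, and the ILP picked three
non-overlapping repeats of `FAM006`. Note the third repeat scores 27.4
bits, *below* its family threshold of 29.5: its two `FAM006 -> FAM006`
self-pair context terms pay the 2.1-bit deficit with room to spare —
exactly the rescue the model exists for. The objective, 13.6 bits, is the
total selection log-odds versus the null model; the brute-force oracle
returns the same value:

```r
brute_force(inst$candidates, inst$meta, inst$model)$objective
#> [1] 13.6007
```

## Command line

```sh
# simulate a dataset, then run the pipeline on it
Rscript -e 'domctx::cli_main()' sim --seed 7 --out-prefix world --n-proteins 4 --k 7
Rscript -e 'domctx::cli_main()' run --hits world.domtbl.txt --meta world.meta.tsv \
    --counts world.counts.tsv --pvalue 1e-4 --out predictions.tsv

# build a count network from ordered architectures; estimate an FDR
Rscript -e 'domctx::cli_main()' net --arch architectures.tsv --out counts.tsv
Rscript -e 'domctx::cli_main()' fdr --labels labeled.tsv
```

Defaults mirror practical use: candidates from
`hmmscan --F1 1e-1 --F2 1e-1 --F3 1e-2 -Z 1 --domZ 1 -E 1e-4 --domE 1e-4`
(E-value columns are then P-values; pass `--z` otherwise), a 1e-4
candidate P-value ceiling, 40-residue / 50% overlap thresholds on envelope
coordinates, `--alpha 1e-3`. `--with-standard-pfam` pools the curated
baseline selections into the candidate set; `--gff3` adds a GFF3 export.

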