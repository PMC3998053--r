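# molmorph

Systematic chemical space exploration by **molecular morphing** in R.

Given a start molecule *M<sub>S</sub>* and a target molecule
*M<sub>T</sub>* — typically two compounds active at the same receptor —
molmorph searches for a connected path of chemically valid molecules
between them. Each search iteration applies small random structural edits
("morphing operators": add/remove atom, add/remove bond, mutate atom,
bond reroute, bond contraction, interlay atom) to the current generation
of molecules, keeps only valence-correct, connected, filter-passing
products, and probabilistically admits those closest to the target into
the next generation. The molecules on and around the resulting path form
a focused virtual library for downstream screening.

The scoring distance is `1 − s(fp(m), fp(M_T))`, by default the Tanimoto
coefficient `s(a,b) = |a∧b| / |a∨b|` on radius-2 circular (Morgan-type)
fingerprints folded to 2048 bits. Products are sorted by distance; the
best *K* are accepted outright and the product at sorted rank *r > K* is
accepted with probability `exp(−λ(r−K)/K)`, up to a per-iteration cap.
Candidates that repeatedly fail to produce accepted offspring are
discarded with their subtrees (a tabu list prevents re-admission), unless
they lie on the lineage of the current best molecule. Optional decoy
molecules reshape the landscape: with decoys the score becomes
`(d_target + min_k d_decoy_k)/2`. Morphs can be filtered by molecular
weight (default ≤ 500 Da) and by a synthetic-accessibility score
(1 = easy … 10 = hard; default threshold 6).

The package also provides exhaustive neighbourhood generation around a
molecule of interest, 2D maps of the explored space (PCA of fingerprint
space and a Kamada–Kawai embedding of the pairwise distance matrix), SDF
and SMILES+ID pair-file I/O, a repeated-run benchmark harness, a
synthetic start/target pair generator with replayable operator traces,
and a batch command-line interface.

## Worked example

Build a synthetic pair three edits apart from propranolol and let the
explorer find a path back:

```r
library(molmorph)

pair <- make_synthetic_pair("CC(C)NCC(O)COc1cccc2ccccc12", k = 3, seed = 42)
pair$start$canonical_form    # "OC(COc1cccc2c1cccc2)CNC(C)C"
pair$target$canonical_form   # "OC(COc1c(C)ccc2c1cccc2)CNC(C)C"
round(pair$similarity, 3)    # 0.652  (Morgan/Tanimoto)

cfg <- exploration_config(n_gen_per_parent = 30, accept_best = 15,
                          accept_cap = 30, idle_threshold = 3, seed = 7)
res <- run_exploration(pair$start, pair$target, cfg, verbose = TRUE)
#> iter 1: candidates 1, generated 30, filtered 19, accepted 19, pruned 0, best 0.3404
#> iter 2: candidates 19, generated 570, filtered 356, accepted 27, pruned 0, best 0.2128
#> iter 3: candidates 37, generated 1110, filtered 747, accepted 30, pruned 0, best 0.0000

print(res$path)
#> <morphing_path> 4 molecules, 3 operators, complete
#> OC(COc1cccc2c1cccc2)CNC(C)C
#>  [MA] OC(COc1cccc2c1cccc2)CNC(N)C
#>  [AA] OC(COc1c(C)ccc2c1cccc2)CNC(N)C
#>  [MA] OC(COc1c(C)ccc2c1cccc2)CNC(C)C
```

Each verbose line reports, per iteration: the number of candidate
parents, morphs generated, morphs surviving dedup + filters, morphs
accepted into the next generation, molecules pruned, and the best
distance to the target so far. Here the target (an aryl-methylated
analogue) is reached in 3 iterations after exploring 77 unique molecules;
`validate_path(res$path)` replays every recorded edit and confirms the
chain. `write_sdf(res$path$molecules, "path.sdf")` exports the path.

The same job from a shell:

```sh
Rscript inst/scripts/molmorph.R run \
  --start "CC(C)NCC(O)COc1cccc2ccccc12" \
  --target "CC(C)NCC(O)COc1ccc(C)c2ccccc12" \
  --seed 7 --out results/
```

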