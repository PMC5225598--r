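# pocketmotif

Structural classification of RNA-binding pockets on protein surfaces.

RNA-binding proteins recognize their partners through surface pockets —
solvent-open concavities of roughly ten residues. Pockets with similar 3D
residue arrangements bind RNA in proteins that share neither sequence nor
global fold, and the pocket residues appear in no consistent order along
the chain. `pocketmotif` is for structural bioinformaticians who want to
find these recurring local arrangements: it aligns pockets without
sequence-order constraints, calibrates the significance of the similarity
scores, clusters pockets into structural groups over a similarity network,
and condenses each group into a consensus alignment and sequence/structure
motif profile.

## The method

Two pockets are aligned by alternating an optimal one-to-one residue
assignment (minimum-cost linear assignment on squared distances, pairs
beyond 5 Å forbidden — maximal correspondence first, then minimal squared
distance) with a least-squares Kabsch superposition, from a deterministic,
rigid-motion-covariant set of rotation seeds. The converged alignment is
scored by

    Q = N_align^2 / ((1 + (RMSD/R0)^2) * N1 * N2),   R0 = 3 Å

in [0, 1]. Because random small pockets align deceptively well, raw Q is
never thresholded: the null distribution of Q over random background pocket
pairs is fitted by a generalized extreme value law, and significance is its
survival value

    P(s > x) = 1 - exp(-[1 + k (x - mu) / sigma]^(-1/k)).

Pocket pairs with P < 0.05 become edges of a similarity network, which is
decomposed by greedy modularity maximization into pocket groups. Each
group's pockets are then jointly aligned by maximizing the number of
pairwise-aligned residue pairs consistent with a set of consensus columns
(max Σ δ_ijkl·x_ikc·x_jlc under one-to-one constraints; greedy seed triple
+ maximum-weight matching + iterative refinement), yielding per-column
residue frequencies, occupancies and RNA-binding ratios. Hypergeometric /
EASE enrichment of annotation terms and a protein-level network with a
pocket↔protein correspondence table complete the pipeline. A synthetic
generator (pocket families with planted structure, toy protein–RNA
complexes with planted contacts, planted-partition graphs) makes every
stage testable offline; see the vignette in `vignettes/` for the full
methods account.

## Worked example

```r
library(pocketmotif)

# a synthetic study set: 3 pocket families x 8 noisy permuted copies,
# 10 unrelated pockets mixed in, plus a separate calibration background
fam        <- make_family_set(family_spec(n_templates = 3, members_per_template = 8,
                                          n_background = 10, seed = 42))
background <- make_background(120, seed = 4242)

res <- run_pipeline(fam$pockets, background, "demo_run",
                    pipeline_config(n_pairs = 5000, seed = 42))

res$model
#> CalibrationModel (mle, n = 5000): k = -0.1890, mu = 0.56045, sigma = 0.04644, KS = 0.0193
res$net
#> SimilarityNetwork: 34 nodes, 94 edges (alpha = 0.05)
res$groups[[1]]
#> PocketGroup 1 (major): 11 members, representative FAM1:5:A
res$profiles[["1"]]
#> MotifProfile: 10 columns, consensus GNNEQWRSRF
```

The calibration says random background pockets score Q ≈ 0.56 ± 0.05 —
small point clouds align deceptively well, which is why significance, not
raw Q, draws the edges. The 34 network nodes are the pockets with at least
one alignment computed; the three planted families come back as the three
major groups (the 11-member group is one complete 8-member family plus
three unrelated pockets attached through chance edges — the expected cost
of an uncorrected α = 0.05), each with its highest-degree representative
and a 10-column motif profile. A single pair looks like:

```r
align_pockets(fam$pockets[[1]], fam$pockets[[2]])
#> AlignmentResult FAM1:1:A vs FAM1:2:A: n_align 10/10,10  rmsd 0.687 A  Q 0.9502
p_value(0.9502, res$model)
#> [1] 0
```

All ten residues match at sub-Å RMSD despite the random residue
permutation and rigid motion applied by the generator; Q = 0.95 is far
above the null's upper support endpoint, so its survival probability
underflows to exactly 0.

`run_pipeline()` writes every intermediate table (pockets, alignments,
EVD parameters, edge list, groups, per-group consensus / profile /
sequences) plus a manifest with the resolved configuration and file
checksums into the run directory.

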