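# apophore

Receptor-based pharmacophore generation and virtual-screening evaluation in R.

Pharmacophore-based virtual screening ranks candidate molecules by how well
their chemical features (hydrogen-bond donors and acceptors, charged centres,
hydrophobic and aromatic groups) superimpose onto an abstract model of what a
binding site requires. Most tools derive that model from a bound ligand, which
fails for apo structures and ties the model to one observed binding mode.
`apophore` builds the model from the **receptor alone**: it scans chemical
probes over a binding-pocket grid, filters the resulting hot spots, projects
complementary interaction sites from the pocket residues using SP2/SP3
hybridization geometry, detects pocket-facing aromatic rings, and merges the
evidence into a compact six-type pharmacophore. A triangle-hash matcher and
ROC/enrichment metrics close the loop for screening evaluation. The package is
aimed at computational chemists prototyping structure-based screening
workflows and at method developers who need a transparent, fully scriptable
reference pipeline.

## Method

Given a pocket grid (from any cavity-detection program, or the built-in
synthetic generator), the pipeline is:

1. **Probe map.** Five probe types (HBD, HBA, positive, negative,
   hydrophobic) are scored at every lattice point against complementary
   receptor atoms with a distance-damped Gaussian well centred at the ideal
   contact distance, combined across atoms into a score in [0, 1].
2. **pt1 filter.** Per probe type: scores below a threshold are zeroed
   (0.15 for HBD/HBA, 0.2 hydrophobic, 0.5 for the charges); points without
   strictly more than 30/30/40/5/5 same-type nonzero neighbours are dropped;
   the survivors are reduced by greedy non-maximum suppression with a 2.5 Å
   radius to representative points **pt1**.
3. **Hybridization projection (pt2).** Every donor/acceptor/charged atom of
   the pocket residues projects candidate interaction sites at distance
   `d + e` along its ideal lone-pair / hydrogen directions (SP2: in-plane at
   120°; SP3: tetrahedral fan). The hydrogen-bond action scope is a cone with
   base radius `c = 1.5` Å and reach `e = 2.0` Å, giving a maximal half-angle
   `C = atan(c/e) ≈ 37°` and a minimal D−H···A angle `B = 180° − C ≈ 143°`.
4. **Aromatic features.** A hydrophobic pt1 point with ≥ 6 aromatic atoms
   within 4.5 Å, whose nearest ring has its normal oriented into the pocket,
   additionally becomes an aromatic feature.
5. **Merge (pt3/pt4).** A polar pt1 point survives only if a same-type pt2
   site lies within 3 Å; survivors keep the probe-map position and score and
   gain the projected direction. The final model **pt4** is the merged polar
   set plus the hydrophobic and aromatic features.

Screening uses triangular hashing: feature triples are indexed
by type and binned side lengths, compatible triples seed a Kabsch
superposition, matches are extended greedily and refined, and a ligand scores
`n_matched / n_model_features`. Libraries are summarised by ROC AUC and
enrichment factors `EF = (Hits_sampled / N_sampled) × (N_total / Hits_total)`.

## Worked example

```r
library(apophore)

toy <- make_toy_pocket(seed = 1)      # synthetic pocket, six planted environments
model <- pharmacophore(toy$structure, toy$grid)
model
#> <pharmacophore> 55 features (HBD: 11, HBA: 8, POS: 7, NEG: 5, HYDROPHOBIC: 23, AROMATIC: 1)

compact <- prune_model(model, 1)      # strongest feature per type
coef(compact)[, c("type", "x", "y", "z", "score", "provenance")]
#>          type    x    y    z score provenance
#> 1         HBD -5.5 -1.5 -0.5     1     MERGED
#> 2         HBA -0.5  5.0  1.0     1     MERGED
#> 3         POS -4.5 -0.5 -3.0     1     MERGED
#> 4         NEG -0.5  4.5  1.5     1     MERGED
#> 5 HYDROPHOBIC  0.0 -0.5  4.5     1        PT1
#> 6    AROMATIC  0.0 -0.5  4.5     1   AROMATIC

fx <- make_screening_fixture(compact, n_active = 20, n_decoy = 100,
                             noise_sd = 0.3, seed = 7)
scores <- predict(compact, c(fx$actives, fx$decoys))
evaluate_screen(scores, fx$labels)
#> <enrichment_report> 20 actives / 120 molecules; AUC = 1.000
#>   EF@1% = 6.00 (2 of 2 sampled)
#>   EF@2% = 6.00 (3 of 3 sampled)
#>   EF@5% = 6.00 (6 of 6 sampled)
```

The six features recover the six planted residue environments (His donor and
acceptor, Asp carboxylate → positive site, Arg guanidinium → negative site,
Leu hydrophobic fork, inward-facing Phe ring → hydrophobic + aromatic). An
AUC of 1.0 means every jittered active outranks every shuffled decoy; EF@5% =
6 is the maximum attainable at a 1:5 active:decoy ratio (the top 6 of 120 are
all active). Models serialize to versioned JSON (`write_model`/`read_model`)
and to a LigandScout-style PML export.

A command-line front end with `generate`, `screen`, `eval` and `fixtures`
subcommands is installed at `inst/scripts/apophore`.

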