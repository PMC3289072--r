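# groovepred

Predicting **where** and **in which orientation** double-stranded DNA binds
on a protein structure, from the structure alone.

## The problem

DNA-binding proteins recognise their targets through side chains that
protrude into the major or minor groove of the double helix.  When no
co-crystal structure is available, the binding geometry — which surface
patch binds, where the DNA duplex runs, where individual bases sit — is
unknown, and docking tools need exactly this information as a starting
point.  `groovepred` implements a knowledge-based geometric method that
answers three questions for a query protein structure (bound or unbound)
plus a list of conserved residues:

1. **Which residues form the DNA-binding unit (DBU)?**  Conserved residues
   with relative solvent accessibility (RSA) > 0.25 are clustered at the
   atom level (Euclidean metric, average linkage, merging cut at 11 Å —
   about three successive bases along a groove).  A cluster is accepted as
   a DBU when its summed DNA-binding propensity exceeds the expectation
   `|cluster| × mean propensity`, where the per-type propensity learned
   from training complexes is

   ```
   propensity(a) = #{residues of type a with distance to DNA < 4.5 Å}
                   ─────────────────────────────────────────────────
                   #{residues of type a}
   ```

2. **In which direction does the groove run?**  Three representative atoms
   per DBU residue (the type's highest-propensity contact atom, CA, and C)
   are pooled and the first principal component of their covariance is
   reported as the tangent direction of the bound groove, an undirected
   line.

3. **Where do the bases sit?**  From training complexes, every
   (amino-acid type *a*, base type *b*) combination gets a geometric model
   `M[a–b]`: the atom clouds of all type-*b* nucleotides seen within 4 Å of
   a binding residue of type *a*, expressed in a canonical residue-local
   frame built from the type's top-3 contact atoms (80 models total).
   Around a DBU these clouds are mapped back into query coordinates and a
   candidate position **x** is scored by a Gaussian density

   ```
   P_b(x) = Σ_{r ∈ DBU} (1 / n_aa(r)) Σ_{i placed via r} exp(−‖x − y_i‖² / 2σ²)
   ```

   Candidates falling into the protein core are removed (a Gaussian sum
   over query CA atoms, keeping low-score placements until the first one
   closer than 2 Å to the protein), survivors are thinned greedily so that
   kept placements differ by RMSD > 5 Å, and the highest-density placement
   is the predicted base location.

Evaluation against a reference complex follows the same conventions as the
method's original benchmark: location error is the distance to the nearest
base centroid (failure when > 6 Å), and the reference groove tangent is the
chord of backbone phosphates — P(i−3)→P(i−4) for a major-groove site at
base pair *i*, P(i)→P(i+1) for a minor-groove site, the better of the two
strands — with success when the cosine to the prediction exceeds 0.9
(≈ 25°).

Because the original training corpus (170 complexes) and the external
conservation web tool are not reproducible offline, the package ships a
first-class synthetic-data module: an ideal B-DNA generator (3.38 Å rise,
36° twist, phosphate backbone, planar base templates) with DBUs planted in
a chosen groove at known ground truth, so the whole pipeline is testable
end to end.

## Worked example

```r
library(groovepred)

# a 16-bp ideal duplex with one ARG/LYS/ASN unit planted in the major groove
fx <- make_fixture(tempdir(), name = "demo", n_bp = 16,
                   dbus = list(dbu_spec(groove = "major", center_bp = 8,
                                        jitter_sd = 0.3, seed = 7)))
complex <- fx$structure
complex
#> pdb_structure 'bdna16': 322 atoms, 3 protein / 32 dna / 0 other residues

kb <- build_knowledgebase(list(complex))
kb
#> knowledgebase: 1 training structure(s), 7/80 non-empty models, 7 base instances

res <- run_pipeline(complex, kb, conserved = "all")
res
#> pipeline_result: 3 conserved -> 3 surface -> 1 clusters -> 1 DBUs; 1 analysed
#> -- DBU rank 1 (score 3.000, 3 residues)
#> orientation: direction (-0.464, 0.687, 0.559), 95% variance, anchor (2.6, 7.5, 24.3)
#>    top placement: base A density 12.2585 at (-1.18, -0.21, 23.66)
#> location error 0.00 A (success); groove major; orientation error 3.7 deg (success)
```

Reading the output: the three planted residues pass the RSA screen, form
one spatial cluster whose propensity score (3.0, every member always binds
in this one-complex training set) beats its expectation, the PCA tangent
explains 95% of the representative-atom variance and lies 3.7° from the
phosphate-chord reference, and the top-density base placement falls exactly
on a base of the reference duplex (location error 0.00 Å, well under the
6 Å failure cutoff).

A command-line front end mirrors the pipeline
(`inst/scripts/groovepred`): subcommands `fixture`, `kb build`,
`dbu find`, `predict`, `evaluate`.

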