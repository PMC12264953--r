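---
title: "Scaffold hopping with a reward-steered SMILES language model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Scaffold hopping asks for molecules that keep what makes a reference ligand
active -- its peripheral interaction groups and its 3D shape and
pharmacophore profile -- while replacing the central scaffold with a
chemically different one. `scaffhop` frames this as goal-directed generation:
a SMILES language model proposes molecules, a staged scoring function rewards
designs that contain the reference decorations on a *dissimilar* scaffold
with a *similar* 3D profile, and reinforcement learning moves the generator
toward high-reward regions.

## Scaffold decomposition by fuzzy decoration matching

A *decoration* is a substructure fragment with one attachment dummy. Given a
design and the set of reference decorations, `find_scaffold()`:

1. **Fuzzy matching.** Finds the largest common connected substructure
   between the decoration and the design that includes the dummy atom. The
   dummy may stand for any heavy atom of degree greater than one, connected
   by a single bond; matched atoms must be disjoint from those claimed by
   previously accepted decorations; and the match must cover at least
   `alpha` times the decoration's heavy-atom count.
2. **Peripheral selection.** Among competing placements, the one leaving the
   most atoms on the scaffold side of the cut is chosen (ties broken by the
   smallest matched atom index, for determinism).
3. **Test cleavage.** The bond at the attachment is cut; the cut must yield
   exactly two valid fragments (ring bonds cannot be cleaved), and the
   cleaved fragment's atom count `n_d` must lie in the window
   `[n_r * alpha, n_r / alpha]`. Both bounds are inclusive: for a 10-atom
   decoration at `alpha = 0.8` this admits fragments of 8 to 12 atoms, which
   is the behavior the strict-inequality reading of the success-score
   formula would *not* reproduce -- we follow the worked window.

The success score `S_s` is the fraction of decorations that passed. Only at
`S_s = 1` is the scaffold (the remainder with one dummy per attachment site)
returned. Decorations are processed largest-first: large fragments are more
specific and constrain the shared atom bookkeeping before small, promiscuous
ones run. If every placement at the maximal common-substructure size fails
cleavage, the search continues at the next smaller size rather than failing
outright; this is slightly more permissive than a strict maximum-only
reading and is monotone in `alpha` by construction.

The matcher itself is an exact connected subgraph-monomorphism search on
element/aromaticity/charge/ring-membership-labeled graphs with
bond-order-exact comparison (aromatic bonds compare as aromatic, not by
their kekulized order). Decorations are small, so exhaustive search with
BFS-anchored pruning is fast and needs no timeout.

## The staged reward

Designs pass through three stages:

1. **Molecule filter.** Molecular weight, rotatable bonds and stereocenter
   count must not exceed thresholds. The published threshold table is not
   reproduced in the main text, so defaults derive from the reference
   itself: MW + 100 g/mol, rotatable + 3, stereocenters + 2 -- "reasonably
   above" the reference, and overridable. Filtered designs score 0.
2. **Decomposition.** `S_s = 0` scores 0; a strict subset (`0 < S_s < 1`)
   earns the flat partial reward 0.3 and -- deliberately -- skips 3D scoring
   entirely, which both saves conformer generation time and shapes the
   sparse-reward landscape.
3. **2D x 3D.** The 2D score is the Jaccard distance between 2048-bit,
   radius-3 circular fingerprints of the design and reference scaffolds
   (dummies retained on both sides; higher = better hop). The 3D score is
   the best conformer score against the bioactive pose (below). The final
   reward is their weighted harmonic mean with `w_2D = 1.5`, `w_3D = 1.0`,
   so neither score can be optimized at the other's expense; if either
   score is 0 the reward is 0 (the continuous limit of the harmonic mean).
   A perfect self-copy of the reference therefore scores 0: its scaffold
   distance vanishes.

## 3D backend

The open backend replaces licensed conformer/overlay tools and is held to a
behavioral contract (scores in [0, 1], self-overlay scores 1, rigid-motion
invariance) that any substitute passed via `reward_config(score3d_fun=)`
must also satisfy; the test suite is the contract.

* **Conformers.** Tetrahedral stereoisomers are enumerated (2^k over
  unassigned centers, capped at 5 centers; double-bond geometry is not
  enumerated). Each isomer is embedded once with OpenBabel's 3D builder,
  then up to 32 poses per isomer are produced by seeded random torsion
  sampling over the rotatable bonds, clash-filtered, and MMFF94-minimized.
  The builder's internal rotor search is not seedable, so base embeddings
  are cached per structure: ensembles are reproducible within a session,
  while bitwise identity across sessions is not guaranteed. Any ring of 10
  or more atoms classifies the molecule as a macrocycle, which is excluded
  from 3D scoring (ensemble empty, `S_3D = 0`).
* **Shape.** Heavy-atom Gaussian-volume overlap (Grant-Pickup first order,
  element vdW radii), reported as an overlap Tanimoto.
* **Color.** Typed pharmacophore points -- donor, acceptor, cation, anion,
  hydrophobe, aromatic-ring centroid -- from rule-based typing on the
  3D structure (explicit hydrogens drive donor perception), scored as a
  per-type Gaussian overlap Tanimoto with 1 angstrom feature width. Two
  feature-less conformers score color 1 (identity convention); one-sided
  emptiness scores 0.
* **Alignment.** Rigid rotation + translation maximizing the
  `w_s`-shape/`w_c`-color combination, Nelder-Mead from up to 10 starts
  (principal-axes alignments with sign flips plus fixed 90/180-degree
  offsets). The conformer score is `rho = (S_S w_s + S_C w_c)/(w_s + w_c)`
  with `w_s = 1.0`, `w_c = 1.2`; a design's `S_3D` is the max of `rho` over
  the whole ensemble (greedy: no hits lost).

## The generator

The SMILES language model is an LSTM (embedding, stacked cells, softmax)
implemented directly in base R matrix algebra with hand-derived
backpropagation and Adam -- no autodiff framework is involved. Its
correctness rests on two oracles in the test suite: finite-difference
gradient checks, and the agreement of empirical sampling frequencies with
`exp(-NLL)` at 10,000 draws. NLLs are in nats and include the end token;
the reward scaling `sigma` of the learning loss lives on this scale.

Defaults are desk-scale (1 layer x 64 units): the package targets
reproducible small-corpus experiments, and layers/units/embedding are
plain arguments for anyone with the patience (or hardware) for more. The
tokenizer covers bracket atoms, two-character elements, ring-closure
digits and `%nn` closures; tokenize-then-join is the identity on every
corpus string.

**Transfer learning** toward a reference molecule trains each epoch on
randomized SMILES enumerations of the reference (emitted by a seeded
graph traversal; literal single-string training degenerates), samples
10,000 strings and stops at the first model whose canonical-match
frequency for the reference exceeds 5%. The randomized emitter writes
aromatic-form, stereo-free strings (matching the dialect the prior was
trained on), so the frequency criterion operates on stereo-free canonical
forms.

## Reinforcement learning

Per epoch: sample 64 strings at temperature 1; score; apply the diversity
filter; form the augmented target `NLL_Aug = NLL_Prior - sigma * S_F` with
`sigma = 128`; take one Adam step on the mean squared residual
`mean((NLL_Aug - NLL_Agent)^2)` over the batch plus the inception replay.
Invalid strings stay in the batch with reward 0.

* **Diversity filter.** Designs scoring at or above 0.4 are stored (unique
  by canonical SMILES) and counted per Bemis-Murcko framework; once a
  framework exceeds 30 such designs, further ones are zeroed -- a hard
  cutoff, matching the bucket semantics of the framework this design
  follows, rather than a graded penalty. All acyclic frameworks share one
  reserved class. Stored designs keep their pre-penalty scores; they are
  the run's output.
* **Inception.** A bounded buffer of the best 100 scored strings (raw
  sampled form, so they always re-tokenize); 10 are replayed per epoch,
  every epoch -- the schedule the source framework uses by default.

With the seed fixed, a 2D-only run is fully deterministic end to end.

## Evaluation

* **Scaled Shannon Entropy.** `SSE = (-sum p_i log2 p_i)/log2 n` over
  cyclic-substructure classes of the design scaffolds, with `n` the number
  of designs. The denominator choice is forced: it is the only
  normalization that yields 0 for a homogeneous set and 1 for an
  all-singleton set simultaneously.
* **Retrieval curves.** Frameworks ranked by production frequency;
  cumulative unique-framework fraction against cumulative design fraction.
* **Quality filter.** Exact decoration inclusion (`alpha = 1`), a compact
  catalog of well-known pan-assay interference motifs (a subset, stored as
  plain-text SMARTS under `extdata`), a package-native synthetic-
  accessibility heuristic (size, ring fusion, stereocenters, macrocycles,
  charges; the published fragment-contribution score is not redistributable
  here), and a ring-aromaticity consistency check. Rules are independent
  predicates; elimination counts are reported per rule.
* **Distance panel.** Full-molecule and scaffold Jaccard distances to the
  reference with mean and standard deviation; designs without a
  decomposition are excluded from scaffold distances and counted.

## The synthetic task

`make_task()` emulates the structure of a scaffold-hopping case study at
desk scale: a reference (ethyl + aminomethyl on para-benzene), ten ring
scaffold families, and design sets with controlled decoration inclusion
(positives verified to decompose exactly at construction). The toy corpus
(~400-1000 unique SMILES from a substituent-by-scaffold grid) stands in for
the 1.5M-molecule drug-like corpus a production prior would use; training
runs 50 epochs on it where a production prior trains 20 epochs on ChEMBL.
What passing desk-scale tests shows is that the machinery -- decomposition,
reward shaping, policy updates, diversity filtering -- behaves as
specified; it does not show that the toy generator's chemistry transfers
to real targets, which additionally needs the full corpus, licensed-grade
conformer ensembles, and bioactive poses from crystal structures.

The desk-scale learning experiment (200 epochs x 64 samples, seed 42,
2D-only scoring with the 3D stage stubbed to 1) is the package's analog of
a learning-curve acceptance: mean reward over the last 20 epochs exceeds
the first 20, and the diversity-filter memory is dominated by designs
containing all decorations. Problem sizes throughout (corpus ~400, 200
epochs, ensembles of at most 8 poses in tests) were chosen once as
desk-scale study conditions.

## Numerical choices and degenerate inputs

* Validity is stricter than the underlying toolkit: standard-valence
  checking rejects hypervalent parses the toolkit would accept.
* Fingerprints are a package-native Morgan implementation (iterated
  neighborhood hashing of element/charge/hydrogen/degree/ring/aromaticity
  invariants, aromatic bonds hashed as their own bond class, identifiers
  folded onto 2048 bits), computed on the canonical re-parse so they are
  invariant to input atom order. Bit positions are not interchangeable with
  any other toolkit's ECFP, but every Jaccard comparison in the package uses
  the same implementation on both sides.
* Jaccard distance of two empty fingerprints is an error, not 0.
* Ties in peripheral selection break on the smallest matched atom index;
  decoration processing order is descending size.
* Stereocenter detection is branch-signature based (iterative neighborhood
  hashing), covering ordinary tetrahedral centers; exotic stereo
  (atropisomerism, double-bond geometry) is out of scope.
* `SSE` requires at least two designs; one-class sets return exactly 0.

## Known limitations

* The 3D backend approximates licensed shape/color tooling behaviorally,
  not numerically; absolute 3D scores are not comparable with published
  overlay scores.
* Cross-session bitwise reproducibility of conformer ensembles is limited
  by the unseedable 3D builder (see above).
* The PAINS catalog is a subset; the accessibility score is a heuristic.
* The generator at its default size is a toy; production-scale priors
  require an autodiff/GPU stack out of scope for this package.
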