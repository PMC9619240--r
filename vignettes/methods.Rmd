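---
title: "Evolutionary screening of TADF emitter libraries: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary screening of TADF emitter libraries: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Thermally activated delayed fluorescence (TADF) emitters are purely organic
donor–acceptor (DA) molecules whose first singlet–triplet gap
$\Delta E_{\mathrm{ST}} = E_{S_1} - E_{T_1}$ is small enough — below roughly
0.15 eV — that triplet excitons can be thermally up-converted and harvested
as delayed fluorescence. Finding such molecules in a combinatorial DA space
is a needle-in-a-haystack search: the space grows exponentially with the
number of substitutable positions, while each accurate quantum-chemistry
evaluation costs hours.

`tadfscreen` implements an evolutionary high-throughput virtual screening
engine around that bottleneck. Each generation, only a small random subset
of the current compound library is evaluated by the (expensive) property
engine; a random-forest surrogate trained on that subset predicts
$\Delta E_{\mathrm{ST}}$ and $E_{S_1}$ for the whole library; the best
tenth of the library (smallest predicted gap) is selected and mutated at
aromatic C–H positions to form the next generation, with the parents
retained. "Optimal" molecules (predicted gap below the threshold) are
accumulated across generations, classified by emission color, and finally
ranked by synthetic accessibility.

## The generational protocol

Writing $G_n$ for the library at mutation generation $n_g = n$:

1. **Initial library.** $G_0$ is the combinatorial coupling of every donor
   with every acceptor fragment (single attachment point each, joined by
   one single bond), deduplicated by canonical SMILES and capped at
   $10^3$ molecules by a seeded uniform subsample. Uniform sampling is the
   least-biased way to reduce an oversized enumeration; truncation in file
   order would bias the library toward the first donors.
2. **Training selection.** A uniform random 10% of the library is
   evaluated by the property engine. A floor of 20 molecules (the
   surrogate's minimum training size) keeps late, shrunken generations
   trainable; for the standard cap of 1000 the floor is inactive until the
   library falls below 200 molecules.
3. **Completeness gating.** Real engines fail on some molecules. A batch
   passes when at least 80% of geometries and 90% of the property
   evaluations on those geometries succeed; otherwise the run aborts with
   both achieved ratios. Failed molecules are flagged, never dropped.
4. **Surrogates.** Two independent random forests are trained each
   generation from scratch — one for the gap (drives selection), one for
   $E_{S_1}$ (drives the color sieve). Two single-output models rather
   than one multi-output model keeps the two predictions independently
   interpretable and lets either target be re-fit alone.
5. **Prediction and selection.** The *entire* library is predicted,
   including the evaluated molecules; selection uses predicted values
   uniformly so that all molecules compete on the same scale. The top
   $\max(1, \lfloor 0.10\,n \rfloor)$ by smallest predicted gap become
   parents, with lexicographic SMILES order as the deterministic
   tie-break.
6. **Mutation.** Parents are mutated at aromatic C–H sites (below) and the
   parents themselves are always carried into the next library — this
   accumulation property is what makes the optimal-molecule count
   non-decreasing. If parents plus offspring exceed the cap, offspring are
   subsampled with the run seed; parents are never sampled away.
7. **Analytics.** Per generation the engine records the material abundance
   $\omega_{\mathrm{MA}}$ (fraction of the library with predicted gap
   $< 0.15$ eV), the library-mean aromatic C–H count $n_{\mathrm{aCH}}$,
   the mean predicted gap, the accumulated optimal count, the color-sieve
   histogram, Murcko skeleton frequency tables, and the group similarity
   to the previous generation ($\Delta_{\mathrm{MSPR}}$, with the
   intersection count $n_{\mathrm{inter}}$).
8. **Convergence.** The loop stops at the generation limit or when the
   optional targets on the accumulated count or the abundance are met;
   with several criteria configured, "any" semantics are the default (an
   "all" switch exists) since each criterion alone already indicates a
   saturated search.

## Mutation operators

Ten operators act on aromatic C–H positions, the only sites the protocol
considers substitutable:

| label | operation | sites/offspring |
|-------|-----------|-----------------|
| Sub1  | ring C–H → ring N ("slow") | 1 |
| Sub2  | ring C–H → ring N ("fast") | up to 2 |
| Sub3–Sub6 | H → F, CN, OMe, NMe2 | 1 |
| Sub7–Sub10 | H → one of {F\|OMe, F\|NMe2, CN\|OMe, CN\|NMe2} | 1 |

Every site × group combination is enumerated, products failing Open
Babel's sanitization are dropped, and the set is deduplicated by canonical
SMILES; the parent is never its own offspring. Products with adjacent ring
nitrogens (pyridazine-like) are legitimate and kept whenever they
sanitize. The methyl hydrogens introduced by OMe/NMe2 are aliphatic, so a
substituent is never re-substituted within a generation, but it can sit
next to later substitutions in subsequent generations — molecular
complexity grows along the run, which is exactly why the final synthetic
accessibility control exists.

An aromatic C–H site is identified on the kekulized connection table as a
ring carbon with exactly one implicit hydrogen that carries a double bond
(the sp2 signature; sp3-bridged polycycles such as fluorenes or
dihydroacridines keep their benzo sites). On the package's all-aromatic
chemical space this coincides with aromaticity-perception counts (`[cH]`
SMARTS matches), which the test suite cross-checks on library samples.

## Molecular representations

* **Canonicalization** and all SMILES I/O go through Open Babel
  (ChemmineOB); the canonical string is the dedup key everywhere.
* **Fingerprints** are binary extended-connectivity fingerprints of radius
  2 (the conventional ECFP4 configuration), folded from Open Babel's
  4096-bit output to 2048 bits by OR-ing halves. Bits, not counts: the
  similarity analytics and the surrogate both consume presence/absence
  structure, and bit vectors keep Tanimoto algebra exact. The fingerprint
  words are decoded directly from the toolkit's packed 32-bit
  representation (one native call per molecule) because the wrapped
  per-bit accessor is three orders of magnitude slower at library scale.
* **Tanimoto similarity** is intersection-over-union; two all-zero vectors
  score 0 by convention (moleculeless vectors should not count as
  similar).
* **Murcko skeletons**: the *common core* is the molecule's ring systems
  plus linkers, obtained by iteratively pruning terminal atoms, then
  re-attaching atoms multiply bonded directly to the framework (sulfonyl
  oxygens on a linker stay; whole side chains, including their terminal
  =O, go). The *generic core* re-types every atom to carbon and every
  bond to single, leaving pure connectivity. Generic cores are therefore
  a coarsening of common cores — a property the tests assert on real
  libraries.

## The synthetic property oracle

Real gap calculations (semi-empirical geometry plus TD-DFT excited
states) live behind a pluggable engine contract; the package ships the
contract, a CSV-lookup stub for externally computed tables, and a
deterministic **synthetic oracle** used for all desk-scale runs and tests:

$$\Delta E_{\mathrm{ST}} = \mathrm{clamp}\big(g_0 - w_{\mathrm{sub}}\,
 n_{\mathrm{sub}} - w_N\, n_{\mathrm{aN}} - w_{\mathrm{amine}}\,
 n_{\mathrm{NAr_2}} + \varepsilon,\ 0.01,\ 1.5\big)\ \mathrm{eV}$$

with $g_0 = 0.70$, $w_{\mathrm{sub}} = 0.06$ per terminal substituent
(F/CN/OMe/NMe2), $w_N = 0.05$ per pyridine-type ring nitrogen,
$w_{\mathrm{amine}} = 0.10$ per diarylamine-type nitrogen, and
$\varepsilon$ a zero-mean pseudo-noise of amplitude 0.05 eV derived from a
hash of the canonical SMILES. The two nitrogen counts are disjoint by
construction (two-coordinate ring N versus three-coordinate N with two
aryl neighbours), so no atom is double-counted. $E_{S_1}$ analogously
starts at 3.30 eV and red-shifts by 0.08 eV per ring nitrogen or strong
donor feature, clamped to [1.5, 4.0] eV.

Hash-derived noise (rather than RNG-stream noise) makes the oracle a pure
function of the structure: results are independent of evaluation order and
of how batches are split, which is what makes whole trajectories
bit-reproducible.

The oracle emulates the *direction* and rough magnitude of real
substituent effects — donors/acceptors and heteroatoms shrink the gap —
so the evolutionary loop reproduces the qualitative phenomenology of a
QC-driven run (abundance rising from near zero toward saturation, gap
collapse, skeleton convergence). It does **not** emulate conformational
effects, charge-transfer physics, excited-state orderings, or engine
failures; passing tests therefore validate the screening machinery, not
any quantitative claim about real emitters.

## Fragment pools

The packaged donor and acceptor pools are curated stand-ins (49 donors, 60
acceptors): carbazole, phenoxazine, phenothiazine, dimethylacridine and
di/triarylamine donors; cyano, triazine, azine, sulfonyl, carbonyl,
phosphoryl and fluorinated acceptors; plus plain aromatic couplers in both
pools. The composition was balanced once so that the oracle's
generation-0 library starts around a mean gap of 0.56 eV — a realistic
"mostly non-TADF" starting point bracketing reported QC starting means —
and was not revisited. `fixture_fragments(30, 43, seed)` draws the
standard study-sized set.

## Group similarity ($\Delta_{\mathrm{MSPR}}$)

The similarity between two libraries is the mean Tanimoto similarity over
a **maximum-similarity pairing**: repeatedly take the globally most
similar unpaired cross-library pair until the smaller library is
exhausted. The greedy rule is the defined index — it is order-symmetric,
equals 1 exactly on identical libraries, and is bounded below by
$n_{\mathrm{inter}}/\min(n_A, n_B)$ since intersection molecules pair at
similarity 1. An assignment-optimal variant (which can differ: on the
2×2 similarity matrix [[0.9, 0.8], [0.8, 0.1]] greedy gives 0.50, the
optimal assignment 0.80) is provided behind `method = "optimal"` for
sensitivity analysis on small libraries; greedy is the contract. The
pairing is meant for libraries of comparable sizes — with very unequal
sizes the unpaired excess is simply ignored.

## Synthetic accessibility

The final ranking uses a fragment-contribution synthetic accessibility
score on the standard 1 (easy) – 10 (hard) scale: the mean log-frequency
of each atom's radius-2 circular environment in a reference corpus (the
full coupling enumeration of the shipped pools, built lazily and cached),
minus complexity penalties for size ($n^{1.005}-n$), ring-fusion atoms and
ring count, affinely mapped onto [1, 10]. Unseen environments are treated
as rare. The scorer is pluggable — any `function(smiles) -> scores` can
replace it, e.g. one backed by an external implementation with a
PubChem-scale fragment table; scores from different references are
comparable in rank but not in absolute value.

## Numerical and reproducibility choices

* One master seed feeds named substreams (library sampling, training
  selection, cap sampling, model fitting), so each component is
  independently reproducible; all derived seeds stay below $2^{31}$.
* Selection sizes use $\max(1, \lfloor f\,n\rfloor)$ throughout; ties in
  ranked selections break lexicographically on canonical SMILES.
* Sieve boundaries are green: $E_{S_1} > 2.80$ eV is blue, $< 2.50$ eV is
  red, the closed interval [2.50, 2.80] is green.
* Abundance and accumulation use a strict `<` at the 0.15 eV threshold,
  on *predicted* gaps for every molecule (including QC-evaluated ones)
  for scale uniformity.
* Random-forest hyperparameters are chosen by 5-fold cross-validated grid
  search over trees {100, 300} × depth {unlimited, 10, 20}, scored by
  MSE; ties resolve to the first grid row. Fold assignment and forest
  growth are seeded; single-threaded fitting keeps results exactly
  reproducible.
* The Kabsch RMSD uses SVD superposition with the determinant correction
  (proper rotations only); it backs geometry-comparison workflows of
  external engines and is validated against a refined rotation-grid brute
  force.

## Problem sizes

Desk-scale study runs use the full protocol at cap 1000 for 6 generations
(about four minutes on one CPU with the synthetic oracle); module-level
tests use libraries of 100–300 molecules. Under the fluorine mutation the
library shrinks over generations — selected parents are increasingly
substituted and increasingly similar, so they yield fewer unique mutants
than the cap; the engine shrinks only when the parent∪offspring union is
genuinely smaller than the cap, it never discards below it.

## Known limitations

* The oracle's additivity means no epistasis between substituents; real
  gap surfaces are not additive.
* Aromatic-site perception relies on kekulized connection tables plus a
  ring-system unsaturation rule; exotic mesoionic or charged aromatics
  are outside the supported space (fragments are validated at ingest).
* The SAS reference corpus is the package's own DA space, so absolute
  scores are corpus-relative.
* Single-objective selection only; multi-property sieving (e.g. adding a
  fluorescence-rate criterion) would need an extended selection rule.
* No crossover operator: offspring descend from a single parent.
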