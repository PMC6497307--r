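---
title: "Building biomass objective functions from experimental data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building biomass objective functions from experimental data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bofkit)
```

## The model behind the package

Flux balance analysis (FBA) predicts growth by maximizing the flux
through the biomass objective function (BOF), a pseudo-reaction whose
stoichiometric coefficients `c_i` (mmol/gDW, negative for consumed
species) encode the cell's net demands per gram dry weight. FBA's growth
prediction is only meaningful on a 1 gDW basis, which is why every
coefficient calculator here is anchored on macromolecular weight
fractions (MWFs): the fraction of dry mass contributed by DNA, RNA,
protein, lipids and the soluble pool. If the supplied MWFs sum to 1, the
assembled BOF accounts for the full gram;
`validate_weight_fractions()` checks this and warns on over-unity
totals.

### Step 1 — macromolecule coefficients

For each category the package computes molar frequencies `f_i` of the
building blocks and converts them with the closed form

$$c_i = -\,\frac{1000 \cdot wf \cdot f_i}{\sum_j f_j \, MW_j},$$

where `MW_j` is the formula weight stored in (or computed from) the
model. The denominator is the frequency-weighted mean monomer weight, so
each category's mass audit `sum |c_i| MW_i / 1000 = wf` holds to machine
precision — this identity is asserted throughout the test suite.

Frequencies come from:

* **DNA** — nucleotide counts over the genome. Both strands are counted
  by default (chromosomes are double-stranded, so A pairs with T and C
  with G); a `both_strands = FALSE` switch gives forward-strand counts.
* **RNA / protein** — counts per transcript or protein weighted by its
  linear-scale relative abundance:
  `f_i = sum_g a_g n_gi / sum_g a_g L_g`. Log-transformed abundances
  must not be used. Scaling all abundances by a constant cancels, and
  setting them all to 1 (no expression data) degrades gracefully to the
  length-weighted mean composition.
* **Lipids** — measured lipid abundances mapped from common names to
  model identifiers, interpreted as molar fractions (a
  `mass_fractions = TRUE` switch divides by molecular weight first, for
  datasets reported by mass). Generic acyl chains appear in model
  formulas as the pseudo-element `R`; each `R` contributes a
  configurable default mass of 100 g/mol, and its use is reported so the
  default is never silent.

Polymerization byproducts (pyrophosphate for nucleic acids, water for
peptide bonds) are *not* added to the composition: the coefficients are
monomer demands, which keeps the mass audit interpretable. Monomer
weights are the charged species' formula weights as stored in the model,
without residue water subtraction.

**Maintenance costs.** For each measured condition the exchange fluxes
and the growth rate are fixed and the flux through the ATP hydrolysis
reaction is maximized; ordinary least squares of maximal ATP turnover on
growth rate gives the growth-associated maintenance (GAM, slope, mmol
ATP/gDW) and non-growth-associated maintenance (NGAM, intercept, mmol
ATP/gDW/hr). Conditions are weighted equally. The GAM enters the BOF as
ATP + H2O consumption balanced by ADP + Pi + H production; the NGAM is
not a BOF term — it belongs on the ATP hydrolysis reaction as a lower
bound and is returned separately.

### Step 2 — coenzymes, ions, soluble pool

Currency metabolites (ATP, NAD, and friends) take part in very many
reactions. The degree of a metabolite is defined as the number of
reactions it participates in; metabolites already placed by Step 1 are
excluded from the analysis, and everything strictly above
`mean + 1 population SD` of the degree distribution is reported as a
coenzyme. Two deliberate choices: the *population* standard deviation
(the degree table is the whole population, not a sample), and a
*strict* comparison (with a flat degree distribution, SD = 0, a
non-strict rule would select everything). The literature also uses a
neighbor-count definition of degree; it is available via
`definition = "neighbors"` but the two are not equivalent and are not
reconciled.

Inorganic ions are matched from a packaged 16-entry list of universal
ions recurring in published biomass functions. Matching strips the
trailing compartment token; when an ion exists in several compartments
the cytosolic species is preferred. The list is a plain text data file
(`inst/extdata/universal_ions.txt`) and user-replaceable.

The soluble pool's weight fraction (default 0.05, i.e. 5% of dry mass —
override it with organism-specific measurements when available) is
split *evenly by mass* across the selected metabolites:
`c_i = -1000 (wf/N) / MW_i`, conserving the fraction exactly.

### Step 3 — metabolic end goals from gene essentiality

Adding a metabolite to the BOF forces flux through its producing
pathways, making their gene knockouts lethal in silico. Step 3 exploits
this: it searches for the metabolite set whose induced essentiality
pattern best matches genome-wide experimental essentiality calls, scored
by the Matthews correlation coefficient (MCC; 1 = perfect, 0 = random,
with the 0-on-degenerate-confusion-matrix convention).

*Feature selection.* Step 2 metabolites are removed; metabolites the
network cannot produce individually are removed (LP with a
unit-consumption objective must be optimal with flux > 1e-6); each
survivor is screened alone and kept when its single-metabolite MCC is
strictly above the screen's mean + 1 population SD.

*Search.* Individuals are binary inclusion vectors over the screened
subset. The genetic algorithm uses tournament selection (size 3),
one-point crossover (probability 0.8), per-individual mutation
(probability 0.2) flipping each bit with probability `1/|subset|`, and a
fitness of `(MCC, size)` with weights `(1.0, -0.25)`. The comparator is
lexicographic: MCC dominates and the penalized size only breaks ties.
This reproduces the intended behavior of a small negative size weight —
individual size stabilizes instead of drifting upward — without ever
trading MCC away for parsimony; a scalar weighted-sum comparator is
available behind `comparator = "weighted_sum"`. Crossover and mutation
probabilities are package defaults (no canonical values exist); they are
recorded in `ga_config()` and echoed in run manifests. Individuals are
initialized with 60–100 metabolites (clamped to the subset size), and
because an evolution's outcome depends on its initial population,
multiple independent evolutions (`run_evolutions()`, seeded
`seed + index`) are recommended. Evaluation is a pure function of the
bits and is memoized; an all-zero individual receives the worst fitness
`(-1, 0)` rather than raising, so the operators may produce it freely.
Each evolution maintains a hall of fame (capacity 1000) of the best
distinct individuals and a logbook of per-generation fitness statistics.

*Interpretation.* Members of all halls of fame are pooled; the best 20%
by fitness are kept; each metabolite's frequency of apparition among the
kept individuals is computed; metabolites strictly above the mean
frequency (over the observed support) are retained. When the support is
flat — every observed metabolite equally frequent — the whole support is
retained, since nothing distinguishes its members. Pairwise
shortest-path distances (one reaction = one unit) are computed on the
metabolite co-occurrence graph after removing metabolites above the
Step 2 degree threshold, whose ubiquity would shrink all distances.
Removing hubs can disconnect metabolites; unreachable pairs receive the
maximum finite distance + 1 (or the graph order + 1 when no pair is
reachable), keeping them strictly farther than any connected pair.
DBSCAN with a precomputed distance matrix (defaults `eps = 8` reactions,
`min_samples = 1`; at `min_samples <= 1` clusters are exactly the
connected components of the eps-graph and there is no noise) groups the
metabolites into metabolic end goals, ranked by cluster frequency (the
sum of member frequencies). The automated final selection takes each
cluster's highest-frequency member, ties broken lexicographically — a
documented interpretation, chosen because the representative should be
the metabolite the search itself favored. `eps_guidance()` sweeps eps
and reports cluster counts; a practical eps yields about half as many
clusters as metabolites. Final coefficients are unit consumption
(-1 mmol/gDW) by default — essentiality topology does not depend on the
magnitude — or an even mass split of the residual weight fraction.

## Numerical and infrastructure choices

* **LP backend.** FBA, knockouts, producibility and maintenance all go
  through one pluggable solver seam (`solver` argument). The default is
  a dense two-phase simplex with Bland's anti-cycling rule written for
  this package: the LPs here are small but routinely degenerate (fixed
  exchange fluxes, knocked-out reactions with zero-span bounds), and the
  general-purpose simplex routines available in the R ecosystem
  mis-handle such instances (see `R/lp.R`). The backend is validated in
  the tests against hand-enumerated optima and, where they work, against
  external routines. Default tolerance 1e-9.
* **Growth binarization.** A knockout is called lethal when growth
  drops below 1e-6 (absolute) — no canonical cutoff exists, so this is
  a package constant (`GROWTH_ZERO_TOL`); a relative mode (< 5% of wild
  type) is available in `predict_essential()`.
* **GPR semantics.** Boolean gene–protein–reaction rules are parsed
  once per model; genes missing from a rule evaluate as present, so only
  the named deletions can disable a reaction. Reactions whose rule goes
  false get bounds (0, 0).
* **Levenshtein on metabolite lists.** Token-level edit distance with
  both lists sorted first, so the distance reflects set composition and
  not serialization order (`sort = FALSE` preserves order). Coefficient
  magnitudes are ignored in all composition comparisons.

## What the fixtures emulate — and what they do not

The fixture generators plant ground truth so that each stage's output is
checkable: linear-pathway toy models where demanding a terminal
metabolite makes exactly its pathway's genes essential; an energy model
whose maximal ATP-hydrolysis flux responds linearly to uptake, making
planted GAM/NGAM analytically invertible; essentiality datasets
simulated from a planted BOF with optional symmetric label noise; and
seeded random sequences and abundances. All generators are deterministic
under their seeds.

These fixtures are deliberately small — a few parallel pathways, tens of
reactions — and free of the pathologies of real reconstructions:
blocked reactions, dead-end metabolites, compartment shuttling, lumped
reactions, incomplete GPRs and noisy essentiality screens. Passing
tests therefore demonstrate the correctness of the calculations and the
search machinery, not the performance of the workflow on a real
genome-scale model, which additionally depends on network completeness
and data quality. Problem sizes used by the test suite and the
acceptance script — toy networks of 4 pathways (13 reactions), GA runs
of 20 individuals for 15–200 generations over 8 candidates, exhaustive
enumeration of all 256 subsets as the optimality oracle, genomes of a
few kilobases — were chosen so each planted truth is recoverable
exactly while the whole suite runs in well under a minute per file.

## Known limitations

* The built-in simplex is dense and suited to desk-scale networks; for
  genome-scale models plug in an industrial LP solver through the
  `solver` seam.
* Carbohydrate and cell-wall coefficient calculators are intentionally
  absent: those species are expected to surface through the Step 3
  search (as clusters such as murein precursors) rather than through a
  dedicated closed form.
* Step 2 quantifies the soluble pool as an even mass split; true per-ion
  abundances would require experimental data the workflow does not
  demand.
* Cluster naming (mapping end-goal clusters to ontology terms) is a
  manual, knowledge-driven act and out of scope; the package reports
  clusters, frequencies and representatives.
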