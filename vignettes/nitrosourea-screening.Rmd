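---
title: "Screening lomustine-analog nitrosoureas for CNS drug-likeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening lomustine-analog nitrosoureas for CNS drug-likeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroscreen)
```

## The problem

Chemotherapy of brain and spinal-cord tumors is limited less by cytotoxic
potency than by delivery: a drug must cross the blood-brain barrier (BBB) by
passive diffusion, which constrains its size, lipophilicity and polarity.
Lomustine, a small nitrosourea alkylator used against childhood
medulloblastoma, does cross, and analogs that keep its
`O=C(NHR)N(N=O)CH2CH2Cl` warhead while varying the R substituent are natural
candidates for CNS-directed drug design. `nitroscreen` implements the
property-based screening workflow for such candidates: compute the standard
drug-likeness descriptors from structure, filter with published CNS
criteria, predict the brain-to-blood concentration ratio, and characterize a
candidate library with a small multivariate statistics toolkit. The package
embeds the descriptor table of lomustine plus 17 proposed analogs
(`builtin_table1()`) as its reference fixture, and every headline number it
reports is recomputed from that table at run time.

## Descriptors

`compute_descriptors()` assembles, per molecule, the nine-column record used
throughout:

* **Formula weight** (`formula_weight`): sum of IUPAC standard atomic
  weights, hydrogens included; full precision internally, one decimal in
  reports.
* **Heavy-atom count** (`heavy_atom_count`): non-hydrogen atoms. (The
  reference table's "Number of atoms" column matches heavy atoms for
  lomustine, 15, which fixes the convention.)
* **Topological polar surface area** (`tpsa`): the Ertl fragment-contribution
  method over nitrogen and oxygen environments, using the published
  contribution table (`tpsa_contributions()`). For lomustine the five polar
  environments (amide N-H 12.03, carbonyl O 17.07, tertiary N 3.24, nitroso N
  12.36, nitroso O 17.07) sum to 61.77 squared Angstroms, matching the
  tabulated value. Sulfur and phosphorus deliberately contribute zero: the
  reference calculator uses the N/O-only convention (its thio-substituted
  agent keeps PSA 61.77), whereas e.g. Open Babel's TPSA adds sulfur terms.
  Environments without a tabulated contribution (charged atoms, exotic
  valences) contribute zero with a warning rather than failing the pipeline.
* **H-bond donors / acceptors** (`hbd_count`, `hba_count`): donors are
  *hydrogens* on N or O — one hydroxyl plus one secondary amine count as 2 —
  and acceptors are the total N plus O atoms. These are the conventions of
  the screening rules below, not the pharmacophoric definitions.
* **Rotatable bonds** (`rotatable_bond_count`): acyclic single bonds between
  two non-terminal heavy atoms, excluding amide C-N bonds. This definition
  reproduces lomustine's count of 4 (ring-C-N, N-N, N-CH2, CH2-CH2).
* **Log P** (`logp_estimate`): delegated to Open Babel's atom-contribution
  model. The reference values come from a proprietary calculator; agreement
  is only expected within about ±1 log unit (lomustine: 2.64 computed vs
  2.965 tabulated), so all reproduction statistics use the tabulated Log P,
  and `compute_descriptors(logp_override =)` lets users substitute their own.
* **Molecular volume** is *not* computed: the reference volumes come from an
  unpublished 3D-fitted group-contribution method, and presenting a different
  method's numbers under the same name would be misleading. Fixture volumes
  are used where volume enters (correlations, clustering, path analysis);
  tables without a volume column simply drop it from those analyses.

Structures enter as SMILES (`parse_smiles`), parsed by Open Babel with
explicit hydrogens, and are held as a light heavy-atom graph. Formal charges
are read from the molfile; the screening chemistry here is neutral, and
charged polar atoms fall back to the zero-contribution warning path of
`tpsa()`.

## Screening rules

Criteria sets are data (`criteria_set()`), so users can define their own;
two published CNS-penetration sets ship built in:

* **CNS-A**: FW ≤ 400, Log P ≤ 5, donors ≤ 3, acceptors ≤ 7.
* **CNS-B**: PSA ≤ 90 squared Angstroms, FW ≤ 450.

`rule_of_five_violations()` counts Lipinski violations with the literal
boundary conventions of the rule's wording: mass *less than* 500 Da (so a
violation at FW ≥ 500), Log P *not greater than* 5, donors *not more than*
5, acceptors *not more than* 10. A record at (499.9, 5.0, 5, 10) therefore
has zero violations. `screen_library()` applies any number of sets plus a
Rule-of-5 cap (default 0, the value every reference agent attains) and
reports per-set pass counts and fractions.

## The brain/blood partition model

`log_bb()` evaluates the two-descriptor linear model

Log BB = −0.0148·PSA + 0.152·LogP + 0.139,

with BB = 10^LogBB the brain-to-blood concentration ratio. The base of the
logarithm is fixed as 10 by the reference partition table itself
(10^−0.325 = 0.473 matches lomustine's printed pair). Predictions are kept
at full precision; reports round half-away-from-zero to three decimals.

Two numerical caveats are documented rather than hidden. First, the printed
reference BB column was evidently produced by exponentiating the *rounded*
Log BB values, and one printed Log BB (agent 10) is off by one unit in its
last decimal relative to recomputation; full-precision recomputation
therefore agrees with every printed value to within 0.001 but not always to
an exact three-decimal round. Second, the source's two printed values for
the mean Log BB (−0.108 and −4.08) are both inconsistent with its own
partition table, whose direct mean is −0.408; `bbb_summary()` reports the
computed value. The BB summary itself (mean 0.405, SD 0.102, min 0.144, max
0.662 at printed precision, with the maximum inheriting the rounding chain)
reproduces on both the full-precision and printed-value paths.

## Statistics layer

* `summarize_properties()` — mean, min, max, median, sample SD (n−1
  everywhere; this convention is pinned by the reference Log P SD 0.5337).
  The reference summary prints a rotatable-bond mean of 2.3 that contradicts
  its own min/median/max (4/5/8); direct computation gives 5.28, and the
  package reports the computed value.
* `pearson_matrix()` — product-moment correlations; zero-variance columns
  (the all-zero violations column) are dropped with a message.
* `grubbs_test()` — the extreme studentized deviate test for a single
  outlier, with the exact two-sided critical value from the Student-t
  quantile formula rather than lookup tables (it matches the published 5%
  table at n = 10/18/30 within 0.01).
* `ols_fit()` — ordinary least squares via `lm()`, erroring with the names
  of collinear predictors on rank deficiency.
* `path_coefficients()` — standardized regression weights of a
  single-equation path model (all listed predictors as direct causes).
  On the reference table the seven-predictor variant is *degenerate*: the
  z-scored acceptor and donor columns are identical, and PSA differs from
  them only through a fourth-decimal entry, so OLS either fails or returns
  exploding coefficient pairs. The `method = "minnorm"` option returns the
  minimum-norm least-squares solution (SVD pseudoinverse with a relative
  singular-value cutoff), which shares weight across collinear causes and
  keeps every coefficient finite. Even so, no single-equation least-squares
  variant reproduces the reference path-coefficient ranking (volume, nearly
  collinear with the response, absorbs the fit); those printed coefficients
  evidently come from a different, unstated multi-stage model, and the
  package does not claim to reproduce them.
* `anosim_test()` — analysis of similarities on mid-ranked Euclidean
  distances with Clarke's statistic R = (r̄_between − r̄_within)/(n(n−1)/4)
  and a seeded permutation p-value that includes the observed labelling in
  numerator and denominator. R = 1 exactly when all between-group distances
  exceed all within-group distances. The reference reports R = 1.000 for its
  agent set without stating the grouping, so that value is reported only for
  user-chosen groupings, never pinned. (A grouping by hydroxylation —
  `psa > 70` — does give R = 1 on the reference table.)
* `cluster_tree()` — agglomerative single-linkage clustering on Euclidean
  distances. Standardization is on by default and is load-bearing: raw
  distances are dominated by formula weight and isolate the heaviest agent
  (13), while z-scored distances isolate the hydroxylated agent 12 — the
  structure shown in the reference dendrogram — because its PSA, acceptor
  and donor deviations are the only ones spanning several standard
  deviations. The reference analysis does not state its preprocessing; this
  inference is therefore a documented design decision. Trees export as
  Newick (`as_newick`) and as a merge table (`merge_table`).

## Synthetic data

The generator exists so that every pipeline stage is testable without
external data, and its defaults are the reference set's conditions, chosen
once: Log P ~ Normal(2.524, 0.5337) truncated to [1.0, 4.5] (bracketing the
observed 1.537-3.924 range with margin), PSA fixed at 61.77 with a rare
hydroxylated variant at 82.0 carrying one extra acceptor and donor (rate
1/18; `n_hydroxylated = 1` reproduces the fixture's exactly-one-agent-12
condition), atom and rotatable-bond counts uniform on the observed 12-17 and
4-8 ranges, and formula weight regenerated from the fitted linear
formula-weight relation plus Gaussian noise (SD 16, the relation's residual
scale on the reference set) clamped to 190-315. Volume follows its
near-linear relation to atom count (slope 15.3, residual SD 5.4, fitted on
the reference set). `enumerate_analogs()` builds real structures instead:
R-group fragments spliced onto the fixed nitrosourea core (cyclohexyl
reconstructs lomustine exactly), spanning the substituent chemistry of the
reference series (cycloalkyl, alkyl, alkenyl, halogenated, hydroxyalkyl,
other rings, thio).

What the generator does *not* emulate: real candidate libraries have
correlated descriptors arising from shared substructure, discrete formula
weights tied to composition, and a search-dependent pass rate. Passing
recovery tests on these tables shows the statistics are implemented
correctly under the stated model, not that the model describes any
particular vendor library. `screening_fixture()` likewise imitates only the
*outcome ratio* of a library search (e.g. 17 passers among 200 candidates,
a sub-10% hit rate) by construction, not its chemistry.

## Numerical and design choices

* Rounding for display is half-away-from-zero at 3 decimals (the reference
  tables' convention); all computation is at full precision.
* Grubbs, ANOSIM and the permutation machinery require an explicit seed;
  reports are byte-identical across runs with the same config and seed, and
  timestamps are confined to logs.
* Single-linkage ties (exactly equal inter-cluster distances) are resolved
  by the underlying agglomeration order; continuous descriptors make ties
  measure-zero, and the brute-force oracle used in the tests applies a
  lexicographic tie-break for determinism.
* Problem sizes in the test-suite simulations — 100 seeded clustering-
  isolation runs, 200 ANOSIM calibration repeats at 199 permutations,
  recovery fits at n = 120-150 — were chosen as the smallest sizes at which
  the binomial / Monte-Carlo error of the checked property is comfortably
  below the asserted margins.
* The ANOSIM size check asserts a type-I error within three binomial
  standard errors of the nominal 5% rather than a hard "95% of runs"
  cut-off, since the latter equals the expected value exactly and would fail
  half the time by construction.

## Limitations

* Log P and molecular volume from the reference's proprietary calculator are
  not reproducible; the package substitutes an open Log P (documented ±1
  tolerance) and omits volume computation.
* Aromatic systems are handled through their Kekulé forms; the TPSA table's
  dedicated aromatic-nitrogen environments are approximated by the
  corresponding double-bonded forms (irrelevant for the nitrosourea space,
  which contains no aromatic N/O).
* Charged species are parsed but their polar atoms have no tabulated TPSA
  contribution and count zero, with a warning.
* The reference path-coefficient table and its ANOSIM R = 1.000 are reported
  claims whose generating procedures (path-model structure, grouping) are
  unstated; the package provides the standard single-equation and
  user-grouping versions and documents the mismatch instead of fitting to
  the printed numbers.
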