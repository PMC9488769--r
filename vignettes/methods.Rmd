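---
title: "From ensemble enzyme annotation to a simulation-ready metabolic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ensemble enzyme annotation to a simulation-ready metabolic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzmodel)
```

`enzmodel` turns per-tool EC-number predictions into a gap-filled,
simulation-ready metabolic model. This vignette explains the statistical
model and the optimization it rests on, the tunable parameters and their
defaults, the numerical choices, what the synthetic-data generators emulate,
and the limits of what the test suite can show about real data.

## 1. The ensemble classifier

Upstream annotation tools emit (protein, EC, score) triples on wildly
different score scales, so each tool is described by a *profile*: its score
kind, an ordered set of confidence bins over its score domain, which bin
counts as high-confidence, and its *predictive range* — the set of ECs the
tool can emit at all. Binning is configuration rather than code because
published per-tool cutoffs differ and change between tool releases; the
default profile is two bins (low/high) split at the tool's published
high-confidence cutoff. Tools that emit no score (CatFam-style output) are
treated as emitting only high-confidence predictions. Only complete
four-field EC numbers are admitted; partial identifiers are dropped and
counted.

For each EC $x$ predictable by $k$ tools, a Bernoulli naive Bayes
classifier is trained on proteins with known annotations. Positives are
proteins truly of class $x$; negatives are *other proteins predicted by some
tool to have activity $x$* — the classifier's job is to arbitrate among tool
predictions, not to screen the whole proteome. For the same reason, scoring
is restricted to (protein, EC) pairs that at least one tool predicted. The
likelihood score of a feature vector $f \in \{0,1\}^k$ (1 = predicted at
high confidence by that tool) is the posterior

$$p(y=1 \mid F=f) = \frac{p(y=1)\prod_i p(F_i = f_i \mid y=1)}
{\sum_{C\in\{0,1\}} p(y=C)\prod_i p(F_i = f_i \mid y=C)},$$

with add-$\alpha$ smoothing ($\alpha = 1$) on the prior and the
class-conditional Bernoulli parameters. Smoothing is not optional: with
$\alpha = 0$ a feature never seen in one class produces a hard 0/1
probability and the posterior degenerates. Scores strictly above 0.5 are
high-confidence; the inequality is strict, so a score of exactly 0.5 is not
selected.

Two rules extend the trained classifier:

* **Auto-assignment.** An EC predicted in the training data by every tool
  able to predict it, with no false positives from any tool, is assigned
  whenever any tool predicts it. We evaluate "without false positives" on
  the training data only, since the rule is a model parameter; evaluating it
  on test data would leak labels.
* **Pass-through.** ECs with fewer than 10 known sequences are excluded from
  training (too little signal to fit per-EC parameters), which would leave
  them unreachable. High-confidence predictions from a designated
  broad-range tool are therefore accepted verbatim for ECs outside the
  trained range.

Alternative ensembles are provided for comparison: logistic regression on
one-hot confidence levels, random forest on ordinal levels (seeded;
hyperparameters are library defaults exposed as configuration, since no
canonical values exist for this problem), majority rule (assign iff strictly
more than half of the tools *able* to predict the EC did so — counting only
able tools keeps the vote meaningful for ECs covered by one or two tools),
and per-EC best tool (highest training F1 decides; ties assign if any tied
tool predicts; ECs missing from the performance table fall back to majority
rule with a warning).

An optional multifunctional-protein filter retains, per protein, only the
top-scoring EC(s) (ties all kept) and ECs frequently co-occurring with a
retained EC in training (defaults: co-annotated on at least 10 proteins and
on at least half of the proteins carrying the top EC). It is off by default;
evaluation elsewhere in the package considers all high-confidence ECs.

## 2. Evaluation conventions

Macro-averaged precision/recall weight every EC class equally; micro
averages pool counts. Two conventions needed fixing where definitions are
ambiguous: ECs with no predictions have undefined precision and are excluded
from the macro-precision mean (the exclusion count is reported), and macro
F1 is the mean of per-class F1 ($2TP/(2TP+FP+FN)$, defined whenever any
count is nonzero) rather than the harmonic mean of macro precision and
recall — both values are reported. Specificity on a non-enzyme set is the
fraction of those proteins receiving zero high-confidence predictions.

Cross-validation uses a stratified k-fold split in which every EC keeps at
least one training example in every fold. Multifunctional proteins appear in
exactly one test fold; assignment is greedy from rarest EC to most common,
spreading each EC's unassigned proteins over the least-loaded folds and
auditing coverage afterwards. This approximates published
multifunctional-split protocols without reproducing any specific one.

## 3. Draft assembly

Reactions linked to high-confidence ECs are collated from the reaction
database *indiscriminately* — a multi-reaction EC contributes all of its
reactions — together with spontaneous reactions, user-specified reactions
(exactly one of which must be the objective, e.g. a biomass pseudo-reaction)
and, for BiGG-like databases only, non-EC reactions supported by sequence
similarity (tabular BLAST hits, E-value at most 1e-20; the boundary is
inclusive since "cutoff" does not specify open or closed). Gene associations
are flat OR sets: the proteins supporting each EC of the reaction. The model
is single-compartment with COBRA-style default bounds, $(-1000, 1000)$ for
reversible and $(0, 1000)$ for irreversible reactions; substrates carry
negative stoichiometric coefficients. Compartment and transport prediction
are out of scope. Every reaction carries a provenance tag
(`ec_high_conf`, `spontaneous`, `user`, `similarity`, `gapfill`).

## 4. Gap-filling

A dead-end metabolite can never be produced, or never consumed, by any
reaction of the combined base-plus-candidate network, accounting for
reversibility and bounds; dead ends block every reaction touching them. The
candidate pool combines (1) reactions of ECs scored in $(0.0001, 0.5]$ —
per reaction the *highest* score over its EC annotations, with the EC score
being the maximum over proteins; (2) unscored database reactions (scores at
or below the 0.0001 floor count as unscored, since the stated interval
leaves them unaddressed); and (3) one synthesized exchange per dead-end
metabolite. Whether unscored database reactions enter the pool is
configurable (`include_no_conf`), defaulting to inclusion. Dead-end
exchanges drain by default; a metabolite that is never producible gets a
supply-only exchange and an isolated one gets both directions — a drain-only
exchange could never unblock a consumed-only metabolite.

Scored candidates are normalized to median 1 ($s'_i = s_i / s_M$; midpoint
interpolation for even-sized sets) and penalized $p_i = 1/(1+s'_i)$, a
strictly decreasing map so better-supported reactions are always cheaper.
Unscored candidates pay `default_penalty` (1); dead-end exchanges pay
`deadend_penalty` (1 by default; set it to 10 to force the model onto
user-specified media instead of inventing uptakes).

The repair is the minimum-penalty candidate subset that permits steady-state
objective flux of at least $\beta$ (default 0.1 h⁻¹):
$\min \sum_{i \in R} p_i y_i$ subject to $Sv = 0$, bounds, indicator
coupling $y_i v_{L,i} \le v_i \le y_i v_{U,i}$, and $c^T v \ge \beta$. It is
solved by LP-relaxation branch and bound: depth-first, branching on the most
fractional indicator (exploring $y=1$ first, which tends to stay feasible),
pruning nodes whose relaxation bound cannot beat the incumbent, integrality
tolerance 1e-6. Only the single optimum is returned; ties are accepted as
the solver finds them, with an optional lexicographic tie-break
(deterministic epsilon perturbation of the penalties, 1e-7 per rank — far
below any meaningful penalty difference) for reproducible tests. If the
problem is infeasible even with every candidate open, the error names the
objective precursors that cannot be produced.

## 5. The linear-programming core

No linear or mixed-integer programming backend ships with the package's
target environment, and the gap-filling formulation is the heart of the
method, so the package carries its own dense two-phase simplex. Flux balance
systems are maximally degenerate — the steady-state right-hand side is
identically zero — which defeats naive tableau implementations; the
implementation therefore uses Bland's rule (finite termination under
degeneracy), refactorizes the basis at every iteration, sign-normalizes all
rows, shifts variables to the nonnegative orthant and turns finite upper
bounds into explicit rows. Pivot and feasibility tolerances are 1e-9;
objective values below 1e-9 are reported as zero. This is entirely adequate
at the package's problem sizes (tens to low hundreds of reactions); it is
not tuned for genome-scale LPs with tens of thousands of reactions, where a
sparse revised simplex with proper factorization updates would be needed.

## 6. Simulation

`fba()` maximizes the objective under $Sv = 0$ and bounds; media override
exchange lower bounds (uptake is negative exchange flux). Knockouts exploit
the flat-OR gene model: only reactions associated with exactly one gene can
be forced off, genes appearing only in multi-gene reactions are reported
untestable, and a gene is essential when maximal growth falls below the
growth threshold (default 1e-4 h⁻¹, reusing the phenotype growth call,
with a 1e-9 numerical grace so bound-limited optima sitting exactly on the
threshold are not misclassified). Phenotype arrays block the default source
and open the alternate at 10 mmol·gDW⁻¹·h⁻¹; growth is positive at or above
1e-4 h⁻¹ (inclusive). Yield analysis bounds substrate uptake at
1 mmol·gDW⁻¹·h⁻¹ (closing oxygen uptake for anaerobic runs) and maximizes
either biomass or an ATP hydrolysis reaction
(ATP + H₂O → ADP + phosphate + proton), added transiently if absent. Every
yield run includes a zero-substrate control: a positive objective with no
substrate reveals a thermodynamically impossible energy-generating cycle, a
known failure mode of reaction databases with permissive reversibilities.
A flux-variability diagnostic reports blocked reactions (max |v| below
tolerance under the model's bounds); it is informational only.

## 7. Serialization

Models are written as SBML Level 3 Version 1 with the fbc-v2 package: bounds
as shared parameters, the objective as an fbc objective, genes as fbc gene
products with flat-OR associations. Every species element carries
SBO:0000247, every reaction SBO:0000375 and every gene product SBO:0000243.
EC links, provenance tags and gap-fill penalties travel in reaction notes,
so `read_sbml(write_sbml(m))` restores the stoichiometric matrix, bounds,
gene sets, objective and annotations exactly. Identifiers are sanitized to
SBML-safe form (non-alphanumerics to underscore, `R_`/`M_`/`G_` prefixes)
with original names kept in `name`/`label` attributes and the mapping
returned. The spreadsheet exporter writes one TSV per sheet (reactions,
metabolites, objective) — plain tabular files that any spreadsheet
application opens directly.

## 8. What the synthetic data emulates — and what it does not

`synth_predictions()` emulates the upstream-annotation stage: each protein
carries one true EC (a configurable fraction carries two), each tool
predicts true ECs within its range with a per-tool sensitivity and false
ECs with a per-tool false-positive rate, true-prediction scores are drawn
uniformly from the high bin (0.5, 1] and false scores from the full range —
the simplest model in which true predictions skew high. Defaults in the
examples (about 100–240 proteins, 4–6 EC classes, sensitivities 0.6–0.9,
false-positive rates 0.01–0.05, 5–10% multifunctional) are sized so that
every class clears the 10-sequence training floor while tests stay fast.
`synth_network()` generates four archetypes — a linear chain whose FBA
optimum equals the uptake bound, a parallel-route network for knockout
logic, a gapped chain whose withheld reactions are the unique
minimum-penalty repair (decoy reactions and scores are randomized but the
construction keeps the intended repair strictly cheapest), and an
energy-cycle network whose loop regenerates ATP from nothing. Both
generators are pure functions of their arguments and seed.

What passing these tests does **not** show: real tool score distributions
are not uniform, real EC class sizes are heavy-tailed, real proteomes have
correlated tool errors (shared training data), and real reaction databases
have inconsistent reversibility curation. The tests certify the algebra and
the optimization — posterior correctness to 1e-12 against brute-force class
enumeration, MILP optimality against exhaustive subset enumeration on pools
of up to 12 candidates, exact FBA closed forms, byte-level SBML round-trips
— not annotation accuracy on any real organism.

## 9. Problem sizes and known limitations

Test and example workloads use networks of roughly 10–30 reactions and
candidate pools of at most 12, where exhaustive enumeration remains a
practical oracle, and annotation sets of a few hundred proteins; these sizes
were chosen so the full suite exercises every code path in seconds. Known
limitations, deliberate for this scope: no compartments or transport
prediction, flat-OR gene associations (no enzyme complexes), no
thermodynamic constraints or reversibility inference, dense linear algebra,
and single-optimum gap-filling (no enumeration of alternative optima).
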