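# enzmodel

Ensemble enzyme annotation and metabolic model reconstruction in R.

Automated genome-scale metabolic reconstruction starts from enzyme (EC
number) annotations, and no single annotation tool is both sensitive and
precise across the whole EC hierarchy. `enzmodel` implements a pipeline for
research groups building draft metabolic models from protein function
predictions: it combines the outputs of several upstream EC-annotation tools
into calibrated per-EC likelihood scores, uses the high-confidence scores to
assemble a draft stoichiometric model from a reaction database, completes the
model by likelihood-weighted mixed-integer gap-filling, exports it as SBML
Level 3 (fbc), and evaluates it by flux balance analysis (growth optima,
single-gene knockouts, phenotype arrays, ATP and biomass yields).

## The models at the core

**Per-EC ensemble classifier.** For an EC predictable by *k* tools, each
protein gets a binary feature vector *F* with *F<sub>i</sub>* = 1 iff tool
*i* predicted the EC at high confidence. Each feature is modelled as a
class-conditional Bernoulli variable, and the likelihood score is the naive
Bayes posterior

> p(y = 1 | F = f) = p(y=1) ∏<sub>i</sub> p(F<sub>i</sub>=f<sub>i</sub> | y=1) / Σ<sub>C∈{0,1}</sub> p(y=C) ∏<sub>i</sub> p(F<sub>i</sub>=f<sub>i</sub> | y=C)

with add-one smoothing. Scores strictly greater than 0.5 are
high-confidence. Two rules extend the classifier: ECs predicted in training
by every able tool without false positives are auto-assigned whenever any
tool predicts them, and a designated broad-range tool's high-confidence
predictions pass through for ECs outside the trained range.
Logistic-regression, random-forest, majority-rule and per-EC-best-tool
ensembles are available as alternatives.

**Likelihood-weighted gap-filling.** Candidate reactions are those seen only
at low confidence (score s<sub>i</sub> in (0.0001, 0.5], taking the highest
EC score per reaction), unscored database reactions, and synthesized
exchange reactions for dead-end metabolites. Scored candidates are scaled to
median 1, s′<sub>i</sub> = s<sub>i</sub>/s<sub>M</sub>, and penalized
p<sub>i</sub> = 1/(1+s′<sub>i</sub>); unscored candidates pay 1 and dead-end
exchanges a user-settable penalty. The repair is the minimum-penalty subset
allowing steady-state growth:

> min Σ<sub>i∈R</sub> p<sub>i</sub>y<sub>i</sub>  s.t.  Sv = 0,
> v<sub>L</sub> ≤ v ≤ v<sub>U</sub>,
> y<sub>i</sub>v<sub>L,i</sub> ≤ v<sub>i</sub> ≤ y<sub>i</sub>v<sub>U,i</sub>,
> y<sub>i</sub> ∈ {0,1}, cᵀv ≥ β

with β = 0.1 h⁻¹ by default, solved by branch and bound over an internal
two-phase simplex.

## Worked example

```r
library(enzmodel)

## annotate: two synthetic tools with different error profiles
ecs <- sprintf("%d.1.1.%d", 1:4, 1:4)
specs <- list(detectish = list(sensitivity = 0.9, fpr = 0.05),
              priamish  = list(sensitivity = 0.6, fpr = 0.01))
train <- synth_predictions(120, ecs, specs, seed = 42)
test  <- synth_predictions(120, ecs, specs, seed = 43)
model <- train_ensemble(train$table, train$gold, train$profiles,
                        method = "naive_bayes")
hc <- select_high_confidence(score_proteins(model, test$table),
                             model, test$table)
macro_metrics(hc, test$gold)

## reconstruct and gap-fill a deliberately broken pathway
net  <- synth_network("gapped", size = 5, seed = 7)
pool <- compute_penalties(build_candidate_pool(net$db, net$scored, net$model))
prob <- gapfill_problem(net$model, pool, net$db, beta = 0.1)
res  <- solve_gapfill_milp(prob)
filled <- augment_model(net$model, res, prob)
write_sbml(filled, "filled.xml")
```

This prints:

```
high-confidence annotations: 140
macro precision/recall/F1: 0.905 / 0.963 / 0.932
draft model growth: 0.000
gap-fill selected: R02, R03 (penalty 0.339)
growth after gap-filling: 1.000
```

The held-out annotations are recovered with macro-averaged precision 0.905
and recall 0.963; the gapped draft cannot grow at all, the solver selects
exactly the two withheld pathway reactions (the cheapest repair, total
penalty 0.339), and the repaired model reaches the full growth rate set by
the substrate uptake bound.

A command-line interface wrapping the same functions is available as
`exec/enzmodel` (subcommands `ingest`, `train`, `score`, `evaluate`,
`gapfill`, `fba`, `fixtures`).

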