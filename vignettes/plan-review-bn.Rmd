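---
title: "A Bayesian-network assistant for initial radiotherapy plan review"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian-network assistant for initial radiotherapy plan review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Before a radiotherapy plan is delivered, a physicist reviews its technical
and prescription parameters — beam energy, gantry and collimator angles,
fractionation scheme, monitor-unit (MU) burden, patient setup — against what
is clinically sensible for the diagnosis. `planreviewr` automates the
probabilistic half of this initial plan review: it learns, from a clinic's
historical treatment plans, a discrete Bayesian network (BN) over 24 plan
variables, and flags any plan value whose conditional probability under the
fitted model falls below a configurable anomaly threshold.

The package also reproduces the surrounding study apparatus: a synthetic
multi-clinic cohort generator, a failure-mode error injector, and an ROC/AUC
harness for single-site, cross-site, two-train-one-test and pooled training
designs, so that the detector's transfer behaviour between clinics with
different technology and practice profiles can be studied without access to
protected institutional data.

## The model

The joint distribution over the 24 discretized plan variables factorizes over
an expert-style DAG with 41 edges:

$$P(x_1,\dots,x_{24}) = \prod_{i=1}^{24} P(x_i \mid \mathrm{pa}(x_i)).$$

Five variables are *diagnostic* (T, N and M stage, anatomic tumor location,
treatment intent); they are treated as confirmed upstream of planning and are
used only as evidence, never scored. The remaining 19 variables span patient
setup (bolus, orientation, table angle, tolerance table), treatment planning
(technique, laterality, image guidance, beam energy, radiation type, beam
count, SSD, collimator and gantry angle, wedge, MU/cGy, MU/degree) and dose
prescription (PTV dose, number of fractions, dose per fraction).

The shipped edge list is this package's own transcription of that review
topology: diagnosis drives prescription, prescription determines total dose
(PTV dose has dose-per-fraction and fraction-number as parents), and
technique plus anatomy drive the geometric and complexity variables. Node and
edge counts (24/41) are asserted by `validate_structure()`.

### Discretization

Numeric variables are binned (`default_binning()`): angles into 10° bins over
[0°, 360°), dose per fraction into 50 cGy bins up to 500 cGy plus an open top
bin, PTV dose into 500 cGy bins, fraction numbers into 5-fraction bands,
MU/cGy and MU/degree into fixed complexity bands. Intervals are half-open and
lower-inclusive, so the bin map is total and deterministic; values outside
the declared domain map to an explicit reserved out-of-range label, never to
silent missingness. The 10° angle resolution guarantees that the simulated
error magnitudes (a 10° table-angle offset, 20–30° gantry/collimator offsets)
always cross a bin boundary. The exact vocabularies are deliberately
overridable — a clinic with different linac energies or protocols supplies its
own schema and binning via YAML (`read_schema_yaml()`).

### Parameter learning

CPTs are fitted by EM with a per-cell Laplace pseudocount of $\alpha_i =
1/q_i$, where $q_i$ is the number of parent-state combinations of node $i$ —
the prior's total weight per node thus stays bounded however large the table.
On complete data the estimate is the closed form $(N_{ijk} + 1/q_i) /
(N_{ij} + r_i/q_i)$ and EM converges in a single M-step. With missing data,
the E-step exploits that a record is observed everywhere except its missing
set: conditional on the observed values, the posterior over the missing
variables factorizes over connected components of the graph that links
missing variables sharing a CPT family, and each component's posterior is a
small product of evidence-sliced CPT factors. Components and their
observation keys do not depend on the parameters, so they are precomputed and
memoized across records and iterations; in the common case (a few percent
missingness, or one structurally unrecorded leaf variable) the E-step is a
handful of table lookups per record.

Convergence is declared when the relative change of the *penalized
observed-data log-likelihood* (data log-likelihood plus the Dirichlet prior
term) drops below $10^{-4}$, with a cap of 200 iterations. The paper trail on
metric choice is thin in this field's tooling; we monitor the penalized
observed-data likelihood because its monotone increase is exactly what EM
guarantees, and the property suite asserts that monotonicity on every run.
The fit is deterministic — initialization uses available-case counts, so no
random restarts are involved.

Laplace smoothing keeps every CPT entry strictly positive, which in turn
guarantees that scoring can never encounter impossible evidence on any
combination of observed states. (Networks loaded from hand-written XMLBIF
files may contain zeros; the detector then floors the score at the smallest
representable positive value and flags the row.)

### Inference

All scoring uses exact inference — the network is small and its moralized
treewidth modest, so there is no reason to accept Monte-Carlo noise.
`marginal()` implements variable elimination with evidence slicing, barren
node pruning (only the ancestral closure of target and evidence is
retained), and a greedy smallest-factor elimination order. For the
all-evidence strategy a closed-form fast path applies: with every other
assigned variable instantiated, $P(\text{target} \mid \text{evidence})$
depends only on the CPT factors touching the target and any missing
variables connected to it through shared families; fully observed families
cancel. The fast path is checked against generic variable elimination to
$10^{-9}$ in the test suite, and both against full joint enumeration on
random small networks.

## Scoring and tiers

For each plan, every assigned non-diagnostic variable is scored by
$P(\text{observed state} \mid \text{evidence})$ under one of two strategies:

* `diagnostic_only` — evidence is the (assigned) diagnostic set, mirroring a
  review that trusts only the confirmed diagnosis; missing diagnostic values
  shrink the evidence set rather than aborting.
* `all_but_target` — evidence is every other assigned variable. Note that an
  injected error in variable $X$ then contaminates the evidence when scoring
  the *other* variables of the same plan; this is faithful to how such a
  reviewer would be deployed (observed values are instantiated as-is) and is
  deliberately not corrected.

Scores map to tiers: `pass` at or above the alert threshold (default 0.05),
`alert` between the warning threshold (default 0.01) and the alert
threshold, `warning` below. Both thresholds are configuration, not truth —
the local QA team chooses the trade-off between false alerts and missed
errors; the defaults are illustrative.

## The synthetic study apparatus

The institutional datasets behind this class of study are not publicly
available, so the package generates cohorts with the statistical structure
such a study assumes, without claiming fidelity to any real institution.

* **Base ground truth.** `base_network()` carries hand-authored, clinically
  plausible CPTs: palliative intent implies short hypofractionated courses;
  breast 3D-conformal plans have two tangent-like beams and wedges; VMAT has
  high MU/cGy but low MU/degree; PTV dose concentrates on dose-per-fraction
  × fraction-number. These dependencies are what the reviewer network is
  meant to exploit.
* **Clinic profiles.** `build_profiles()` derives per-clinic ground truths by
  drawing each CPT row from a Dirichlet centred on the base row with
  concentration $20/\text{divergence}$. Divergence 0 leaves clinics
  identical; the default 1.5 was calibrated once so that clinic CPT rows
  differ by a mean total-variation distance of about 0.2 — a "visibly
  different technology and practice" regime. Clinic A does not record wedge
  or tolerance-table settings and clinic B cannot extract bolus, emulating
  structural non-applicability; missing-at-random rates (about 2–5% on
  staging, SSD, image guidance and wedge) emulate routine record
  incompleteness.
* **Error injection.** `inject_errors()` embeds errors into exactly
  `round(0.05 n)` test plans (the conventional simulated-error rate for this
  protocol), one error event per plan by default, drawn from three equally
  weighted categories. Setup: table angle off by exactly one 10° bin
  (direction random, wrapping at 360°), bolus toggled, orientation or
  tolerance table swapped. Planning: gantry/collimator rotated by a uniform
  20–30° offset and re-binned, MU/cGy or MU/degree forced to an extreme bin,
  categorical planning variables swapped uniformly. Prescription: three
  approaches — (1) a different (dose-per-fraction, fraction-number)
  combination preserving the total-dose bin, (2) a different (PTV dose,
  fraction number) with dose per fraction stable, (3) a different (PTV dose,
  dose per fraction) with fraction number stable; approaches 2–3 draw the
  two altered bins independently, so the altered prescription is generally
  no longer arithmetically consistent — which is what makes it an error
  rather than an alternative scheme. Approaches may alter two variables; one
  injection record is emitted per actually-changed cell so ROC labels mark
  every wrong value.
* **Evaluation.** `roc_curve()` sweeps every distinct score (lower marginal
  probability = more anomalous), computes sensitivity/specificity per
  threshold and the trapezoidal AUC, which equals the Mann–Whitney statistic
  with ties counted one half. Overall AUC pools all (plan, variable)
  instances — it is not a mean of per-variable AUCs. Variables structurally
  missing at a test clinic simply produce no instances there.

## Experiment designs

`experiment_config()` validates the four designs: single-site (train = test
clinic, 80/20 split), cross-site (train on some clinics, test on disjoint
others), two-train-one-test, and pooled (train and test everywhere). The
80/20 split is per clinic, before merging, and is stratified by clinic when a
cohort spans several; errors are injected after the split, into test
partitions only. A single master seed fans out deterministically to every
stage (profile perturbation, sampling, splitting, injection), and the result
manifest records all derived seeds, so identical configs give bit-identical
results. `compare_strategies()` evaluates both evidence strategies on one
shared preparation, so strategy contrasts are never confounded by sampling.

At the default study conditions (three clinics, 2000 plans each, divergence
1.5, 5% injection) the suite checks the three qualitative patterns this kind
of multi-site validation reports: same-site training outperforms cross-site
transfer; instantiating all variables is at least as good on average as
diagnostic-only evidence; and pooled three-clinic training stays within 0.1
AUC of the best single site. Only these *orderings* are meaningful for real
data — the absolute AUCs depend on the synthetic generator and carry no
institutional meaning.

Of the three, the strategy ordering is the most seed-sensitive in this
generator: most synthetic dependencies emanate from the diagnostic
variables, so diagnostic evidence already captures much of the signal, while
the all-evidence strategy additionally pays the contamination cost described
above (an injected value appears as evidence when the *other* variables of
its plan are scored). Averaged over seeds the all-evidence strategy is at
least as good; on an individual replicate either strategy can come out
ahead. On real clinical data, where inter-parameter dependencies (machine,
energy, technique, complexity) are stronger than any diagnosis-driven
summary, the all-evidence advantage can be expected to be larger than the
synthetic study shows.

## Numerical choices and edge cases

* CPT rows must sum to 1 within $10^{-9}$; denormalized files are rejected.
* Ties and orderings: states keep schema order everywhere; no reordering.
* `split_cohort()` uses `round(fraction × n)` per clinic; fraction 1 yields
  an empty test set; fraction outside (0, 1] errors.
* An error event that cannot apply to a plan (variable missing, or only one
  state in its vocabulary) triggers a spec re-draw, then a plan re-draw,
  logged in the injection report.
* Zero-probability evidence raises a typed condition
  (`planreviewr_impossible_evidence`), never NaN.
* The all-evidence fast path falls back to variable elimination when a
  plan's missing-variable component would exceed 20,000 joint states.
* Problem sizes in the test suite (2000 plans/clinic, 5 seeds for the
  pattern study; 50,000 plans for the largest recovery fit) were chosen as
  the smallest at which the qualitative patterns are stable run-to-run.

## What passing tests do and do not show

The generator emulates clinic-specific practice distributions, structural
non-applicability and missing-at-random records. It does not model temporal
drift, correlated multi-error plans, free-text setup fields, or the
institution-specific frequency tables of any real clinic. Passing the
pattern suite therefore shows that the method behaves as the multi-site
methodology expects *given its assumptions* — not that any particular AUC
will be achieved on real institutional data. Real deployments should re-fit
on local data, re-tune thresholds with the local QA team, and re-validate.

## Known limitations

* Structure is fixed and expert-authored; no structure learning is offered.
* Scoring treats plans independently; no patient-level longitudinal model.
* The error catalogue covers the classic setup/planning/prescription
  failure modes over this schema's variables only; compound or correlated
  errors are out of scope.
* Annual model refresh is plain re-training on pooled data; no incremental
  "experience count" update scheme is implemented.
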