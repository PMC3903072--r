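---
title: "Timing tumor evolution from passenger alteration counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing tumor evolution from passenger alteration counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutclock)
```

## The model

Most somatic alterations found in a tumor genome are passengers: they are
neutral, so they accumulate at a roughly clock-like rate along the lineage
of the tumor's founder cell. The count of passenger alterations in a
sample is therefore an imperfect clock for the *tumor lineage age* — the
number of cell divisions between the patient's birth and the biopsy along
that lineage. The catch is that some driver alterations (in mutator genes
such as TP53, BRCA1/2, or regions whose loss destabilizes the genome)
raise the rate at which subsequent passengers accumulate. Ignoring that
rate change makes heavily mutated samples look older than they are and
misdates the drivers themselves.

`mutclock` implements a Bayesian latent-variable model that estimates,
per sample \(i\):

* the tumor lineage age \(T_i\) in cell divisions,
* the alteration time \(X_{ij}\) (in cell divisions) of each driver
  \(j\) altered in the sample,

and, per driver \(j\), the increase \(\Delta_j \ge 0\) of the passenger
alteration rate caused by its alteration. The observed data per sample
are the passenger count \(N_i\), the patient age \(S_i\), and indicator
pairs \(A_{ij}\) (driver altered) and \(G_{ij}\) (alteration is
germline; \(G_{ij} = 1\) forces \(X_{ij} = 0\), present from birth).

Given the latent state, the passenger count is Poisson:

\[
N_i \sim \mathrm{Poisson}\bigl(\lambda T_i +
  \textstyle\sum_{j : A_{ij} = 1} \Delta_j (T_i - X_{ij}) + E_i\bigr),
\]

where \(\lambda\) is the baseline rate per division and \(E_i\) an
exposure term absorbing extra alterations from unmodelled mutagens
(smoking, UV). The priors are:

* \(T_i \sim \Gamma(\alpha, \beta)\) truncated to
  \([t_{\min}, S_i / r]\), where \(r\) is the tissue's cell division
  time in years per division and \(t_{\min} = 50\) divisions by default —
  a lineage is unlikely to have divided fewer than 50 times, and cannot
  have divided more often than the patient's lifetime allows;
* \(X_{ij} = \infty\) with probability \(p_j\) (the driver never
  alters), otherwise \(X_{ij} \sim \Gamma(\alpha_j, \beta_j)\);
* \(E_i \sim \mathrm{Exponential}(\rho)\).

\(A_{ij} = 1\) confines \(X_{ij}\) to \((0, T_i]\); \(A_{ij} = 0\)
implies \(X_{ij} > T_i\). The hyperparameters
\((\alpha, \beta, \{\alpha_j, \beta_j, \Delta_j, p_j\}, \rho)\) are
estimated by maximizing the marginal likelihood of
\((N_i, A_{i\cdot})\) given \((G_{i\cdot}, S_i)\) over all samples;
\(\lambda\), \(r\) and \(t_{\min}\) are fixed constants. The likelihood
uses the *unnormalized* restriction of the \(X\) prior to the range
consistent with \((A, G)\) — it is a joint probability of the count and
the alteration pattern, not a conditional density — which is what makes
the per-pattern probabilities sum to one (a property the test suite
checks numerically).

The baseline rate is calibrated outside the likelihood:
\(\lambda^{\mathrm{MUT}} = 10^{-9} \times\) (base pairs sequenced in
non-driver genes), using the experimentally established per-base,
per-division mutation rate; the copy-number alteration rate is
\(\lambda^{\mathrm{CNA}} = R\,\lambda^{\mathrm{MUT}}\) with \(R\) the
ratio of average passenger CNA to passenger mutation counts per sample
(`compute_lambda()`).

## Preprocessing rules

`preprocess`-layer functions turn raw tables into the model's observed
data. For sequencing data, mutations in catalog driver genes are driver
alterations; somatic mutations in all other genes are passengers. For
segmented copy-number data:

* segments with \(\log_2\) ratio strictly above \(+1\) (amplification)
  or strictly below \(-1\) (deletion) are CNAs (`call_cnas()`);
* a CNA at least \(10^6\) bp from both ends of every recurrent region on
  its chromosome (either type) is a passenger; a CNA overlapping a
  same-type recurrent region for strictly more than two thirds of the
  region's length is a driver call for that region; everything else is
  discarded (`classify_cnas()`);
* same-type passenger CNAs separated by fewer than \(10^5\) intervening
  base pairs are merged (`merge_passenger_cnas()`).

Coordinates are treated as 1-based inclusive (SEG convention), so an
overlap length is `min(end) - max(start) + 1` and the gap between two
calls is `start2 - end1 - 1`. Drivers altered in at most 10 samples are
dropped (a keep-list can force-retain a known mutator observed less
often), and drivers altered in more than 90% of samples are dropped with
a warning — with almost no unaltered samples their parameters are not
estimable, and keeping them silently would bias every age upward.
Recurrent-region finders sometimes emit several "satellite" regions for
one underlying event; `dedupe_satellite_regions()` automates the cleanup
with a sample-set Jaccard similarity rule (default threshold 0.6,
transitively closed, keeping the most-altered region). The rule is an
automated stand-in for what is otherwise a visual heatmap check, and is
deliberately an optional, logged step.

## Numerical evaluation of the likelihood

The per-sample marginal likelihood integrates the Poisson kernel over
\(T\), over \(X_j\) for every somatically altered driver, and over
\(E\). Three observations make this fast and robust without any
stochastic integration:

1. **Count decomposition.** Conditional on \(T = t\), the passenger
   count is a superposition of independent Poisson components — a
   baseline (plus germline drivers, whose \(\Delta_j t\) is
   deterministic), one component per somatically altered mutator driver,
   and the exposure component. The joint integral over all \(X_j\) and
   \(E\) therefore factors into one 1-D integral per component, combined
   by discrete convolution over count allocations. The integral's
   dimension never grows with the number of altered drivers.
2. **Closed-form exposure.** A Poisson count with exponentially
   distributed extra mean is a geometric mixture; the baseline-plus-
   exposure component satisfies the O(1)-per-count recursion
   \(e_k = e_{k-1}/(1{+}\rho) + \tfrac{\rho}{1+\rho}\,
   \mathrm{Pois}(k; m_0)\).
3. **Prior-probability-space quadrature.** The \(T\) integral uses
   Gauss–Legendre nodes placed at quantiles of the truncated \(T\)
   prior, and each \(X_j\) integral uses equal-prior-mass cells of the
   driver's Gamma prior, each cell represented by its conditional mean
   (computed from the shape+1 partial-moment identity). Integrating in
   probability space keeps the rules accurate *no matter how
   concentrated a fitted prior becomes*. This matters: with fixed nodes
   on \((0, t]\), a maximizer can wander into sharply peaked prior
   configurations where an under-resolved quadrature overestimates the
   likelihood by hundreds of log units, and the "optimum" is an
   artifact. Mass-space rules bound the error by the integrand's
   variation per mass cell and close that loophole.

`quad_spec(n_t, n_x)` freezes the resolution. The default (24, 64) gives
relative likelihood errors around \(10^{-4}\); the simulation studies in
the test suite use (10, 24) for point fits — the tumor-age rule needs
about ten nodes before rate-increase estimates stop drifting — and
(6, 16) for bootstrap replicate refits, whose percentile intervals are
insensitive to the shared, smaller-resolution bias; single-sample checks
against a dense 3-D Riemann oracle use (48, 256). Samples sharing a patient age share
their \(T\) grid, so per-driver quantities are cached per unique age,
and samples sharing age and indicator pattern share the entire count
vector.

## Fitting, bootstrap, and boundary inference

`fit_timing_model()` maximizes the cohort log-likelihood with `nlminb`
(bound-constrained quasi-Newton) on transformed parameters: logs for the
positive hyperparameters, the natural \([0, 1]\) box for \(p_j\), and
the dimensionless fold increase \(\Delta_j / \lambda\) on \([0, 30]\).
Two details are deliberate:

* \(\Delta_j\) is *not* log-transformed, so the no-mutator boundary
  \(\Delta_j = 0\) is attainable exactly — percentile bootstrap
  intervals for a boundary parameter are meaningless if the estimate can
  only approach zero asymptotically;
* the \(X\)-prior shape is constrained to \(\alpha_j \ge 1\): shapes
  below one put an integrable singularity at \(x = 0\) that no fixed
  rule resolves well, and the \(\alpha_j = 1\) (exponential) boundary
  already expresses "earliest-heavy" timing distributions.

Starts are deterministic: moment-style values for \((\alpha, \beta)\)
from the counts, \(p_j\) from carrier fractions, and two starting points
for the rate increases (all zero; all equal to \(\lambda\)). The best
converged start wins; a fit that cannot produce a finite objective from
any start is an error, and cohorts with fewer usable samples than free
parameters warn.

`bootstrap_timing()` resamples whole samples with replacement (the
default \(B = 400\), 90% percentile intervals), refits each replicate
warm-started from the point estimate with a capped iteration budget
(default 12), collapses duplicated rows into weights, and recomputes the
posterior summaries of the *original* cohort under each replicate's
parameters. Because \(\Delta_j\) lives on a boundary, each replicate is
also offered a second start in which the boundary-candidate rate
increases are zeroed; a driver is a boundary candidate when zeroing its
\(\Delta_j\) alone costs the point fit fewer than 3 log-likelihood
units. Without this, warm-started replicates in flat directions never
reach zero within the budget and the resulting intervals are spuriously
narrow around small positive estimates. Replicates in which a driver
loses all carriers contribute no \(\Delta_j\) draw for it; replicate fit
failures are dropped, and more than 10% of failures aborts.

`call_mutators()` reports the drivers whose interval lower bound is
strictly positive. `posterior_summaries()` computes posterior mean ages
and alteration times as ratios of integrals sharing the likelihood's
quadrature; a germline driver has posterior time exactly zero, and the
per-sample order sorts altered drivers by posterior mean time with an
alphabetical tie-break. `build_order_tree()` summarizes the orders as a
prefix trie, pruning subtrees whose first-two-alteration prefix occurs
fewer than `min_support = 2` times. `comparator_test()` is the naive
alternative — a Welch test of passenger counts by alteration status —
kept because it illustrates the method's point: a driver that merely
alters *late* is also enriched in high-count samples, so the comparator
flags late drivers as spurious "mutators" while the model attributes the
correlation to timing.

## The simulator and what the tests show

`simulate_cohort()` runs the generative model forward, bit-reproducibly,
with one seeded substream per sample (so enlarging a cohort leaves
earlier samples unchanged). Its default conditions (`sim_params()`)
emulate a copy-number cohort: baseline rate \(\lambda = 0.01\) per
division (roughly ten passenger CNAs over a thousand-division lineage),
tumor-age prior with untruncated mean 1100 divisions and shape 4
(posterior ages spanning a few hundred to a few thousand divisions),
an 8-day division time, integer patient ages uniform on 40–80 years,
exposure mean 1, and two drivers with mean alteration time 400 divisions
and never-alters probability 0.4 — one mutator at
\(\Delta = 2\lambda\), one null. The full-scale studies in the test
suite use cohorts of 300–500 samples, \(B\) of 100–200, point-fit
quadrature (10, 24) with replicate quadrature (6, 16), and an optimizer
budget of 150 iterations (point fits) / 12 (replicates); these sizes
were fixed once as the study design.

The simulator draws from exactly the distributions the likelihood
integrates over, so recovery tests validate the inference machinery, not
the model's fit to real tumors. Real data violate the model in known
ways the simulator does not reproduce: subclonal structure (counts mix
lineages), per-gene and per-site rate heterogeneity, rate changes that
are not single steps, measurement error in calling alterations, and
driver catalogs that are themselves estimates. Passing tests therefore
demonstrate correct computation and calibrated inference *under the
model*, nothing more.

## Numerical and design choices worth knowing

* Likelihood errors surface as errors, not values: a sample with zero or
  non-finite likelihood names itself; during optimization such regions
  are penalized and avoided.
* Patients too young for the age bound (\(S/r \le t_{\min}\)) are
  excluded with a warning rather than clamped.
* Percentiles everywhere (bootstrap intervals, the cohort age summary)
  use linear interpolation (R's default type 7), stated in the report
  header.
* Order confidence is the fraction of bootstrap replicates reproducing a
  sample's *entire* driver sequence, the strictest reading of "same
  order".
* The comparator test reports raw Welch p-values against a 0.01
  threshold, deliberately uncorrected — it is the foil, not the method.
* Mutation and copy-number data for the same samples are fitted
  separately by default; a shared-age joint fit would force one \(T_i\)
  across data kinds whose rate calibrations differ in reliability, so it
  is left out of scope.
* Bootstrap intervals for posterior quantities may occasionally fail to
  contain the point estimate (resampling plus refitting does not
  guarantee containment); the package warns rather than hiding it.
* When rate increases are pinned to zero (`fix_delta_zero = TRUE`), a
  refit routes part of a genuine mutator's excess counts into the
  exposure term, so the age inflation caused by ignoring a mutator is
  concentrated in — and should be assessed on — the samples carrying the
  mutator; non-carrier ages can even deflate as the exposure channel
  recalibrates.

## Known limitations

Rate-increase estimates for drivers altered in few samples are noisy and
their intervals wide; the timing of non-mutator drivers is informed only
through the correlation between carrier status and inferred age, so
posterior times for such drivers lean on the fitted prior; and the
capped replicate budget trades a small amount of interval width for a
large amount of speed — studies needing publication-grade intervals
should raise `control$iter_max` in `bootstrap_timing()` and the
quadrature resolution, at proportional cost.
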