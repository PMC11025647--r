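---
title: "Methods: surprisal, Agent Preference, and topographic N400 models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surprisal, Agent Preference, and topographic N400 models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question and the shape of the pipeline

During incremental comprehension of verb-final sentences, a
role-ambiguous initial noun phrase can be read in two ways: as the
agent or as the patient of the upcoming verb. The *Agent Preference*
hypothesis holds that comprehenders commit, transiently, to the agent
reading, and must reanalyse — at a measurable neural cost indexed by
the N400 — whenever the verb disambiguates the NP towards a patient.
The competing, leaner hypothesis is that the N400 at the verb simply
tracks *surprisal*, $s(w) = -\log P(w \mid \text{context})$, under a
probabilistic model of linguistic experience: if patient-initial
continuations are rare, the disambiguating verb is surprising, and no
dedicated reanalysis mechanism is needed.

`n400stack` implements the complete chain of machinery needed to pit
these hypotheses against each other on *simulated* data whose ground
truth is known: generate a toy language and factorial stimuli; train
small probabilistic language models and extract critical-word
surprisal; verify the models behave (grammaticality and condition
contrasts); generate single-trial ERP amplitudes with configurable
condition and surprisal topographies; fit a family of topographic
additive models; and let leave-one-out stacking decide which predictors
earn weight. Every downstream claim in the package is a *recovery*
claim: with effects present, the combined (surprisal + Agent
Preference) model should win the stack; with an effect removed, it
should not.

# Toy languages and the reanalysis coding

A `language_spec` describes a language at the constituent level:
single-token noun phrases, verbs and auxiliaries, a discrete
distribution over ordered templates (`"A-P-V"`, `"P-V-A"`, ...), and
marking probabilities. Case marking is a suffix on the noun form;
*syncretism* — the engine of the designs' ambiguity — is modeled as
surface-form identity: a syncretic marked form carries the role-neutral
suffix `-x`, and unmarked forms are bare, hence equally role-neutral.
We deliberately model no real morphology and use synthetic symbol
strings (`n017`, `v003`): the package makes no pretense of modeling
German, Hindi or Basque lexically; it reproduces the *structural*
mechanism (who is marked, when marking is ambiguous, which orders are
licit).

Three presets mirror the structural gradient of the three designs:

* `german_like` (accusative): agents unmarked, patients marked
  (`p_mark_patient = 0.9`), rigid verb-final orders with a final
  auxiliary. Unmarked patients are *rare*.
* `hindi_like` (split): agent marking conditioned on an aspect-like
  label (ergative marking in the perfective only), patients marked
  about half the time. Unmarked patients are *mixed*.
* `basque_like` (ergative): agents marked, patients unmarked.
  Unmarked patients are *common*.

Stimulus sets are 2×2 factorials with lemmas shared across the four
cells of an item. The binary Agent Preference predictor is coded by a
single rule — reanalysis if and only if the initial NP is
role-ambiguous *and* the critical word disambiguates it to patient —
which yields, per design: German-like, both patient-initial cells;
Hindi-like, both ambiguous cells (all items are patient-disambiguating);
Basque-like, only the ambiguous patient cell. The twelve
design-by-condition rows are frozen as a fixture in the test suite.

Default stimulus count is `n_items = 40` per design; the per-language
counts of the original experiments are not part of the package's
inputs, and 40 items keeps every recovery experiment comfortably
desk-sized. Ungrammatical variants for the grammaticality test permute
*constituents* (e.g., auxiliary displacement), never words inside a
constituent, and are checked against the language's grammatical
templates by exhaustive enumeration.

# Language models and surprisal

The analysis layer needs *multiple surprisal columns with different
conditioning behavior*, not architectural fidelity; the package
therefore provides count-based incremental estimators (unigram /
bigram / trigram; additive or interpolated smoothing) and maps the
three architecture families onto them in the pipeline defaults:
`lstm` = bigram scored incrementally, `bert` = trigram scored in
mask-and-truncate mode, `gpt` = trigram scored incrementally. A
`tiny-rnn` estimator would slot into the same interface but is not
provided. For left-to-right count models, mask-and-truncate scoring
(mask the target, drop all right context) coincides with incremental
scoring by construction; the mode is recorded so that genuinely
bidirectional estimators could differ.

Conventions worth stating once:

* Surprisal is in **nats** everywhere; `nats_to_bits()` converts.
* An implicit begin-of-sentence symbol conditions the first word; no
  end-of-sentence event is scored.
* The vocabulary is capped by frequency (ties broken
  lexicographically); all other forms map to a reserved OOV symbol
  which receives smoothed probability mass like any other form.
  Critical words that are OOV *raise* rather than score, and
  `filter_oov()` drops affected items across all four cells (keeping
  the factorial balanced), considering only positions up to and
  including the critical word.

# Evaluating the language models

**Grammaticality.** For each grammatical sentence we draw two to four
ungrammatical constituent permutations, score every word in linear
order, and average per sentence. ΔSurprisal (scrambled minus
grammatical) is then estimated by a hierarchical normal model with
sentence-level random intercepts (`lme4`); the model "passes" when the
central interval (default 89%) excludes zero from above. A unigram
model is order-insensitive, so its ΔSurprisal is *exactly* zero — a
useful built-in null. Degenerate inputs (all deltas identical) shortcut
to a width-zero interval rather than a mixed-model fit.

**Condition contrasts.** Critical-word surprisal is heavy-tailed
(near-deterministic contexts produce many identical low values, rare
contexts produce large ones), so the condition-contrast model draws
surprisal from a Student-t distribution with the two design conditions
and their interaction as fixed effects and by-item random intercepts
and condition slopes. Priors: $\nu \sim \mathrm{Gamma}(2, 1)$,
residual and random-effect SDs $\sim \mathrm{Exponential}(1)$,
intercept and slopes $\sim \mathrm{Normal}(0, 2)$; inference is MCMC
(JAGS, 2 chains, 2000 iterations by default) with R-hat / effective
sample size flags. The reported contrast is "N400-eliciting level minus
the other", within each level of the control condition, as a posterior
mean with an 89% central credible interval (50/80/90% summaries can be
had from the stored draws). Scale parameters are truncated below
(residual SD at $10^{-3}$, random-effect SDs at $10^{-4}$): with
near-deterministic toy estimators the residual scale can otherwise
collapse to zero and overflow the likelihood — a degenerate-input guard,
not a prior choice with practical influence elsewhere. Classical paired
t tests accompany the posterior summaries; zero-variance differences
return $t = \pm\infty$, $p = 0$ with a flag.

# The synthetic ERP generator

The generator produces the *analysis-ready* quantity directly — the
300–500 ms window-mean amplitude per participant × stimulus ×
electrode — rather than simulating time series; nothing downstream
consumes time-resolved data. Electrodes live on the closed unit disk,
nose up, `Cz` at the origin (a 32-channel 10-20-like montage ships
with the package; arbitrary deterministic layouts are available).

$$\mu V = \beta_0 + \beta_{trial}\,\mathrm{trial}_z
  + f_{cond}(x, y)\,\mathrm{cond}
  + f_{surp}(x, y)\,\mathrm{surp}_z
  + a_p(x, y) + b_i(x, y) + \varepsilon$$

Effect fields $f$ are sums of isotropic Gaussian bumps; random
participant ($a_p$) and item ($b_i$) topographies are low-rank bump
fields with Normal amplitudes — cheap, smooth, and sufficient to
exercise the random-effect smooths, though they span a much smaller
function class than real inter-individual variability. N400-like
(negative-going) effects are encoded as negative amplitudes; nothing
flips signs at analysis time. Continuous predictors are z-scored over
the generated dataset.

Reference conditions (the package's defaults, used by all recovery
experiments): baseline 2 µV; trial drift **0.5 µV/z**; condition field
one bump, **−1.0 µV**, width 0.5, centered right-posterior
(0.35, −0.45); surprisal field one bump, **−0.8 µV/z**, width 0.6,
centered centro-posterior (0, −0.35); random-field amplitude SDs 0.5
(participant) and 0.3 (item); noise SD **2 µV**; **12 participants**.
Presentation is Latin-square by default in the pipeline: each
participant sees each item in exactly one of its four cells, cells
rotating across participants, which is how the factorial designs are
actually run and which keeps one amplitude per participant × item ×
electrode. The stimulus random topography is keyed to the *item*, the
grouping the downstream models also use.

What the generator does **not** emulate: volume conduction and the
resulting spatial correlation structure of real EEG, artifacts and
preprocessing residue, non-Gaussian noise, oscillatory activity,
habituation beyond a linear trial drift. Passing recovery tests
therefore shows the *pipeline* is sound — unbiased where it should be,
ranking models correctly under known truth — not that real N400 data
satisfy the generator's assumptions.

# Topographic additive models

The model family mirrors the standard eight-row table: a baseline
(`1 + trial + re(participant) + re(item)`), an Agent-Preference-alone
model, one surprisal-alone model per surprisal column, and one
combined model per surprisal column, each with tensor smooths varying
by the predictor:

$$\mu V \sim 1 + \mathrm{surp} + \mathrm{cond} + \mathrm{trial}
 + t_2(x, y,\ by = \mathrm{surp}) + t_2(x, y,\ by = \mathrm{cond})
 + \mathrm{re}(participant) + \mathrm{re}(item)$$

**Basis and penalties.** Each margin is a B-spline basis (cubic where
the dimension allows) on equally spaced knots over $[-1, 1]$ with a
second-difference penalty; the tensor term takes all products of
marginal functions with the two Kronecker penalty blocks
$S_x \otimes I$ and $I \otimes S_y$, so smoothness in $x$ and $y$ is
penalized separately. Marginal dimensions default to
$k_x = k_y = 5$ (25 tensor functions) for by-smooths and $3 \times 3$
(9 functions) for the random topographies; the coarser random basis
reflects their nuisance role and keeps the coefficient count linear in
the number of participants and items.

**Identifiability.** B-splines are a partition of unity, so the
constant function is the coefficient vector $\mathbf 1$; each
by-smooth is reparameterized onto the orthogonal complement of
$\mathbf 1$ and the constant is carried by the predictor's fixed main
effect. The penalty null space then contains the (centered) linear
surfaces, which are estimated unpenalized. Random topographic effects
are per-level coefficient vectors on the shared coarse tensor basis
with one ridge penalty (one variance parameter) per grouping factor.

**Fitting and the posterior.** The likelihood is Gaussian; penalized
blocks are equivalent to mean-zero Gaussian priors with precision
proportional to the smoothing parameter. Smoothing parameters are
estimated by REML (the extended Fellner–Schall update, which is
markedly faster than full Newton with six or more penalty blocks and
agrees closely), and the posterior is the standard Gaussian
approximation (coefficient mean plus covariance) *conditional on* the
estimated smoothing parameters — the same object a fully Bayesian fit
with those priors would center on, at a fraction of the cost. Specs
with no penalized terms reduce exactly to ordinary least squares,
which the tests pin to $10^{-8}$. Random-slope extensions of the
tensor models (beyond random topographies) are not offered; the
single-electrode models carry the random slopes instead.

**Difference surfaces.** `difference_surface()` evaluates the
posterior of $\widehat{\mu V}(\mathrm{level}_1) -
\widehat{\mu V}(\mathrm{level}_2)$ on a lattice over the disk, holding
other covariates at 0 on the z-scale (the reference is a choice; it is
stated here once). Default levels: condition 1 vs 0; surprisal $+2$
vs $-2$ SD. Evidence per point is
$\max\{P(\Delta > 0), P(\Delta < 0)\}$ from posterior draws (0.5 for a
degenerate zero contrast, ties split evenly), masked for display below
0.8.

A calibration note: on null data the masked fraction at the 0.8
threshold averages roughly one half, not near one. The surface's
posterior at every grid point inherits the predictor's *unpenalized*
fixed main effect, whose posterior sign probability under the null is
approximately uniform — a single draw of $|z| > 0.84$ unmasks the
whole map. Any calibrated fit that keeps an unpenalized (or, with a
weak $\mathrm{Normal}(0,2)$ prior, effectively unpenalized) main
effect behaves this way; only full shrinkage of the main effect would
change it, at the price of leaving the stated model family. The test
suite asserts a stricter masking expectation and deliberately leaves
it failing rather than altering the model family to meet it; the
measured masked fractions are computed by the test itself.

**Single electrodes.** At one electrode the tensor term is replaced by
random slopes: `amplitude ~ cond + surp + trial + (1 + cond + surp |
participant) + (1 | item)` (REML via `lme4`), reported with Gaussian
posterior summaries and sign probabilities — the residual
autocorrelation objection to scalp-level smooths does not apply when
no spatial structure is present.

# Leave-one-out stacking

For each candidate model the package computes pointwise out-of-sample
predictive densities $p(y_i \mid y_{-i}, M_k)$, holding smoothing
parameters and residual variance at their full-data estimates:

* **exact** — closed-form Gaussian case deletion via hat values:
  $m_{-i} = (\mu_i - h_i y_i)/(1 - h_i)$,
  $v_{-i} = \sigma^2/(1 - h_i)$;
* **psis** — importance ratios $1/p(y_i \mid \theta_s)$ from posterior
  draws, upper 20% tail replaced by expected order statistics of a
  generalized Pareto fit (Zhang–Stephens profile posterior), truncated
  at the raw maximum; points with tail shape $\hat k > 0.7$ fall back
  to the exact computation and are counted in the diagnostics.

The leave-one-out *unit is the observation row*. With grouped data
this is a deliberate, consequential choice: the item random topography
partially absorbs item-level predictors, so row-wise LOO differences
between candidate models are small (fractions of a millinat per
observation) and model discrimination needs enough distinct items —
which is why the recovery experiments use 24 items rather than a
handful. Row-wise densities keep the stack comparable with standard
stacking practice; a grouped (leave-one-item-out) variant would
sharpen discrimination but change the estimand.

Weights maximize the concave objective
$\frac 1 n \sum_i \log \sum_k w_k\, p_{k,i}$ over the simplex by
exponentiated-gradient ascent with step halving, stopping when the
objective improves by less than $10^{-10}$; identical columns keep
exactly symmetric weights (uniform start, identical gradients), and
weights below $10^{-3}$ are snapped to zero only when that does not
lower the objective, so dominance cases return exact unit vectors.
The tests verify the optimum against a 0.01-step simplex grid search.

# Problem sizes, seeds, and reproducibility

All randomness flows from explicit integer seeds; per-stage seeds are
derived from a master seed by stable hashing of stage names, so stages
reproduce independently of execution order, and the pipeline manifest
records per-stage seeds, timings and MD5 checksums (a rerun with the
same configuration is checksum-identical).

Sizes used by the recovery experiments, chosen as representative
desk-scale versions of the designs: grammaticality, 200-sentence
corpora with 20 evaluated sentences and 20 replicates; condition
contrasts, 40 items with 20 null replicates; fixed-effect recovery,
12 participants × 24 stimuli × 16 electrodes (4,608 rows) with 20
replicates; stacking recovery, 6 participants × 24 stimuli × 10
electrodes (1,440 rows) with 20 effect and 10 null replicates.

# Known limitations

* Surprisal estimators are count-based stand-ins; nothing is claimed
  about neural-architecture differences beyond their conditioning
  windows.
* The Gaussian-bump function class used for random topographies is
  narrower than real inter-participant variability; random-effect
  variance estimates on real data would be less well behaved.
* The GAM posterior is conditional on estimated smoothing parameters;
  peak heights of penalized surfaces are shrunk toward zero (the
  electrode-averaged effect, carried by the unpenalized direction, is
  not), and smoothing-parameter uncertainty is not propagated.
* Row-wise LOO with item-level predictors limits model discrimination
  at small item counts, as discussed above.
* At realistic EEG spatial resolution, scalp smooths cannot be
  distinguished from residual spatial autocorrelation; the
  single-electrode models are the package's answer, with their own
  loss of information.
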