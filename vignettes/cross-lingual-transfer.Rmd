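---
title: "Zero-shot cross-lingual transfer of form-meaning and form-class mappings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-shot cross-lingual transfer of form-meaning and form-class mappings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iconotrans)
```

## The question

A strictly arbitrary lexicon carries no information about a word's meaning in
its sound. Two departures from arbitrariness are of interest: *iconicity*, a
resemblance-mediated link between phonological form and the referent
(bouba--kiki), and *systematicity*, statistical regularity between form and a
word's class or usage pattern. If such links are shared across languages --
rather than being language-specific convention -- then a mapping from sound
to meaning learned in several languages should transfer, without any further
training, to a language from an entirely different family.

`iconotrans` implements that transfer test end to end:

1. words are decomposed into sequences of subsegmental articulatory feature
   vectors (one ternary vector per phone), zero-padded to 15 positions and
   masked;
2. a many-to-one recurrent network (a single LSTM layer plus a dense output)
   maps each padded sequence to a dense *visual* vector, a dense *semantic*
   vector, or a one-hot *word class*;
3. models are trained on the concatenated training material of all languages
   but one and evaluated on held-out concepts in the held-out language
   (leave-one-language-family-out, each language held out exactly once);
4. every experimental model is paired with a *randomized baseline*: an
   identically configured and identically seeded twin trained on the same
   inputs after the output vectors have been permuted, which quantifies what
   the architecture achieves with the form--target pairing destroyed;
5. the two models are contrasted per fold with a paired t-test over per-item
   cosine similarities (regression) or a McNemar chi-square over per-item
   correctness (classification).

## The mapper

The regressor minimizes the negative mean cosine similarity
$\mathcal{L} = -\tfrac1B\sum_b \cos(\hat y_b, y_b)$ with Adam
(learning rate 0.01); the classifier minimizes categorical cross-entropy over
softmax outputs. Defaults follow the reference design and were not tuned:
dropout 0.2 and recurrent dropout 0.2 (variational masks, one per word,
reused across timesteps, inverted scaling; evaluation is always
deterministic), one training epoch, batch size 32 (configurable; the source
design leaves it open). Hidden sizes default to 500 (visual), 50 (semantic)
and 25 (word class). For the semantic experiment the output layer is linear
and its width equals the target dimensionality; the alternative reading of
the reference design (a dense layer shaped like the 50-unit recurrent layer)
would decouple the output from the target and is not adopted. Rectified
outputs are used for the visual experiment because pooled convolutional
feature maps are nonnegative.

Masked positions leave the hidden and cell state untouched, so predictions
are a function of the unmasked prefix only -- appending or corrupting padding
rows cannot change a prediction, which the tests assert bitwise. Gate
parameters use Glorot-uniform input kernels, orthogonal recurrent kernels
(sign-fixed for determinism), and a unit forget-gate bias. All gradients are
exact (verified against central finite differences to `1e-4`) and the whole
train-plus-predict path is bit-reproducible given the seed. Training words
longer than 15 phones keep their word-initial 15 phones. When a trained
model reports its training metric it recomputes it with a deterministic
forward pass, so the logged value equals an external recomputation.

## Folds, shuffling, oversampling

Concepts are split once into train and test (ratio 0.8 for the regression
experiments, 0.5 for classification so minority classes retain test
support), with the train size rounded half-up -- this reproduces published
splits such as 1161 -> 929/232 and 24612 -> 19690/4922, where flooring would
not. Training material for a fold concatenates the train split of every
language whose family differs from the held-out language's; the test set is
the held-out language's test split only. Train and test are therefore
disjoint in concepts, languages and families, and `verify_disjoint()` audits
all three invariants.

The baseline permutation is drawn once over the whole concatenated training
set (a per-language variant is available behind a flag). Class imbalance in
the classification experiment is handled by random oversampling of every
non-majority class up to the majority count, per language, before
concatenation -- consistent with the published per-language balanced size
(64,600) scaling fivefold to the concatenated size (323,000). The test set
is never oversampled.

## Statistics

Per-fold summaries report mean, sample SD and the normal-theory 95% interval
$\bar x \pm 1.96\,s/\sqrt n$. This construction reproduces the published
interval pairs from their printed (mean, SD, n) to the printed four decimals
wherever the rounded inputs permit it (a printed bound can sit half an ulp
away; the tests therefore require exact agreement where it is attainable and
one-printed-ulp agreement everywhere). The paired effect size is Cohen's d
for paired data, $\bar d / s_d$: the published effect sizes are not
reproducible from the published t and n under any standard formula, so they
are not treated as targets. P-values are two-sided (the published tables
report a negative-t fold with p far from zero, consistent with two-sided
reporting). McNemar uses the plain $(b-c)^2/(b+c)$ chi-square without
continuity correction, with the corrected variant behind a flag; the
degenerate $b+c=0$ table reports $\chi^2=0,\,p=1$ with a warning. Weighted
precision and F1 weight per-class scores by true-class support; a class that
is never predicted contributes zero precision; support-weighted recall is
omitted because it equals accuracy.

One statistical subtlety deserves emphasis. The per-fold paired t-test
treats test items as the unit of analysis, but the two models being compared
are each a single draw from a training process: whole-model variation
induces correlated per-item differences, so item-level tests on one model
pair are anticonservative under a model-level null. For the type-I
calibration check the package therefore aggregates first -- one mean cosine
per fold per model -- and applies the paired test across the six folds of a
run. On lexicons generated with no planted signal this fold-level test
rejects at about its nominal rate, which the acceptance suite verifies over
20 independently generated null lexicons.

## The synthetic generator

No external datasets ship with the package; a generative model produces
multilingual lexicons with the structure the design assumes and a
controllable signal:

* each concept has a latent meaning $m_i \sim N(0, I_M)$ and a class
  $c_i \sim \mathrm{Cat}(\pi)$ with a skewed 1/rank default for $\pi$;
* targets are noisy linear readouts: visual
  $v_i = \max(0, A m_i + \sigma\varepsilon)$ (rectified, like pooled
  convolutional features), semantic $s_i = B m_i + \sigma\varepsilon$, with
  $A, B$ entries $N(0, 1/M)$ so targets have unit-order scale;
* word forms are sampled phone by phone from a softmax over the inventory
  with logits
  $[\beta \cos(f_p, u_i) + \gamma \cos(f_p, w_{c_i}) + \lambda\, b_{lp}]/\tau$,
  where $u_i = \tanh(G m_i)$ and $w_c = \tanh(H e_c)$ are feature-space
  readouts through matrices shared by **all** languages (the cross-lingual
  carrier of the signal), and $b_{lp} \sim N(0,1)$ are language-specific
  phone biases playing the role of phonotactics. $G$ has $N(0, 1/M)$
  entries so the pre-tanh activations are unit-scale; $H$ is standard
  normal. Word lengths are uniform on [3, 9] by default.

Defaults: 6 languages with one family each (so family-disjointness equals
language-disjointness), 40 phones, 24 features, $\lambda = 1$,
$\sigma = 0.1$, $\tau = 0.5$. At $\beta = \gamma = 0$ the lexicon is
arbitrary and serves as the null. Feature vectors take values in
\{-1, 0, +1\}, the ternary convention of articulatory feature systems; the
all-zero vector is reserved for padding and rejected as a phone vector, so
the padding symbol is unambiguous.

What the generator does *not* emulate: syllable structure and sonority
constraints, morphology, etymological relatedness between languages, and --
importantly -- heterogeneity of signal strength across word classes. Because
$H$ is i.i.d. and $\gamma$ is a single scalar, the synthetic classes are
statistically exchangeable: no class is systematically more "iconic" than
another, unlike real parts of speech where interjections carry far more
form-class signal than nouns. Cross-language agreement of *per-class*
accuracy profiles is therefore weak on synthetic data even when the class
signal itself transfers strongly, and passing or failing that agreement
check says little about real lexicons.

A second structural property matters for power analysis. The iconic term
$\beta\cos(f_p, u_i)$ is a cosine of 24-dimensional ternary vectors and so
has spread of roughly $1/\sqrt{24} \approx 0.2$ across phones, against a
language-bias spread of $\lambda = 1$: at full strength the planted signal
perturbs phone logits at about one fifth the magnitude of the phonotactic
bias. The per-word information about the target is correspondingly small,
and detecting the transfer advantage at conventional significance in a
single fold requires either large concept inventories or aggregation across
folds. The test suite runs the recovery experiment at 600 concepts and the
calibration experiment at 120 concepts with reduced target dimensionality
and hidden size; these sizes were chosen to probe exactly this
signal-to-noise regime while keeping each experiment to a few minutes of
single-core compute; with larger concept inventories the same pipeline gains
single-fold power, since the per-word signal accumulates over training
items while the phonotactic bias averages out across the five training
languages.

## Numerical and interface choices

* Greedy longest-match segmentation resolves multi-character IPA symbols;
  whitespace separates tokens and never joins a symbol.
* Splits, shuffles, model initialization and oversampling take seeds by
  role, so ablating one randomization leaves the others fixed; the baseline
  twin shares the experimental model's seed, isolating the pairing as the
  only difference.
* Zero vectors have no direction: `cosine_sim()` errors rather than
  returning 0 silently.
* The word-class collapse map is a user-supplied CSV (`raw_tag,supertag`)
  rather than a hard-coded table, because the published 54-to-11 collapse is
  not recoverable; the bundled default is the identity over the synthetic
  classes. A tag collapsing to a dropped supertag yields a skip marker, not
  an error, mirroring the silent removal of a class dimension that does not
  survive preprocessing.
* Interchange formats are plain text throughout: TSV lexicon entries, CSV
  feature tables, word-embedding text format (`"N dim"` header) for dense
  targets.

## Limitations

The generator's arbitrariness null is idealized: real "null" lexicons still
contain morphological families and loanwords. The LSTM is deliberately the
reference architecture, not a state-of-the-art sequence model. Effect sizes
on synthetic data depend on generator settings and transfer to real lexicons
only qualitatively. Published headline cell values (per-fold cosines,
t statistics, chi-squares on the original datasets) require the original
images, embeddings and dictionaries and are out of scope; what the package
reproduces exactly is the fold arithmetic and the interval reconstruction,
and what it establishes behaviorally -- signal recovery, null calibration,
disjointness, determinism -- it establishes on synthetic data.
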