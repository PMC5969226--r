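---
title: "Models and methods behind morphsurp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind morphsurp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`morphsurp` studies a single scientific question end to end: how much of the
item-level variation in evoked brain responses and reaction times during
visual word recognition can be accounted for by information-theoretic
properties of the words themselves. The package provides (i) a
minimum-description-length (MDL) morph segmentation model that turns a word
frequency list into per-word surprisal estimates, (ii) six further surprisal
predictors spanning visual, orthographic, morphological and lexical levels
of description, (iii) a generator for synthetic lexica, stimulus sets and
lexical-decision responses with planted linear effects, and (iv) the
item-level analysis stage (z-scoring, item averaging, simple correlations,
forward stepwise regression, tertile-binned curves). This vignette documents
the models, the tunable parameters, and the design decisions where the
methodology was genuinely open.

## The MDL segmentation model

A model consists of a lexicon of letter strings ("morphs") and the corpus is
re-expressed as pointers into that lexicon. Candidate models are scored by
their total two-part code length in bits:

* **Pointer message (corpus cost)**: with morph token counts $n(m)$ summing
  to $N$, the message costs $-\sum_m n(m)\,\log_2 \frac{n(m)}{N}$ bits —
  $N$ times the entropy of the morph token distribution.
* **Lexicon cost**: each distinct morph is spelled out character by
  character plus one end marker `#`, under a maximum-likelihood character
  model estimated over all lexicon entry characters and end markers.

Frequent shared substrings (stems, suffixes) earn their place in the lexicon
because pointers to them are cheap and they shorten many entries at once; a
rare long word stays whole. A morph's surprisal is
$-\log_2 \frac{n(m)}{N}$ and a word's surprisal is the sum over its morphs,
so the model interpolates naturally between full-form storage and full
decomposition. All code lengths are base-2 (bits).

### Count dampening

`mdl_train()` exposes a `dampening` argument controlling how word token
counts weight the pointer message: `"types"` (default; every word type
counts once), `"log"` ($1 + \log_2$ count), or `"none"` (raw token counts).
With raw counts the pointer message dominates the (count-independent)
lexicon term by orders of magnitude on realistic corpora, and the greedy
search then leaves frequent words unsegmented: splitting one word in
isolation always raises the total cost, even when a jointly segmented
configuration would be globally cheaper. We verified this numerically on a
planted 30-root × {∅, *-er*, *-s*} corpus at 10 tokens per type: no single
split is ever accepted under raw counts (the first split costs ≈ +38 bits),
while under type-based training the planted boundaries are recovered with
F1 ≥ 0.95 across seeds. Type-based training is also the convention of
baseline morph-induction tools. Raw counts remain available and are the
natural setting when the object of interest is the compression of a
specific token stream rather than morphology; the exhaustive-oracle
comparisons in the test suite use them for exactly that reason.

### Search procedure

Training is greedy:

1. **Incremental first pass.** Word types enter the model one at a time in
   a seeded shuffled order. Each entering word is segmented by recursive
   binary splitting: the word as a single morph is compared against every
   two-way split (with all counts updated), the cheapest option wins, and
   accepted parts are split recursively. Adding words incrementally matters:
   against a small partial corpus the lexicon savings of a shared substring
   outweigh the pointer-message penalty, which is how suffix morphs get
   established at all. (Initializing the full corpus unsegmented and only
   then re-segmenting — the obvious alternative — is a fixed point of the
   search on shared-suffix corpora.)
2. **Re-segmentation epochs.** Each later epoch revisits all word types in
   a fresh seeded shuffle, removes the word's current morphs, re-segments it
   from scratch, and reverts the move if the total cost rose. The cost
   trajectory after the first pass is therefore nonincreasing, and training
   stops when an epoch improves the total by less than `epsilon_bits`
   (default 0.1 bits) or after `max_epochs` (default 20) epochs. If the
   final cost somehow exceeds the unsegmented baseline (possible only on
   degenerate corpora), the baseline model is returned.

Ties prefer no split, then the earliest split point — determinism given the
seed is part of the contract. `mdl_exhaustive()` enumerates the joint
segmentation space of all words (bounded, by default, at $10^6$
combinations) and serves as the brute-force oracle in the tests; greedy
training is not guaranteed to reach the global optimum, and the test suite
asserts a ≤ 5% cost gap on enumerable corpora under raw-count training.
Under type weighting the global optimum of very small artificial corpora
tends to atomize words into single letters, a regime the greedy search
(deliberately) does not chase.

### Decoding

`mdl_segment()` performs Viterbi decoding over split points: a lexicon morph
costs its surprisal; any other substring falls back to the character model
(letter costs plus end marker). The fallback is available during decoding
only — it prices unseen material so that pseudowords receive a finite
"word-likeness" score from the same code, without letting training hide
probability mass in it. Ties break toward fewer morphs, then the
leftmost-longest morph. Exact additivity (word surprisal = sum of morph
surprisals) and per-string optimality against exhaustive enumeration are
asserted in the tests.

## The predictor set

Seven item-level predictors, in the canonical column order used throughout:

| column | definition | units |
|---|---|---|
| `image_complexity` | GIF/bitmap byte ratio of the rendered string | ratio |
| `length` | letter count (equiprobable-letter surprisal is ∝ N) | letters |
| `bigram_surprisal` | −log₂ mean per-million open-bigram frequency | bits |
| `tpl` | surface frequency ÷ lemma frequency | probability |
| `mdl_surprisal` | summed morph surprisal of the MDL decoding | bits |
| `lemma_surprisal` | −log₂ lemma (root-pooled) probability | bits |
| `surface_surprisal` | −log₂ whole-form probability | bits |

Decisions worth recording:

* **Image complexity.** Strings are rendered with a synthetic 5×7
  dot-matrix monospaced face into fixed-size cells (defaults: 6×9 px cells,
  gray background 192, ink 0) on a fixed 16-cell canvas, and encoded with a
  built-in GIF89a writer (variable-width LZW, 12-bit dictionary). The index
  is the encoded byte length divided by the raw 8-bit pixel-buffer size
  (width × height bytes, headers excluded). A synthetic face keeps the
  measure bit-identical across platforms, where a named system font would
  not be. The fixed canvas mirrors presentation on a fixed screen and makes
  the index increase with the amount of rendered material; on a tight
  per-word canvas the constant file overhead dominates and the direction
  reverses. Only ordinal behavior of the index is asserted anywhere.
* **Open bigrams** are unrestricted in distance (a 4-letter word yields all
  6 ordered pairs). Bigram tables are token-weighted by default
  (type-weighting is an option); unseen bigrams in the mean are floored at
  ε = 0.01 per million so pseudoword values stay finite. Real-word surface
  and lemma lookups are never smoothed — a missing stimulus word is an
  error, not a guess.
* **TPL** enters analyses on the probability scale (a `log = TRUE` variant
  exists but is off by default), and the three frequency-based columns
  (`tpl`, `lemma_surprisal`, `surface_surprisal`) are undefined — masked as
  `NA` — for pseudoword items.

## The synthetic experiment

`generate_corpus()` samples word tokens from a concatenative grammar: a
Zipf law (default exponent 1) over root ranks, then independent categorical
draws per suffix slot. Every type carries its gold segmentation and lemma,
which is what makes boundary-recovery scoring possible. `demo_grammar()`
ships a 150-root, two-slot configuration whose word lengths span 3–16
letters, so that a 360-item stimulus set with mean length 10.3 (SD 2.8) —
the design statistics the stimulus sampler targets by default — is
comfortably feasible. Pseudowords come from a letter n-gram model (default
order 3, additive smoothing 0.1 — configuration, not a claim) trained on
the same corpus, constrained to match the word set's length multiset and to
avoid all real words.

`simulate_amplitudes()` plants linear predictor effects into four evoked
components with conventional analysis windows: occipital (80–120 ms),
occipito-temporal (140–200 ms), and left/right temporal (300–700 ms), in a
−200..800 ms epoch at 1 kHz. Per participant, amplitudes are scaled by a
lognormal gain (sdlog 0.2) and shifted by a normal offset — the
inter-individual variation that within-participant z-scoring is designed to
remove; per-trial noise is Gaussian. The reference effect sizes and
explained-variance totals shipped in `default_effects()` mirror a published
item-level MEG lexical-decision study of morphologically rich word reading;
they are the package's fixed reference conditions, not tuning knobs.
Reaction times follow the same linear scheme (baseline 852 ms, 95 ms per
standardized response unit) with per-participant accuracy drawn around 92%
(SD 4%); accuracy is predictor-independent by default.

**Noise calibration.** Given standardized coefficients β, predictor
correlations Σ and a target item-level R², `calibrate_noise_sd()` solves
σ² = βᵀΣβ·(1−R²)/R². When the analysis averages over P participants before
regressing, independent trial noise shrinks by 1/P in variance, so the
per-trial SD achieving the same item-level target is √P larger — this is
why `default_components()` takes the cohort size as an argument.

**Time courses** are Gaussian bumps at the component's peak latency, scaled
so the analysis-window mean reproduces the window amplitude exactly. Bump
SDs default to 15/20/100/100 ms for the four components. Note that a bump
at 400 ms only stays essentially inside a 300–700 ms window for SDs up to
about 30 ms (at SD 60 the window edges still see ~25% of the peak); the
wide temporal bumps are a visual convention for sustained activity, and no
quantitative claim rests on their tails.

The generator deliberately does **not** emulate: sensor-level physics or
artifacts, oscillatory (non-phase-locked) activity, noise-masked or
symbol-string stimulus rendering (those exist only as category labels),
real morphophonology (vowel harmony, stem alternation), or any dependence
of accuracy on the predictors. Passing tests therefore demonstrate that the
analysis stage recovers what the generative model plants — internal
consistency — not that real MEG data would behave this way.

## The analysis stage

The pipeline mirrors standard item-level practice: trials are kept iff the
response was correct and the RT lies in [350, 1500] ms; participants with
fewer than 290/360 valid word trials are excluded; window amplitudes are
z-scored within participant × component (n−1 SD; exact invariance to
per-participant affine transforms is tested), then averaged across
participants per item, with missing trials excluded rather than
zero-filled.

* **Simple correlations** report Pearson r with the equivalent
  simple-regression F on (1, n−2) df; at the design size n = 360 that is
  F(1, 358). Significance stars follow the two conventional raw thresholds
  (p < .05, p < .001); no multiple-testing correction is applied, matching
  the reporting convention the package emulates.
* **Stepwise regression** is forward-only with a partial-F entry test at
  α = 0.05: at each step the candidate with the largest R² increase enters
  if its entry p-value clears α. Predictors and response are z-scored
  internally, so coefficients are standardized β. Entry ties and the
  median-bin construction resolve by fixed column/item order; a condition
  number above 10⁸ among selected predictors is an error rather than a
  silent pseudo-inverse. Standardization happens after cross-participant
  averaging (the default reading of the emulated workflow). Forward-only
  selection was chosen over bidirectional elimination because the emulated
  procedure is described as adding predictors one by one.
* **Tertile bins** for visualization take the lowest 60, highest 60, and 60
  items centered on the median of the chosen predictor — three disjoint
  bins at the 360-item design size.

## Problem sizes and numerical conventions

Simulation-based tests run at the design size of the emulated study — 360
items × 20 participants — with 100 replicates for effect-recovery and
internal-consistency checks and 200 replicates for the stepwise
false-entry calibration; synthetic corpora of 2×10⁵ tokens (~3,000 types)
back the predictor and stimulus tests. Cost comparisons use a 10⁻⁹-bit
tolerance; stored model costs must agree with from-scratch recomputation to
10⁻⁶; the exhaustive oracle is capped at 10⁶ joint combinations. Planted
effects are judged recovered when the mean standardized coefficient over
replicates deviates from the planted value by less than three times the
mean per-fit standard error (recovery is assessed on the full linear model
over the planted predictor set; stepwise selection is assessed separately,
because conditioning estimates on selection would mix recovery with
selection bias).

## Known limitations

* The greedy MDL search carries no global-optimality guarantee; the oracle
  gap is certified only on enumerable corpora.
* Morph surprisals under type-based training reflect type (productivity)
  statistics, not token frequencies; raw-count training is available where
  token-level compression is the quantity of interest.
* The response simulator is linear-Gaussian by construction; it cannot
  falsify the linear analysis stage, only calibrate it.
* Printed reference effect tables are internally inconsistent at the third
  decimal (coefficients, correlations and R² were each rounded
  independently), so reconstructed summary statistics carry a systematic
  deviation of up to ~0.02 beyond Monte-Carlo error.
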