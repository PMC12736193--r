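---
title: "Methods: protein-conditioned molecule generation and affinity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein-conditioned molecule generation and affinity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

seq2mol implements a three-model drug-discovery pipeline operating purely in
1D sequence space:

1. a **target-identification layer** that turns a free-text disease query
   into a protein sequence (literature retrieval, LLM-based name extraction,
   sequence lookup — all behind pluggable providers so the graph runs
   offline under mocks);
2. a **chemical language model (CLM)**: a decoder-only transformer trained
   on paired protein + SMILES sequences, prompted with a protein and sampled
   autoregressively to propose a ligand;
3. a **regression convolutional network (RCNN)** that predicts the binding
   affinity pKi of the (protein, ligand) pair from its character encoding.

Raw CLM output is frequently not a parseable molecule; a deterministic
**trimming repair** shortens each raw string from the end, one character at
a time, until a sanitizing SMILES parser accepts it or nothing remains.
Every non-empty repaired string is therefore valid by construction — the
pipeline's one exact guarantee, and the property the acceptance script
re-derives.

# Data model and preprocessing

A dataset is a tibble of ligand–protein records: `smiles`, `protein_seq`,
`ki_nM`, `pki`, `pair_length`. The affinity transform is the standard pKi
convention,

$$\mathrm{pKi} = -\log_{10} K_i[\mathrm{M}] = 9 - \log_{10} K_i[\mathrm{nM}],$$

so 1 nM maps to 9 and 0.1 nM to 10. Preprocessing retains pairs with
combined SMILES + protein length at most 800 characters and pKi at most 10;
both bounds are inclusive (pairs *longer than* 800 or *stronger than* pKi
10 are excluded). The length bound is interpreted on the combined pair
because the models consume the pair as one sequence and the 800-position
encoder input matches it. Filtering preserves row order, logs per-reason
exclusion counts, and is idempotent. Duplicate pairs are retained — the
upstream export is taken as-is.

Splitting is a uniform random partition at the pair level
(`floor(n * fraction)` training rows), driven by a caller-supplied seed and
restoring the caller's RNG state afterwards. Whether identical pairs should
be deduplicated before splitting is an open question for real exports; the
package deliberately does not deduplicate, so leakage checks on real data
are the user's responsibility.

# Tokenization

Two encoders serve the two models.

**BPE for the CLM.** A byte-pair-encoding tokenizer is trained from scratch
on corpus lines `"<protein> <smiles>"`: whitespace pre-tokenization, an
end-of-word marker on each word's final symbol, iterative merging of the
most frequent adjacent symbol pair until the vocabulary budget (default
30,000 types) is reached or no pair attains the minimum frequency (default
2). Ties between equally frequent pairs break lexicographically, making
training deterministic. Out-of-vocabulary symbols encode to `<unk>`; there
is no byte-level fallback. The training layout is
`<bos> protein-tokens smiles-tokens <eos>`, truncated or padded with
`<pad>` to 128 tokens. Protein first: an autoregressive model prompted with
the conditioning sequence must see it before the continuation it is asked
to produce. The whitespace separator is carried by the protein's
end-of-word token, so a generation prompt (`<bos> protein-tokens`) leads
the model into a fresh word — the SMILES. Pairs whose token count exceeds
128 are truncated silently with a flag recorded for corpus diagnostics.

**Character codes for the RCNN.** The distinct characters of the corpus
(protein + SMILES concatenated, scanned in row order) receive contiguous
codes 1..K in first-seen order, capped at 70; code 0 is reserved for
padding and for unknown characters at inference. The pair is concatenated
without a separator symbol — none is needed within the ≤ 71-symbol budget,
since amino-acid and SMILES alphabets already occupy distinct ranges in
practice — and padded or truncated to a fixed width (800 by default).

# The chemical language model

A GPT-style decoder-only transformer: token + learned positional
embeddings, pre-norm blocks of causal multi-head self-attention and a
4×-wide GELU MLP, a final layer norm, and a weight-tied output projection.
The full-scale recipe is 10 epochs, batch 64 with gradient accumulation 8,
learning rate 5e-4 under a cosine schedule with 1000 linear warmup steps,
decoupled weight decay 0.1, evaluation every 5000 steps, and a 1024-token
context window. The transformer's depth and width at full scale are not
fixed by the recipe; the `"paper"` preset uses the small-GPT-2-like
12 × 12 × 768, while tests and the acceptance run use the `"tiny"` preset
(2 layers, 4 heads, width 64) — the training dynamics, not the capacity,
are what the desk-scale checks exercise. The implementation is base R
matrix algebra with hand-derived backpropagation; gradients are verified
against central finite differences in the test suite. Loss is next-token
cross-entropy with shifted labels; positions whose target is `<pad>` are
masked out.

Sampling encodes the protein prompt, draws tokens at the configured
temperature (temperatures below 1e-3 switch to greedy argmax to avoid
degenerate exponentials), stops at `<eos>` when early stopping is on —
"early stopping" here is a sampling-termination rule, not a training
criterion — and decodes only the newly generated tokens. Because the
training layout contains a whitespace separator, a raw generation may
contain word boundaries; everything from the first whitespace onward is
dropped before repair, since SMILES cannot contain spaces.

**Trimming.** The repair removes raw *characters* (not tokens) from the
end until the validity oracle accepts the string or it is empty; an
already-valid input is returned unchanged. The result equals the longest
valid prefix, so the implementation checks all prefixes of a batch in one
oracle call rather than looping. The oracle is a sanitizing SMILES parser
(rdkit's `MolFromSmiles`, reached through a batched subprocess bridge):
"valid" means parse **and** sanitize succeed, so valence errors fail, not
just syntax errors. The empty string is counted as invalid. An
OpenBabel-based oracle was rejected because it silently repairs syntax
errors (`"CCO("` parses as `CCO`), which would make the trimming loop a
no-op on exactly the inputs it exists to fix.

# The affinity regressor

The RCNN maps the character-encoded pair to a scalar pKi: an 8-dimensional
embedding; six blocks of 1D convolution (kernel 8) → batch normalization →
leaky-ReLU (slope 0.01) → max-pool (2); flatten; dense 512 → dense 10 (both
leaky-ReLU) → linear output. Filter counts rise from 32 to 64 as
`[32, 32, 32, 64, 64, 64]` — the simplest monotone progression honoring
both endpoints. With 800 input positions the six floor-division pools leave
800 → 400 → 200 → 100 → 50 → 25 → 12 positions before the flatten.
Convolutions use "same" padding (left `floor((k-1)/2)`, remainder right) so
six kernel-8 layers fit any input length cleanly; batch normalization
precedes the activation (the conventional order where the recipe does not
pin one down). Optimization is RMSprop (ρ = 0.9, ε = 1e-7) at learning
rate 0.001 with MSE or MAE loss; the full-scale recipe runs 200 epochs.

Two numerical choices matter at desk scale:

* **Output-bias centering.** The linear output's bias is initialized to
  the training-target mean before the first step. RMSprop's
  magnitude-normalized updates move any single scalar by roughly the
  learning rate per step, so pushing the output from 0 to the target mean
  (~4–7 pKi units) would otherwise consume thousands of steps — a
  negligible cost at hundreds of thousands of steps per run, but most of
  the budget of a few-hundred-step test run. Centering removes that drift
  without changing what is learned.
* **Batch-norm running statistics** use momentum 0.9. Evaluation-mode
  predictions rely on running means/variances; at momentum 0.99 they lag
  the batch statistics by far more steps than a short run contains,
  which shows up as spurious evaluation noise rather than any property of
  the model.

`evaluate_regression` reports Pearson's R, R² = 1 − SS_res/SS_tot, and
RMSE; the test suite checks all three against an independent brute-force
recomputation at 1e-9. The repeat protocol re-splits 70/30 with a fresh
seed per repeat (five by default), trains from scratch, and reports each
metric's mean and SD after the first and the final epoch, mirroring the
usual stability table.

# Generation metrics

* **Validity** — fraction of strings the sanitizing parser accepts
  (empty strings invalid). Reported both over all outputs and over
  non-empty outputs; the latter is the natural reading when empty
  repairs are discarded before scoring.
* **Uniqueness** — distinct canonical SMILES over valid entries, so
  `"CCO"` and `"OCC"` count once. Invalid strings have no canonical form
  and are excluded from both numerator and denominator.
* **Internal diversity** — 1 − mean pairwise Tanimoto similarity of
  radius-2, 2048-bit Morgan fingerprints over all unordered pairs of valid
  molecules. The upstream description does not fix the fingerprint or the
  similarity; this is the field-standard choice, and the test suite
  cross-checks it against an independent toolkit computation.
* **QED** — the standard quantitative estimate of drug-likeness, averaged
  over valid molecules.

# The synthetic fixture generator

Every stage must be testable offline, so the package ships a generator for
paired corpora with a *known, learnable* affinity law:

$$\mathrm{pKi} = \mathrm{clip}\big(2 + 1.5\,\#\{\texttt{N} \in \mathrm{SMILES}\}
  + 6\,\mathrm{frac}(\texttt{K} \in \mathrm{protein}) + \varepsilon,\; 0, 10\big),
  \quad \varepsilon \sim \mathcal N(0, \sigma^2).$$

Molecules are built compositionally from a closed set of valence-safe
fragments (chain extensions, one aromatic and one aliphatic ring template,
halogen/amine substitutions), so every generated SMILES is valid by
construction — verified against the parser for whole batches in the tests.
Proteins are uniform random strings over the 20-letter alphabet with
lengths 20–40 by default: long enough that the K-fraction varies smoothly,
short enough that desk-scale models see the whole signal. The affinity law
uses only character counts so that both the token-level CLM and the
character-level RCNN can in principle capture it, and the clip range
mirrors the preprocessing pKi bound. Ki values are back-computed from pKi,
so the transform round-trips exactly and every fixture pair passes the
default filters.

What the fixtures do **not** emulate: real chemistry (no property matching
to empirical affinity distributions beyond the pKi range), protein domain
structure, assay noise heterogeneity, or the heavy class imbalance of real
binding databases. A passing parameter-recovery test therefore shows the
optimization and architecture can extract a recoverable character-level
signal at small scale — not that the models reach any particular accuracy
on real binding data.

# Problem sizes and study conditions

The checks run at sizes chosen to exercise every code path in minutes on a
single CPU: the generation study trains the tiny CLM on a 200-pair corpus
(BPE vocabulary 512, 10 epochs) and samples one continuation for each of
100 fixture prompts at temperature 1; the recovery study trains the
six-block RCNN on a 500-pair noise-free corpus (70/30 split, 30 epochs,
batch 8, MAE loss) with the encoder width set to 256 positions — fixture
pairs are at most ~80 characters, so 256 covers them with ample margin
while keeping the padding fraction, and with it the compute, proportionate
to the corpus; the four post-pool positions it leaves also give the head
enough spatial resolution to separate nitrogen counted in the ligand from
asparagine in the protein. MAE is used for the recovery run because the
clipped synthetic law produces a short heavy tail that the absolute-error
loss handles more gracefully in few-step regimes. Memorization checks use
a single repeated pair (CLM) and five pairs (RCNN), the smallest corpora
where recovery is meaningful.

Desk-scale training runs are deterministic given their seeds, but their
endpoint quality is run-to-run variable across seeds (a few hundredths of
a correlation unit) because a few hundred optimizer steps resolve the
counting circuitry only approximately; the recovery check pins one seeded
configuration rather than claiming uniformity over seeds.

# Known limitations

* The CLM and RCNN are base-R implementations; they are exact (gradients
  are finite-difference-verified) but not fast, and full-scale corpora are
  supported by configuration, not by desk-scale compute.
* The validity oracle requires a `python` interpreter with rdkit on the
  PATH; without it the chemistry-dependent functions error with a clear
  message (everything else works).
* Generation quality metrics at tiny scale describe the toy grammar, not
  drug-like chemical space; only the post-trim validity guarantee
  transfers to any scale.
* Live literature retrieval and sequence lookup are provider contracts;
  the shipped implementations are offline mocks, and network adapters are
  intentionally out of scope.
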