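---
title: "Conditional Transformer generation of target-specific molecules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional Transformer generation of target-specific molecules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

De novo molecular design asks for novel, synthesizable, drug-like
compounds, and — in lead finding — for compounds likely to be active
against a chosen protein target. `condsmiles` treats this as conditional
language modelling over SMILES strings: a decoder-only Transformer is
pre-trained to predict the next SMILES token given the previous ones, so
that sampling from the model produces syntactically valid, drug-like
strings; a per-target *condition embedding* then steers generation toward
the chemical space of a target's known actives.

## The model

A SMILES string is tokenized (bracket atoms, `Cl`/`Br`, and `%NN` ring
closures are single tokens; everything else is one character — the split
is exactly reversible) and framed as `BOS t_1 ... t_N EOS`. Token
embeddings are scaled by `sqrt(d_model)` and summed with sinusoidal
positional encodings. Each of the `n_layers` identical decoder layers
applies three sublayers, each wrapped in a residual connection followed by
layer normalization (post-LN, exactly in this order):

1. **masked multi-head self-attention** over the token positions, with a
   causal mask (position *i* attends only to positions `j <= i`; masked
   scores are set to `-Inf` before the softmax, so excluded positions get
   *exactly* zero weight and causality holds bitwise);
2. **condition attention**, a multi-head attention whose keys and values
   are the condition memory `e_c` — a learned per-target embedding taking
   the place of the encoder "memories" of a sequence-to-sequence
   Transformer;
3. a position-wise **feed-forward network** (ReLU).

Next-token logits come from a separate (untied) output projection. The
training objective is the conditional negative log-likelihood

    NLL(S | c) = - sum_{i=1..N} ln P(t_i | t_{1:i-1}, c),

in nats, averaged over non-padding token positions per batch so the
reported loss is batch-size invariant.

**Base mode.** With no condition (`condition_id = NULL`) the condition
memory is the zero matrix. Attention projections deliberately carry no
bias terms, so the zero memory yields zero values and the entire
condition-attention sublayer contributes exactly zero before its
residual: base mode is *exactly* the reduced stack in which that sublayer
is the identity inside `LN(z + 0)`. This equivalence is tested bitwise.

**Condition memory length.** `e_c` is presented as a single embedding
vector, so the default memory length is `m = 1`; the softmax over a
single key is then constant (weight 1) and the sublayer reduces to a
query-independent, LN-gated additive injection of a per-target vector.
Because a longer memory is conceivable, the length is exposed as
`cond_memory_len`; nothing in the implementation assumes `m = 1`.

## Training workflow

1. **Pre-training** (`pretrain()`): next-token training on an unlabeled
   corpus, base mode throughout. The model learns SMILES grammar and the
   corpus's structure distribution.
2. **Fine-tuning** (`finetune()`): training continues on
   `<compound, target>` pairs with each sequence's target embedding fed to
   the condition-attention sublayers. By default all weights plus the
   condition embeddings are updated — the most direct reading of
   "fine-tuning" — and `scope = "embeddings"` freezes the shared weights
   instead. A condition's embedding receives gradient only from sequences
   carrying that condition.
3. **Sampling** (`generate()`): autoregressive, starting from `BOS`,
   drawing each token from the temperature-scaled softmax (multinomial at
   `T = 1` by default; optional top-k truncation, disabled by default —
   the stochasticity is what makes the generator produce variations rather
   than reciting its training set). `PAD`/`BOS` can never be emitted;
   a sequence ends at `EOS` or at `max_len` tokens, and truncated strings
   are kept and validity-checked rather than discarded. Each sequence runs
   on its own seeded RNG stream (`seed + i`), so batches are reproducible
   and prefixes are invariant to the `max_len` budget.

The optimizer is Adam (default peak learning rate 3e-4, 500-step linear
warmup, global gradient-norm clip 1.0, mini-batches of 32 sequences) — a
standard small-GPT recipe. One deliberate sign decision: the NLL is the
negative sum of *all* per-step log-probabilities; a formulation that adds
(rather than subtracts) the terms beyond the first would not be a loss.

### Desk-scale ("tiny") preset

Since no hyperparameters are prescribed for the full-size model, the
default configuration is a standard small-GPT scale (8 layers, 8 heads,
`d_model = 256`, `d_k = d_v = 32`, `d_ff = 1024`, dropout 0.1). The test
suite and examples use `tiny_config()`: 2 layers, 4 heads,
`d_model = 64`, `d_ff = 256`, no dropout. At this width the 3e-4 learning
rate is needlessly conservative: the desk recipes (test fixtures, the
acceptance pipeline, the CLI examples) pass `learning_rate = 1e-3`, which
converges on the toy grammar within ~10 epochs while 3e-4 would need
several times more steps for the same held-out NLL. This is a width-scaled
choice, not tuning against any acceptance threshold: larger learning
rates for smaller models are the usual Transformer practice, and 3e-4
remains the package default for full-size configurations.

## The synthetic world

Real corpora (the ~1.8M-molecule drug-like pre-training sets and
per-target active collections of a production run) cannot ship with the
package, so the `toy_grammar_spec()` generator states a small world with
the properties the pipeline needs:

- **valid by construction**: scaffold templates (benzene, cyclohexane,
  pyridine-like rings, amides, short chains) composed with substituent
  pools; every composition is canonicalized at construction time and the
  grammar is rejected if any fails;
- **condition-dependent motifs**: condition 0 draws fluorinated
  substituents, condition 1 chlorinated ones — mutually exclusive,
  tokenizer-visible motifs (`F` vs `Cl` tokens) that a 2-layer model can
  learn in minutes on one CPU, the desk analogue of target-biased
  fine-tuning;
- **known activity ground truth**: `synth_activity()` sets pXC50 =
  6.5 + (linear function of 20 seeded fingerprint bits) + N(0, 0.3²),
  drawn from the same 2048-bit FCFP6 block the QSAR featurizer uses, with
  weights of magnitude 0.3-0.8 and random sign. The mapping is stored so
  recovery tests can verify the noiseless limit exactly. The 0.3 noise SD
  against a signal SD near 1 makes a Pearson of ~0.95 the ceiling for a
  perfect model — comfortably above the 0.9 recovery bar without being
  trivial.

Defaults (5,000 molecules, ≤ 25 tokens, two conditions) are the stated
desk scale. What the toy world does *not* emulate: the property
distributions, fragment diversity, and long-range ring/branch structure of
real drug-like corpora. A green conditional-recovery test therefore
establishes that the architecture, objective, conditioning mechanism, and
sampler work end-to-end — not that paper-scale validity/novelty numbers
are reproduced, which would require the full corpora and days of
compute.

## Metrics

Implemented to the MOSES reference definitions, since those are the field
standard the evaluation adopts: **Valid** (fraction of parseable
strings), **Unique@k** (distinct canonical SMILES among the first k valid
molecules), **Novelty** (distinct generated canonical forms absent from
the canonicalized training set — comparisons are always on canonical
SMILES, never raw strings, so trivially rewritten molecules do not count
as novel), **Frag** (cosine similarity between BRICS fragment-frequency
vectors), **SNN** (mean nearest-neighbour Tanimoto over Morgan
fingerprints, radius 2, 1024 bits; parameters config-exposed), the
empirical **Wasserstein-1** distance between property distributions (MW,
LogP, QED, SA), and the drug-likeness profile (MW 200-500, TPSA 20-130,
LogP -1-6, HBD ≤ 5, HBA ≤ 10, QED ≥ 0.4, SA ≤ 5). All metrics except
validity are computed over valid molecules only. Degenerate inputs are
data, not crashes: an unparseable SMILES canonicalizes to `NA`, an
all-invalid batch yields a report with explanatory flags, and a set with
no BRICS-fragmentable molecule has Frag defined as 0 with a warning.

## QSAR activity model

Each molecule is represented by 2533 features: 2048 hashed circular
fingerprint bits of radius 3 with feature-based atom invariants (the
standard reading of "FCFP6"), 166 MACCS key bits, and a physico-chemical
descriptor block. The original descriptor list of that width is not
recoverable — the available toolkit exposes 210 descriptors — so the
block is pinned to the alphabetized toolkit list zero-padded to 319
slots: the 2533-feature contract holds exactly and the realized
descriptor names are recorded in the fitted bundle. Non-finite descriptor
values are imputed to 0 with a warning. Input SMILES are canonicalized
before featurization, so spelling variants map to identical vectors.

The regressor is a histogram gradient-boosted tree ensemble (the
LightGBM family) with library-default hyperparameters and early stopping
on an internal validation fold, fitted on a seeded 80/20 random
train/test split (the split ratio is a package choice; only the existence
of a test set is given). The bundle records held-out Pearson and RMSE; a
degenerate (constant) held-out activity vector flags Pearson as undefined
rather than reporting a spurious number. Ranking generated libraries uses
descending predicted pXC50 with ties broken by canonical-SMILES
lexicographic order, so top-k selections are deterministic.

## Numerical choices and edge cases

- Layer-norm epsilon 1e-5; initialization N(0, 0.02²) for weights and
  embeddings, zeros for biases/LN offsets, ones for LN scales,
  deterministic given a seed.
- Softmax rows with all positions masked are an error (undefined), not a
  silent NaN.
- Temperatures below 1e-6 are treated as the argmax limit.
- Gradients are computed by a hand-derived backward pass (verified
  against central finite differences to ~1e-5 relative error during
  development, and against per-head brute-force attention oracles in the
  test suite).
- Training, sampling, the toy generator, and the QSAR split are all
  seed-deterministic; two runs with the same seeds produce identical NLL
  trajectories and identical batches.

## Build-vs-buy boundary

The model, its gradients, the training loop, and the sampler are native R
— they are the package's contribution. Chemistry (parsing,
canonicalization, fingerprints, MACCS keys, descriptors, QED/SA, BRICS,
substructure search) and the boosted-tree fit are delegated to the
canonical toolchain (RDKit, scikit-learn) through a batched subprocess
bridge, because no equivalent R-native implementations exist in the
supported environment and hand-rolling them would be both wasteful and
less trustworthy. The bridge is one process per batched request with JSON
(and CSV for matrices) interchange; canonicalization results are memoized
per session.

## Known limitations

- A freshly fitted QSAR bundle references a model file under `tempdir()`;
  use `save_qsar_bundle()` / `load_qsar_bundle()` (which copy the model
  side file next to the RDS) to persist one across sessions.
- Generation recomputes the full prefix forward pass per token (no KV
  cache); correct but quadratic in sequence length.
- The condition-attention design with `m = 1` cannot express
  query-dependent conditioning; it is an additive steering signal.
- Paper-scale corpora are supported (nothing assumes the toy world) but
  full-scale training on CPU R is slow; the package is tuned for
  correctness and desk-scale experiments.
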