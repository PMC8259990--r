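---
title: "Conditional language modeling of biomedical abstracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional language modeling of biomedical abstracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(condlm)
```

This vignette is the package's own account of the model it implements,
the assumptions behind it, the parameters that matter, what the
synthetic corpus generator does and does not emulate, and the design
choices made where the design was genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

A conditional language model assigns

$$\Pr(s \mid c) = \prod_{i=1}^{n} \Pr(s_i \mid s_1, \dots, s_{i-1}, c),$$

where $s$ is a subword-token sequence and $c$ an *unordered set* of
condition embeddings — one per indexed metadata keyword plus one for the
publication year. Training minimizes the dataset negative log-likelihood
plus three auxiliary sequence-labeling terms:

$$L = L_{\text{token}} + L_{\text{POS}} + L_{\text{dep}} + L_{\text{entity}},$$

each a cross-entropy between a linear head over the decoder state at
position $i$ and the label of the *following* token (shift-by-one
teacher forcing; the same decoder state predicts the next token and that
token's part of speech, dependency tag, and entity class). The auxiliary
tracks inject grammatical and biomedical-entity structure into the
representation without extra annotated corpora: the labels come from a
pluggable annotation provider, and the package treats them as input.

The architecture is an encoder–decoder transformer:

* **Encoder** (shallow, default 2 blocks): self-attention over the $m$
  condition embeddings. No positional encoding is added, so the encoder
  output — and hence every model output — is invariant to permutation of
  the condition set. This is a modeling *assumption*: metadata keywords
  carry no order.
* **Decoder** (deep, default 16 blocks): causal self-attention over
  token embeddings plus sinusoidal positional encoding,
  $\mathrm{PE}_{pos,2i} = \sin(pos/10000^{2i/d})$,
  $\mathrm{PE}_{pos,2i+1} = \cos(\cdot)$; then unmasked encoder–decoder
  attention (queries from the decoder stream, keys/values from the
  encoder output); then a position-wise feed-forward layer
  $\max(0, XW_1)W_2$.
* Every sublayer uses the **post-norm** residual layout
  $\mathrm{LayerNorm}(f(x) + x)$. GPT-2 itself uses pre-norm; the
  post-norm layout is kept because it is the layout this model family
  printed, and at desk scale the difference is immaterial. Dropout, when
  enabled, is applied to each sublayer output before its residual add —
  the conventional site; only the *presence* of dropout, not its
  placement, is fixed by the model family.
* Four separate head matrices map the final decoder state to logits.
  The token head is *untied* from the input embedding table, and
  condition embeddings live in their own table (years and keywords share
  it, with disjoint contiguous index ranges).

### The per-task loss, read literally

The printed form of the per-task loss in this model family applies a
softmax and then re-exponentiates inside a log-sum over an index set
"$j \neq i$", which is ill-typed if taken literally (softmax outputs are
already normalized; the index set mixes positions and classes). The
package implements what the surrounding text states — minimize the sum
of negative log-likelihoods — i.e. standard cross-entropy
$-\log \mathrm{softmax}(\text{logits})_{\ell_i}$, averaged over
positions. Averaging (rather than summing) over positions and over the
windows of a batch keeps the loss scale independent of window length and
batch size, which makes learning rates transferable across
configurations; the choice is otherwise inconsequential.

### Why the gradients are hand-written

No automatic-differentiation framework is part of this package's
dependency footprint; the backward pass of every block (attention,
feed-forward, layer norm, embeddings, heads) is derived by hand and
implemented in base R matrix code. Correctness rests on two pillars in
the test suite: finite-difference agreement of the analytic gradient at
relative error $\le 10^{-3}$ on sampled coordinates of every parameter
group, and the optimization sanity checks (a small step along the
negative gradient decreases the loss; small models memorize a fixed
batch).

## Tokenization

The unigram subword tokenizer is self-contained:

1. the training sample is lowercased (inside the tokenizer — callers
   never pre-normalize), and every observed character receives a piece,
   so segmentation never fails on covered text; unknown characters map
   to the unknown id rather than erroring, because real MEDLINE text
   contains rare glyphs;
2. frequent within-word substrings (up to 8 characters) are proposed as
   candidates, scored initially by frequency × (length − 1);
3. piece log-probabilities are refined by hard-EM sweeps (Viterbi
   segmentations of a sentence subsample provide usage counts; the
   M-step renormalizes with additive smoothing), and the inventory is
   pruned by usage to exactly the requested size — usage-based pruning,
   not raw frequency, is what lets whole words displace their own
   fragments;
4. segmentation is Viterbi by default; sampling mode draws a path with
   probability proportional to $\exp(\text{score}/\alpha)$, so
   $\alpha \to 0$ recovers Viterbi (verified by test at
   $\alpha = 0.05$). Training uses Viterbi segmentation; sampled
   segmentation is available but off by default, since the sampling
   hyperparameters of the original subword-regularization recipe are
   not part of this package's contract.

The vocabulary serializes as a two-column TSV (piece, log-probability;
specials `<s> </s> <unk> <pad>` first) and round-trips bit-exactly.

## Corpus pipeline

* **Filtering** keeps records that are in English and have at least one
  non-title sentence; records without keywords are kept. Records
  without a parseable year are dropped — the year is the one condition
  every record must carry.
* **Document layout**: the document text is the title followed by the
  abstract, wrapped as `<s> title abstract </s>`, with the title counted
  as the first sentence. The title must sit at the sequence head because
  generation prompts with it; whether title tokens also serve as
  training context was an open choice, resolved here in favour of
  including them, which keeps training and prompting consistent.
* **Year indexing** is half-open $[\text{min\_year}, \text{cutoff})$:
  with the earliest training year 1790 and cutoff 2020 this yields
  exactly 230 year indices (the printed embedding count of the
  full-scale reference configuration); an inclusive reading would give
  231. Years outside the range clamp to the nearest end.
* **Keyword indexing** prunes keywords occurring fewer than 10 times in
  the training partition (case-insensitive after trimming); keywords are
  opaque strings, with no resolution of free text to MeSH descriptor
  ids.
* **Splitting** ranks record ids by a seeded 32-bit FNV-1a hash and
  assigns the top fraction to the training partition: deterministic for
  a given id set and seed, exhaustive, disjoint, and on-ratio to within
  one record. An independent per-record Bernoulli draw would satisfy
  determinism but not a 1% ratio guarantee at a thousand records.
* **Annotation alignment**: each subword inherits the POS/dependency/
  entity labels of the word span covering its first character; subwords
  outside any span (spaces, specials, stray punctuation) take null
  labels (`SPACE`, `dep`, `not_an_entity`). Overlapping entity spans are
  a contract violation of the annotation provider and raise an error.
* **Window sampling**: each document view draws a fresh window of at
  most 128 tokens whose first token is a sentence start (uniformly over
  eligible starts — verified against a $3\sigma$ band over $10^4$
  draws); all four target tracks are the source tracks shifted left by
  one. Sentence boundaries come from a deterministic rule-based splitter
  (terminal punctuation + whitespace + uppercase-or-digit lookahead);
  the splitter is pluggable in spirit — it lives behind
  `split_sentences()` — because sentence logic is not this package's
  contribution.

## Optimization

`train_config()` defaults: batch size 16 at desk scale (the full-scale
reference setting is an effective 480, reachable via
`grad_accum`), base learning rate $10^{-3}$, 500-step linear warmup,
flat thereafter (no decay is applied because none is part of the
reference recipe), checkpoint every 5% of the corpus viewed. Both LAMB
(the large-batch optimizer of the reference configuration) and Adam are
implemented; Adam is the desk-scale default since LAMB's trust-ratio
scaling matters at batch sizes far beyond what a single CPU sees.
Training is deterministic given the config seed; checkpoints carry
parameters, optimizer state, step counter and RNG state, so a resumed
run replays the exact loss trajectory (verified by test).

## Generation

Ancestral sampling with temperature, top-k and nucleus truncation;
temperature 0 is the greedy argmax. The prompt is `<s>` plus the Viterbi
segmentation of the title; generation stops at `</s>` or a length cap.
When the context outgrows `max_seq`, the most recent `max_seq − 1`
tokens are kept (a sliding window — some such policy is required for
abstract-length outputs, and recency is the natural choice for a causal
model). Unknown keywords are dropped with a warning rather than
erroring, mirroring the pruned-index reality. The padding id and the
start id are masked out of the sampling distribution.

## Evaluation metrics

The sentence-wise protocol splits a generated abstract into sentences
and scores each against the full set of reference-abstract sentences:

* **BLEU$_k$** is implemented exactly as the model family prints it:
  clipped $k$-gram matches divided by the number of $k$-gram *positions*
  in the hypothesis, no brevity penalty, no geometric mean across
  orders; `bleu_sum()` adds orders 1–4. The printed denominator
  "$|G_k|$, the set of all $k$-grams" is ambiguous between positions and
  distinct grams; the position count makes identical texts score exactly
  1 even with repeated grams and coincides with standard modified
  precision, so it is the default, with the distinct-gram reading
  available behind `distinct_denominator = TRUE`. Multi-reference
  clipping takes the maximum reference count per gram (whether the
  original protocol clipped per-reference or concatenated is unstated;
  max-clip is the standard choice).
* **ROUGE-L** uses the longest common subsequence with
  $F_\beta$, $\beta = 1.2$; multi-reference takes the maximum.
* **CIDEr** uses TF-IDF $n$-gram vectors (raw counts × $\log(N/df)$
  document-frequency weights over the reference corpus), cosine
  similarity per order averaged over references, mean over orders 1–4,
  scaled by 10 — order range, uniform order weights and scale follow
  the original reference convention since none is specified otherwise.
  IDF statistics default to the evaluation set's own reference
  sentences. **CIDEr-Title** zeroes the weight of every $n$-gram that
  occurs in the prompt title, in hypothesis and reference vectors alike,
  so a sentence composed entirely of title material scores 0.
* **meteor_lite** implements the classic METEOR alignment with exact
  and Porter-stem matching stages, $F = 10PR/(R + 9P)$ and the
  fragmentation penalty $0.5(\text{chunks}/\text{matches})^3$. The
  synonym-matching stage is deliberately omitted — it requires a lexical
  database — and the metric is named accordingly.

Reports carry per-sentence scores, means, and cumulative distributions
(fraction of sentences at or above each threshold; non-increasing by
construction). BLEU and ROUGE-L are verified against brute-force
enumeration oracles (exhaustive subsequence search for the LCS), CIDEr
against hand-built TF-IDF vectors on a toy corpus.

## The synthetic corpus generator

`synthetic_grammar()` fixes a word inventory partitioned into
per-keyword topic supports and a background support, each carrying a
Zipf-like (1/rank) distribution; a document with keyword set $S$ draws
its words i.i.d. from

$$p_S = \lambda \cdot \mathrm{mean}_{k \in S}(\text{topic}_k) +
        (1 - \lambda)\cdot \text{background},$$

with mixing weight $\lambda$ (default 0.75). Records carry 1–3
keywords, a year, a one-sentence title, a 2–6 sentence abstract, and
word-level annotations from a label map fixed at grammar construction —
so labels are a pure function of the word, annotations never overlap,
and `true_conditional_distribution()` returns the exact next-word
distribution in closed form. Defaults (200 words, 4 keywords, 5–9 words
per sentence, years 1990–2019) are sized so that a corpus of a few
hundred documents exposes every pipeline feature while remaining
trainable on one CPU in minutes.

What the generator emulates: condition-dependent token distributions,
metadata keywords and years, sentence structure, complete word-level
annotations. What it does not: real syntax or discourse (words are
i.i.d. within a document), polysemy, the heavy-tailed keyword vocabulary
of MEDLINE, annotation noise, or non-English contamination. Passing
tests on this corpus therefore demonstrate that the machinery —
conditioning pathway, multi-task heads, tokenizer, metrics — behaves as
specified, not that the model reaches any particular quality on real
biomedical text, which requires full-scale training outside this
package's scope.

## Study designs used by the tests and acceptance script

Two desk-scale studies are fixed once and reused:

* **Memorization**: 16 short synthetic documents (30-word grammar,
  4–6-word sentences), one fixed 16-window batch, the diagnostic
  configuration from `tiny_model_config()` (64-dim embeddings, 2 heads,
  1 encoder / 2 decoder blocks, feed-forward width 128, dropout 0 —
  dropout is a regularizer against exactly the memorization these
  diagnostics measure), Adam at $2\times10^{-3}$ with 100-step warmup,
  capped at 2000 steps. The token loss must fall below 0.3, and greedy
  decoding from the shortest document's title must replay its abstract
  token-for-token.
* **Conditional control**: 500 documents from a 2-keyword grammar with
  disjoint 10-word topic supports over a 36-word inventory,
  $\lambda = 0.8$, vocabulary size 96 (large enough that every grammar
  word earns its own piece, making the model's word distribution
  directly readable from token probabilities), window 48, 2400 training
  steps. The model's averaged next-word distribution under each
  condition — softmax rows at word-start positions of in-distribution
  probe contexts, restricted to word pieces and renormalized — must be
  within total-variation 0.15 of the grammar's true conditional, and
  sampled text under each condition must contain more than 10× as many
  on-topic as off-topic words. Disjoint supports are chosen for a sharp
  signal: any off-topic mass is attributable to the model, not the
  generator.

Problem sizes (500 documents, 48-token windows, 2400 steps, batch 16)
are the package's chosen desk-scale study conditions; they give the
conditional signal a comfortable margin on one CPU within minutes.

## Numerical choices and degenerate inputs

* Layer-norm epsilon $10^{-5}$; population variance per row.
* Attention scores scale by $1/\sqrt{d_h}$ with $d_h$ the per-head
  width; masked positions receive weight exactly 0; a fully masked row
  is an error (undefined softmax) rather than a silent NaN.
* Initialization: scaled normal, sd 0.02, for all matrices; layer-norm
  gains 1, offsets 0 — the convention of this model family's published
  configurations.
* Cross-entropy clamps probabilities at $10^{-300}$ before the log; a
  non-finite training loss aborts with the step number.
* Unknown characters segment to the unknown id with a fixed penalty
  log-probability (−20), so Viterbi never prefers them when a covered
  path exists.
* Ties: `max.col`-based softmax maxima take the first maximum;
  candidate pruning in the vocabulary trainer breaks usage ties by raw
  frequency, then lexicographically, keeping builds deterministic.
* Empty hypotheses score 0 (with a warning where the protocol calls for
  one); an empty generation produces a zero-sentence report flagged by
  a warning rather than an error.

## Known limitations

* The transformer runs on one CPU in plain R: fine for the desk-scale
  studies above, far from full-scale pretraining (which the reference
  configuration performed on a GPU cluster over days); no
  mixed precision, no multi-device support, no KV caching during
  generation (each step re-runs the prefix).
* The annotation provider is out of scope: real corpora need external
  POS/dependency/entity annotations in the documented JSON-lines
  format; the synthetic generator stands in for them during testing.
* `meteor_lite` omits synonym matching; scores are not comparable to
  full METEOR implementations.
* The MEDLINE XML reader covers the common `PubmedArticle` layout
  (title, abstract, year, language, MeSH descriptors, keyword lists),
  not every historical DTD variant.
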