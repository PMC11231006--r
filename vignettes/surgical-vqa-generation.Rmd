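---
title: "Scene-graph driven surgical VQA: generation, curation, bias auditing and a reference model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scene-graph driven surgical VQA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgvqa)
```

## The problem

Surgical visual question answering asks a model to answer natural-language
questions about a laparoscopic video frame: which instruments are present,
where an anatomy sits, which action is being performed on which structure.
Two things make good benchmarks hard to build. First, hand-written QA
datasets are small and their questions leak: when a question's wording alone
predicts its answer ("how many livers are there?" — always one), a model can
score well without ever looking at the image. This package calls that
*question–condition bias* and ships tooling to measure and remove it.
Second, answering compositional questions ("what is the tool to the left of
yellow anatomy?") needs object-level scene structure, not just a global
image embedding.

`surgvqa` addresses both ends: it generates question–answer pairs from
attributed *scene graphs* by executing functional programs, curates the
result for balance and leakage, audits residual text-only predictability,
and provides a desk-scale reference implementation of a scene-aware VQA
network whose components (attention, a scene-embedded interaction module,
RoIAlign pooling, a fusion classifier) can be trained and ablated on
synthetic data in minutes on one CPU.

## Scene graphs

A frame's scene graph has one node per detected object, carrying name
(e.g. `hook`, `gallbladder`), category (`instrument` / `anatomy`), a
per-class color, the bounding box and a location token. Conventions:

* Coordinates are 0-based with origin top-left, x rightward, y downward;
  boxes are half-open `[x1, x2) x [y1, y2)` in continuous pixels.
* The location grid is 3x3 equal thirds with hyphenated labels
  (`top-left` … `bottom-right`, frame centre `mid-mid`). A centroid exactly
  on an interior grid line resolves to the lower-index cell (left/top wins)
  so assignment is deterministic.
* Spatial edges come from centroid comparison: `(a, "left of", b)` iff a's
  centroid x is strictly smaller, similarly `above`; converses are always
  emitted. An exact centroid tie on an axis emits *no* edge on that axis —
  an arbitrary direction would make question answers depend on iteration
  order.
* All pairwise relations are emitted (no nearest-neighbour restriction);
  with at most ~8 objects per frame the quadratic edge count is trivial.
* Colors are per-class constants from the vocabulary (gallbladder→yellow,
  liver→brown, …), not pixel estimates. This matches how the questions use
  color: as a referring attribute, not a measurement.
* Action edges are `<instrument, verb, target>` triplets resolved against
  the frame's detections; a triplet naming an absent object is reported and
  dropped while the frame is kept.

Anatomies occur at most once per frame — in a cholecystectomy field there
is one liver, one gallbladder — and the generator enforces this. That fact
is load-bearing: it is exactly why anatomy counts are constant and why such
questions are curated away.

## The question engine

Questions are instantiated from a registry of 40 templates over five typed
slots — `<C>` color, `<L>` location, `<T>` type, `<N>` name, `<R>`
relationship — spanning five question types (query object, query attribute,
query relation, existence, counting) and three complexity classes. The
registry is a reconstruction distributed across those types and classes and
anchored to the attested worked examples (the tool-relation query, action
queries on anatomies, location existence probes, anatomy counting); it lives
in `inst/extdata/templates.yaml` as data, not code.

Every template binds its text pattern to a *functional program*: a chain of
primitives (`filter_*`, `relate_spatial`, `relate_action`, `unique`,
`query_*`, `exist`, `count`, `intersect`) executed against the scene graph.
The stored program is the ground truth: each emitted QA pair re-executes to
its stored answer, which the test suite checks against an independent
brute-force evaluator.

Design choices that were genuinely open:

* **Complexity classes.** Zero relate steps → `zero_hop`; one → `one_hop`;
  two relate chains joined by one `intersect` (two reference objects
  constraining one queried object) → `single_and`. Nested booleans beyond
  one `and` are out of scope.
* **Null-slot grammar.** Optional slots realize as nothing (relation,
  color), as `"thing"` (type), or as `"in the frame"` (location in counting
  questions) — "how many instruments are?" is never produced. Verbs surface
  as past participles ("being retracted"); relations as "to the left of"
  style phrases. Realized text is lowercased with whitespace collapsed.
* **Candidate enumeration.** Query templates enumerate slot values attested
  in the graph (anything else is unanswerable by construction); existence
  and counting probe slots enumerate the full vocabulary so that "no" and
  "0" answers occur — existence questions that are always true are
  uninformative.
* **Referent uniqueness.** A binding survives only if every `unique()` step
  succeeds, so no emitted question contains an ambiguous or unmatched
  referring expression; `INVALID` is a value, not an exception.
* **Closed answers.** Counts above the configured maximum (6) are dropped,
  keeping the answer set closed: names ∪ colors ∪ locations ∪ types ∪
  verbs ∪ {yes, no} ∪ {"0" … "6"}.
* **Determinism.** Per-scene generation orders candidates canonically by
  (template id, binding) and samples without replacement under a fixed
  seed, honouring a per-scene cap (default 50) and optional per-type
  quotas.

## Curation

Three passes reduce class imbalance and leakage:

1. **Phase-balanced frame sampling.** Real cholecystectomy timelines are
   heavily skewed toward preparation and Calot-triangle dissection. With m
   the minimum per-phase frame count, each phase contributes between m and
   m + tolerance frames (default tolerance 0), drawn uniformly without
   replacement. "Nearly equal" is thereby formalized as a hard band around
   the minimum.
2. **Template blocklist.** Templates that leak by construction are excluded
   before generation; by default the name-counting template (the source of
   "how many livers are there?") is blocked.
3. **Degenerate-question elimination and answer rebalancing.** Query
   questions whose referent class is absent, counting questions whose
   counted class is an anatomy (constant answers), and programs returning
   `INVALID` are dropped; then, within each question type, answers are
   rejection-subsampled so no single answer exceeds a configured fraction
   (default 0.6) of the pool — a type with only one observed answer is
   exempt. Both the answer cap and the blocklist are exposed knobs because
   "class distribution balancing" can plausibly mean either; the default
   applies both.

All filters are idempotent and seed-deterministic.

## Bias audit

The audit asks: how well can the answer be predicted from the question text
alone? Two non-neural probes implement this: a majority probe
(normalized question string → most frequent training answer, global
majority fallback, lexicographic ties) and a multinomial naive-Bayes probe
over whitespace tokens with additive smoothing. Text-only leakage is a
property of the dataset, not of the probe's capacity, so any text-only
predictor measures it; pretrained language models are deliberately not a
dependency. Reports carry accuracy, macro-averaged recall and F-score over
the answer classes present in the test split (a predicted-but-absent class
is excluded from the macro average), and the per-question answer entropy —
zero bits everywhere means the text fully determines the answer.

Two purpose-built fixtures calibrate the audit: a *leaky* family (anatomy
counts, per-class colors, present-anatomy existence — all deterministic
functions of the wording) on which the majority probe must reach held-out
accuracy 1.0, and a *balanced* family (answers uniform within type,
independent of wording) on which probes must sit at the chance rate implied
by the answer marginals. Curation can only remove or rebalance questions,
so it never increases probe accuracy on the leaky family.

## Synthetic procedures

`random_procedure()` emulates the structure of a laparoscopic
cholecystectomy stream without rendering pixels: seven phases in canonical
order laid out as contiguous blocks proportional to duration weights
(default `4, 6, 2, 3, 1, 2, 1` over 140 frames at 854x480 — preparation and
Calot-triangle dissection overrepresented, as in real timelines); per-block
object presence (liver probability 1.0, gallbladder 0.95, rarer structures
lower) with instruments drawn from phase-typical pools; Gaussian centroid
jitter (sd 12 px, extents clamped to the frame) giving temporally coherent
boxes; and one action triplet per frame linking a present instrument to a
phase-typical anatomy with a phase-conditioned verb. Everything is a pure
function of the config seed.

What the fixture does *not* emulate: detector noise (false or missed
boxes), class confusion, multi-triplet frames, inter-phase transitions
blending objects, or any appearance variation. Tests passing on this
fixture therefore certify the generation/curation/audit machinery, not
robustness to real detection errors.

## The reference model

The network consumes three sequences in a common dimension d (default 64,
single attention head — head count and widths are unreported in the
literature this mirrors, so they are config knobs): text token embeddings T
(learned table over a whitespace tokenizer), scene embeddings S (a linear
*scene encoder* over per-object class one-hot plus box corners normalized
to [0,1]; width |classes| + 4 before projection), and object-wise visual
embeddings V. The *scene-embedded interaction module* (SIM) applies two
interaction layers, each cross-attention (S as query, T as key/value), then
self-attention over the scene sequence, then a feed-forward sub-layer, with
residual connections and layer normalization around every sub-layer —
standard transformer practice where the source material shows sub-layers
but no residual scheme. Scene nodes carry no positional encoding, so SIM is
permutation-equivariant in object order and the fusion output is
permutation-invariant. The refined scene, visual and text sequences are
concatenated, passed through one self-attention fusion layer, masked
average-pooled (dividing by the count of unmasked positions) and mapped to
the closed answer set.

RoIAlign divides a box into equal cells, samples each cell at 2x2 regularly
spaced sub-points (a common convention) via bilinear interpolation on the
feature grid (value (i, j) at continuous coordinate (j−0.5, i−0.5),
clamping at borders), and averages sub-points per cell. Attention rows over
masked keys renormalize over the unmasked set; a query whose keys are all
masked yields a defined zero row and a logged message.

Everything trains through a small reverse-mode autodiff over dense matrices
written for this package (tape of nodes in creation order; matmul, softmax,
layer-norm, embedding-gather, masked pooling and softmax cross-entropy
primitives; full-batch Adam). At desk scale — dozens of samples, d = 64 —
an epoch takes on the order of a second; nothing here is meant for real
corpora.

### The toy benchmark and the ablation direction

The two ablation knobs mirror the structure of the scene-knowledge
ablation: `use_sim = FALSE` removes the scene branch (scene encoder + SIM)
from the fusion input entirely, leaving a visual + text model;
`use_visual = FALSE` removes the object-wise visual stream, leaving a
scene + text model.

`toy_vqa_dataset()` builds scenes of one instrument and two anatomies and
asks one question per scene from three families, each answerable from
exactly one input stream: *"what is the location of the instrument?"* — the
grid bin is a function of the box coordinates, which only the scene branch
carries (instrument centroids are sampled well inside a cell on the grid
diagonal, making it a clean 3-way task learnable at this sample size);
*"what is the texture of the instrument?"* — the texture token exists only
as a strong pseudo-random pattern added to the hash-based visual features;
*"what is the color of the `<name>`?"* — colors are class
constants, readable from the question text alone. Removing a stream
therefore imposes a chance-level ceiling on its question family, making the
streams complementary by construction. The ablation asserts the
*direction* of that complementarity: after seed-fixed training (160
training / 96 validation samples, 35 epochs, Adam lr 3e-3, best validation
accuracy over the trace as the early-stopping selection), the full model
scores at least as high as the scene-only and visual-only variants. It is a
≥ relation on this synthetic task — not any benchmark's printed numbers,
which require real corpora, pretrained backbones and GPU budgets and are
out of scope here. A separate capacity check trains on 64 samples and
requires ≥95% training accuracy within 200 epochs.

The deterministic hash-based visual provider stands behind the same
interface as a real backbone + RoIAlign path; swapping in genuine features
only requires implementing that interface.

## Numerical and degenerate-input choices

* Centroid ties: no spatial edge on the tied axis (see above).
* Grid-line centroids: lower-index cell.
* Probe ties: lexicographically first answer.
* Empty scenes: generation still emits existence/counting questions with
  answers "no"/"0"; the scene encoder returns a 0 x d sequence; fusion of a
  fully masked sequence is an error.
* Zero-area RoI boxes and boxes outside the map extent are errors.
* Attention softmax subtracts the row maximum for stability; layer-norm
  uses eps 1e-5; cross-entropy clamps probabilities at 1e-12.
* All stochastic functions take explicit seeds and restore the caller's RNG
  state; derived seeds stay below 2^31.

## Known limitations

* The template registry is a faithful reconstruction spanning the attested
  examples and the declared type/complexity space, not a verbatim copy of
  any external template list.
* Query-relation questions cover the attested action form ("what is the
  action being performed on …"); spatial relations are not themselves
  query targets.
* The bias probes are intentionally simple; they lower-bound what a large
  language model could extract from question text.
* The model is single-head and small; it demonstrates correctness
  properties (shape contracts, masking, equivariance, trainability), not
  state-of-the-art accuracy.
* Problem sizes in the test suite (100-frame procedures, 1000-program
  oracle sweeps, 128/96-sample training splits) were chosen so the whole
  suite runs in minutes on one CPU; they are stated here as the package's
  own reference conditions.
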