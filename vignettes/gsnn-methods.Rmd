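---
title: "Graph-structured neural networks for perturbation biology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-structured neural networks for perturbation biology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsnn)
```

## The modeling problem

Chemical perturbation experiments measure how a cell line's transcriptome
responds to a drug at a given dose. The response arises from a cascade of
physical interactions — a drug engages protein targets, signal propagates
through protein-protein interactions, transcription factors alter RNA
abundance — and decades of literature curation have produced directed
interaction networks describing which molecular entities can influence which
others. This package implements a neural predictor whose computation is
*constrained* by such a network: the model can only learn relationships that
correspond to paths in the prior-knowledge graph, so accurate prior knowledge
acts as inductive bias and the fitted model can be interrogated in the
vocabulary of molecular interactions.

## The structural graph

The *structural graph* has three node roles. Input nodes carry the
observation: one node per drug (a transformed concentration) and one node per
cellular-context ('omic) feature such as an expression, copy-number, mutation
or methylation value; input nodes have in-degree zero. Function nodes are the
proteins and RNAs; each is realized as a small neural map and must have
nonzero in- and out-degree. Output nodes represent measured transcripts; each
has exactly one incoming edge from its RNA node and out-degree zero. Edges
are classed as input, function, or output edges (classification into an
output node takes precedence), and cycles among function nodes are allowed.
Because an entity may act both as a protein and as an RNA, function nodes are
namespaced `PROTEIN_<id>` / `RNA_<id>`; an expression feature `EXPR_<id>`
connects to both nodes when both exist, since transcript abundance is
relevant to both molecular forms.

Node order (lexicographic by entity class, then name, under C collation) and
edge order (by source index, then target index) are deterministic so that
every derived matrix layout — masks, parameter blocks, importance scores —
is reproducible across sessions.

One open design point was what to do when a data source implies two
regulators writing a single output node: we reject such graphs during
validation rather than silently merging edges, because a multi-regulator
output contradicts the read-out semantics (an output is a measurement of its
single RNA parent, not a computation).

## The model

The hidden state is a scalar per *edge*, updated in L residual layers.
Function node $n$ with in-degree $D^{in}_n$ and out-degree $D^{out}_n$ owns a
one-hidden-layer network: a gather of its incoming-edge values, a linear map
to $C_n$ hidden channels, per-node layer normalization, an ELU nonlinearity,
optional dropout on the hidden channels, and a linear scatter onto its
outgoing edges. No parameters are shared between function nodes. A layer
applies every node's map to the previous edge state and adds the result back
(`state <- F(state) + state`), so signal accumulates over depth and
propagates one function-node hop per layer — the depth L bounds how far a
stimulus can travel, which also models the latency of multi-step signaling.
The whole layer is equivalent to multiplying by two masked block matrices of
shapes (sum of channels x E) and (E x sum of channels); the implementation
executes the per-node blocks directly, and the test suite checks it against
an explicit dense masked-matrix oracle.

Input handling: the encoded input value of an input node is written onto its
outgoing edges at initialization. Function nodes never write input edges, so
the residual update leaves them fixed — the stimulus is effectively clamped
at every depth. We chose clamping (rather than injecting the input only once
and letting the residual stream carry it) because residual accumulation of a
re-injected input would double-count the stimulus; with clamping, a layer's
view of the input is constant and the zero-weight model is exactly the
identity on edge states.

Normalization is layer normalization *within* each function node (mean and
variance over that node's hidden channels, per observation), applied before
the activation with learnable per-(node, layer) scale and shift. Batch
normalization is deliberately avoided: the edge-state representation forces
small training batches, where batch statistics are unreliable. When weights
are shared across layers (`share_layer_params`), normalization parameters
remain per-layer because activation statistics change with depth. With one
hidden channel, layer normalization degenerates (the normalized value is
identically zero), so degree-scaled channels should be combined with
`norm = "none"` or a channel floor above one if that matters.

Initialization is degree-aware: weights of node $n$ are drawn from
$\mathcal N(0,\, 2/D^{in}_n)$ (kaiming) or
$\mathcal N(0,\, 2/(D^{in}_n + D^{out}_n))$ (xavier), where the second
argument is the variance and the fans are the node's degrees in the graph
(self-edges included — they are real computation edges). Degenerate degrees
(possible in randomized control graphs) clamp the fan at one. Biases start
at zero, normalization at identity.

Hyperparameters and defaults: channels C = 8, layers L = 5, dropout 0
(applied to hidden channels, not edge states — the edge state is the
residual stream and dropping it would sever the graph), ELU activation
(unstated for the constrained model in the source literature; ELU matches
the baselines), optional self-edges and degree-scaled channels
(`C_n = max(1, min(C, max(D_in, D_out)))` — one concrete realization of
"scale capacity with degree"). Training is minibatch Adam on mean squared
error over output nodes with early stopping on validation mean-Pearson
(patience 10); gradients are computed by hand-written reverse-mode
differentiation through the gather/norm/activation/scatter/residual chain,
verified against finite differences in the tests.

## Evaluation protocol

Data partitions are disjoint sets of (drug, cell line) *pairs* — 60% train,
20% validation, 20% test, counts rounded by floor with the remainder going
to train — so evaluation measures interpolation to unseen drug-cell
combinations, not generalization to unseen drugs or lines. Performance is
the mean Pearson correlation: per output gene, the correlation between
prediction and target across test observations, averaged over genes
(zero-variance columns are skipped and counted). Method comparisons use a
two-sided paired t-test across fold scores with Bonferroni adjustment
(`min(1, p * n_tests)`); note that fold scores rounded to two decimals can
produce exactly constant paired differences, which the implementation flags
as a zero-variance condition rather than reporting a p-value. Grouped local
performance compares two methods within observation groups (by drug, gene,
target, ...) with a paired t-test per group and Benjamini-Hochberg or
Benjamini-Yekutieli FDR control at threshold 0.1; groups with fewer than 5
observations in any fold are dropped. Hyperparameter grids are searched
within each fold and selected on validation score only — test targets are
never consulted before final scoring.

The fully connected baseline is a two-layer network (linear, batch
normalization, ELU, linear); its *cell-agnostic* variant removes all
'omic input positions at encoding time and therefore can only predict each
drug's average response.

## Randomized control graphs

To test whether performance derives from the prior knowledge, a control
graph resamples edges within classes: input edges keep their input-node
source and draw a uniform function-node destination, output edges keep their
output-node destination and draw a uniform function-node source, function
edges draw both endpoints uniformly. Class counts and the node set are
preserved exactly; individual function-node degrees are not, so control
graphs may contain function nodes with zero in- or out-degree and the
validator accepts these under a `allow_degenerate` flag. Self-loops are
resampled away unless the original graph used self-edges; duplicates are
redrawn (with a bounded number of rounds).

## Biological subgraph construction

Raw interaction tables (drug targets, protein-protein interactions, TF and
miRNA regulation, translation, pathway membership) are reduced to a
pathway-focused subgraph in a fixed order: pathway proteins, then RNAs
reachable through regulator chains within a user depth (depth 1 = direct TF
targets; a TF to miRNA to mRNA chain needs depth 2; chains are only followed
through retained nodes so every included RNA keeps a retained regulator),
then drugs with a retained target, then measurable outputs, then all edges
with both endpoints retained. Drugs whose descendants cover less than a
fraction (default 25%) of the output nodes are pruned — they are too
constrained by the available knowledge to matter for most outputs — followed
by protein/RNA nodes with no downstream output. Pruning counts are taken on
the pre-'omics graph, and 'omic input nodes are attached last so they can
never resurrect pruned entities. A final cascade removes function nodes left
degenerate by pruning so the returned graph always validates. Confidence
scores on interaction rows are not thresholded; all provided rows are used.

## Dose encoding

Drug concentration in micromolar is mapped through
$x = -(\log_{10}(c + \varepsilon) - \log_{10}\varepsilon) / \log_{10}\varepsilon$
with $\varepsilon = 10^{-6}$: zero concentration stays exactly zero, 1 uM
maps to 1, and the transform is log-linear over the assay-relevant range.
'Omic values are passed through unchanged; the package does not prescribe an
'omics normalization (the fixture generator standardizes features to zero
mean and unit variance, which is what we would also recommend for real
inputs).

## Edge-mask explanation

To explain one prediction relative to a baseline observation (for a drug
response: the same cell line at dose zero), the explainer learns one logit
per edge. Masked-out edges cannot be set to zero — edges carry endogenous,
context-driven activations even without drug — so they are pinned, after
every layer, to the *baseline's* recorded layerwise activation. An all-ones
mask reproduces the model's prediction exactly and an all-zeros mask
reproduces the baseline prediction exactly (both identities are tested to
machine precision). Each iteration draws several relaxed binary masks from a
binary-concrete (Gumbel-softmax) distribution at the current temperature
(annealed geometrically from 5.0 to 0.5 — the schedule is our choice),
scores the masked differential prediction against the model's differential
prediction by MSE, and adds a mask-size penalty
$\beta \max(0, \sum M - E_{free})$ plus weight decay $\gamma\|\theta\|^2$.
We hinge the size penalty at the free-edge budget rather than using the
plain $\beta(\sum M - E)$ form, which would reward masks smaller than the
budget even when they destroy the prediction. Logits start at a high
inclusion prior (P = 0.9) so optimization begins from nearly the full graph
and the penalty must argue edges away. Scores are the final inclusion
probabilities; hard masks threshold at 0.5; all edge classes are maskable.
Because excluded edges revert to baseline activations, edges not downstream
of the perturbation receive exactly zero gradient and keep their prior
score — a useful diagnostic of which part of the score vector is
data-driven. Replicate explanations differ through the concrete sampling;
averaging replicate score vectors reduces this variance, and the tests
verify that averaged pairs agree better than raw replicates.

## Viability head and drug prioritization

A probabilistic viability head is trained on top of the *frozen* expression
model: a single linear layer maps the predicted expression vector to two
outputs, pushed through softplus plus $10^{-6}$ to Beta concentration
parameters (a, b), trained by the exact Beta negative log-likelihood with
viability clipped into $[10^{-4}, 1 - 10^{-4}]$ for stability. Uncertainty
comes from a deep ensemble (default 10 members — the ensemble size is not
fixed by the source method description) differing in initialization and data
order; the predictive distribution is the uniform mixture of member Betas.

The selective-response statistic of a drug, $p_{sens}$, is the probability
that the mean viability over user-designated *target* lines is lower than
over *background* lines. A mixture of Betas has no convenient closed form,
so the statistic is estimated by Monte Carlo (default 1000 rounds): per
round and per line, draw one ensemble member uniformly, then one viability
sample from its Beta, and compare group means. Drugs are ranked by
$p_{sens}$ descending with ties broken by drug id. Rankings are evaluated
against indication labels by AUROC with a permutation null (the p-value is
the fraction of shuffled rankings with at least the observed AUROC). The
dose at which $p_{sens}$ is computed is a user choice (default 1 uM, i.e. a
transformed value of 1); the source method does not state one, and we do not
aggregate over doses. Two-drug combinations are encoded by setting both dose
positions simultaneously on the expression model's input.

## Synthetic data: what it emulates and what it does not

The fixture generators produce everything the pipeline consumes. Interaction
tables are random but guaranteed connected (a protein backbone chain, at
least one regulator per RNA, and a first drug targeting the chain head so
default pruning always retains a drug). Perturbation responses are simulated
by an independent ground-truth process — not the model's own forward pass:
each function node applies a random linear read-out squashed by tanh, with a
per-cell gain `1 + 0.4 * (its EXPR feature)`, and signal propagates
synchronously for 10 steps (unrolling cycles; 10 matches typical model
depths). Edges arriving directly from drugs get weights of guaranteed
magnitude (|w| in [1.5, 2.5]) so perturbations register above the
'omics-driven background; these constants were chosen so that the
true-graph-versus-random-graph advantage is a detectable property at desk
scale (a few dozen nodes, a few hundred observations) — with weaker
coupling the comparison is dominated by cell-baseline variance that either
graph can fit. Gaussian noise (default sd 0.05) is added to outputs.

The planted-path instance wires exactly one drug-to-output chain (the chain
weights are pinned to a high positive gain so the response is unambiguous)
next to a disjoint 'omics-driven decoy chain, giving the explainer a ground
truth. The viability generator draws from Beta distributions whose mean is a
logistic function of the simulated expression shift, normalized by the
dataset's upper-quantile shift; a planted drug whose input signal is
suppressed outside two designated target lines is therefore selectively
cytotoxic by construction, with a margin the tests assert.

What passing these tests does *not* show: the simulator has smooth, weakly
nonlinear node functions, homoscedastic noise, complete and perfectly
correct prior knowledge, standardized 'omics, and a handful of cell lines —
none of which hold for real assay data, where measurement noise structure,
missing interactions, and batch effects dominate. The synthetic results
validate the machinery (gradients, masking, ranking logic, protocol
hygiene), not biological performance.

## Numerical choices and problem sizes

Layer-norm epsilon $10^{-5}$; Beta-head positivity epsilon $10^{-6}$ and
clip $10^{-4}$; Adam with $(\beta_1, \beta_2) = (0.9, 0.999)$; dose epsilon
$10^{-6}$ exposed in configuration. All stochastic entry points take
explicit seeds and run under isolated RNG scopes; named sub-streams are
derived from a global seed so components are independently reproducible.
The shipped experiments use fixture graphs of roughly 50 nodes and 100
edges, 240 simulated observations, models with 4-5 channels and 4-6 layers,
and 5-seed repetitions — sizes we consider representative for a desk-scale
property harness while keeping every suite run comfortably interactive.

## Known limitations

Pure-R execution of the per-node blocks is practical for hundreds of nodes,
not for genome-scale graphs; a compiled or sparse-matrix backend would be
the natural next step. The explainer optimizes a relaxed objective and its
hard-threshold subgraph carries no optimality guarantee. The viability head
is linear in predicted expression; strongly nonlinear viability
relationships will be underfit. The cell-agnostic baseline, randomization
scheme and MCCV protocol are faithful to their definitions, but the
package deliberately re-implements no message-passing (GCN/GAT/GIN-style)
baselines.
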