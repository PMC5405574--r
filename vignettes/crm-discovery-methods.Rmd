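---
title: "Modelling cis-regulatory modules with an explicit-duration HMM"
author: "crmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cis-regulatory modules with an explicit-duration HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmscan)
```

# The problem

Cis-regulatory modules (CRMs) — promoters, enhancers, silencers — are DNA
segments of roughly 100–2000 bp that carry several transcription-factor
binding sites acting together. Given a set of regulatory sequences from
co-expressed genes and a library of motifs (position weight matrices,
PWMs), `crmscan` locates CRMs, labels the motif sites inside them with
strand and score, and reports which CRMs recur across sequences. The
premise is that co-expressed genes are driven by CRMs with a shared
internal grammar: which motifs occur, how often, in what order and
orientation, and how far apart. The model makes that grammar explicit and
learns it from the data.

# The generative model

A sequence is modelled as alternating inter-CRM background and CRMs:

* **Inter-CRM background** `b_g` emits one base at a time from an
  order-*k* Markov chain θ₀ (default *k* = 1) and continues with
  probability 1 − p_r per base, so its run length is geometric with mean
  1/p_r.
* **CRM initiation.** At each background decision point a CRM starts with
  probability p_r (default 0.001, i.e. roughly one CRM per kilobase of
  candidate region). The first motif state is drawn from the frequency
  vector q.
* **Motif states.** Each of the K′ motifs contributes two fixed-duration
  states — the PWM and its reverse complement — so sites are found on
  either strand. A site of length ℓ is emitted with probability
  ∏ᵢ w[xᵢ, i].
* **Continuation and termination.** After each site the CRM terminates
  with probability q₀ (default 0.1, giving ten sites per CRM on average)
  or continues, choosing the next motif state by the transition law below
  and first emitting a **spacer** `b_c`: an order-*k′* Markov chain θ₁
  (default *k′* = 2) whose length is geometric on {1, 2, …} with mean
  *h* (default 50 bp; ~20 bp suits densely packed CRMs).

The transition law makes motif arrangement part of the model. Each state
*i* carries a (possibly empty) set Rᵢ of correlated partners with
probabilities r_{i,j}; uncorrelated successors share the remaining mass in
proportion to their frequencies:

$$q_{i,j} = r_{i,j} \;\; (j \in R_i), \qquad
  q_{i,j} = q_j\,\frac{1 - \sum_{k \in R_i} r_{i,k}}
                      {\sum_{k \notin R_i} q_k} \;\; (j \notin R_i).$$

This captures composite elements — motif pairs that sit next to each
other far more often than their frequencies explain — with one parameter
per detected pair rather than a full K′ × K′ transition table.

Auxiliary bookkeeping states (CRM start/end markers, next-motif
selectors) emit nothing and are compiled away: the implementation works
on the compact state set {b_g, m₁…m₂ₖ′, b_c}, with background duration
realised as a per-base self-transition (exactly equivalent to the stated
geometric law) and spacer duration as an explicit geometric. A CRM still
open when the sequence ends pays its termination probability; trailing
background is censored (no terminal factor). Spacer and background
emissions condition on the observed preceding bases, with lower-order
fallback at the sequence start and around `N` (which always emits 0.25).
Because the geometric spacer law is defined on lengths ≥ 1, two sites
within a CRM never abut directly.

# Training

PWMs, θ₀, θ₁, p_r and q₀ are held fixed: the backgrounds are estimated
up front from the full input (true intra-CRM regions are unknown a
priori) with a pseudocount of 1 per context cell, and p_r/q₀ come from
configuration because re-estimating rare-event rates from a few dozen
sequences overfits. The free parameters λ = {q, p_h, r} are estimated by
an extended Baum–Welch EM:

* **E-step.** An exact forward–backward pass over the duration HMM (Rcpp,
  log-space) yields per-sequence posteriors: expected first-motif usage,
  expected adjacent-pair counts T_{ij} (motif *i*, one spacer, motif
  *j*), expected spacer bases, and site posteriors. Sequences are
  independent; accumulation follows the fixed input order, so a serial
  and a concurrent E-step give identical results.
* **M-step.** p_h is the expected spacer count over expected spacer
  bases. q maximizes the expected complete-data log-likelihood exactly:
  the objective couples the frequencies through the renormalization in
  the transition law, so the maximizer is found by an MM scheme
  (linearize the −log Σq terms, solve the resulting separable problem,
  iterate), which provably does not decrease the objective — EM
  monotonicity is preserved and is asserted by the test suite to 1e-6.
  By default the forward and reverse-complement states of a motif share
  one frequency parameter: a site on the reverse strand is the same
  binding event read from the other side, so motif frequency is
  strand-symmetric; tying pools the counts and roughly halves the
  variance of the estimate. Correlations r_{i,j} remain
  orientation-specific, because arrangement and orientation preferences
  are exactly the signal the correlation parameters exist to capture.
  Gated r values are re-estimated as expected-count shares
  r_{i,j} = T_{ij} / Σ_k T_{ik}. (The share form with the row total in
  the denominator is used deliberately: renormalizing within the gated
  set alone can push r above 1 whenever the gated pairs carry most of
  the row's counts, violating the parameter's meaning.)
* **Correlation detection.** All pairs start uncorrelated. After a
  burn-in (default 5 iterations) each pair's co-occurrence count is
  compared with a no-correlation null in which the N = ΣT adjacency
  slots draw their (predecessor, successor) identity independently from
  the observed marginals, so T_{ij} ~ Binomial(N, aᵢbⱼ). A pair is
  declared correlated when z = (T − E)/σ ≥ 1 **and** E ≥ 1 — the
  expectation gate stops rare pairs from looking significant. The
  detected set is then frozen; its r values keep updating. The z ≥ 1
  bar is deliberately permissive, so occasional spurious pairs are
  expected; they receive r values close to what the frequency channel
  would give them and have little effect on predictions. The posterior
  second moment of any pair count is also available exactly (a
  moment-propagating forward pass) for diagnostics.

Two schedule details matter in practice and are part of the package's
design: q is held at its initialization until the gate has run, because
frequencies and correlations are confounded while pairs are still
(wrongly) assumed independent — updating q during burn-in folds the
correlation mass into the frequencies, and EM does not recover from
that; and convergence (relative log-likelihood improvement below `tol`,
default 1e-4) is not declared until `burn_in` iterations after the gate
fires, so the posterior re-equilibrates under the new structure.

# Inference and scoring

A duration Viterbi pass decodes the most likely segmentation, with
deterministic tie-breaking (background preferred, then lower motif index,
then shorter spacer). Maximal motif/spacer runs become CRM predictions
spanning first-site start to last-site end. Each CRM is scored by the
log-likelihood ratio of its decoded internal generative probability
(site emissions, transitions, spacer durations and θ₁ emissions,
termination) against θ₀ emitting the same span; the score conditions on
the decoded segmentation rather than marginalizing over all internal
segmentations — the conditional version is reported because it scores
the annotation actually being output. Natural-log and log₂ values are
both reported.

Candidates below a configurable LLR weight threshold w_c (default 0) are
flagged out. When more than three sequences carry predictions, CRMs are
screened for conservation: a graph joins CRMs from different sequences
whose similarity

$$D(c_1, c_2) = \mu_m\,J(M_1, M_2) + (1 - \mu_m)\,J(MS_1, MS_2)$$

reaches 0.5 (J = Jaccard; M = motif sets; MS = site identity sets;
μ_m = 0.5), and maximal cliques with ≥ 3 nodes are conserved CRM types,
scored by the summed pairwise similarity divided by the total number of
input sequences N (an alternative per-pair normalization is available).
Because sites in different sequences have different coordinates, site
identity is positional-rank-based: (motif id, strand, ordinal occurrence
of that motif within its CRM). Screened-out CRMs stay in the output,
flagged, so screening never silently drops data.

# Evaluation utilities

Predictions are evaluated at nucleotide level: per-base confusion counts
pooled over sequences, sensitivity, precision, F1, ASP and the
Matthews-style correlation coefficient (returned as 0 with a flag when a
denominator factor vanishes). A fixed-length protocol supports
length-controlled benchmarking — one window of the subdataset's mean CRM
length per sequence, anchored on the best-scoring candidate — which
forces nPP = nAP and hence Sn = Pr; significance comes from an empirical
p-value, the fraction of uniformly random same-length placements whose
sensitivity reaches the observed one, computed with the add-one
(r+1)/(n+1) estimator and a `>=` count so it is conservative and never
zero. The best achievable pooled sensitivity under the protocol is
Σ min(Lᵢ, target)/Σ Lᵢ; this surrogate bound reproduces the published
per-subdataset values shipped in
`inst/extdata/redfly_protocol_summary.tsv` (loaded by
`redfly_protocol_summary()`), whose recomputed summaries are asserted in
the test suite.

# The synthetic benchmark generator

Two modes, all randomness from one seed (same seed ⇒ bit-identical
output):

* **Implanted-CRM mode** (`generate_xie_style()`) emulates the classic
  spiked benchmark: 22 sequences of 1000 bp, 20 carrying one implanted
  CRM of at most 164 bp built from 3–6 sites of the true motifs (motif
  and strand uniform, bases drawn from the PWM), inter-site gaps Poisson
  with mean 10 resampled to be ≥ 1 (the model's spacer floor; the
  truncation shifts the mean by ~5·10⁻⁴, negligible), the CRM placed
  uniformly. The background is a near-uniform order-1 chain with mild AT
  richness (A = T = 0.3) and a 15 % same-base stacking preference —
  enough texture to exercise the Markov backgrounds without dominating
  the signal. Decoy motif sets at the benchmark's noise ratios (7/10,
  17/20, 27/30, 37/40; 10 collections each) are built by column-shuffling
  true PWMs (column order permuted, base identities permuted within each
  column), which preserves per-column information content so decoys look
  like real motifs while matching none of the implanted sites.
* **Model mode** (`generate_from_model()`) samples the generative story
  above exactly and records the true state path, for parameter-recovery
  experiments. An element that would cross the sequence end closes its
  CRM after the last complete site; the remainder is background. This
  truncation slightly shortens observed spacers near sequence ends, a
  bias that is negligible when sequences are much longer than a CRM.

What the generator does **not** emulate: real inter-site dependence
inside binding sites (PWM columns are independent), repeat structure and
compositional heterogeneity of genomic background, overlapping or nested
CRMs, and motif libraries whose PWMs are themselves noisy. Passing tests
on synthetic data therefore demonstrate correctness of the machinery and
identifiability under the model's own assumptions — not performance on
any particular genome.

# Numerical choices and problem sizes

All HMM arithmetic is in natural-log space; forward and backward
likelihoods agree to 1e-8 and are checked against exhaustive
enumeration of every segmentation on short sequences. Viterbi
tie-breaking is fixed as above, so decoding is deterministic. Count
matrices get a 0.01 pseudocount per base before normalization (a zero
PWM entry would veto a site outright). The test suite runs the
parameter-recovery experiment at 50 sequences × 1000 bp with two
10 bp motifs whose columns put 0.95 on the consensus base — informative
enough that single sites outweigh the CRM-entry cost of
log p_r ≈ −6.9; with weak 8 bp motifs a lone site is below that cost
and the posterior smears successor identities, which is a property of
the model, not of the implementation. The recovery data are drawn at
initiation rate 0.004 so that ~450 adjacency slots are realized and the
planted pair share concentrates; the fit itself uses the default
configuration (p_r = 0.001, q₀ = 0.1, h = 50). Oracle comparisons use
sequences of ≤ 12 bp with 1–2 motifs of length ≤ 3, where exhaustive
enumeration is feasible.

# Known limitations

* PWM similarity for the optional redundancy filter is an
  information-content-weighted best-offset agreement; with the default
  minimum overlap of 4 columns, unrelated informative motifs
  occasionally reach ~0.84 on a chance 4–5 column alignment, so the
  default edge threshold of 0.8 can over-cluster small libraries —
  raise it (0.9) when the motifs are known to be distinct.
* The co-occurrence z-gate at threshold 1 admits occasional spurious
  pairs by construction; downstream effects are small, but the detected
  pair list should be read as candidates, not confirmed interactions.
* p_r and q₀ are not estimated; grossly mis-set values shift the
  CRM-length and CRM-count priors.
* The LLR conditions on the Viterbi segmentation; a
  marginalized variant would score CRM regions independently of one
  particular internal annotation.
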