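---
title: "Simulating coordination games and measuring consensus on networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating coordination games and measuring consensus on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcoord)
```

## The problem netcoord addresses

When people coordinate labels with network neighbours — a name for a face, a
hashtag for a news story — the group's convention dynamics depend jointly on
the network's wiring and on how much background knowledge individuals bring
to each response. netcoord simulates this setting: `N` agents on a fixed
graph play `T` rounds of a pairwise matching game (one point per round when
a pair produces the same canonicalized token), and a measurement suite
quantifies the resulting group convergence, individual decision strategies
and, for narrative content, the semantic alignment of responses with the
causal events of a focal story.

## Network structures and pairing

Two topologies are supported, chosen to contrast neighbourhood size against
global mixing:

* **Homogeneously mixed** — the complete graph; neighbourhood size `N - 1`,
  diameter 1 at every size.
* **Spatially embedded** — a circulant ring lattice in which node `i` is
  adjacent to `i ± 1` and `i ± 2` (mod `N`), so every node has exactly four
  neighbours regardless of size and the diameter grows with `N`. The
  "four nearest neighbours" reading as `±1, ±2` on a ring is the standard
  spatial-lattice convention for this family of experiments.

With `T` trials and neighbourhood size `k`, a participant expects `T / k`
complete sweeps through their neighbourhood
(`expected_neighbor_sweeps()`): at `T = 40`, 10 sweeps in any spatial
network, but only 81.6% of a single sweep at `N = 50` homogeneous and 40.4%
at `N = 100`. This asymmetry in repeated contact is the structural lever the
simulator reproduces.

Every trial pairs *all* agents: a perfect matching drawn inside the edge
set (`sample_pairing()`). Network sizes must therefore be even, and we
reject odd sizes rather than leaving an agent unpartnered. The sampler is
randomized greedy matching with random augmenting "steals": unmatched nodes
pick a uniformly random neighbour and, if that neighbour is taken, displace
its partner back onto the queue. We initially implemented plain greedy with
full restarts, but on sparse rings a single greedy pass dead-ends with
probability approaching 1 as `N` grows (at `N = 50` effectively every
attempt fails), so local repair is not an optimisation but a correctness
requirement. The steal walk terminates quickly at all supported sizes, every
edge has positive probability of appearing across draws, and we deliberately
do not claim the draw is uniform over perfect matchings — the online
platforms being emulated do not document their matching distribution either.

## The two agent models

**Name Game.** The minimal convention-formation baseline. Each agent keeps a
vocabulary of tokens; responses are uniform draws from it (from the prior
library when it is still empty). After each interaction one member of the
pair, chosen by fair coin, acts as speaker: if the spoken token is already
in the hearer's vocabulary, *both* vocabularies collapse to that single
token; otherwise the hearer adds it. Vocabulary sizes therefore never
decrease except by collapsing to one on a success — a property the test
suite asserts on full runs.

**Context-Aware Agent (CAA).** Adds background knowledge. At trial `t` the
agent samples from its prior library with probability
`p_t = alpha * (1 - (t - 1) / T)` (linear schedule; exponential and constant
schedules are provided for sensitivity analysis) and otherwise from a
*memory trace* of social context: a decay-weighted multiset of every token
it produced or received, updated each trial by multiplying existing weights
by `recency_decay` and reinforcing both tokens of the interaction with
weight 1, scaled by `match_bonus` on a coordinated trial. `alpha` may be
shared or drawn per agent from a Beta distribution (`alpha_beta`); runs are
robust to that substitution.

The memory-trace update is *our* reference formulation — the mechanism it
stands in for is not fully specified in the literature this design follows —
so its three knobs are exposed rather than hard-coded. The defaults were
fixed once by a sensitivity sweep over `match_bonus` in {2, 5, 10} and
`recency_decay` in {0.7, 0.9, 1.0}: with weak reinforcement or no
forgetting, a purely social agent (`alpha = 0`) shows almost no difference
between network structures in final response entropy, i.e. the model fails
to reproduce the canonical finding that fully connected groups converge
faster than ring lattices. At `match_bonus = 5`, `recency_decay = 0.7` that
baseline structure effect is pronounced (spatial minus homogeneous final
normalized entropy ≈ 0.28 at `N = 20`, 20 replicates) and prior sampling at
`alpha = 0.8` attenuates it to ≈ 0.05. We fixed those values as the defaults
and did not revisit them.

Within a trial, semantics are simultaneous: all responses are computed from
pre-trial states, then all updates applied, matching platforms that collect
responses concurrently. Trial-1 responses come from the prior for both
models. Each run is seeded once from its configuration seed, making a
transcript a pure function of its `run_config()`; we use R's single global
RNG stream rather than per-agent streams, so adding an agent re-randomizes a
run — reproducibility is per configuration, which is the contract the
package promises.

## Synthetic prior libraries

The generator emulates skewed background-knowledge distributions over
candidate responses:

* **hashtag** condition: 60% of probability mass (`core_mass`) on 8
  event-anchored tokens — one per causal event of the packaged narrative —
  distributed Zipf-wise (exponent 1.2), with the remaining 40% Zipf over a
  long tail of 42 idiosyncratic tags (50 tokens total).
* **name** condition: a flatter Zipf (exponent 0.8) over 30 interchangeable
  first names with no event anchoring.

These shapes encode the qualitative contrast that matters — narrative
content concentrates prior mass on causally meaningful responses while face
names are near-interchangeable — with sizes a behavioural scientist would
call realistic for a 40-trial game. What they do **not** emulate: real
participants' heavy-tailed idiosyncratic spellings, typos, multi-word
hashtags, or priors estimated from human pre-interaction data. Passing
simulation tests therefore demonstrates properties of the mechanism, not
fidelity to any particular human dataset.

## Measurement suite

All metrics operate on tidy transcripts (one row per agent per trial) and
canonicalize tokens first (strip `#`, trim, casefold).

* `dominant_proportion()` — share of the group on the modal response; tied
  modes share the count, so no tie-break is needed (when a modal token is
  exported we report the lexicographically smallest for determinism).
* `response_entropy()` — Shannon entropy in bits (base 2) of the trial's
  response distribution; the normalized variant divides by `log2(N)` so 0 is
  consensus and 1 is all-distinct. Base 2 and the `log2(N)` constant are our
  declared convention (not inferred from any external source); downstream
  analyses can rescale. No count smoothing is applied.
* `classify_decision()` — per agent-trial strategy: `repeat_self` (own
  previous response; agreement cases where repeating self and partner
  coincide are coded `repeat_self`, since self-consistency was what got
  rewarded), `repeat_partner` (previous received response),
  `earlier_context` (own or received tokens from trials `<= t - 2`;
  unbounded memory, since the behaviour being coded — "a response remembered
  from earlier interactions" — has no stated horizon), else `new`; trial 1
  is always `new`.
* `coordination_rate_by_response()` — per-token matched fraction.
* `partner_context_entropy()` — entropy of the multiset of responses an
  agent received, a measure of social-context variation.

A hand-authored 4-agent, 6-trial fixture (`make_toy_transcript()`) with
enumerated ground-truth labels (`toy_strategy_labels()`) pins the
classifier, covering all four strategies and the repeat-self tie rule, and
all metrics are additionally tested for exact agreement with naive row-scan
recomputation on transcripts of up to 200 rows.

## Narrative alignment

For narrative content, each response is projected onto the causal events of
the focal story: cosine similarities between the response embedding and each
event-text embedding, normalized by a temperature-scaled softmax
(`a_i = exp(s_i / tau) / sum_j exp(s_j / tau)`, computed with max
subtraction). The result is a simplex proxying a narrative credence;
per-agent vectors are averaged (`mean_alignment()`, still a simplex) and
aggregated into causal-role scores (`aggregate_by_label()`: topic, cause,
plant damage, first- and second-order effect). Group contrasts use the
Welch two-sample test (`compare_groups()`).

Design choices here:

* **Pluggable embedder.** Any deterministic `function(text) -> numeric(d)`
  is accepted. The packaged `ngram_embedder()` is a hashed character
  n-gram bag — fully deterministic, no downloads — adequate for lexical
  overlap, blind to true synonymy. Analyses of real text should plug in a
  pretrained sentence encoder; every alignment invariant we assert
  (simplex preservation, argmax preservation, temperature limits,
  monotonicity in a single similarity) is embedder-independent.
* **Temperature.** Default `tau = 0.1`, exposed everywhere; conclusions the
  package itself draws rest only on tau-independent invariants (the two
  limits — uniform as `tau -> inf`, one-hot as `tau -> 0+` — are asserted
  numerically at `10^3` and `10^-6`).
* **Packaged event set.** `fukushima_events()` is a synthetic
  reconstruction: eight single-sentence summaries of the 2011 Fukushima
  disaster's causal chain written for this package, each with distinctive
  vocabulary so that verbatim-token probes resolve to their source event
  under the fixture embedder. It is not the original experimental stimulus
  text, and is labelled accordingly.

## Numerical and degenerate-input conventions

Cosine similarity is clipped to `[-1, 1]` against round-off and errors on
zero vectors; softmax uses max subtraction; simplex checks use a `1e-9`
tolerance. Prior simplices must sum to 1 within `1e-9`. Odd network sizes,
spatial sizes below 6, out-of-range trials, empty priors together with
empty vocabularies, and non-positive temperatures all raise errors naming
the violated constraint rather than propagating nonsense.

## Problem sizes used in validation

The packaged replication grid (`human_design_grid()`) mirrors the 26-run
human design — three runs per structure at `N` in {20, 50} per content plus
one per structure at `N = 100` for hashtag content, 40 trials each — and is
run in full (1,040 agents, 41,600 records, a few seconds) by the acceptance
suite. Stochastic model properties are checked with 20 replicate seeds per
condition at `N` in {10, 20}: complete-graph Name Game consensus by trial
200, the later onset of social-context exploitation as `alpha` grows, and
the attenuation of the structure effect on final entropy at `alpha = 0.8`
versus `alpha = 0`. These sizes give stable averages for qualitative
(directional) claims; per-seed variation at `N = 20` is still substantial,
which is why the properties are asserted on replicate means.

## Known limitations

* The CAA memory rule is a reference stand-in; conclusions about mechanism
  details (e.g. exact decay form) should not be read off its defaults.
* The fixture embedder measures lexical, not semantic, similarity.
* No dropout/attrition, response latency or typing noise is modelled.
* The pairing distribution over perfect matchings is positive-support but
  not uniform, and is not claimed to match any specific human platform.
* Regression-style analyses of exported tables (GLMs over convergence
  curves, categorical models of strategies) are deliberately left to
  standard statistics tooling; `metrics_table()` exports tidy input for
  them.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(network_spec(20, "spatial"), trials = 40,
                  content = "hashtag", model = "caa",
                  caa = caa_params(alpha = 0.8), seed = 3)
tr <- run_simulation(cfg)
convergence_series(tr)[c(1, 40), ]
strategy_time_series(tr)[c(1, 2, 40), ]
aggregate_by_label(
  mean_alignment(tr$response[tr$agent == 0], fukushima_events()),
  fukushima_events())
```
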