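# netcoord

Agent-based coordination games on social networks, with the measurement
suite needed to study how network structure and individual decision-making
jointly shape group consensus over narrative content.

## What it is for

In networked coordination experiments, participants earn a point whenever
they produce the same label as their randomly assigned neighbour — a name
for a face, or a hashtag for a disaster narrative. Whether the group
converges on a shared convention, and on *which* convention, depends on the
network (fully connected vs. locally connected) and on how much background
knowledge constrains viable responses. netcoord provides:

* **Networks** — homogeneously mixed (complete, diameter 1) and spatially
  embedded (ring lattice, every node with exactly 4 neighbours), with
  per-trial random perfect matchings inside neighbourhoods.
* **Agent models** — the minimal **Name Game** (vocabulary collapse on
  success: speaker's token known to the hearer ⇒ both vocabularies reduce
  to it; otherwise the hearer adds it) and the **Context-Aware Agent
  (CAA)**, which at trial *t* samples from a prior response library with
  probability *p_t = α(1 − (t − 1)/T)* and otherwise from a decay-weighted
  memory trace of its interaction history.
* **Metrics** — dominant-response proportion, (normalized) Shannon entropy
  of the response distribution, four-way decision-strategy classification
  (new / repeat self / repeat partner / earlier context, with agreement
  coded as repeat self), per-token coordination rates, and partner-context
  entropy.
* **Narrative alignment** — cosine similarity between a response embedding
  and each causal-event embedding of a focal narrative, normalized by a
  temperature-scaled softmax into a credence simplex
  *a_i = exp(s_i/τ) / Σ_j exp(s_j/τ)*; per-agent means, causal-role
  aggregation and Welch group comparisons. Embedders are pluggable; a
  deterministic n-gram-hash fixture ships with the package.
* **Tooling** — tidy CSV/JSONL transcripts, YAML/JSON run configs, a
  packaged 26-run replication grid (1,040 agents, 41,600 records), sweep
  utilities and a thin command-line wrapper (`inst/cli/netcoord.R`).

## Worked example

Simulate Context-Aware Agents (α = 0.8) coordinating hashtags on a 20-node
ring lattice for 40 trials, then measure the run:

```r
library(netcoord)

cfg <- run_config(network_spec(20, "spatial"), trials = 40,
                  content = "hashtag", model = "caa",
                  caa = caa_params(alpha = 0.8), seed = 3)
tr <- run_simulation(cfg)

convergence_series(tr)[c(1, 10, 40), ]
#>   trial dominant_proportion entropy normalized_entropy
#> 1     1                0.25    3.40              0.788
#> 2    10                0.25    2.77              0.640
#> 3    40                0.55    2.12              0.490

head(coordination_rate_by_response(tr), 3)
#>   response    rate count
#> 1 topic      0.356   253
#> 2 earthquake 0.254   126
#> 3 tag13      0.2      20

strategy_time_series(tr)[c(2, 40), ]
#>   trial new repeat_self repeat_partner earlier_context
#> 1     2 0.6        0.15           0.25             0.0
#> 2    40 0.0        0.55           0.05             0.4
```

The group starts fully spread (normalized entropy 0.79; the modal hashtag
covers 25% of agents) and only partially converges on the ring by trial 40
(0.49; 55% on the mode) — local neighbourhoods keep distinct conventions
alive. Early trials are dominated by sampling *new* responses from prior
knowledge (60% at trial 2); by the end agents exploit social context
(repeat self / earlier context). The most coordination-prone token is the
high-prior `topic` hashtag, matched on 35.6% of the 253 times it was
produced.

Narrative alignment of one agent's responses against the packaged causal
event set:

```r
round(aggregate_by_label(
  mean_alignment(tr$response[tr$agent == 0], fukushima_events()),
  fukushima_events()), 3)
#>              cause  first_order_effect        plant_damage
#>              0.259               0.176               0.030
#> second_order_effect               topic
#>              0.221               0.315
```

This agent's hashtags align mostly with the narrative topic and causes
rather than the downstream effects.

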