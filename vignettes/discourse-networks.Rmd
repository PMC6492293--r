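---
title: "Mapping discourse coalitions from coded media statements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping discourse coalitions from coded media statements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discoursenet)
```

## The model

discoursenet analyses debates that have been manually coded into
*statements*: instances of an individual actor, speaking for an
organization, agreeing or disagreeing with a *concept* (a recurring
argument) in a dated, sourced article. Four coded variables — person,
organization, concept, stance — plus provenance drive everything downstream.

**Stance reduction.** Statements are tallied into an actor x concept matrix
of agree/disagree counts. An actor's position on a concept is the *net
stance* `sign(n_agree - n_disagree)`; equal positive counts give
"contested", no statements give "absent". Contested and absent positions
contribute to neither similarity nor conflict. This net-stance convention is
a deliberate design choice: the tie-weight formula treats "jointly
supported", "jointly rejected" and "diverging" as mutually exclusive for a
concept pair, which only holds after reducing each actor to one position per
concept. Per-statement matching (as in some discourse-network software)
would double-count repeated statements and is intentionally not implemented.

**Tie weights.** For actors $a,b$ with net stances over a common concept
inventory, let $s(a,b)$ be the number of concepts they jointly support or
jointly reject and $d(a,b)$ the number where their net stances oppose. With
activities $n_a, n_b$ (statement counts), the subtract transformation with
average-activity normalization is

$$w(a,b) = \frac{s(a,b) - d(a,b)}{(n_a + n_b)/2}.$$

Congruence ($s$) and conflict ($d$) networks are also available, and the
identity `subtract = congruence - conflict` (pre-normalization) is enforced
by tests pair-by-pair. Under net-stance reduction
$|s - d| \le \min(n_a, n_b) \le (n_a+n_b)/2$, so $|w| \le 1$.

**Thresholding.** Edges with $w \ge$ `threshold` (default 0.4, the value the
motivating study chose exploratorily) are retained; negative and weak ties
are dropped entirely, but isolated actors stay in the node set — the
periphery is part of the picture.

**Coalition detection.** Girvan–Newman edge-betweenness clustering runs on
the *unweighted* thresholded graph (after thresholding, a tie is present or
absent; published embeddedness tables count ties as integers). Edge
betweenness is computed with Brandes' algorithm; one maximum-betweenness
edge is removed per iteration, betweenness is recomputed, and every
component split is recorded. The reported partition is the dendrogram level
maximizing Newman modularity $Q = \sum_i (e_{ii} - a_i^2)$, computed on the
original graph. The full dendrogram is retained for inspecting alternative
cuts.

**Embeddedness.** For an actor with $t$ ties of which $u$ stay inside its
assigned coalition, the external ratio is $(t-u)/t$: 0 means fully embedded,
values near 1 mark brokers. Isolates have no defined ratio and are excluded
from the table (they are reported as singleton coalitions).

**Concept tables.** Per time window, statement-level agree/disagree counts
per concept, ranked by total. "Contestedness" is
$\min(n_a, n_d)/\max(n_a, n_d)$ — an artifact-defined statistic chosen
because it ranks near-balanced concepts (23 vs 22) above clearly lopsided
ones (17 vs 13), matching how divided arguments are discussed narratively;
it is symmetric and scale-invariant.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `level` | organization | actor aggregation (organization or person) |
| `method` | subtract | congruence, conflict, or their difference |
| `normalization` | average_activity | divide by mean pair activity |
| `activity` | statements | activity basis (see below) |
| `threshold` | 0.4 | minimum retained edge weight (inclusive) |
| windows | three half-years from 2011-05-01 | half-open `[start, end)` slices |

The activity basis deserves a note. The normalization's stated purpose is to
remove statement-*rate* effects, but with raw statement counts this is only
partially true: duplicating every statement changes no net stance (numerator
fixed) yet doubles activities, halving every weight. Both readings of
"activity" are therefore exposed: `"statements"` (the literal reading;
default) and `"distinct_concepts"`, which makes weights exactly invariant to
duplication. The tests pin down the direction of the rate effect under the
default.

## The synthetic world

No coded statement corpus was deposited for the motivating study, so the
generator stands in for it. It emulates, at the study's scale (defaults:
1,900 statements, 94 organizations, 56 concepts, three half-year windows):

- two planted coalitions that net-support the concepts they "own" and
  net-reject the opposition's, with per-statement alignment `p_aligned`
  (default 0.9) — cross-coalition agreement is `1 - p_aligned`;
- brokers (default 4) following either side with probability ~0.5;
- heavy-tailed activity (Zipf weights over actors) so a few dominant
  speakers emerge, as in real debates;
- concentrated concept popularity (Zipf over concepts) with a within-actor
  repeat penalty, making actors breadth-dominant: real coded corpora record
  an actor's engagement with many distinct arguments more often than
  verbatim repetition;
- one designated actor whose alignment drops by `window_drift` per window,
  emulating a split party migrating between coalitions;
- uniform dates within windows and newspaper-like source labels.

**Why breadth matters — the weight algebra.** For a within-coalition pair
sharing $k$ net-stanced concepts, each shared concept is congruent with
probability $p^2 + (1-p)^2$ and divergent with probability $2p(1-p)$, so

$$E[w] = \bigl(1 - 4p(1-p)\bigr)\,\frac{k}{\bar n},$$

where $\bar n$ is the mean pair activity. At $p = 0.9$ the first factor is
0.64: even a noiseless pair cannot exceed $k/\bar n$. A world in which
actors repeat one argument (small $k$, large $\bar n$) or spread thinly over
a huge concept inventory (small shared $k$) can *never* produce weights
above the 0.4 threshold — a property of the statistic, not a bug. The
polarized benchmark (`polarized_config()`) therefore uses full breadth:
every actor makes one statement on each of 20 concepts, giving
$E[w] \approx 0.64$ with standard error $\approx 0.17$ within coalitions and
$\approx -0.64$ across. The end-to-end pipeline recovers the planted
bipartition exactly (adjusted Rand index 1.0) in 99 of 100 fixed-seed
replicates; the acceptance criterion requires at least 95.

At the study-scale defaults the thresholded network is sparse and many
low-activity actors are isolated — the generator reproduces the *periphery*
of published discourse networks, and partial recovery there is expected, not
asserted.

The drift property is checked on an unthresholded (weight > 0) network: a
drifting actor's mixed stances cancel in the subtract numerator, so at
threshold 0.4 it simply loses ties rather than gaining visible cross-ties;
the embeddedness contrast the property targets is visible in the sign
pattern of weak positive ties. Asserted stochastically over 12 fixed seeds
(drifter's external ratio exceeds its coalition's mean in the drift window).

**What a green test does not establish.** The generator emits canonical
actor names, independent concept choices and uniform sources. It does not
emulate name variants or coding disagreements, semantically correlated
concepts, article-level clustering of statements, genre or circulation
effects, or coalition sizes drifting over time. Recovery of planted labels
under these idealizations validates the pipeline's mechanics, not the
substantive interpretability of any real corpus.

## Numerical and procedural choices

- **Half-open windows** `[start, end)` make consecutive slices a partition:
  no statement lost or double-counted.
- **Determinism.** All orderings use byte-order (`radix`) sorting, so
  outputs are locale-independent; betweenness ties are broken by the
  lexicographically smallest edge; coalition ids are numbered by each
  coalition's smallest member; identical seed and config give byte-identical
  output files (asserted).
- **Actor identity** is the exact string after trimming and internal
  whitespace collapsing; no fuzzy matching (coding frames canonicalize
  names upstream). Empty person/organization/concept fields are row-level
  errors; a corpus with unaffiliated speakers should code a sentinel such as
  "unaffiliated".
- **Modularity ties** between dendrogram levels resolve to the earlier
  (coarser) level; the improvement must exceed 1e-12 to switch.
- **Zero-weight pairs** get no edge (sparse representation); thresholding
  applies after normalization; weights are stored at full precision and
  rounded to 2 decimals only in display tables.
- **Degenerate inputs**: empty corpora, single-actor matrices, edgeless
  networks and isolated actors raise classed errors (`dn_schema_error`,
  `dn_empty_error`, `dn_too_few_actors_error`, `dn_undefined_ratio_error`,
  ...) that the CLI maps to distinct exit codes (2 usage, 1 data).

## Known limitations

- Girvan–Newman recomputes betweenness after every removal ($O(nm^2)$
  overall); fine for media-debate networks (tens to a few hundred actors),
  not for graphs orders of magnitude larger.
- Whether the original analysis matched stances per statement or per net
  position, and its exact clustering configuration, are unpublished; this
  package's conventions are documented choices, and published embeddedness
  ratios are reproduced from printed tie counts rather than by re-clustering
  the undeposited corpus.
- The weighted variant of edge betweenness is not implemented; clustering
  treats retained ties as binary by design.
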