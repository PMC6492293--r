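# discoursenet

Discourse network analysis of contested policy debates, for researchers who
code media statements — who said what about which argument, agreeing or
disagreeing — and want to map the coalitions those statements reveal. The
motivating application is the UK debate over minimum unit pricing (MUP) of
alcohol, where statements coded from newspaper coverage expose two polarized
coalitions (public-health proponents vs. industry-aligned opponents) bridged
by split political parties.

## The method

The unit of analysis is a **statement**: actor *a* (a person speaking for an
organization) takes a binary stance (agree/disagree) on **concept** *c* (a
recurring argument, e.g. "MUP is illegal") in a dated, sourced article.
Statements aggregate into an actor x concept stance matrix; an actor's
position on a concept is its *net stance* sign(n_agree − n_disagree), with
ties treated as contested.

For actors *a*, *b*, let *s(a,b)* be the number of concepts both net-support
or both net-reject, and *d(a,b)* the number on which they take opposite net
stances. The **subtract transformation with average-activity normalization**
defines the tie weight

    w(a,b) = ( s(a,b) − d(a,b) ) / ( (n_a + n_b) / 2 )

where *n_a* is the number of statements actor *a* made. Positive weights mean
argumentative similarity in excess of disagreement; dividing by mean activity
keeps prolific speakers from dominating. Edges with w ≥ 0.4 (the threshold
used in the MUP study) form the analysis network.

**Discourse coalitions** are detected on the unweighted thresholded graph by
Girvan–Newman edge-betweenness clustering: repeatedly delete the edge
carrying the most shortest paths, and keep the dendrogram level maximizing
Newman modularity Q = Σᵢ (eᵢᵢ − aᵢ²). Per-actor embeddedness is summarized by
the **external ratio**, the fraction of an actor's ties leaving its own
coalition (0 = fully embedded; high values mark brokers). Per-window concept
tables report how common and how contested (min/max of agree vs. disagree
counts) each argument was in each phase of the debate.

Because the original coded corpus was never deposited, the package ships a
seeded synthetic-corpus generator with planted coalitions, brokers, activity
heterogeneity and windowed alignment drift, so the entire pipeline is
testable against known ground truth.

## Worked example

```r
library(discoursenet)

gen <- generate_corpus(sim_config(seed = 42))   # study-scale synthetic corpus
gen$corpus
#> <dn_corpus> 1900 statements, 94 organizations, 165 persons, 56 concepts
#>   dates 2011-05-01 .. 2012-11-30

sm   <- build_stance_matrix(gen$corpus, level = "organization")
net  <- build_network(sm, tie_config(method = "subtract",
                                     normalization = "average_activity",
                                     threshold = 0.4))
net
#> <dn_network> 94 actors, 138 edges (subtract, average_activity, threshold >= 0.4)

part <- girvan_newman(net)
part
#> <dn_partition> 31 coalitions, modularity 0.5579, 138 removals recorded

head(external_ratio_table(net, part), 4)
#>     actor total_ties within_ties external_ratio
#> 1 Org A03          3           3              0
#> 2 Org A04          5           5              0
#> 3 Org A05          5           5              0
#> 4 Org A06          1           1              0

head(concept_frequency(gen$corpus), 4)
#>      concept n_agree n_disagree total contestedness
#> 1 Concept 07      86         77   163     0.8953488
#> 2 Concept 25      62         44   106     0.7096774
#> 3 Concept 55      45         43    88     0.9555556
#> 4 Concept 10      31         43    74     0.7209302
```

The external ratio of 0 for the actors shown means every one of their ties
stays inside their own coalition; contestedness near 1 (e.g. Concept 55,
45 agree vs. 43 disagree) marks the arguments that most divided opinion.
At this realistic noise level many low-activity actors are isolated by the
0.4 threshold and appear as singleton coalitions — exactly the periphery
visible in published discourse networks — so label recovery is partial
(`recovery_score` ≈ 0.24). Under the strongly polarized benchmark world the
pipeline recovers the planted coalitions exactly:

```r
gen  <- generate_corpus(polarized_config(seed = 1))
net  <- build_network(build_stance_matrix(gen$corpus), tie_config())
part <- girvan_newman(net)
recovery_score(part, gen$truth)
#> [1] 1
part$modularity
#> [1] 0.4963899
```

## Command line

```sh
Rscript -e 'discoursenet::dn_cli(exit = TRUE)' simulate --seed 7 --out sim/
Rscript -e 'discoursenet::dn_cli(exit = TRUE)' report --input sim/corpus.csv \
    --threshold 0.4 --out results/ --format csv,graphml
```

Subcommands: `validate`, `build-network`, `cluster`, `external-ratio`,
`concepts`, `simulate`, `report`. Outputs are deterministically sorted;
identical seed and config give byte-identical files.

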