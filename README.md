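# hingo

Gene Ontology annotation of circular RNAs by transfer across a
heterogeneous circRNA–protein network.

## The problem

Circular RNAs (circRNAs) are covalently closed noncoding RNAs with almost
no experimentally determined functions: there is no circRNA equivalent of
UniProt-GOA to train on. What does exist is indirect evidence — circRNA
expression profiles, circRNA–protein associations, and protein–protein
interactions (PPIs) — together with rich GO annotation of the proteins.
`hingo` turns that into circRNA function predictions in three steps:

1. **Global heterogeneous network.** circRNA co-expression edges
   (Pearson correlation ≥ τ), circRNA–protein association edges, and
   STRING-style PPI edges (confidence ≥ cutoff, mutually cross-filtered
   with the associations) are integrated into one typed network.
2. **Meta-path node embeddings.** Random walks over the network generate
   tuples (a, b, z): node pairs within a window *w*, labelled by the
   meta-path relation *z* (the node/edge-type sequence traversed), plus
   negative tuples with a corrupted endpoint. A shared node-embedding
   table W_A and relation table W_Z are trained by SGD on the
   log-likelihood of

   P(z | a, b) = σ( Σᵢ W_A[a]ᵢ · W_A[b]ᵢ · f01(W_Z[z])ᵢ ),

   where f01 maps the relation vector into (0, 1). Every node — protein
   or circRNA — ends up as one d-dimensional vector in the same space.
3. **Hierarchical multi-label classifier.** On protein embeddings and
   their propagated (true-path) GO annotations, a shared fully connected
   layer feeds one sigmoid head per GO term; a max-merge layer replaces
   each term's score with the maximum over itself and its descendants, so
   scores are consistent with the GO DAG by construction. The trained
   model then scores the circRNA embeddings — the annotation transfer.

Evaluation follows the CAFA protocol: per entity, the prediction set at
threshold k is the ancestor closure of the terms scoring ≥ k (root
excluded); precision is averaged over the h(k) entities with non-empty
predictions, recall over all N entities, and

F_max = max_k 2·Prc(k)·Rec(k) / (Prc(k) + Rec(k)).

Because the real association/PPI/annotation corpora are large external
downloads, the package ships a planted-partition generator
(`makeWorld()`) that emits all five inputs with known group-structured
function, so the entire pipeline is testable end to end.

## Worked example

```r
library(hingo)

world <- makeWorld(syntheticConfig(nGroups = 2, circPerGroup = 6,
                                   protPerGroup = 10, nSamples = 8,
                                   dagDepth = 2, seed = 42))
world
#> SyntheticWorld: 12 circRNAs, 20 proteins, 2 groups, 7 ontology terms

res <- runPipeline(world,
                   pipelineParams(d = 16, walksPerNode = 5,
                                  walkLength = 20, embedEpochs = 5,
                                  hidden = 64, epochs = 60),
                   seed = 42)
res$net
#> HetNet: 32 nodes ( circRNA=12, protein=20 ), 103 edges
#>         ( circ_prot=44, co_expr=30, ppi=29 )

round(res$scores[c("CIRC0001", "CIRC0007"), ], 3)
#>          SYN:0002 SYN:0003 SYN:0004 SYN:0005 SYN:0006 SYN:0007
#> CIRC0001        1        0        1        1        0        0
#> CIRC0007        0        1        0        0        1        1

sprintf("Fmax %.3f at threshold %.2f; coverage %d/%d circRNAs",
        res$fmax, res$threshold, res$coverage, nrow(res$scores))
#> "Fmax 1.000 at threshold 0.01; coverage 12/12 circRNAs"
```

The two printed circRNAs belong to the two planted groups: each receives
score ≈ 1 exactly on its group's ontology branch (one internal term and
its two leaves) and ≈ 0 elsewhere, so the threshold sweep recovers the
planted annotations perfectly (`Fmax = 1`) and every circRNA is covered.
On harder worlds (more noise, sparser associations) the same call returns
the full precision–recall curve in `res$curve` for inspection with
`plotPRCurve()`.

A command-line front end over the same functions is in
`inst/scripts/hingo.R` (`simulate`, `build-net`, `embed`, `run`,
`evaluate`), driven either by flags or by a YAML configuration
(`readPipelineConfig()`).

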