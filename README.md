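# metadhgnn

Semi-supervised node classification on **typed, directed graphs**, built
for the question that motivated it: *which cytokines are associated with
cytokine release syndrome (CRS) in CAR-T immunotherapy?* Cytokine
networks are heterogeneous (cytokine and cell nodes) and directed (cells
release cytokines; cytokines influence cells), and curated labels exist
for only a few dozen nodes. `metadhgnn` provides a directed heterogeneous
graph attention network whose initial parameters are found by episodic
meta-learning, plus a repeated-run ranking pipeline that turns the
classifier into a discovery tool, and seeded synthetic-graph generators so
the whole stack is testable without any external data.

## The model

Direction enters through Markov-chain spectral operators. With
$\tilde A = A + I$ and $\tilde P = \tilde D^{-1}\tilde A$, the PageRank
chain $P_{pr} = (1-\alpha)\tilde P + \frac{\alpha}{n}\mathbf{1}\mathbf{1}^\top$
has a unique stationary distribution $\pi$, and

$$L = I - \tfrac12\left(\Pi^{1/2} P \,\Pi^{-1/2} + \Pi^{-1/2} P^\top \Pi^{1/2}\right),
\qquad \Pi = \mathrm{Diag}(\pi)$$

is a symmetric PSD Laplacian for the directed graph (exact and
approximate variants are both implemented). Multi-scale receptive fields
come from k-order proximity matrices that intersect *meeting* and
*diffusion* paths, symmetrically normalized into propagators.

Heterogeneity enters through meta-paths (type sequences such as
cytokine–cell–cytokine). Features are projected per node type into a
common space; node-level multi-head attention
$\alpha_{ij}^{\Phi} = \mathrm{softmax}_{j \in N_i^\Phi}\,
\mathrm{LeakyReLU}(a_\Phi^\top[h_i' \| h_j'])$ aggregates each meta-path
neighborhood (asymmetric, preserving direction), and semantic-level
attention $\beta = \mathrm{softmax}_\Phi\, \frac1{|V|}\sum_i q^\top
\tanh(W z_i^\Phi + b)$ fuses the per-meta-path embeddings. A parallel
inception branch propagates the projected features through the directed
multi-scale propagators; the two branches combine by residual addition
before a softmax classifier trained with masked cross-entropy over the
labeled nodes.

Because labels are scarce, a meta-learner (first-order MAML) pre-trains
the initial parameters on episodic k-shot support/query tasks drawn from
the labeled pool; the base learner then trains from that initialization
with Adam, L2 weight decay and early stopping on validation macro-F1.
All forward/backward passes are hand-written dense linear algebra,
verified against finite differences in the test suite, and every run is a
pure function of its seed.

## Worked example

```r
library(metadhgnn)

# a directed heterogeneous stochastic-block graph with planted classes
graph <- generate_sbm(sbm_spec(seed = 0))
print(graph)

config <- train_config(seed = 0)
net <- dhgnn(graph, sbm_default_metapaths(),
             config = dhgnn_config(dropout = config$dropout), seed = 0)
splits <- split_labeled_nodes(graph$labels, config$split, config$seed)

# episodic meta-learning finds initial parameters ...
meta <- meta_train(net, meta_config(seed = 0), pool = splits$train)
cat("meta phase: best episode", meta$best_episode, "\n")

# ... from which the base learner trains with early stopping
fit <- train_dhgnn(net, config, init_params = meta$params, splits = splits)
cat("base phase: best epoch", fit$best_epoch,
    sprintf("(validation macro-F1 %.4f)\n", fit$best_val_f1))

probs <- dhgnn_predict(fit$model)
report <- evaluate_predictions(probs[splits$test, ], graph$labels[splits$test])
print(report)
```

Output:

```
hetero_digraph: 400 nodes ( typeA=200, typeB=200 ), 12738 directed edges, 200 labeled
meta phase: best episode 47
base phase: best epoch 1 (validation macro-F1 1.0000)
macro precision/recall/F1: 1.0000 / 1.0000 / 1.0000
ROC AUC: 1.0000  PR AUC: 1.0000
```

The graph plants two classes across two node types (within-class edge
probability 0.15 versus 0.01 across; Gaussian features two units apart at
unit noise; half the labels observed). Meta-learning converges in 47
episodes; initialized from it, the base learner is already at validation
macro-F1 1.0 at its first epoch, and the held-out test nodes are
classified perfectly — the model recovers the planted direction, type and
label structure end to end.

The discovery pipeline runs from R
(`run_pipeline()`) or the shell:

```sh
inst/cli/metadhgnn pipeline --edges edges.tsv --nodes nodes.tsv \
    --seeds seeds.yaml --runs 11 --seed 0 --out results/
```

writing `ranked.tsv` (nodes sorted by median positive-class probability,
with the selected far-right set flagged), `histogram.csv`,
`manifest.json` and `run.log`. Subcommands `simulate`, `train`,
`predict` and `evaluate` cover the rest of the workflow.

## Layout

* `R/graph_io.R` — the `hetero_digraph` container, TSV/Matrix-Market I/O,
  meta-path adjacencies
* `R/spectral.R` — transition matrices, stationary distributions, digraph
  Laplacians, proximity stacks
* `R/model.R` — the network: projection, attention, semantic fusion,
  multi-scale branch, hand-written backward pass
* `R/meta.R`, `R/train.R` — episodic meta-learning; Adam training, metrics
* `R/pipeline.R` — negative selection, repeated runs, valley thresholding
* `R/synthetic.R` — SBM and toy cytokine-network generators
* `R/cli.R`, `inst/cli/metadhgnn` — command-line front end
* `vignettes/meta-dhgnn-methods.Rmd` — the methods vignette (model,
  defaults, numerical choices, limitations)
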