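Package: metadhgnn
Title: Meta-Learning Directed Heterogeneous Graph Neural Networks for
    Cytokine Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised node classification on typed, directed graphs
    with a directed heterogeneous graph neural network pre-trained by
    episodic meta-learning. Provides personalized-PageRank digraph
    Laplacians and k-order proximity stacks for multi-scale directed
    propagation, meta-path based node-level and semantic-level attention,
    MAML-style episodic pre-training, a ranking pipeline that scores nodes
    (e.g. cytokines) for association with a positive seed class such as
    cytokine release syndrome, and seeded generators for synthetic directed
    heterogeneous stochastic-block graphs used in testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
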