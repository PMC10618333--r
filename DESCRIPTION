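Package: HitGen
Title: De Novo Molecular Hit Generation with Reinforcement-Learned SMILES Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for goal-directed de novo drug design. A
    recurrent SMILES language model is pre-trained on a drug-like corpus and
    then fine-tuned with the REINFORCE policy gradient against a self-adaptive,
    two-objective reward combining predicted bioactivity (pIC50, from an
    attention-equipped recurrent regressor) and synthetic accessibility.
    Candidate hits are selected from the Pareto front of the two objectives,
    expanded by stereoisomer enumeration and ranked by the predictor, and
    interpreted through per-atom attention maps. Includes distribution-learning
    metrics (validity, uniqueness, novelty, KL-divergence score, Tanimoto
    diversity) and a fully synthetic fixture generator so the whole pipeline
    runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'HitGen-package.R'
    'vocab.R'
    'nn.R'
    'chem.R'
    'sas.R'
    'fixtures.R'
    'generator.R'
    'predictor.R'
    'reward.R'
    'rl.R'
    'hits.R'
    'evaluation.R'
LinkingTo:
    Rcpp,
    RcppArmadillo
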