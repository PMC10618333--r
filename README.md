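# HitGen

De novo molecular hit generation in R: a recurrent SMILES language model is
pre-trained on a drug-like corpus, then fine-tuned with the REINFORCE policy
gradient against a self-adaptive, two-objective reward that combines
predicted bioactivity (pIC50, from an attention-equipped recurrent
regressor) with synthetic accessibility (SAS). Candidate hits are selected
from the Pareto front of the two objectives, expanded by stereoisomer
enumeration, ranked by the predictor, and interpreted through per-atom
attention maps.

The package is aimed at computational chemists and method developers who
want a fully self-contained, desk-scale implementation of this
design-make-test loop: every component — tokenizer, generator, predictor
family, reward engine, optimizer, selection and evaluation metrics — runs
offline on one CPU, with a synthetic fixture module standing in for the
proprietary corpora such pipelines are usually trained on.

## The method

**Generator.** A token-level language model over SMILES (embedding, two
stacked LSTM layers, softmax output) trained by teacher forcing under the
length-averaged categorical cross-entropy
J(θ) = −(1/T) Σₜ log ŷₜ[yₜ], and sampled autoregressively with a softmax
temperature (τ → 0 reduces to greedy decoding).

**Predictor.** pIC50 regression from SMILES tokens or circular fingerprints
in ten configurations (A–J); the default is a bidirectional GRU stack with
additive attention pooling Cₘ = Σᵢ αᵢ hᵢ, αᵢ = softmax(tanh(e(Oₘ, hᵢ))),
whose weights αᵢ double as per-token importance scores. Labels are
standardized by median/IQR; training uses Adam, early stopping (patience
15) and repeated-holdout cross-validation.

**Conditioned generation.** REINFORCE with terminal rewards: each sampled
molecule earns f = w₁·r₁(pIC50) + w₂·r₂(SAS) in [0, 1] (invalid strings earn
0), distributed over its tokens as discounted returns
Rₜ = Σₖ γᵏ rₜ₊ₖ, and the policy descends on
−(1/B) Σ_b Σₜ γᵗ Rₜ ln π(Aₜ|Sₜ). The weights (w₁, w₂) adapt online: when one
objective is favoured while the other's five-batch variation ratio signals a
plateau, weight shifts toward the neglected objective.

**Hit selection.** Non-dominated (maximize pIC50, minimize SAS) solutions
form the front; unassigned tetrahedral stereocenters are enumerated (≤ 2ᶜ
isomers) and ranked by predicted pIC50; similarity to references is reported
as ECFP4 Tanimoto and maximum-common-substructure Tanimoto.

## Worked example

```r
library(HitGen)

corpus <- makeCorpus(2000, seed = 1)              # synthetic drug-like corpus
gen <- pretrainGenerator(corpus,
         generatorConfig(embeddingDim = 64, units = 128, batchSize = 128,
                         learningRate = 3e-3),
         epochs = 60, seed = 1)
validity(sampleSmiles(gen, 500, temperature = 0.8, seed = 2))
#> [1] 0.924

tab <- makeAffinityTable(1453, seed = 3, noiseSd = 0.3)   # smiles + pIC50
pred <- trainPredictor(tab,
          predictorConfig("I", embeddingDim = 48, units = 48, dropout = 0.1,
                          epochs = 20, patience = 20, learningRate = 3e-3),
          seed = 7, cvFolds = 0)
predictorMetrics(pred)$holdout$q2
#> [1] 0.9077791

out <- runOptimization(gen, pred,
         rlConfig(epochs = 30, batchSize = 32, learningRate = 1e-3,
                  temperature = 0.8),
         defaultRewardConfig(), seed = 300)
out$log$mean_scalar[c(1, 30)]
#> [1] 0.3949523 0.7165943

biased <- sampleSmiles(out$generator, 300, temperature = 0.8, seed = 102)
unbiased <- sampleSmiles(gen, 300, temperature = 0.8, seed = 101)
attr(propertyShiftReport(unbiased, biased, pred), "shift")
#>      pic50        sas
#>  1.0203218 -0.6370155
```

Reading the numbers: the pre-trained generator emits 92% syntactically
valid SMILES; the attention predictor explains 91% of the hold-out label
variance on the synthetic affinity table; thirty REINFORCE epochs nearly
double the mean scalarized reward; and the conditioned generator's samples
are about one pIC50 unit more potent and three-quarters of an SAS unit
easier to synthesize than the unconditioned ones — the two shifts the
optimization is supposed to produce, in the directions it is supposed to
produce them.

Hits are then triaged and inspected:

```r
rec <- canonicalizeSmiles(biased)
can <- unique(rec$smiles_canonical[rec$valid])
sol <- data.frame(smiles = can,
                  pic50 = predictPic50(pred, can)$pic50,
                  sas = syntheticAccessibility(can))
front <- paretoFront(sol)$front
iso <- rankStereoisomers(enumerateStereoisomers(front$smiles[1]), pred)
attentionAtomMap(pred, front$smiles[1])   # per-atom importance weights
```

A thin command-line wrapper over these functions is provided in
`inst/cli/hitgen.R` (subcommands `fixtures`, `filter`, `pretrain`, `sample`,
`train-predictor`, `optimize`, `evaluate`, `pareto`, `stereo`, `explain`).

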