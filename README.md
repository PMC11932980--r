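# ProfilePPI

Protein–protein interaction (PPI) prediction from evolutionary sequence
profiles, for computational biologists who want a fully testable,
database-free implementation of the profile → autoencoder → boosted-trees
pipeline together with an honest evaluation harness.

## What it computes

Each protein sequence is represented by its position-specific scoring
matrix (PSSM), an L×20 matrix *P* of log-odds scores produced by
PSI-BLAST (the package parses and writes the `-out_ascii_pssm` dialect;
running PSI-BLAST itself is out of scope — the conventional profile
settings are three iterations at e-value 0.001 against a standard
protein database). The pipeline is:

1. **Equal-size transform** — compress the variable-length profile to a
   fixed matrix, *P̂ = Pᵀ P* (20×20, symmetric PSD, row-order free).
   A zero-padding/truncation baseline keeps the N-terminal 20 rows
   instead.
2. **Denoising autoencoder** — min-max scale *P̂* to [0,1], flatten to a
   400-vector *x*, corrupt with Gaussian noise *x̃ = x + ε*, and train a
   sigmoid encoder/decoder pair *y = s(Wx̃ + b)*, *z = s(W′y + b′)* to
   minimise ‖x − z‖²; the latent activations *y* (default width 128)
   are the protein's learned features. A histogram-of-oriented-gradients
   (HOG) descriptor over the same matrices is included as the baseline
   extractor.
3. **Pair classification** — a pair (a, b) is encoded as the
   concatenation [f_a ‖ f_b] (both orders at training time, averaged at
   prediction time) and scored by gradient-boosted decision trees;
   naive Bayes, LDA, SVM, decision-tree and KNN comparison arms share
   the same interface. The ordered target statistic used by ordered
   boosting to encode categorical features without target leakage is
   implemented and tested as a standalone encoder.
4. **Evaluation** — stratified k-fold cross-validation (the autoencoder
   is retrained inside each fold on training proteins only), reporting
   ACC, precision, sensitivity, Matthews correlation and trapezoidal
   ROC/AUC per fold and as mean ± sd, plus a ranking mode for scoring
   candidate pairs with a trained model.

Because the real curated datasets (DIP yeast, HPRD human) require
external downloads and PSI-BLAST runs, the package ships a synthetic
benchmark generator with a *planted* interaction signal: proteins get
latent compatibility vectors and localization-mimicking clusters, their
amino-acid composition is biased by the latent vector with a tunable
`separation`, positives are high-affinity same-cluster pairs and
negatives span clusters (sampled degree-balanced so protein identity
carries no label information). Every stage of the pipeline is exercised
end-to-end against this generator; see the methods vignette
(`vignettes/profileppi-methods.Rmd`) for the model, the design
decisions and what the synthetic results do and do not show.

## Worked example

```r
library(ProfilePPI)

# a synthetic benchmark: 60 proteins, 120 interacting + 120 non-interacting pairs
b <- generateBenchmark(syntheticSpec(nProteins = 60, nPositive = 120,
                                     nNegative = 120, seed = 42))
p <- b$pssms[["prot0001"]]
p
#> PSSM for prot0001 — 105 positions x 20 amino acids
#>   sequence: KGRRRKAARRQRRRRRYCYKRRRRKRRRRKRRKRRRRRKRRRIRRRRRIRCRRKRRRRRR ...

round(fixedValues(scaleMatrix(equalSizeTransform(p)))[1:4, 1:4], 3)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 0.447 0.262 0.371 0.438
#> [2,] 0.262 1.000 0.407 0.167
#> [3,] 0.371 0.407 0.434 0.395
#> [4,] 0.438 0.167 0.395 0.538

cfg <- pipelineConfig(daeConfig = DAEConfig(layerSizes = c(64, 32), epochs = 30),
                      classifierParams = list(nrounds = 100))
crossValidate(b$pssms, b$pairs, k = 5, config = cfg, seed = 42)
#> 5 fold cross-validated evaluation
#>   ACC  0.9667 +/- 0.0280
#>   PE   0.9611 +/- 0.0455
#>   SN   0.9750 +/- 0.0373
#>   MCC  0.9352 +/- 0.0541
#>   AUC  0.9979 +/- 0.0019
```

The report says the pipeline recovers the planted interaction structure
almost perfectly: 96.7% of held-out pairs are classified correctly and
a random interacting pair outscores a random non-interacting one with
probability 0.998. `runAblation()` runs the full transform × extractor
× classifier grid and `formatAblationTable()` prints it as an aligned
mean ± sd table; `rankPredictions()` produces the ranked candidate
list used for case-study style screening.

A command-line front end over the same functions is installed at
`system.file("scripts", "profileppi.R", package = "ProfilePPI")` with
subcommands `simulate`, `featurize`, `train`, `evaluate`, `predict`,
a YAML config file and flag overrides:

```sh
Rscript profileppi.R simulate --out bench --n-proteins 120 --seed 7
Rscript profileppi.R evaluate --in bench --out results --folds 5 --seed 7
```

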