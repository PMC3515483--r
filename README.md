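# linkAC — link-based weighted associative classification

`linkAC` builds interpretable rule-based classifiers for binary-feature
datasets — compounds described by MACCS/MDL structural key bits,
dichotomized bioassay panels ("MCF7 inactive"), or any transaction data
with a class label — and, unlike classical associative classification, it
weights features by importance *derived from the data itself*.

The package is aimed at cheminformatics and biomedical data-mining work
where one wants both a predictive model and readable class association
rules ("if bits 81 and 83 are set, the compound is active"), without
externally supplied feature weights.

## The method

1. **Link-based feature weighting.** The dataset is viewed as a bipartite
   compound–feature graph, split into an *active* subsystem (incidence
   `L_a`) and an *inactive* one (`L_b`). Feature weights are the fixed
   point of the class-mixed authority recursion

   ```
   x ∝ β · A_a(x) + (1 − β) · A_b(x)
   ```

   where `A` is, by default, the unified HITS/PageRank operator
   `D_in^(−1/2) Lᵀ D_out^(−1) L D_in^(−1/2)` (pure `hits` and `pagerank`
   variants are also available) and the class factor `β` (default 0.9,
   any value > 0.5) promotes features connected mostly to active
   compounds.

2. **Weighted association rule mining.** With itemset weight `W(is)`
   (mean of member weights) and transaction weight `tw(t)` (sum of member
   weights), the miner uses the **adjusted weighted support**
   `AWS(is) = Σ_{t ⊇ is} tw(t) / Σ_t tw(t)`, which — unlike the plain
   weighted support `W(is)·|S|/|T|` — preserves the downward closure
   property, so Apriori-style level-wise pruning is sound.

3. **CBA-style classification.** Frequent antecedents become class
   association rules with AWS-ratio support and confidence, ranked by
   (confidence, support, generation order), pruned by database coverage,
   and applied by first match with a default class. Evaluation is seeded
   stratified k-fold cross-validation.

## Worked example

The bundled six-compound dataset over MDL key bits 81–85 traces every
quantity by hand:

```r
library(linkAC)
toy <- toyCompoundData()
itemsetStats(c("81", "83"), toy$dataset, toy$weights)
#>   itemset size itemsetWeight classicalSupport weightedSupport
#> 1   81;83    2           0.8        0.3333333       0.2666667
#>   adjustedWeightedSupport supportCount
#> 1               0.4351852            2
```

At a 0.3 support threshold, `{81,83}` is infrequent under weighted support
(0.27) while its superset `{81,83,84}` is frequent (0.36) — the downward
closure violation — whereas both have adjusted weighted support 0.44 and
are mined soundly.

Labeling C1–C3 active and C4–C6 inactive, link weighting and training:

```r
d <- toy$dataset
d@labels  <- c("pos", "pos", "pos", "neg", "neg", "neg")
d@classes <- c("neg", "pos")
w <- computeLinkWeights(buildBipartite(d, "pos"), linkWeightParam(beta = 0.9))
w
#> ItemWeights: 5 items (provenance=link, normalization=mean_one)
#>   converged=TRUE after 12 iterations
#>   81=1.192 82=1.23 83=0.8945 84=1.403 85=0.2813
```

Bit 85 occurs mostly in inactive compounds and is demoted; bit 84, present
in all three actives, is promoted. Training and predicting:

```r
clf <- trainClassifier(d, weights = w,
                       miningParam = miningParam(minsup = 0.3, minconf = 0.7))
clf
#> RuleClassifier: 1 rules, default class 'pos', training accuracy 1.000
#>   [1] {85} -> neg (supp 0.529, conf 1.000)
predict(clf, list(c("82", "83", "85"), c("81", "82", "84")))
#> [1] "neg" "pos"
```

A single rule ("bit 85 ⇒ inactive") separates this toy set perfectly; the
default class handles everything else.

Synthetic data with planted rules, file I/O for item-list and fingerprint
bitstring formats, weight-scheme comparison (`compareWeights`) and k-fold
cross-validation (`crossValidate`) are covered in the function
documentation and in `vignettes/link-weighted-associative-classification.Rmd`.

## Command line

A thin `lac` script (installed under `inst/scripts/`) wraps the same
functions:

```sh
Rscript inst/scripts/lac weights --input data.csv --scheme link \
    --positive-class active --beta 0.9 --output weights.tsv
Rscript inst/scripts/lac train --input data.csv --scheme link \
    --minsup 0.2 --minconf 0.7 --model-out model.txt
Rscript inst/scripts/lac cv --input data.csv --scheme link --k 10 \
    --seed 1 --report cv.txt
```

Flags can also be given in a flat `key=value` file via `--config`
(command-line flags win).

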