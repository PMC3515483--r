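---
title: "Link-based weighted associative classification: model and methods"
author: "linkAC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link-based weighted associative classification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkAC)
```

## The problem

Associative classification builds a predictive model from class association
rules (CARs) of the form $X \rightarrow c$, where $X$ is a set of binary
features — in cheminformatics typically MACCS/MDL structural key bits or
dichotomized bioassay readouts — and $c$ is a class label such as
active/inactive. The rules are readable, which matters when the goal is not
only prediction but discovering which substructures or assay profiles drive
an activity. Classical rule mining, however, treats every feature as equally
important. Weighted association rule mining (WARM) fixes this by giving each
item a numeric significance weight, but most weighted schemes presuppose
that weights are supplied externally. linkAC derives the weights from the
dataset itself by link analysis on its bipartite representation, and feeds
them into a weighted Apriori miner and a CBA-style classifier.

## The bipartite model and link-based weights

A transaction dataset is equivalently a bipartite graph: transactions
(compounds) on one side, items (features) on the other, an edge wherever a
compound contains a feature. Web-ranking intuition transfers directly: a
good feature ("authority") occurs in many good compounds ("hubs") and vice
versa. Because compounds carry class labels, the graph is split into an
*active* subsystem $a$ (transactions of the positive class, incidence
$L_a$) and an *inactive* subsystem $b$ ($L_b$), so that the two kinds of
connections can contribute differently to a feature's weight.

`authorityOperator()` exposes three operator variants acting on item-score
vectors $x$, each using the subsystem's incidence $L$ and its diagonal
degree scalings $D_{in}$ (item in-degrees) and $D_{out}$ (transaction
out-degrees):

* **hits** — $A(x) = L^T L\, x$, pure mutual reinforcement;
* **pagerank** — $A(x) = \alpha\, D_{in}^{-1} L^T D_{out}^{-1} L\,\tilde
  x + (1-\alpha)\,u$, the degree-normalized two-step walk with damping
  $\alpha$ and uniform teleport $u$ ($\tilde x$ is the L1-renormalized
  input; the zero vector maps to zero);
* **unified** (default) — $A(x) = D_{in}^{-1/2} L^T D_{out}^{-1} L\,
  D_{in}^{-1/2} x$, HITS-style reinforcement with PageRank-style
  edge-weight normalization.

The published renderings of this operator family differ in detail across
the literature it draws on, so the package keeps the family explicit behind
the `variant` knob instead of hard-coding one form; `unified` is the
default because combining the two normalizations is the point of the
method. Degree scalings are computed within each subsystem, so that each
class's walk is self-contained; items missing from a subsystem simply
contribute nothing there (inverse scalings use the pseudo-inverse
convention $1/0 := 0$).

`computeLinkWeights()` then iterates the class-mixed recursion

$$x^{(k+1)} \;\propto\; \beta\, A_a\!\left(x^{(k)}\right) +
  (1-\beta)\, A_b\!\left(x^{(k)}\right),$$

L1-renormalizing each step from a uniform start, until the L1 change drops
below `tol`. For the unified variant, whose operator carries the
square-root in-degree scaling, $\beta$ and $1-\beta$ enter as their square
roots. The *class factor* $\beta \in [0,1]$ (default **0.9**) controls how
much the active subsystem dominates: any $\beta > 0.5$ promotes features
whose connections are mostly active compounds, and the property suite
checks this monotonicity on matched skewed-item pairs. $\beta = 1$ reduces
to authority ranking of the active subsystem alone, which for the `hits`
variant is the classic principal-eigenvector solution (the test suite
verifies this against a dense eigendecomposition).

Converged authority scores become item weights. They are rescaled to
**mean weight 1** by default so that weighted supports live on the same
scale as classical supports (an L1-normalized vector is available with
`normalizeMeanToOne = FALSE`). Items never observed in the data have no
link evidence and get weight 0. Hub scores of both subsystems are kept as
diagnostics in the weights' metadata but are not used downstream.
Convergence is measured in L1 with default tolerance $10^{-8}$ and at most
1000 iterations; the whole computation is deterministic.

## Weighted supports and the downward closure property

Given item weights $w_i$, the package uses, for an itemset $is$:

* itemset weight $W(is)$ = arithmetic mean of the member weights;
* **weighted support** $WS(is) = W(is) \cdot |S|/|T|$, with $S$ the
  supporting transactions and $T$ all transactions;
* transaction weight $tw(t)$ = sum of the weights of the items in $t$;
* **adjusted weighted support**
  $AWS(is) = \sum_{t \supseteq is} tw(t) \,/\, \sum_{t \in T} tw(t)$.

The mean for $W(is)$ and the sum for $tw(t)$ are the unique simple
aggregates that reproduce the package's bundled worked example
(`toyCompoundData()`) cell by cell. $WS$ violates the downward closure
property (DCP): a superset can be frequent while its subset is not, because
adding a heavy item raises the mean weight. On the worked example at
$\theta = 0.3$, $\{81,83\}$ has $WS = 0.27$ (infrequent) while its superset
$\{81,83,84\}$ has $WS \approx 0.36$ (frequent). $AWS$ repairs this: every
transaction supporting $Y$ supports each $X \subseteq Y$, so
$AWS(X) \ge AWS(Y)$ always, and level-wise Apriori pruning is sound.
Accordingly `mineFrequentItemsets()` refuses `supportMode = "weighted"`
and points to `enumerateItemsets()`, the exhaustive companion for small
universes.

```{r worked-example}
toy <- toyCompoundData()
weightedSupport(c("81", "83"), toy$dataset, toy$weights)
adjustedWeightedSupport(c("81", "83", "84"), toy$dataset, toy$weights)
```

Two cells of the source table for this example are internally inconsistent
with its own definitions (the $WS$ of $\{83,84\}$, which the formulas put
at 0.40, and the $AWS$ of $\{83\}$, which they put at 0.565); the tests
assert the values the definitions produce and document the exclusion.

Mining details: candidates of size $k$ are joined from frequent
$(k-1)$-itemsets sharing a $(k-2)$-prefix under the dataset's fixed total
item order, pruned unless all $(k-1)$-subsets are frequent, and accepted at
support $\ge$ `minsup`. An itemset must also occur in at least one
transaction, so a zero threshold enumerates exactly the observed itemsets.
Defaults follow the method's reference settings: antecedents of at most
**4** items and a cumulative candidate budget of **200,000**; exceeding
the budget truncates deeper levels with a message rather than aborting.
There is no randomness anywhere in mining.

## From rules to a classifier

Class labels are modeled as virtual items: each transaction carries exactly
one, with weight equal to the mean item weight so transaction weights are
shifted uniformly and no class is favored by the weighting itself (the
source method does not specify class-item weighting; this choice keeps one
mining engine for antecedents and rules). For each frequent antecedent $X$
and class $c$,

$$supp(X \to c) = \frac{\sum_{t \supseteq X,\, class(t)=c} tw(t)}{\sum_t tw(t)},
\qquad
conf(X \to c) = \frac{\sum_{t \supseteq X,\, class(t)=c} tw(t)}{\sum_{t \supseteq X} tw(t)},$$

which collapse to ordinary CBA support and confidence under unit weights.
Rules meeting `minsup` and `minconf` are ranked by confidence, then
support, then generation order (earlier-generated, hence shorter-or-equal,
antecedents win ties), and pruned by database coverage: a rule is kept iff
it correctly classifies at least one still-uncovered training transaction,
the transactions it matches are then covered, and the kept list is
truncated at the earliest prefix minimizing total training error, with the
majority class of the uncovered remainder as default. This is the
canonical coverage ("M1") form; pessimistic-error pruning is deliberately
omitted because the method this package implements does not use it.
Prediction is first-match with fallback to the default class. Which CBA
variant (M1 vs M2) the source used is unstated; M1 is implemented as the
canonical published form.

## Evaluation

`crossValidate()` runs seeded k-fold cross-validation (default $k = 10$),
stratified by class by default — stratification is this package's choice to
stabilize folds when one class is rare; plain random folds are available
with `stratified = FALSE`. Item weights are recomputed inside each training
split, so held-out transactions never influence the model; whether the
source method refit weights per fold is unstated, and a deliberate
full-dataset leakage mode is available behind `weightsOnFull = TRUE` for
comparison. Accuracy is the share of correctly classified held-out
transactions. `compareWeights()` reports Pearson and Spearman correlations
(average ranks on ties) plus a per-item rank table for contrasting
weighting schemes such as link-based versus raw bit frequency.

## The synthetic generator

`generateTransactions()` emulates the statistical skeleton of a
fingerprint-style dataset: a class drawn with probability `classBalance`,
independent background items, and planted rules that insert an antecedent
into matching-class transactions with a given penetrance.
`generateClassSkewedFeature()` adds a marker item with different inclusion
rates in the two classes (optionally a mirrored partner with swapped
rates), the construction used to verify that $\beta > 0.5$ promotes
active-skewed features. The stream order of random draws is documented per
transaction (class, background items in item order, rules in list order),
so a seed pins the dataset bit for bit, and the generator restores the
caller's RNG state.

What the generator deliberately does not emulate: correlation structure
among fingerprint bits beyond planted co-occurrence, realistic substructure
frequencies, or assay noise models. Passing tests therefore demonstrate
correctness of the algorithms under controlled conditions — planted signal
is recovered, chance-level data scores at chance — not predictive
performance on real chemical collections, which depends on data properties
the generator does not model.

## Numerical choices and limitations

* Determinism: mining, ranking and classification involve no randomness;
  ties are broken by the fixed item order, generation order, and (for
  majority defaults) the globally more frequent class, then class order.
* Degenerate inputs: empty transactions carry zero weight and are dropped
  from the link graph with a warning; all-zero weight vectors make AWS
  undefined and raise an error; a power iteration that exhausts `maxIter`
  returns its last iterate with a warning and a `converged = FALSE` flag.
* Validation scale: exhaustive cross-checks run on universes of up to 12
  items and graphs up to $8 \times 8$, where brute-force enumeration and
  dense eigendecompositions are exact and fast; statistical checks use
  seeded synthetic datasets of 45–5000 transactions. These sizes were
  chosen as the smallest at which every code path is exercised and
  binomial tolerances are tight.
* The level-wise miner materializes a dense logical incidence matrix; this
  is intended for desk-scale to mid-size datasets (thousands of
  transactions, hundreds of items such as 166-bit MACCS keys), not for
  sparse universes of millions of items.
* Multi-class data is supported structurally, but the bipartite split is
  binary (positive class versus the rest), matching the active/inactive
  framing of the method.
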