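# irtci — Item Response Theory for Categorical Imputation

`irtci` imputes missing cells in case × feature **categorical** tables by
fitting a single unidimensional item response theory (IRT) model to all
features at once, scoring each case's latent trait θ, and filling every
missing cell with its most probable category. It is aimed at biostatistical
and epidemiological tables that mix binary, ordinal, nominal and (after
quantile discretization) continuous features, where popular imputers either
treat categories as numbers or ignore most of the observed information.

## The model

Each feature *i* is an "item" linked to a case's latent trait θ by one of
three logistic-metric families (no 1.7 scaling constant anywhere):

- **binary — two-parameter logistic (2-PL):**
  P(U=1 | θ) = exp(aᵢ(θ−bᵢ)) / (1 + exp(aᵢ(θ−bᵢ))),
  slope aᵢ > 0, difficulty bᵢ.
- **ordinal — graded response model (GRM):** boundary curves
  P\*ᵢₖ(θ) are 2-PLs sharing one slope with strictly increasing thresholds
  bᵢ₁ < … < bᵢ,ₘ₋₁; category probabilities are adjacent differences
  P(U=k) = P\*ᵢₖ − P\*ᵢ,ₖ₊₁ (with P\*ᵢ₀ = 1, P\*ᵢₘ = 0).
- **nominal — nominal response model (NRM):** divide-by-total
  P(U=k | θ) = exp(aᵢₖθ + cᵢₖ) / Σₓ exp(aᵢₓθ + cᵢₓ), identified by pinning
  the lowest category, aᵢ₁ = cᵢ₁ = 0.

Item parameters are estimated by **marginal maximum likelihood** (Bock–Aitkin
EM over a 41-node quadrature grid on [−6, 6] with a standard-normal prior);
missing cells simply drop out of each case's likelihood product. Each case is
then scored by **EAP** (posterior mean of θ), and a missing cell of item *i*
is imputed with argmax of the item's category probabilities at that θ — for a
binary item this is exactly the "over 50% ⇒ 1" rule; ties go to the lowest
category.

Supporting machinery: MCAR amputation (random cell deletion) and MAR
amputation (sort on a conditional column, delete from the top), Little's
chi-square MCAR test with EM-estimated moments, quartile discretization of
continuous features, a response-matrix simulator with known parameters, and
imputed-cell F1 scoring (macro / micro / weighted).

## Worked example

```r
library(irtci)

# simulate 1000 cases on 6 five-category ordinal items with known parameters
set.seed(42)
items <- lapply(1:6, function(i) params_grm(runif(1, 1.2, 2.2),
                                            sort(rnorm(4, 0, 1.2))))
sim <- simulate_responses(items, n_cases = 1000, seed = 7)

# knock out 10% of item 1 completely at random, then impute
full <- sim$responses$values
miss <- sample(1000, 100)
amp  <- full; amp[miss, 1] <- NA
res  <- irtci_impute(response_matrix(amp, sim$responses$item_specs))
res
#> irtci imputation: 100 cells imputed across 1 items

# score against the held-out truth, next to the modal-category baseline
imputed_cell_f1(full[miss, 1], res$completed[miss, 1])$macro_f1
#> [1] 0.3833333
imputed_cell_f1(full[miss, 1], rep(modal_category(amp[, 1]), 100))$macro_f1
#> [1] 0.1142857
```

The IRT imputer recovers held-out categories far better than always guessing
the most frequent one (macro-F1 0.38 vs 0.11 here; chance for 5 balanced
categories is ~0.2). `res$cells` records, per imputed cell, the case, item,
chosen category and the EAP score used; `res$probs` keeps each cell's full
probability vector.

## Command line

An umbrella CLI ships as `inst/cli/irtci` (subcommands `simulate`, `ampute`,
`mcar-test`, `impute`, `score`), e.g.

```sh
inst/cli/irtci impute --input X.csv --schema schema.json --sentinel -1 --out Y.csv
inst/cli/irtci mcar-test --input X.csv
```

where `schema.json` declares each column's type (`binary`/`ordinal`/
`nominal`/`continuous`), role (`feature`/`target`/`outcome`/…) and category
labels in code order. Cells equal to the sentinel (default `-1`) or empty are
treated as missing.

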