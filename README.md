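# claimnet

Most published biomedical claims are never re-tested: exact replication is
expensive, and journals reward novelty. `claimnet` implements a scalable
alternative for **drug–gene interaction (DGI) claims** — triples of a drug, a
gene, and a direction of expression change. It aligns literature-curated
claims with unfiltered high-throughput perturbational expression signatures
and asks, claim by claim, whether the experiment points the same way the
literature does, and *what kind of scientific community* produced the claims
that replicate.

The package is aimed at meta-researchers and computational biologists who
want to run this evaluation on their own claim/signature corpora — or study
its statistical behavior on synthetic corpora with known ground truth, which
the package generates itself.

## What it computes

For each claim with per-condition moderated z-scores `z_1 … z_k`:

* **Combined effect** `Z = Σ z_i / √k` (Stouffer), with a percentile
  bootstrap CI; the claim is *generalized* when the CI excludes 0, and its
  condition-robustness is `CV = σ_z / |μ_z|`.
* **Literature support**: with `γ` supporting findings among `n`, the
  support probability `θ` has a Uniform prior and Binomial likelihood;
  an MCMC sampler (10,000 iterations, 2,500 burn-in, MAP-initialized)
  approximates the posterior, summarized by `L_supt`, the lower bound of the
  one-sided 95% credible interval, and a five-class label (Very High … Not
  Supported) from equal-tailed credible intervals against `μ = 0.5`.
* **Replication**: `R = 1` when `sign(Z)` matches the claimed direction.
  Observed rate `RR_obs` (bootstrap CI) is contrasted with a permutation
  baseline `RR_rand` (re-matching directions to shuffled `Z`), giving the
  relative replication increase `RRI = 100 (RR_obs − RR_rand) / RR_rand`.
* **Community structure**: per multi-paper claim, a multilayer network whose
  layers weight author/method/reference overlap by the Jaccard coefficient;
  independence scores `S_ind, M_ind, K_ind = (E_max − W) / E_max`; and
  centralization `C` = Gini coefficient of the papers-per-author
  distribution (with Lorenz curves).
* **Prediction models**: univariate, multivariate and interaction logistic
  regressions of `R` on the min–max rescaled predictors, with Wald
  odds-ratio CIs and Benjamini–Hochberg correction.

## Worked example

Simulate a 1000-claim corpus under the default study-like conditions (89%
single-finding claims, publication bias filing away contradicting findings,
repeat-collaboration authorship) and run the full pipeline:

```r
library(claimnet)
res <- run_pipeline(config = generator_config(n_claims = 1000), seed = 1,
                    B = 2000, P = 2000)
res$replication[, c("subset", "n", "rr_obs", "rr_rand", "rri", "rri_lo", "rri_hi")]
#>           subset    n rr_obs rr_rand   rri rri_lo rri_hi
#>              all 1000  0.731   0.499 46.48  36.24   58.0
#>      generalized  578  0.882   0.501 76.25  61.36   91.7
#>  non_generalized  422  0.524   0.501  4.61  -8.66   19.2
#>         VeryHigh   10  0.900   0.617 45.80   0.00  100.0
#>             High   18  0.778   0.530 46.81  -7.14  150.0
#>         Moderate   69  0.725   0.500 44.97  11.11  100.0
#>              Low  903  0.729   0.500 45.78  34.89   57.1
```

Claims carrying true effects replicate far above the permutation baseline
(`rri` ≈ 46% overall here), and the excess concentrates in the generalized
subset — the non-generalized claims sit near the baseline (`rri` CI spans
0), exactly the signature the method is designed to expose. Per-claim
detail:

```r
head(res$evaluation[, c("claim_id", "Z", "generalized", "L_supt", "support_class", "R")], 4)
#>  claim_id      Z generalized L_supt support_class R
#>    C00001  22.43        TRUE  0.224           Low 1
#>    C00002 -23.96        TRUE  0.224           Low 1
#>    C00003  20.85        TRUE  0.224           Low 1
#>    C00004   9.88        TRUE  0.224           Low 1
```

A claim supported unanimously by 16 findings:

```r
p <- posterior_support(16, 16, seed = 1)
round(p$L_supt, 2)   # 0.83  (MCMC estimate of the exact 0.8384)
classify_support(p)  # "VeryHigh"
```

Corpora are read from plain TSV/CSV tables with `read_corpus()` (see
`?read_corpus` for the three schemas) and evaluated with the same
`run_pipeline()` call via its `corpus` argument.

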