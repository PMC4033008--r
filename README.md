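# drugwelfare

Estimates the annual national welfare impact of a basket of innovative
drugs from published cost-effectiveness evidence. It is written for
health-economics and HTA analysts who want to turn a table of incremental
cost-effectiveness ratios (ICERs) — reported in assorted currencies, price
years and outcome units — into a single, threshold-dependent figure for
what adopting those drugs is worth to a national economy per year, with a
defensible sensitivity analysis around it.

## The model

For each drug, the welfare impact is the annualized, population-scaled net
monetary benefit at the willingness-to-pay threshold λ per QALY:

```
W = (λ − ICER) × ΔE / T × n
```

where `ICER` is the ratio harmonized to the target country-year, `ΔE` the
incremental effect (QALYs, life years, or monosymptomatic life years) per
patient over the source model's horizon, `T` that horizon in years, and
`n` the number of users. Dominant drugs (negative ICER: cheaper *and*
better) need no special case — signed arithmetic turns `λ − ICER` into
`λ + |ICER|`. The basket total is affine in λ with slope
`Σ (ΔE/T × n)`, the aggregate QALYs gained per year.

Around this core the package provides:

* **Harmonization** (`adjust_ratio()`, `adjust_basket()`): GDP-deflator
  restatement within the source country, then purchasing-power-parity
  conversion into the target currency — in that order.
* **User-count recovery** (`populate_users()`): explicit counts, indirect
  estimation from package-sales volumes, or exact inversion of the welfare
  formula from a published per-drug welfare value (user counts behind such
  analyses are typically confidential).
* **Univariate sensitivity analysis** (`run_sensitivity()`): one-way
  perturbation of ratio, effect, horizon (±20%), users (±50%) and
  threshold (50,000 / 150,000), ranked tornado-style.
* **Synthetic baskets** (`generate_basket()`): reproducible baskets with
  known ground-truth users spanning dominance through above-threshold
  pricing, for end-to-end validation.
* **A bundled reference basket** (`table2_fixture()`): the published
  31-drug Swiss 2010 basket, stored exactly as printed, with its per-drug
  welfare column kept separate (it is an output of the formula, not an
  input).

## Worked example

```r
library(drugwelfare)

fx <- table2_fixture()                                  # 31 drugs, CHF 2010
basket <- populate_users(fx$basket, welfare = fx$welfare)  # invert user counts
total_welfare(basket, threshold = 100000)
#> <welfare_total> 31 drugs at threshold 100,000: total 781.39 million/year (slope 1.041e+04 QALYs/year)
```

Introducing these 31 drugs is worth CHF 781.39 million per year to the
economy at a threshold of CHF 100,000/QALY — about 13% of the CHF 6.05
billion national drug expenditure that year — and the basket delivers
about 10,400 QALYs per additional year across all users (the slope, which
is also the sensitivity of the total to the threshold).

```r
welfare_at_thresholds(basket, c(50000, 150000))
#> # A tibble: 2 × 2
#>   threshold       total
#>       <dbl>       <dbl>
#> 1     50000  260765875.
#> 2    150000 1302011037.

run_sensitivity(basket)$tornado
#> # A tibble: 5 × 5
#>   parameter       low_total  high_total       range  rank
#>   <chr>               <dbl>       <dbl>       <dbl> <int>
#> 1 threshold      260765875. 1302011037. 1041245162.     1
#> 2 n_users        390694228  1172082684   781388456      2
#> 3 time_horizon   976735570   651157047.  325578523.     3
#> 4 delta_effect   625110765.  937666147.  312555382.     4
#> 5 adjusted_ratio 833359797.  729417115.  103942682.     5
```

Every scenario stays a net gain: even at a conservative CHF 50,000/QALY
the basket is worth CHF 260.77 million per year, rising to CHF 1.30
billion at 150,000. The threshold is the most influential parameter,
followed by the number of users; the ICER itself moves the total least.
Per-drug results (`welfare_impact()`) show exactly one drug with negative
welfare at the base threshold — the only basket member priced above
100,000 per QALY.

See `vignette("welfare-impact-methods")` for the model's assumptions, the
harmonization procedure, and what the synthetic generator does and does
not emulate.

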