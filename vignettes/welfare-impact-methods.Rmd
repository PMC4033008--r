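---
title: "Estimating the annual welfare impact of a drug basket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the annual welfare impact of a drug basket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugwelfare)
```

## The model

When a health system adopts an innovative drug in place of standard
treatment, the monetary value of the switch for one treated patient is the
*net monetary benefit* at the system's willingness-to-pay threshold
$\lambda$ per quality-adjusted life year (QALY):
$(\lambda - \mathrm{ICER}) \times \Delta E$, where the incremental
cost-effectiveness ratio (ICER) is the extra cost per extra outcome unit of
the new drug versus its comparator, and $\Delta E$ is the incremental
effect per patient over the model horizon of the source cost-effectiveness
study. drugwelfare scales this to an annual, national figure:

$$W \;=\; (\lambda - \mathrm{ICER}) \times \frac{\Delta E}{T} \times n$$

with $T$ the model time horizon in years (so $\Delta E / T$ is the effect
gained per user-year) and $n$ the number of users in the index year.
Summing $W$ over a basket of drugs gives the annual welfare impact of
innovation on the national economy.

Three modelling consequences fall straight out of the algebra and are
exploited (and tested) throughout the package:

* **Dominance needs no branch.** A drug that is cheaper *and* better than
  its comparator has a negative ICER; $\lambda - \mathrm{ICER}$ then
  becomes $\lambda + |\mathrm{ICER}|$ by plain signed arithmetic, which is
  exactly the intended economics (a bigger per-user gain). The
  implementation has a single code path and a regression test asserts the
  two phrasings agree.
* **The total is affine in the threshold.** With slope
  $\Sigma k = \Sigma\, (\Delta E / T)\, n$ (aggregate QALYs per year),
  $W(\lambda) = \lambda\,\Sigma k - \Sigma\, c\,k$. `total_welfare()`
  reports the slope; `welfare_at_thresholds()` uses the closed form, so
  identities such as $W(\lambda_2)-W(\lambda_1)=(\lambda_2-\lambda_1)\Sigma k$
  hold exactly.
* **Effect and users are interchangeable.** $\Delta E$ and $n$ enter as a
  product, so scaling either by the same factor gives the same total —
  which is why the default sensitivity plan varies users by ±50% rather
  than duplicating the ±20% effect scenario.

## Harmonizing published ratios

Published ICERs arrive in the currency and price year of their source
study. They are transferred to the target country-year (CHF 2010 for the
bundled basket) in two fixed steps — `adjust_ratio()` is pinned to this
order:

1. **Deflate within the source country**: multiply by the ratio of the
   source country's GDP-deflator index at the target year to the index at
   the price year (`deflate()`). The index base year cancels; indices are
   annual and never interpolated — a missing year is a hard completeness
   error naming the `(currency, year)` cell.
2. **Convert with purchasing power parity**: multiply by the target-year
   PPP rate, target-currency units per source-currency unit
   (`ppp_convert()`). PPP, not the market exchange rate, is the standard
   instrument for transferring health-care costs.

The order matters whenever two currency areas inflated at different rates;
deflate-then-convert keeps the cross-currency step at target-year price
levels. The composition is linear in the amount and preserves sign, so a
dominant ratio stays dominant.

The euro area is treated as a single currency area even where source
studies carry country tags (Sweden, Finland, Germany); the tag is kept as
provenance only, since no country-level deflator detail is available at
the ratio level.

Real OECD deflator and PPP series are deliberately not bundled: they are
version-dependent, and the reference basket already prints both the
original and the harmonized ratio for every row, whose quotient
(`implied_adjustment_factor()`) is the ground truth any table must
reproduce. Those implied factors are in fact mutually inconsistent across
rows sharing a currency and price year, so no single table can reproduce
the whole column; the package therefore ships a clearly labelled
*synthetic* table (`synthetic_adjustment_fixture()`) calibrated to the
bosentan row, plus the per-row implied factors as a calibration artifact.

## Tunable parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `threshold` | currency per QALY | 100,000 | the threshold publicly debated for the target system; US practice spans 50,000–100,000 USD, NICE 20,000–30,000 GBP |
| `time_horizon_years` | years | per record | horizon of the source model; fractions allowed (an acute migraine model spans a day) |
| `treatment_days_per_year` | days | 365 | chronic-therapy exposure; episodic therapies must state their own |
| sensitivity factors | — | ±20% (ratio, effect, horizon), ±50% (users), thresholds 50,000/150,000 | the standard one-way plan for this analysis |

Effects measured in life years (LY) or monosymptomatic life years (MLY)
are valued at the QALY threshold — the convention of the welfare framework
— but every such result carries `outcome_unit_caveat = TRUE`, because an
LY is worth at most one QALY and the figure may overstate the gain.

## Recovering confidential user counts

National user counts are usually confidential. Three routes, in fixed
precedence inside `populate_users()`:

1. an **explicit count** on the record (manufacturer or insurer data);
2. **package sales**: `users_from_packages()` divides doses sold per year
   by doses one patient consumes per year — invariant to re-expressing the
   dose, and exact for the stated dosage;
3. **inversion**: welfare is linear in $n$, so a published per-drug
   welfare value determines the count exactly,
   $n = W / ((\lambda - \mathrm{ICER})\,\Delta E / T)$.

Inverted counts are *not* rounded to whole persons: printed welfare
figures generally imply fractional counts, and rounding would break the
reproduction of threshold and sensitivity totals downstream. Inversion is
undefined when the per-user net benefit is zero (ratio exactly at the
threshold) — that is an error, not a zero; a negative count evaluates but
warns, since it signals inconsistent inputs. Sub-year horizons leave open
whether $n$ counts persons or treatment episodes; the engine treats it as
an opaque multiplier.

## Sensitivity analysis

`run_sensitivity()` perturbs one parameter class at a time across the
whole basket — harmonized ratio, incremental effect and horizon to 80% and
120%, users to 50% and 150%, and the threshold evaluated at 50,000 and
150,000 — recomputes the total per scenario, and ranks the five classes by
the induced range (rank 1 = widest tornado bar; ties broken
alphabetically). Bar endpoints are scenario totals, not deltas, so the
global minimum and maximum are read off directly; deltas are also written
by `write_tornado()`. Ratio perturbation scales the *signed* value (80% of
a dominant ratio is less dominant); an absolute-shift alternative is
available via the `shift` argument. A per-drug tornado is out of scope for
the default plan, which ranks parameter classes.

```{r sensitivity}
fx <- table2_fixture()
basket <- populate_users(fx$basket, welfare = fx$welfare)
run_sensitivity(basket)$tornado
```

## The synthetic-data generator

`generate_basket()` exists so every stage is testable against known ground
truth without any external data. Its default ranges span the regimes of
the reference basket rather than fitting its distribution: harmonized
ratios uniform on $[-250{,}000,\ 150{,}000]$ (strong dominance through
well above threshold), incremental effects log-uniform on
$[10^{-4},\ 7]$ QALYs (four orders of magnitude), horizons log-uniform on
$[0.002,\ 75]$ years, user counts uniform on $[10,\ 500{,}000]$. For
baskets of at least four drugs whose ratio range reaches the corresponding
regime, at least one dominant and one above-threshold drug are guaranteed.
Original-basis ratios are derived by dividing out the combined factor of a
generated adjustment table (mild 0–5%/year inflation, PPP rates chosen so
combined factors stay within the 0.8–2.2 band the reference basket's
implied factors occupy), so harmonization round-trips exactly. Generation
is reproducible: same spec and seed, same basket.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: correlation between a drug's price and its
effect size, indication structure (multi-indication drugs dilute the
per-indication effect), reporting heterogeneity across source studies
(perspectives, discount rates, comparator choice), and integer-valued user
populations.

## Numerical choices

* Money is carried in full double precision end to end; rounding is a
  reporting concern (whole units per drug, two decimals in CSV output).
* The affine-identity checks are asserted at $10^{-12}$ *relative* to the
  totals involved — at the $10^9$ scale an absolute binary zero is not
  attainable.
* Missing table entries, zero per-user benefit, and unresolved user counts
  are hard, classed errors naming the offending cell or drug; nothing is
  imputed.
* An absent user count is `NA`, never 0 — zero users is a valid,
  degenerate count that yields zero welfare.
* Test problem sizes: 100 synthetic baskets for the inversion round trip,
  1,000 random ratios for the harmonization oracle; the basket analysis
  itself is 31 rows of closed-form arithmetic and runs in well under a
  second.

## Known limitations

The method inherits every limitation of transferring foreign ICERs:
deflator-plus-PPP adjustment cannot correct for different comparators,
utility sets, or health-system structures; mixed payer/societal
perspectives are carried as provenance only; valuing LY and MLY effects at
the QALY threshold overstates their welfare contribution; and user counts
obtained by inversion reproduce, rather than independently validate, the
published welfare column. The bundled fixture preserves its source's own
blemishes (a 4-unit rounding discrepancy in one row, mutually inconsistent
implied adjustment factors) because a fixture must be auditable against
what was printed.
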