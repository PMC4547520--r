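# mininart

Nonparametric (Mokken) scale analysis for dichotomous test data, built
around the National Adult Reading Test (NART) — the 50 irregular English
words ("ache" … "campanile") whose pronunciation is widely used to
estimate premorbid cognitive ability — and its 23-item invariantly
ordered subset, the mini-NART.

The package is for psychometricians and clinical researchers who want to
ask, of any 0/1 persons × items matrix: do these items form a
unidimensional monotone scale, is the item difficulty hierarchy the same
at every ability level, how reliable is the total score, and how well
does it predict an external criterion?

## What it computes

For items `i, j` ordered by sample difficulty, a *Guttman error* is the
pattern "harder passed, easier failed". With observed errors `F` and the
count `E` expected under independence, the Loevinger scalability
coefficients are

    Hij = 1 - Fij/Eij        (item pair)
    Hi  = 1 - ΣFij / ΣEij    (item; discrimination)
    H   = 1 - ΣΣF / ΣΣE      (scale; < 0.3 unscalable, ≥ 0.5 strong)

On top of these:

- `aisp()` — automated item selection: greedy bottom-up partitioning of
  items into Mokken scales plus an unscalable remainder.
- `check_monotonicity()` — manifest monotonicity of each item against
  rest-score groups (violations > `minvi` = 0.03, one-sided z screen).
- `check_iio()` / `backward_select_iio()` — invariant item ordering:
  pairwise reversal detection and iterative removal of the worst
  violator; `ht_coefficient()` scores ordering accuracy on the transposed
  matrix.
- `ms_reliability()` — Molenaar–Sijtsma total-score reliability.
- `mini_nart_predictor()`, `nart_predictor()`, `predict_iq()`,
  `conversion_table()` — the published regressions estimating age-11 IQ
  from mini-NART and NART scores, with score→IQ tables.
- `order_by_difficulty()`, `run_session()` — adaptive administration of
  an invariantly ordered scale from either end of the hierarchy.
- `synthetic_spec()` / `generate()` and presets, including
  `nart_like_preset()` — a 2PL-form response generator with known ground
  truth, used to validate every stage (the raw cohort data behind the
  published analysis are not publicly deposited).
- `load_nart_fixture()` — the published per-item statistics: percent
  correct for all 50 items and the mini-NART's item scalabilities.

## Worked example

```r
library(mininart)

spec <- synthetic_spec(1000, a = rep(2.2, 8),
                       b = seq(-1.5, 1.5, length.out = 8), seed = 42)
m <- generate(spec)$responses

scale_scalability(m)
#> Scale H = 0.635 (strong), 1000 persons
#>   item    Hi
#> 1   I1 0.736
#> ...

backward_select_iio(m)
#> IIO backward selection (minvi = 0.03): 0 removed, 8 retained, HT = 0.692

ms_reliability(m)
#> Molenaar-Sijtsma reliability: MS = 0.824 (reliable, MS > 0.7)
```

Eight equally discriminating items form a strong scale (H = 0.635): the
summed score orders respondents on the latent trait. No item is removed
by the IIO step and the ordering accuracy HT = 0.692 approaches the
"strong" band, as expected for non-crossing response functions; MS = 0.824
says the total score is reliable. The published regression then converts
an observed score to an estimated premorbid IQ:

```r
predict_iq(mini_nart_predictor(), 20)
#> mini-NART score 20 -> predicted IQ 111.84, 95% CI [107.54, 116.14]

fx <- load_nart_fixture()
items <- order_by_difficulty(fx$mini_items)   # "AISLE" ... "LABILE"
run_session(items, guttman_responder(18, items), "descending")
#> Adaptive session (descending, stop after 2): 7 of 23 items administered, imputed score 18
```

The adaptive session starts at the hardest word, stops after two
consecutive successes, imputes everything easier as passed, and recovers
the respondent's full-scale score of 18 from 7 administrations.

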