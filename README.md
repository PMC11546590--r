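# raschlink

Concurrent Rasch calibration of multiple measurement instruments linked by
**equate clusters** — groups of items from different instruments that measure
the same behaviour in slightly different ways. Constraining the items of an
*active* cluster to one common difficulty anchors otherwise unconnected
instruments to a single logit scale, so that ability estimates (for child
development, a D-score-style summary) become comparable across cohorts that
never answered a common item.

The intended users are psychometricians and epidemiologists who need to pool
item-level data from several studies — each assessed with its own instrument —
onto one metric for comparison or meta-analysis.

## The model

For person *n* and item *i*, the dichotomous Rasch model gives

    P(pass) = exp(β_n − δ_i) / (1 + exp(β_n − δ_i))

with abilities β and difficulties δ in logits. For an active equate cluster
*q* with members Q_q, difficulties are restricted to a common δ_q, estimated
inside the iteration as the respondent-weighted average
δ̂_q = Σ_{i∈Q_q} δ̂_i w_i / Σ w_i. Estimation is pairwise conditional
(win counts of item pairs), which conditions out person parameters and
handles incomplete multi-instrument designs natively. Cluster quality is
assessed with dedicated *equate infit/outfit* statistics (cutoff 1.5), a DIF
ANOVA on standardized residuals within each cluster (effect size η² with
0.01/0.06/0.14 severity thresholds), and fit-based item purification. The
calibration is frozen as a *key*; persons are scored against the key by
weighted likelihood (finite for perfect response patterns).

A Monte-Carlo framework generates multi-instrument data under a factorial
design (item-range overlap, number and placement of anchors, ability
differences, anchor misspecification Δ) and evaluates calibrations by the
correlation ρ with reference difficulties and the misalignment γ — the
instrument-index coefficient in the regression δ = c + b·δ̂ + γ·k (0 means
one common scale).

## Worked example

```r
library(raschlink)

# two instruments, disjoint samples, one bridging cluster
fx  <- make_fixture("two-instrument-bridge", seed = 3, n_persons = 400)
validate_connectivity(fx$data, fx$clusters)
#> Design connectivity: 1 component(s)
#>   [1] A, B

fit <- rasch_fit(fx$data, fx$clusters)       # constrained calibration
summary(fit)
#> Equate-cluster fit:
#>   cluster_id active n_members infit outfit
#> 1        eq1   TRUE         2 0.906  0.829

dif_test(fit)
#> DIF test (ANOVA on standardized residuals, alpha = 0.05)
#>   cluster_id n_members F_item p_item F_interaction p_interaction eta_squared
#> 1        eq1         2  0.345  0.557        0.0211         0.885    0.000427
#>   severity significant  max_gap unreliable
#> 1     none       FALSE 4.9e-06      FALSE

scores <- score_abilities(fx$data, fit$key)  # abilities on the common scale
head(scores, 2)
#>   person_id   beta    se n_items flag
#> 1   A_p0001 -0.748 0.828       7
#> 2   A_p0002 -0.748 0.828       7
```

The equate cluster fits well (infit/outfit ≈ 0.9, far below the 1.5 cutoff),
shows no DIF between instruments (η² ≈ 0.0004, "none"), and both samples'
abilities land on one scale with standard errors of ~0.8 logits from 7 items
each.

A simulation cell comparing anchored and unanchored calibration when the two
samples differ by 2 logits in mean ability:

```r
cond <- sim_condition(2, overlap = "close", n_equates = 5,
                      placement = "spread", abilities = "different")
run_cell(cond, replicates = 25, seed = 42)$summary
#>           model    rho     gamma abs_gamma
#> 1   constrained 0.9995 -0.002764   0.03389
#> 2 unconstrained 0.7884  2.023068   2.02307
```

With active anchors the split-design estimates reproduce the reference scale
almost perfectly (ρ ≈ 0.999, γ ≈ 0); without them the two instruments'
scales are offset by about the ability difference (γ ≈ 2 logits).

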