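# posacea

Cost-effectiveness of antifungal prophylaxis with **posaconazole** (oral
suspension or tablets) versus **first-generation triazoles**
(fluconazole/itraconazole) in hematological-malignancy patients at high
risk of invasive fungal infection (IFI), from the Chinese healthcare
perspective. The package is aimed at health-economics analysts who want a
scriptable, testable re-implementation of this published model — base case,
one-way and probabilistic sensitivity analyses, acceptability curves, and
province-level willingness-to-pay scenarios — rather than a point-and-click
decision-tree tool.

## The model

A hybrid of two standard components:

- a **100-day decision tree**: with regimen IFI probability *p*,
  IFI-related mortality *d<sub>I</sub>* and other-cause mortality
  *d<sub>O</sub>*, terminal-state probabilities are *p·d<sub>I</sub>*,
  *p·(1−d<sub>I</sub>)*, *(1−p)·d<sub>O</sub>*, *(1−p)(1−d<sub>O</sub>)*.
  All costs (drug acquisition Σ wⱼcⱼtⱼ, plus IFI management
  *p* × $5,423.3) fall in this period and are undiscounted;
- a **lifetime two-state Markov model** for 100-day survivors: monthly
  death probability *p<sub>m</sub>* = 1 − S₅^(1/60) from the 5-year
  relative survival of AML (0.44) or MDS (0.52), 600 monthly cycles,
  half-cycle correction, benefits discounted at 5%/year, QALYs weighted by
  the remission utility 0.830 (induction utility 0.648 during the first
  100 days), cohort mixed 86% AML / 14% MDS.

Strategies are compared by the incremental cost-effectiveness ratio
ICER = Δcost/ΔQALY against a willingness-to-pay threshold of
$31,315/QALY (3× 2020 GDP per capita), and probabilistically via the net
monetary benefit NMB = WTP·QALY − cost.

## Worked example

```r
library(posacea)
run_base_case()
```

```
Base-case cost-effectiveness analysis
Per-strategy results (USD, years):
                   strategy drug_cost ifi_cost total_cost    ly  qaly
 first_generation_triazoles      15.5    600.6      616.0 4.176 3.416
    posaconazole_suspension    1321.2    249.8     1571.0 4.266 3.491
        posaconazole_tablet    3479.4    249.8     3729.2 4.266 3.491

Incremental results vs. first_generation_triazoles :
                  reference             alternative delta_cost delta_ly
 first_generation_triazoles posaconazole_suspension      955.0     0.09
 first_generation_triazoles     posaconazole_tablet     3113.1     0.09
 delta_qaly icer_per_ly icer_per_qaly quadrant dominance
      0.075     10611.1       12784.4       NE      none
      0.075     34591.7       41676.7       NE      none

WTP threshold: $31,315/QALY
```

Read: prophylaxis with the oral suspension costs an extra $955 per patient
and returns 0.075 extra QALYs, i.e. $12,784 per QALY gained — well below
the $31,315 threshold, so it is cost-effective; the tablet formulation
buys the same health at a much higher drug cost. (Life-year and QALY
levels depend on Markov conventions the source publication does not state;
see the vignette for how they are fixed here and how the results compare
to the published ones.)

Uncertainty analyses chain the same way:

```r
psa <- run_psa(n = 1000, seed = 1)
glance(psa)                       # mean increments, P(cost-effective)
ceac_crossing(ceac(psa))          # WTP where the curve passes 0.5
plot_psa_scatter(psa); plot_ceac(ceac(psa), wtp = 31315)
one_way_dsa() |> plot_tornado(wtp = 31315)
```

with `probability_cost_effective(psa, 31315)` ≈ 0.95 and the 0.5-crossing
at ≈ $12,750/QALY under the default seed. A thin command-line wrapper
(`inst/cli/posacea`) exposes the same runs as subcommands (`basecase`,
`dsa`, `psa`, `ceac`, `scenario`, `synth`, `params-export`) writing CSV/JSON
plus a `run_record.json` with the seed and a digest of every effective
parameter.

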