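# momentumcf

Counterfactual trend analysis of conflict impacts on public health.

Armed conflict kills directly, and it also kills by stalling a health
system's momentum: lives that would have been saved had pre-war progress
continued are lost invisibly. `momentumcf` measures that opportunity cost
for infant mortality (IMR) and maternal mortality (MMR), both in deaths per
1,000 live births, at the district and national level. It was built around
the Sri Lanka 1982–2002 civil-war analysis, whose published national and
district tables ship as plain-text fixtures, and it generalises to any
long-format annual indicator panel.

The method, per unit (district or national):

1. **Pre-war trend** — two-point average annual proportional change over a
   pre-war window: `r = ((V_present − V_past) / V_past) / years`.
2. **Counterfactual** — project the baseline (1982) level to the conflict
   endpoint (2002, or 1999 where data stop earlier) under that rate;
   compound growth `V0 (1 + r)^t` by default, with linear, exponential and
   logarithmic variants for sensitivity analysis.
3. **Classification** — flag the conflict-period rate of change and the
   achieved endpoint as worse / better / same relative to the
   counterfactual, and map flag pairs to the published label vocabulary.
4. **Impact index** — one point per worse component (IMR rate, IMR
   endpoint, MMR rate, MMR endpoint): a 0–4 conflict impact weight, plus
   headline tallies and choropleth-ready GeoJSON export.

Intended users: epidemiologists and conflict-and-development researchers
who want a tested, reusable implementation of interrupted-trend
counterfactual gap analysis with honest reconciliation of rounded published
inputs.

## Worked example

```r
library(momentumcf)
library(dplyr)

# National conflict-period trends from the packaged national table
t2 <- national_table()
average_annual_change(34.00, 18.20, 20) |> round(2)   # IMR: -0.02
average_annual_change(0.60, 0.14, 20) |> round(2)     # MMR: -0.04
project_value(0.60, -0.08, 20) |> round(2)            # MMR counterfactual: 0.11

# District classification and headline tallies from the packaged tables
imr <- classify_units(district_table("IMR"))
tally_classifications(imr, sri_lanka_meta())$counts
#>   indicator metric                            n
#>   IMR       endpoint_worse                   10
#>   IMR       endpoint_worse_outside_zone       8
#>   IMR       rate_worse                       16
#>   IMR       rate_worse_endpoint_not_worse     6
```

Ten districts ended 2002 with higher infant mortality than their pre-war
momentum predicted; eight of them lie outside the high-conflict zone, and
sixteen saw their rate of improvement slow — the war's cost was national,
not merely local. The full pipeline runs on any panel:

```r
panel <- generate_panel(synthetic_config(n_units = 25, seed = 1))
fit <- analyze_conflict_impact(panel$series, panel$meta)
glance(fit)         # one-row summary of tallies
tidy(fit)           # per unit x indicator flags, labels, weights
autoplot(fit)       # actual-vs-counterfactual gap plot
```

File-based runs (`run_analysis()`, `run_sensitivity()`, `export_map()`)
write deterministic CSV/JSON/GeoJSON outputs with a run manifest; a thin
command-line wrapper lives at `inst/scripts/conflict-impact.R`.

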