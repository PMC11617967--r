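# transpirest

Transpiration-resistance determination for fruit and vegetables from
differential weighing.

Postharvest water loss of fresh produce follows a diffusion law in
series-resistance form,

```
E = (x_p − x_a) / (r_T + r_B) = Δx / r_tot ,
```

where `E` is the area-related transpiration rate (mg cm⁻² h⁻¹), `x_p` the
water-vapour concentration of the saturated (or near-saturated, water
activity ≈ 0.985) air in the intercellular spaces of the produce, `x_a` that
of the ambient air (both g m⁻³), `r_T` the tissue resistance of skin and
flesh and `r_B` the boundary-layer resistance of the air film at the surface
(s cm⁻¹). `E` is measured non-destructively by weighing on a 0.1 mg balance,
`E = ΔFM / (A·Δt)`, with the surface area `A` from calibrated allometric
regressions. Measuring once under free convection and once with the boundary
layer stripped (forced airflow > 2 m s⁻¹, or a wetted surface) separates
`r_T` from `r_B`; for packed fruit the bulk boundary-layer resistance follows
from the packaged total minus the individual tissue resistance. With `r_B`
known, the humidity at the produce surface is recovered from
`x_pS = x_a + E·r_B/3.6` by an inverse psychrometric solve.

The package is aimed at postharvest physiologists and storage engineers. It
provides the full psychrometric chain (forward and inverse), surface-area
regressions for seven produce types, the four measurement protocols
(`free`, `forced`, `wetted`, `bulk`), Arrhenius temperature adjustment of
resistances, CSV ingestion/validation of weighing and climate logs, and a
forward simulator that generates synthetic experiments with known
resistances so the whole estimation chain can be verified by parameter
recovery.

## Worked example

Simulate the reference apple experiment (131 g apple, 20 °C, 50 % rH,
tissue resistance 391 s cm⁻¹, boundary layer 4.8 s cm⁻¹, 2 h weighings over
24 h) and estimate back:

```r
library(transpirest)

apple <- produce_item("apple-1", "apple", mass_g = 131)
spec  <- simulation_spec(apple, r_T_s_cm = 391, r_B_s_cm = 4.8,
                         temp_c = 20, rh_pct = 50, duration_h = 24,
                         weighing_interval_h = 2, balance_resolution_mg = 0)
sim   <- forward_simulate(spec)
run_protocol(sim$weighing, sim$climate, apple,
             protocol_config("free", rb_default_s_cm = 4.8))
#> Transpiration resistance result ('free' protocol, item 'apple-1')
#>   E            0.0779 mg cm-2 h-1
#>   x_p          17.260 g m-3
#>   x_a           8.699 g m-3
#>   delta_x       8.561 g m-3
#>   r_tot        395.80 s cm-1
#>   r_T          391.00 s cm-1
#>   r_B            4.80 s cm-1
#>   x_pS          8.803 g m-3 (surface rH 50.6 %)
```

The apple loses 0.372 g of water over the 24 h (transpiration rate
0.0779 mg cm⁻² h⁻¹ over its 199.2 cm² regression-estimated surface); the
total resistance of 395.8 s cm⁻¹ splits into the assumed 4.8 s cm⁻¹ boundary
layer and a recovered tissue resistance of 391 s cm⁻¹, and the air
immediately at the apple surface sits at 50.6 % rH — barely above the 50 %
ambient, as expected when the tissue dominates the series resistance.

A thin command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "transpirest.R", package = "transpirest"))')
Rscript $CLI psychro --temp 20 --rh 50
Rscript $CLI area --species apple --mass 131
Rscript $CLI simulate --spec spec.yaml --out-prefix run1
Rscript $CLI resist --weighing run1_weighing.csv --climate run1_climate.csv \
        --species apple --mass 131 --protocol free --rb-default 4.8
```

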