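# asnkin

Mechanistic kinetic modeling of glutamine-dependent **asparagine
synthetase** (EC 6.3.5.4), the enzyme that controls free asparagine —
and hence acrylamide-forming potential — in wheat grain. The package is
for enzymologists and systems biologists who want to simulate the
reaction mechanism of the wheat isoforms TaASN1/TaASN2, generate
realistic synthetic HPLC-assay data, and fit mass-action rate constants
to time-course measurements.

## The model

The catalytic cycle is represented as a continuous Petri net — species
("places") with continuous concentrations, mass-action reactions
("transitions") — and compiled to ODEs. The canonical net has 11
species and 5 reactions:

    r1: ASNe + Gln                     -> ASNe·Gln                    (k1)
    r2: ASNe·Gln                       -> Glu + ASNe·NH3              (k2)
    r3: ASNe·NH3 + Asp + ATP + Mg2+    -> βAsp-AMP·ASNe·NH3 (+ Mg2+)  (k3)
    r4: βAsp-AMP·ASNe·NH3              -> Asn + ASNe + AMP            (k4)
    D : ASNe·NH3                       -> ASNe                        (kD)

ATP and Mg²⁺ are clamped boundary species (derivative zero). Fluxes are
mass-action, `v_j = k_j * prod(c_i^s_ij)`, and the dynamics are
`dc/dt = N v(c)` with clamped rows of `N` zeroed. The dissociation step
D is the mechanistic reason glutamate keeps accumulating after
asparagine synthesis stalls for lack of aspartate. Rate-constant fitting
uses a from-scratch Hooke–Jeeves pattern search on log10-transformed
parameters, minimizing the sum of squared Asn/Glu residuals.

See the methods vignette (`vignettes/asn-kinetics.Rmd`) for the full
account: assumptions, units, noise model, optimizer details and
limitations.

## Worked example

```r
library(asnkin)

net <- asn_network()
net
#> Continuous Petri net: 11 places, 5 reactions
#>   species: AMP, Asn, ASNe, ASNe_Gln, ASNe_NH3, Asp, ATP, bAsp_AMP_ASNe_NH3, Gln, Glu, Mg
#>   clamped: ATP, Mg
#>   r1: ASNe + Gln -> ASNe_Gln  [k1]
#>   ...

traj <- simulate_network(net, asn_rate_params("TaASN1"),
                         asn_initial_state("TaASN1"))   # 2100 s, 2001 points
m <- plateau_metrics(traj)
m$per_species[m$per_species$species %in% c("Asn", "Glu", "Asp", "Gln"), ]
#>    species      final         max   t95_s
#> 2      Asn 0.09109644  0.09109644 1564.50
#> 6      Asp 1.50890302  1.60000000 1564.50
#> 9      Gln 0.36579959 10.00000000 1573.95
#> 10     Glu 9.63400560  9.63400560 1573.95
m$glu_asn_ratio
#> [1] 105.7561
```

Glutamine (10 c.u.) is almost fully converted to glutamate, while
asparagine plateaus at 0.091 — far below the 1.6 of aspartate nominally
available — because the fast dissociation step (kD = 700) discards most
of the enzyme-bound amide nitrogen before aspartate can be activated.
The final glutamate:asparagine ratio of ~106 reproduces the qualitative
finding that glutamate output exceeds asparagine more than two-fold.

Parameter recovery on noiseless self-simulated data:

```r
recovery_experiment("TaASN1", noise_cv = 0, n_replicates = 1, seed = 1)
#> parameter recovery - TaASN1
#>   parameter    true    estimated rel_error
#> 1        k1   0.016   0.01600017  1.06e-05
#> 2        kD 700.000 700.00742249  1.06e-05
#> SSE at estimates: 7.840399e-08
```

A command-line wrapper over the same functions ships at
`inst/scripts/asnkin.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","asnkin.R",package="asnkin"))')" \
    simulate --enzyme TaASN1 --out-dir out
```

with commands `simulate`, `synth`, `fit` and `recover`.

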