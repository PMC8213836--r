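# leverlink

Simulation and analysis of multivalent receptor crosslinking on biosensor
surfaces.

Biparatopic and multivalent anti-HER2 antibodies can crosslink neighbouring
receptors into large, signalling-incompetent clusters ("lockdown"). On a
switchSENSE-type biosensor the receptor extracellular domain is carried by
fluorophore-labelled DNA nanolevers at controlled surface density, which
makes interlinking measurable — and simulatable. `leverlink` is for
protein engineers and biophysicists who want to model and analyse such
experiments. It provides three connected analyses, each with its own
synthetic-data generator so everything runs without measured data:

1. **Crosslinking simulation.** A square surface is tessellated into
   hexagons of in-radius *r* = 2.5 nm (minimum lever spacing 5 nm); each
   hexagon holds a lever with probability *p* = (*r* / (*d*/2))², realizing
   a mean inter-lever distance *d*. Crosslinkers with maximal
   anchor-to-anchor reach *R* = 2·32 nm (DNA levers) + 2·8 nm (HER2 ECD) +
   *s* (paratope span) are bound one-by-one — random free lever first, then
   the closest other free lever within *R* — until every binding site is
   occupied. The readout is the fraction of levers incident to at least one
   bridge. Preset spans: 20 nm (tetravalent scFv–IgG "441"), 2 nm
   (bivalent scFv–Fab "841"), 14 nm (two-IgG combination).
2. **Binding kinetics.** Mono-/biphasic exponential fitting of
   association/dissociation traces under the 1:1 Langmuir model
   (*k*<sub>obs</sub> = *k*<sub>on</sub>·*c* + *k*<sub>off</sub>,
   *K*<sub>D</sub> = *k*<sub>off</sub>/*k*<sub>on</sub>), with AICc model
   selection.
3. **Immobile fraction.** Density clustering (DBSCAN) of single-molecule
   localizations with a temporal-persistence criterion: a cluster counts as
   an immobile particle only if it spans enough distinct frames.

See `vignettes/crosslinking-methods.Rmd` for the full model description,
parameter defaults and limitations.

## Worked example

```r
library(leverlink)

# interlinking of the three binder architectures at chip densities d = 50/100/200 nm
curve <- crosslink_curve(base_seed = 1)   # 10 surfaces x 10 repeats per cell
as.data.frame(curve)
#>        spec mean_distance_nm      mean          sd   n
#> 1       441               50 0.9902373 0.001814303 100
#> 2       441              100 0.9083192 0.012610833 100
#> 3       441              200 0.5520142 0.029273808 100
#> 4       841               50 0.9824595 0.002565558 100
#> 5       841              100 0.8312786 0.018505597 100
#> 6       841              200 0.3954423 0.029553244 100
#> 7 mAb_combo               50 0.9883552 0.001817319 100
#> 8 mAb_combo              100 0.8881513 0.014337009 100
#> 9 mAb_combo              200 0.4842585 0.040331252 100
```

At high lever density (*d* = 50 nm) all three binders interlink nearly
every lever. Diluting the surface separates them by reach: at
*d* = 200 nm the long-span tetravalent molecule still bridges ~55% of
levers while the short-span bivalent one drops to ~40% — dilution hits the
shortest crosslinker hardest.

```r
# kinetics round trip at the measurement conditions (20 nM analyte)
tr <- simulate_trace(k_on = 1e5, k_off = 1e-3, conc = 20e-9,
                     noise_sd = 0.01, seed = 3)
fit <- fit_kinetics(tr, n_phases = 1)
c(k_on = fit$k_on, k_off = fit$k_off, K_D = fit$K_D)
#>          k_on         k_off           K_D
#>  9.835657e+04  9.975542e-04  1.014223e-08
```

The true values (10⁵ M⁻¹s⁻¹, 10⁻³ s⁻¹, 10⁻⁸ M) are recovered within ~2%
at 1% noise.

```r
# immobile fraction of a 60:40 immobile:mobile mixture (200 particles)
locs <- simulate_localizations(n_mobile = 80, n_immobile = 120, seed = 5)
estimate_immobile_fraction(locs)
#> <immobile_estimate> immobile fraction 0.605 (121 of 200 units; 0.622 by localization)
#>   eps = 60 nm, min_samples = 10, min_frame_span = 10
```

Configured runs (`run_stage()`, YAML configs) and a thin command-line
wrapper (`inst/cli/lever-xlink.R`) write CSV/JSON outputs plus a
reproducibility manifest.

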