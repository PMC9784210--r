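# pefsim

Coupled electro-thermal finite-element simulation of **epicardial
pulsed-field ablation (PFA) near a coronary artery, with and without a
metal intracoronary stent**, in a 2D cross-section.

PFA kills cells non-thermally wherever the pulsed electric field exceeds an
irreversible-electroporation threshold (1000 V/cm in cardiac tissue). When
the ablation device sits on the epicardial fat directly above the left
circumflex artery, the highly conductive blood — and even more so a stented
vessel — distorts the field. `pefsim` answers, for a configurable geometry:

* how large the **PEF-zone** (the |E| ≥ 1000 V/cm region, a lesion-size
  proxy) is, and whether it stays confined to the fat layer;
* how much field reaches the **artery lumen** (with a stent: essentially
  none — the Faraday-cage effect);
* whether the field distortion causes **Joule heating hot spots** between
  electrode and artery, how hot they get over a 10-pulse train, and whether
  any thermal latency follows the last pulse.

## Model

Quasi-static conduction per time instant,
∇·(σ∇φ) = 0, **E** = −∇φ, with the electrode at the pulse voltage (10 ×
1000 V, 100 µs pulses; 100 µs or 10 µs intervals) and a dispersive ground
pad at the domain bottom. The conductivity of cellular media follows a
sigmoid electroporation law with a +2 %/°C thermal factor,

    σ(E,T) = [σ0 + (σ1 − σ0) / (1 + 10 e^(−(|E|−58000)/3000))] · 1.02^(T−37),

and heat transport is the bioheat equation ρc ∂T/∂t = ∇·(k∇T) + σ|E|²,
advanced by backward Euler with lumped mass over the pulse train and a
10 ms latency window; blood pools act through convective film conditions
(1417 W/m²K endocardium, 63.19 W/m²K artery lumen, 20 W/m²K ambient air).
The solver stack — a deterministic block-structured triangle mesher with an
O-grid around the artery/stent, P1 stiffness with sparse Cholesky, damped
Picard iteration for σ(|E|), marching-triangles isolines — is pure R
(`Matrix`). See the methods vignette
(`vignettes/pef-ablation-model.Rmd`) for assumptions, parameter
sensitivities and numerical choices.

## Worked example

```r
library(pefsim)

# artery (2.3 mm) with a 100 um stent, 0.25 mm below the electrode,
# 10 x 1000 V / 100 us pulses at 100 us intervals
sc <- scenario(geometry_config(artery_present = TRUE, stent_present = TRUE,
                               electrode_artery_gap = 0.25),
               pulse_train(), label = "stent_0.25mm")
res <- run_scenario(sc, solver_profile("standard"))
metrics_summary(res)
```

```
      scenario width_mm depth_mm confined_to_fat lumen_mean_Vcm
1 stent_0.25mm 9.351426        5            TRUE   0.0003187159
  lumen_center_Vcm  front_T   rear_T     Tmax t_peak_s latency_flag
1     0.0003178482 45.14963 39.27279 45.14963   0.0019         TRUE
```

Reading: the lesion is ~9 mm wide and stops at the fat/myocardium interface
(5 mm deep, `confined_to_fat`); the stented lumen sees ~3 × 10⁻⁴ V/cm —
five orders below the electroporation threshold — while the fat between
electrode and stent reaches 45.1 °C at the end of the last pulse
(`t_peak_s` = 1.9 ms = the last pulse's falling edge; no thermal latency),
well under the ~55 °C lethal isotherm. Without the stent the same run peaks
at 43.4 °C; without the artery at 39.2 °C.

The ten-run study matrix (no artery; artery ± stent at 1 mm and 0.25 mm;
both inter-pulse intervals) is generated by `study_scenarios()`, and a thin
CLI wraps the same functions:

```sh
inst/cli/pefsim run --matrix --out results/
inst/cli/pefsim report --dir results/
```

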