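# memdock

Quantitative analysis of membrane–membrane docking interfaces and bilayer
relaxation kinetics.

## The problem

When two lipid vesicles dock tightly on the way to fusion, the apposed
membranes sit less than a nanometre apart, proteins are cleared from the
contact, and the bilayers *thicken* locally. Establishing that chain of
events takes two kinds of measurement:

* **Imaging.** In cryo-EM-style micrographs a bilayer appears as two dark
  lines — the headgroup layers. Membrane thickness is the peak-to-peak
  distance in an intensity profile: a line scan across a docking
  interface, or an azimuthally averaged radial profile on free membrane.
  In fluorescence images of docked giant vesicles, the docking state is
  read from the labelled-protein channel: tight interfaces deplete the
  protein signal, loose ones retain or enrich it, so the ratio of
  background-subtracted interface signal to free-membrane signal
  classifies the pair.
* **Simulation observables.** From particle coordinates of one or two
  bilayers (P/N headgroup particles, chain beads, waters), per-frame
  metrics: thickness from the mean P-atom layers, inter-membrane
  distance, lateral area, volume (area × thickness), headgroup tilt
  cos φ of the P→N vector against the membrane normal, chain order
  S = (3⟨cos²θ⟩ − 1)/2, gap hydration, and leaflet-internal electrostatic
  energy (cutoff Coulomb, f = 138.935 kJ mol⁻¹ nm e⁻²). Equilibration of
  two stacked single bilayers into a docked double membrane is analysed by
  fitting each replica of each observable with the exponential relaxation

  `f(t) = x∞ + (x0 − x∞) e^(−t/τ)`

  and comparing the time constants: τ_tilt < τ_area < τ_thickn orders the
  mechanism — headgroups tilt first, the area shrinks, and (the membrane
  being nearly incompressible) the bilayer thickens. The package adds a
  bootstrap-over-replicas support level for that ordering, and implements
  the angle-restraint bias `k(1 − cos(φ − φ0))` (with analytic forces)
  used to enforce headgroup tilt.

A seeded synthetic-data module generates ground-truth-annotated vesicle
images, bilayer frames and relaxation ensembles, so the entire pipeline
runs and is scored without any external data.

## Worked example

```r
library(memdock)

# a tightly docked synthetic pair: density + protein channels + ground truth
spec <- vesicle_image_spec(docking_type = "tight", seed = 7)
bundle <- generate_vesicle_pair_image(spec)

# thickness across the interface (truth: 4.0 nm free + 0.6 nm thickening)
measure_synthetic_image(bundle, pipeline_config())
#>     context membrane_id thickness_nm resolved n_peaks
#> 1 interface           1     4.700843     TRUE       4
#> 2 interface           2     4.710845     TRUE       4

# docking call from the protein channel
segs <- lapply(bundle$truth$segments, function(s) c(s, list(width_px = 11L)))
classify_interface(bundle$protein, segs$interface, segs$free)
#> <docking_call> tight (interface/free protein ratio 0.154, threshold 0.60)

# double-bilayer frame at 0.5 nm separation: exact metric closure
fr  <- generate_bilayer_frame(bilayer_frame_spec(n_membranes = 2,
         intermembrane_distance_nm = 0.5, positional_noise_nm = 0, seed = 1))
asg <- assign_leaflets(fr, 2)
membrane_thickness(fr, asg, 1)    # 4 (nm)
intermembrane_distance(fr, asg)   # 0.5 (nm)

# relaxation ensemble -> per-replica fits -> tau ordering with bootstrap support
ens <- generate_relaxation_ensemble(relaxation_ensemble_spec(n_replicas = 100, seed = 2))
tau_ordering(fit_ensemble(ens), seed = 3)
#> <ordering_result> median tau (ns): tilt=0.05005, area=0.1497, thickness=0.3996
#> declared ordering: tilt < area < thickness (all pairwise supports >= 0.95)
```

The two interface membranes read ~4.7 nm against a free-membrane 4.0 nm —
the +0.6 nm contact-zone thickening plus a ~0.1 nm peak-pull bias discussed
in the methods vignette. The protein ratio 0.15 ≪ 0.6 calls the pair
tight. The fitted medians recover the generator's time constants
(0.05/0.15/0.40 ns) within a fraction of a percent and declare the
tilt → area → thickness sequence with full bootstrap support.

`run_pipeline(pipeline_config(), out_dir = "out")` executes the whole
chain (generate → measure → classify → stats → metrics → fit → order) and
writes CSV/JSON artifacts plus a log of every parameter and seed.

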