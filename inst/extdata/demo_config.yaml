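# Demo scenario: three summer seasons of systematic line-transect effort
# over a coastal domain with a latitudinal SST gradient, surveying a
# warm-affinity delphinid-like species. Mirrors default_run_config().
seed: 1
out_dir: runs/demo
env:
  extent: [-126.0, -122.0, 34.0, 40.0]
  days_per_year: 16
  years: [1996, 2001, 2005]
  heatwave_years: []
  anomaly_c: 2.0
truth:
  name: sim_delphinid
  lambda0: 0.01
  sst_slope: 0.25
  sst_ref: 18.0
  group_meanlog: 2.0794   # log(8)
  group_sdlog: 0.6
design:
  n_transects: 8
  step_km: 1
  target_segment_km: 5
  truncation_km: 5.5
models:
  density:
    response: encounter_rate
    terms: [sst, depth]
    interaction: "lon:lat"
  presence:
    terms: [sst, depth]
    interaction: "lon:lat"
  brt:
    min_trees: 60
    n_iterations: 2
    cv_folds: 5
    variants: dyn_bathy
strata:
  n_bands: 4
  isobath_m: 2000
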