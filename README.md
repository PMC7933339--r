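# mwfp — multi-wavelength HPLC fingerprint fusion and quantified similarity grading

Geographical-origin identification of *Panax notoginseng* (San-qi) from
HPLC-DAD fingerprints. The pharmacopoeial saponin contents alone cannot
separate material from the genuine Yunnan producing area and the newer
Sichuan region; the whole chromatographic fingerprint can — and more of it
becomes usable when the traces recorded at several detection wavelengths
(203, 270, 325 nm) are **fused** into one multi-wavelength profile, the
projection of the time × wavelength response surface along the wavelength
axis. Saponins absorb only near 203 nm, flavonoids at 270/325 nm and amino
acids at 270 nm, so every single channel is blind to part of the extract
while the fused profile sees all of it.

The package implements the complete workflow for analysts reproducing or
extending this kind of study:

- chromatogram and study I/O in plain delimited text, with strict grid
  validation (`read_chromatogram()`, `load_study()`);
- rolling-minimum baseline correction, prominence-based peak detection
  with valley-to-valley trapezoidal integration, and greedy retention-time
  matching into co-possessing-peak matrices (`subtract_baseline()`,
  `detect_peaks()`, `match_peaks()`);
- signal-level fusion and per-channel fingerprint construction
  (`fuse()`, `build_fingerprints()`);
- quantified-fingerprint similarity with the averagely linear parameters

  `Sm = (S_cos + S_prof)/2`,  `Pm = 100 · mean(x_i/y_i)`,
  `alpha = sd(x_i/y_i)/mean(x_i/y_i)`,

  graded on the eight-level nested threshold scale, worst-of-three
  (`similarity_parameters()`, `assign_grade()`, `evaluate_study()`,
  `grade_discrimination()`);
- chemometrics implemented in-package and checked against independent
  oracles: between-groups (average) linkage HCA on squared Euclidean
  distances, PCA, two-class OPLS-DA with VIP scores (`hca()`, `pca()`,
  `oplsda()`, `vip()`);
- linear calibration, mg/g content conversion, per-compound mean/RSD and
  Welch origin-difference tests (`fit_calibration()`, `to_content()`,
  `summary_stats()`, `group_difference()`);
- a deterministic synthetic-study generator reproducing the 32-batch
  two-origin design (15 Sichuan + 17 Yunnan, 33 shared constituents) for
  end-to-end testing (`synthetic_study_config()`, `generate_study()`), and
  the published concentration and similarity tables bundled as data
  (`saponin_concentration_table()`, `reported_similarity_results()`).

The methods vignette (`vignettes/origin-fingerprinting.Rmd`) documents the
models, the reference-fingerprint conventions, the generator calibration
and the known limitations.

## Worked example

```r
library(mwfp)

# reanalyse the bundled published similarity table
rg <- regrade_reported_results("fused")
sum(rg$recomputed_grade == rg$reported_grade)      # 26 of 32
grade_discrimination(rg$reported_grade, rg$origin, cutoff = 4)$errors  # 5

# simulate the study design and run the full pipeline
report <- run_origin_pipeline(synthetic_study_config(seed = 1))
print(report)
```

```
<mwfp_report> 32 samples; channels: 203, 270, 325, fused
  reference: mean (single) / scaled_mean (fused); grade cutoff 4
  grade errors [203]: 17 of 32 (Sichuan 11/15 within, Yunnan 4/17 beyond)
  grade errors [270]: 16 of 32 (Sichuan 14/15 within, Yunnan 2/17 beyond)
  grade errors [325]: 18 of 32 (Sichuan 12/15 within, Yunnan 2/17 beyond)
  grade errors [fused]: 5 of 32 (Sichuan 10/15 within, Yunnan 17/17 beyond)
  HCA (k = 2) misassigned: 0
  PCA var explained (PC1, PC2): 46.1%, 10.5%
  OPLS-DA R2Y = 0.940; 13 variables with VIP > 1; recovers 87% of injected discriminators
  saponin content recovery: median |rel. error| = 2.63%
```

Reading the report: each single wavelength grades almost every batch
"similar" (its quantitative similarities centre near 100%), so at the
grade-4 cutoff nearly all Yunnan batches are miscalled — 16–18 errors,
matching the published single-channel failure. The fused profile, graded
against the consensus pattern scaled to the most content-rich benchmark
batch, separates the origins with 5 errors of 32 — the published fused
error rate. The 2-cluster dendrogram cut recovers the origins exactly,
and OPLS-DA VIP > 1 flags 13 peaks that recover 87% of the 15 injected
origin markers, whose true contents are re-estimated from the 203 nm
channel through calibration curves to within ~2.6%.

The numbered scripts under `analysis/` run the same workflow as a
step-by-step narrative (simulate → fingerprints → grading → chemometrics →
quantitation), writing all tables under `results/`.

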