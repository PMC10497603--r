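# specband

Signature-band extraction from hyperspectral fruit images by
integrated-gradients attribution.

## The problem

Hyperspectral cameras measure fruit reflectance in hundreds of contiguous
nanometer-wide bands; deployable multispectral instruments can afford six
wide filters. `specband` finds which six. It calibrates raw hypercubes
against dark/white references, denoises spectra with a Savitzky–Golay
filter, converts them to multispectral band sets

R_M(λ_c) = Σ_{i=a}^{b−1} R(λ_i)(λ_{i+1} − λ_i) / (λ_b − λ_a)

over grids of bandwidths ±5…±15 nm in the VIS/VISNIR/SWIR/VISWIR ranges,
trains small CNN (20×20×bands image input) and FNN (mean-spectrum input)
regressors for sugar content (°Brix) with an RMSLE loss and exponential
learning-rate decay, scores every band of a trained model F by the
absolute mean of integrated gradients

MIG = (1/S)(1/M) Σ_s Σ_{k=1..M} ∇F(R′ + (k/M)(R_s − R′)),
Score(λ_c) = | spatial mean of MIG(·, ·, λ_c) |,

and greedily selects six signature bands whose centers are pairwise
≥ 20 nm apart (equality admissible). Selected bands are then resampled and
compact signature architectures retrained to verify six bands suffice.

Because the original wax-apple dataset is not public, the package ships a
first-class synthetic generator that plants a known linear band→Brix
structure (default: bands at 560/660/1170 nm, five °Brix groups of
218/162/218/218/218 samples), so the entire pipeline is testable
end to end, including whether the selected bands recover the planted ones.

## A worked example

```r
library(specband)

params <- synthParams(wavelengths = seq(400, 1700, by = 5),
                      groupSizes = c(8L, 6L, 8L, 8L, 8L), seed = 1L)
gen <- generateSynthetic(params, return = "cubes")
cfg <- pipelineConfig(rangesA = "VISWIR", bandwidthsA = 10,
                      rangesBC = "VISWIR", bandwidthsBC = 10,
                      families = "fnn", epochs = 300L, patience = 100L,
                      seed = 1L)
a <- runBlockA(gen$cubes, gen$labels$brix, cfg)
a$table
#> MaeTable
#>  family  range halfBandwidth   mae    r2
#>     fnn VISWIR            10 0.241 0.982
sets <- runBlockB(a, cfg)
sets[[1]]
#> SignatureSet (fnn_multi, VISWIR, +/-10.0 nm, literal IG):
#>   550,  570,  670,  730, 1010, 1550 nm
```

The MAE cell is the test-set mean absolute °Brix error of the trained
model; the signature set lists the six center wavelengths whose
attribution scores survive the 20 nm spacing rule. Three of them sit at or
immediately beside the planted centers of the synthetic data (550/570
bracket 560; 670 neighbors 660); at this demonstration size (38 samples)
the remaining bands are noise picks — the full-scale recovery experiment
in `scripts/acceptance.R` (1034 samples, five seeds) recovers the planted
bands far above chance. A thin CLI over the same functions is installed at
`inst/scripts/specband` (`grid`, `synth`, `run-all` subcommands).

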