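# periFISH

Quantitative tools for studying mRNA export at the nuclear periphery of
trypanosomes. Trypanosome genes are transcribed as polycistrons and
matured by trans-splicing, and nuclear export of mRNA can begin while
transcription and processing are still ongoing. Testing that claim
quantitatively needs three things this package provides:

1. **A coordinate system for the nuclear border.** The DAPI stain has no
   sharp edge, so a position is expressed on a profile running from the
   cytoplasm (0% DAPI) over the peak (100%) towards the DAPI-dark
   nucleolus. Two independent calibrations anchor the border on that
   scale: the peak of a nuclear-pore marker along each profile, and the
   intersection point of a cytoplasmic marker's curve with the DAPI
   curve. A molecule with any FISH signal between 10 and 66.6 %DAPI
   (cytoplasmic flank) is classified as *nuclear periphery*.

2. **Multi-colour single-molecule FISH quantification.** Spots from a 5'
   probe (red), an internal probe (infrared) and a 3' probe (green) are
   detected with sub-voxel 3D Gaussian fits, linked into molecules by
   mutual-nearest-neighbour pairing with a 0.5 um cap (single mRNAs are
   compact; the 22,197-nt reporter would be 7.5 um fully extended),
   classified by colour combination — intact (red+IR+green), 5' part
   (red+IR), 3' part (IR+green), read-through (colours spanning two
   genes) — and by location. For periphery molecules the *export
   orientation* statistic asks whether the 5' signal sits further
   towards the cytoplasm than the internal signal:
   %DAPI(5') < %DAPI(internal), counted over molecules whose connecting
   segment intersects the nucleus.

3. **Nuclear-proteome enrichment statistics.** Label-free quantitation
   with two conditions x three replicates is filtered (flags removed;
   >= 2 of 3 values in at least one condition), log2-transformed,
   imputed per column from a down-shifted normal (width 0.3, downshift
   1.8 column sds), and tested with the moderated statistic
   `d = (mean2 - mean1) / (se_Welch + s0)`, `s0 = 0.5`, against 250
   balanced label permutations at FDR 0.05. Enriched proteins are then
   characterised by Q-rich regions (non-overlapping 60-mers with >= 7
   glutamines, reported per 100 aa) and by reciprocal-best-hit homology
   (top hit reciprocity with e < 1e-5) across four reference taxa.

Because the original images and proteome are external data, a
synthetic-data module generates ground-truthed cell image stacks
(ellipsoidal cell/nucleus/nucleolus geometry, logistic DAPI edge,
pore-ring and cytoplasm markers, Gaussian spots, Poisson noise), LFQ
matrices with abundance-dependent missingness, protein sequences with
planted Q-rich windows, and reciprocal hit tables — so every estimator
is validated against known truth.

## Worked example

```r
library(periFISH)

# a synthetic cell with known molecule content
counts <- molecule_counts(intact.nucleus = 3, intact.cytoplasm = 4,
                          five_prime_part.nuclear_periphery = 4,
                          three_prime_part.cytoplasm = 3)
scene <- generate_cell_scene(counts, seed = 11)
stack <- render_image(scene, optics_params(), seed = 12)   # Poisson noise

# detect, group, classify
spots <- do.call(rbind, lapply(c("red", "ir", "green"),
                               function(ch) detect_spots(stack, ch)))
res <- localize_molecules(group_spots_to_molecules(spots), stack)
subset(per_cell_counts(res$molecules)$counts, n > 0)
#>             species          location n
#> 1            intact           nucleus 3
#> 7   five_prime_part nuclear_periphery 4
#> 11           intact         cytoplasm 4
#> 13 three_prime_part         cytoplasm 3

# border calibration from the pore-ring marker (four profiles, focus plane)
profs <- border_profiles(stack, channels = c("dapi", "pore"), mode = "plane")
calibrate_border(profs, method = "marker_peak")
#> border calibration (marker_peak): 54.8 +/- 5.6 %DAPI (n = 4), 0.0% below 33.3%

# proteome enrichment on a synthetic two-condition triplicate dataset
lfq <- generate_lfq_dataset(lfq_ground_truth(), seed = 13)
m <- impute_mnar(log2_transform(filter_matrix(lfq$matrix)), seed = 14)
sam_welch_test(m, seed = 15)
#> enrichment (treat vs ctrl): 23 significant of 187 proteins (20 up, 3 down)
#> s0 = 0.50, 250 randomizations, FDR = 0.05, frontier |d| = 1.09
```

The recovered count table equals the generating specification exactly on
noise-free renders and within a few percent under Poisson noise; the
calibration recovers the analytic border (50 %DAPI for this forward
model) within sampling error; of the 23 enrichment calls, the 20
up-calls are the 20 planted proteins.

`run_pipeline(pipeline_config(seed = 1), out_dir = "run1")` executes all
stages end to end (simulate, calibrate, quantify, orient, enrich,
qrich, rbh), writing TSV/TIFF/FASTA outputs plus a manifest with file
digests; identical config and seed reproduce byte-identical outputs.

## Documentation

The methods vignette (`vignettes/perifish-methods.Rmd`) describes the
forward model, every tunable with its default and rationale, the
numerical choices (tie rules, tolerances, degenerate inputs), what the
simulator does and does not emulate, and known limitations.
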