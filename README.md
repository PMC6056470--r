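# thymometry

Quantification of the developing mouse thymic epithelium: in-situ TEC
counting, cortex/medulla morphometry, stereological whole-organ totals,
and reconciliation with flow cytometry after enzymatic dissociation.

## The problem

Thymic epithelial cells (TECs) are routinely counted by digesting the
organ and gating CD45⁻/EpCAM⁺ events on a cytometer. But digestion
destroys TECs — cortical TECs, entangled with thymocytes through their
reticular processes, most of all — so flow-based counts are far too low.
Counting reporter-labelled TEC nuclei directly in tissue sections exposes
the bias through the **thymopoietic index** (TI), the ratio of thymocytes
to TECs:

- TI by histology at P10: **~61** thymocytes per TEC
- TI by flow cytometry at P10: **~810**
- correction factor `TI_flow / TI_hist = 810/61 ≈ 13.3` (at least 13)
- corrected whole-organ TEC count at 4 weeks:
  `1.12×10⁵ flow TECs × 13 ≈ 1.5×10⁶`

The package implements the full measurement chain needed to obtain and
cross-check those numbers, together with a ground-truthed synthetic-data
generator that emulates the two-reporter cryosections (nuclear reporter +
DAPI), anisotropic light-sheet stacks, and flow-cytometry event tables,
so every stage is testable end to end:

| module | functions |
|---|---|
| generator | `make_scenario`, `render_section`, `render_stack`, `render_points_section` |
| detection | `detect_spots_2d`, `detect_spots_3d`, `match_to_truth` |
| segmentation | `segment_compartments`, `area_fractions`, `mask_iou` |
| morphometry | `compartment_density`, `ctec_mtec_ratio`, `thymopoietic_index`, `whole_organ_ti`, `extrapolate_total_tecs`, `reconcile`, `fold_change` |
| dissociation/flow | `population_spec`, `dissociate`, `gate`, `bulk_expression`, `ratio_fold_change`, `recovery_timeline` |
| orchestration | `default_config`, `run_reproduction`, TIFF/CSV/YAML readers and writers |

## Worked example

```r
library(thymometry)

# a synthetic E15.5 section with known ground truth
sc  <- make_scenario("E15.5")      # cortex 13, medulla 23 TECs per 1e4 um^2
out <- render_section(sc, field_size = c(600, 600), seed = 4)

spots <- detect_spots_2d(out$image)              # LoG nuclear detection
mask  <- segment_compartments(out$image, window = 30)
match_to_truth(spots, out$truth, radius = 3)$recall
#> [1] 1

compartment_density(spots, mask, "cortex")$density
#> [1] 13.99433
compartment_density(spots, mask, "medulla")$density
#> [1] 21.58343

# the headline reconciliation from the measured TI pair
reconcile(ti_hist = 61, ti_flow = 810, flow_tec_count = 1.12e5)
#> <reconciliation_report>
#>   TI histology 61 | TI flow 8.1e+02 | correction factor 13
#>   flow TECs 1.12e+05 -> corrected whole-organ total 1.5e+06
#>   recovery rate 0.075 (ti_ratio_assuming_equal_thymocyte_recovery)
```

The recovered densities sit within ~10% of the preset values (13 and 23
per 10⁴ µm²; a single section carries ~12% Poisson noise on the medullary
count, and pooling sections tightens the estimate — the acceptance run
pools twenty). The reconciliation prints the ≥13-fold
correction factor, the ~1.5×10⁶ corrected TEC total, and the implied
~7.5% TEC recovery through dissociation.

On the flow side:

```r
pop <- default_population_spec("P10")   # survival: thymocytes 1.0, cTEC 0.035, mTEC 0.118
g <- gate(dissociate(pop, seed = 1, scale = 0.01))
g$ti_flow
#> [1] 803.2661
```

the simulated dissociation reproduces the ~810 flow-cytometric TI from a
true TI of ~61 purely through class-specific survival.

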