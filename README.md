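# cartistrain

Full-volume strain analysis of articular cartilage from displacement-encoded
MRI, with the graft-congruity analytics used to study osteochondral
allograft (OCA) transplantation of the patella.

Displacement-encoded (stimulated-echo) MRI acquires complex volumes whose
voxel phase is proportional to tissue displacement: `phi = 2*pi*u/lambda`,
with encoding wavelength `lambda` (1 mm here, so displacements wrap every
0.5 mm). `cartistrain` turns those wrapped, noisy acquisitions into tissue
strain maps and graft-interface metrics:

1. **phase** — Gaussian phasor smoothing, quality-guided 3-D phase
   unwrapping (region growing over a local-variance quality map,
   deterministic tie-breaks), reference-region offset fixing, conversion to
   displacement, vector-field assembly with masked smoothing;
2. **strainfield** — trilinear upsampling to the anatomical grid, cartilage
   meshing (marching tetrahedra surface + Kuhn-lattice tetrahedralization),
   per-element Green-Lagrange tensors `E = (H + H' + H'H)/2` from linear
   shape functions, lumped-mass L2 projection to nodes, principal strains:
   the minimum principal strain `E_min` (most negative eigenvalue) and the
   maximum shear strain `E_maxshear = (E1 - E3)/2`; an independent
   grid-differencing oracle cross-validates the mesh path;
3. **graftmetrics** — top-view maps (column-wise 95th-percentile projection
   along the thickness axis), donor-recipient step-off profiling around the
   graft rim (signed mm; negative = donor subchondral bone recessed),
   matched strain sampling on both sides of the interface, percent change
   `100*(donor - recipient)/recipient`, and descriptive linear fits;
4. **phantom** — a synthetic indentation dataset (flat cartilage slab,
   spherical-indenter displacement bump with exact closed-form strain,
   tilted donor plug, complex-noise encoding at configurable SNR) so the
   entire chain is testable without any scanner data;
5. **volio / cli** — NIfTI, binary STL, VTU and CSV I/O with explicit grid
   geometry, plus a `run_pipeline()` orchestrator and a thin command-line
   script (`inst/cli/cartistrain.R`).

It is written for researchers processing displacement-encoded MRI of
cartilage (or similar soft tissue) who need a tested, reproducible pipeline
from raw complex volumes to strain outcomes and graft-congruity tables.

## Worked example

Simulate a noiseless phantom at the study conditions (0.5 mm compression,
3.9 mm cartilage, 1 mm encoding wavelength, 0.5 mm rim step-off amplitude),
recover the displacement field from the encoded volumes, compute strain, and
profile the graft interface:

```r
library(cartistrain)

spec    <- phantom_spec(compression = 0.5, noise_snr = Inf,
                        stepoff_amplitude = 0.5, seed = 42)
phantom <- generate_phantom(spec, truth_highres = FALSE)

mask <- dilate_mask(phantom$mask_lowres, 3L)
disp <- recover_displacement(phantom$encoded, mask,
                             phantom$ref_region_lowres$values,
                             sigma_complex = c(0, 0, 0),
                             sigma_displacement = c(0, 0, 0))

cart    <- grid_with_values(phantom$labels,
                            array(phantom$labels$values %in% c(1, 3),
                                  dim(phantom$labels$values)))
disp_hr <- upsample_trilinear(disp, cart, extrapolate = "clamp")
dfield  <- assemble_displacement_field(
  lapply(1:3, function(k) grid_with_values(
    cart, array(disp_hr$values[, , , k], dim(cart$values)))),
  cart$values, sigma_vox = c(0, 0, 0))

strain <- grid_strain_oracle(dfield)
ps     <- principal_strains(strain)
e_min  <- principal_outcome_volume(ps, "E_min")
min(e_min$values)
#> [1] -0.1157869

tab <- stepoff_table(phantom$labels,
                     e_min = grid_with_values(e_min, abs(e_min$values)))
head(tab[is.finite(tab$pct_change_Emin), c(1:4, 6)], 4)
#>   slice_index     side stepoff_mm E_min_recipient pct_change_Emin
#> 1          49   distal       0.34        0.000349             317
#> 2          49 proximal      -0.34        0.000349             317
#> 3          52   distal       0.51        0.000414             350
#> 4          52 proximal      -0.34        0.000414             350
```

The peak compressive strain, `-0.116`, sits under the indenter and is within
4% of the phantom's analytic centre-column value
`-(d/t - (d/t)^2/2) = -0.120` at `d = 0.5` mm, `t = 3.9` mm; the remaining
gap is intravoxel dephasing plus interpolation of the coarse in-plane
acquisition. Step-off values are quantized to the 0.17 mm anatomical voxel
and follow the phantom's tilted plug: elevated (positive) on the distal arc,
recessed (negative) proximally. In this phantom the donor side always lies
nearer the indentation axis than the matched recipient sample, so the strain
percent change is large and positive — it reflects the radial decay of the
indentation field, not graft material contrast (the phantom's donor tissue
is mechanically identical).

`percentile_projection()` gives the top-view map (`autoplot()` renders it),
and `stepoff_scatter(tab)` the descriptive percent-change-vs-step-off fits.
`run_pipeline()` chains all stages and writes NIfTI/VTU/CSV products plus a
manifest with input hashes, stage wall times and the seed.

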