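# arbormetrics

Morphometry of arterial centerline trees in R.

Quantitative descriptions of how an arterial tree branches — how much
cross-sectional area is gained at a junction, how symmetric the daughters
are, how long segments are relative to their calibre, whether vessels taper —
are the raw material of hemodynamic models of the cerebral circulation.
`arbormetrics` computes these branching-pattern statistics from centerline
reconstructions (trees of 3D nodes with per-node radii, e.g. traced from
high-field MRI of corrosion casts), and tests whether a tree complies with
the principle of minimum work (Murray's law). It is aimed at anatomists and
vascular modellers working in the 30 µm – 1.6 mm radius range where such
data are scarce.

## The statistics

For a bifurcation with parent radius $r_0$ and daughter radii
$r_1 \ge r_2$:

- **Area ratio** $AR = (r_1^2 + r_2^2)/r_0^2$ (any number of daughters).
- **Asymmetry ratio** $AS = r_2^2/r_1^2 \in (0, 1]$ (bifurcations only).
- **Minimum-work statistic** $n = (r_1^3 + r_2^3)/r_0^3$; $n = 1$ means the
  junction obeys Murray's law $r_0^3 = r_1^3 + r_2^3$.
- **Junction exponent**: the $x$ solving $r_0^x = r_1^x + r_2^x$ (solved
  numerically; 3 for the laminar optimum, 2.33 for fully turbulent flow).

For a segment (the stretch between consecutive branch points) of length $L$
(summed Euclidean node distances): **tapering**
$T = r_\mathrm{distal}/r_\mathrm{proximal}$ and the **length-to-radius
ratio** $LR = L/r_\mathrm{proximal}$. Because node radii dip just before
and after a junction, the end radii are estimated by an ordinary
least-squares line through the radii of the middle two quartiles of each
segment's nodes, evaluated at the segment ends; segments and bifurcations
whose diameters fall below two voxels are excluded.

Tree-level compliance is assessed by regressing
$r_1^3 + r_2^3$ on $r_0^3$ across junctions — a slope of 1 indicates
minimum-work compliance — and the population area ratio by the analogous
squared-radius regression. Both regressions are cleaned by ROUT
(robust Lorentzian fit + false-discovery-rate outlier scan, budget
Q = 1%); distribution summaries are reported as median (n, IQR, range)
with per-parameter ROUT cleaning, except the bounded asymmetry ratio, which
is never outlier-trimmed.

The package also ships a synthetic tree generator (exact minimum-work
junction radii, Beta-distributed asymmetry, log-normal LR, optional taper,
multiplicative node noise, detection-radius censoring) with full ground
truth, and a full-width-at-half-maximum radius estimator for signal-void
volumes, validated on rasterized tube phantoms.

## Worked example

```r
library(arbormetrics)

syn <- generate_tree(generator_config(seed = 42, max_bifurcations = 300,
                                      radius_noise_sd = 0.02))
res <- run_morphometry(list(list(tree = syn$tree, label = "synthetic")))
res
#> Arterial-tree morphometry run (ROUT Q = 1%)
#>     source segments_total segments_included bifurcations_total bifurcations_included
#>  synthetic            601               601                300                   300
#>
#> Parameter summaries (median (n, IQR, range)):
#>   synthetic    AR  1.19 (300, 0.14, 0.93-1.42)
#>   synthetic    AS  0.38 (300, 0.48, 0.00-0.99)
#>   synthetic    LR  9.10 (568, 6.53, 1.83-26.67)
#>   synthetic    T   1.00 (601, 0.05, 0.86-1.12)
#>
#> synthetic: AR slope 1.189 ± 0.001 (R²=1.00); minimum-work slope 1.002 ± 0.000 (R²=1.00)
```

The tree was grown under the exponent-3 minimum-work relation with no
taper, so the pipeline recovers a median tapering of 1.00 and a
minimum-work slope of 1.002 ± 0.0003: the synthetic tree complies with
Murray's law, and the 2% node-radius noise moves the slope only in the
third decimal. The AR slope (1.19) sits between the symmetric laminar
optimum 1.26 and lower values caused by asymmetric junctions. Real trees
are read with `read_swc()` / `read_node_table()` (radius-bearing SWC or CSV
node tables, mm), `censor_tree()` emulates a modality's detection limit,
and `radius_at_node()` estimates radii from image volumes by FWHM.

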