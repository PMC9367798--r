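# lesim — land-use simulation under ecological security constraints

`lesim` is an R toolkit for landscape ecologists and spatial planners who
want to project future land-use patterns while accounting for the
ecological security of the land system. It couples two stages that are
usually run in separate tools:

1. **Land ecological security evaluation.** Per grid unit, a composite
   land ecological security index (LESI) is computed from a
   pressure–state–response (PSR) indicator system by the catastrophe
   progression method (CPM): indicators are standardized to
   `H = (x − min)/(max − min)` (reversed for cost-type indicators),
   ranked by entropy weights, and aggregated bottom-up through a
   hierarchy of catastrophe models — the k-th ranked control variable is
   normalized as `v^(1/(k+1))` (fold √, cusp ∛, swallowtail ∜, butterfly
   fifth root) and combined by the complementary (mean) or
   non-complementary (min) principle. Because raw CPM indices crowd near
   1, the index is re-expressed against the reference levels `n_i`
   obtained by propagating uniform leaf values 0, 0.1, …, 1.0 through the
   hierarchy, and the adjusted index is cut into four ecological zones
   (core ECZ, buffer EBZ, optimization EOZ, urban development UDZ) by
   exact Fisher–Jenks natural breaks.

2. **CA–Markov scenario simulation.** A Markov transition matrix
   estimated from two dated maps sets the quantity of change,
   `s_ij(t+1) = f[s_ij(t), h_ij(t), Q]`: per-class suitability atlases
   `Q` are built by multi-criteria evaluation — Boolean restriction masks
   times a weighted linear combination of fuzzy (min–max) constraint
   factors, with signed weights derived from per-class binary logistic
   regressions on sampled cells — and a cellular automaton allocates the
   projected change over 10 cycles by suitability × 5×5 neighborhood
   contiguity. Under the ecological-protection (EP) scenario the
   ecological core zone is closed to construction and the LESI joins the
   constraint factors; the natural-development (ND) scenario omits both.
   Validation uses full-map confusion matrices and Cohen's kappa
   `(p0 − pe)/(1 − pe)`, plus change and zone accounting tables.

A seeded synthetic-world generator (`synth_spec()`, `synth_landscape()`,
`synth_drivers()`, `synth_indicators()`) emulates co-registered
categorical rasters with contiguous patches, monotone driver surfaces and
mixed-attribute indicator tables, so the full pipeline runs and is tested
without any external data.

## Worked example

```r
library(lesim)
spec <- synth_spec(rows = 120, cols = 120, seed = 7)
lw   <- synth_landscape(spec)        # land-use maps for two dates
drv  <- synth_drivers(spec, lw$t0)   # POP, DR, DRS, DH, DT, SLO, ELE

# 1. ecological security evaluation and zoning
ind  <- synth_indicators(spec, lw$t1)
sec  <- lesi(ind)
br   <- jenks_breaks(sec$adjusted, 4)
uoc  <- attr(ind, "unit_of_cell")
adj  <- units_to_raster(sec$adjusted, uoc, lw$t1)
zone <- classify_zones(adj, br,
                       raw = units_to_raster(sec$raw, uoc, lw$t1)$values)
print(zone)

# 2. fit the change model, simulate an ecological-protection scenario
mod  <- lucc(lw$t0, lw$t1, c(drv, list(LESI = adj)), seed = 42)
atl  <- suitability_atlas(mod$drivers, c(drv, list(LESI = adj)), lw$t1,
                          scenario = "EP",
                          eco_core = zone_mask(zone, "ECZ"))
sim  <- simulate(mod, atlas = atl)

# 3. accounting
change_table(lw$t1, EP = sim$map)
```

which prints

```
<eco_zoning> breaks: 0.3233, 0.3951, 0.464
 zone area_km2 share_pct mean_raw
  ECZ     3.56      27.5    0.964
  EBZ     3.95      30.5    0.956
  EOZ     3.82      29.5    0.947
  UDZ     1.62      12.5    0.937

         class area_base area_EP diff_EP     pct_EP
1     farmland    3.2463  2.8629 -0.3834 -11.810369
2     woodland    5.1156  5.0481 -0.0675  -1.319493
3    grassland    0.4824  0.4464 -0.0360  -7.462687
4        water    1.0368  1.0368  0.0000   0.000000
5 construction    2.8323  3.3318  0.4995  17.635844
6       unused    0.2466  0.2340 -0.0126  -5.109489
```

The zoning table gives each zone's area (km², cells × 900 m²), share of
the study area, and mean raw LESI — decreasing monotonically from ECZ to
UDZ. The change table compares the simulated 10-cycle EP projection with
the base map: construction grows (here +0.50 km², +17.6 %), farmland
supplies most of it, and water is frozen. Every number above is actual
package output.

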