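# growspace

Exhaustive enumeration of small-molecule chemical space and combinatorial
growth of scaffold superstructures, for fragment-based inhibitor design.

Fragment screens sample the space of all chemically stable molecules up
to a heavy-atom limit; fragment elaboration then explores the
superstructures of one scaffold. growspace implements both sides in R:

- **Enumeration** (`enumerate_space`): skeleton graphs (connected, max
  degree 4, planar) → saturated hydrocarbons → 3D strain filter
  (tetrahedral volume < 0.145 Å³ at a quaternary center discards the
  molecule) → combinatorial unsaturation → N/O heteroatom mutation →
  forbidden-motif filter (acyclic N–N, acyclic O–O, cumulated double
  bonds) → functional-group decoration (acids → sulfonic acids, phenols →
  halides), with global canonical-SMILES deduplication.
- **Activation** (`activate_library`, `activate_scaffold`): growing
  vectors marked by tag elements for five connection mechanisms — single
  (Lu), double (Hf), triple (Ta) bond, ring fusion (W), spiro (Re) — with
  hydrogen-budget rules, symmetry-orbit deduplication, and substituent
  shelves keyed by (size, mechanism, chemotype) with compatibility rules.
- **Growth** (`distribute_atoms`, `grow`, `generate_superstructures`):
  all compositions of N added heavy atoms over K tagged sites
  (`choose(N-1, K-1)` of them), Cartesian attachment of compatible shelf
  substituents, optional growing-vector masks.
- **Extrapolation** (`fit_growth_model`, `extrapolate`,
  `coverage_percent`): least-squares fit of
  `log10(cumulative count) = a + b·n_heavy` and order-of-magnitude
  extrapolation of space sizes.
- **Screening support**: constrained SMARTS superstructure patterns
  (`scaffold_pattern`, `substructure_search`), PAINS/exclusion filters
  (`structural_filters`), reaction-based library enumeration
  (`react_enumerate`), greedy docking-rank leader clustering
  (`leader_cluster`, Morgan-type 1024-bit fingerprints, Tanimoto > 0.5),
  and common-core RMSD pose filtering (`core_rmsd_filter`, lowest energy
  with core RMSD < 2 Å among the 50 best-scored poses).

## Worked example

Enumerate chemical space to 7 heavy atoms, fit the growth curve, and
activate the sub-library up to 5 heavy atoms:

```r
library(growspace)

space <- enumerate_space(enumeration_config(7))
space$count_table
#>   n_heavy  count cumulative
#> 1       1      3          3
#> 2       2     10         13
#> 3       3     53         66
#> 4       4    372        438
#> 5       5   2661       3099
#> 6       6  23240      26339
#> 7       7 227869     254208

model <- fit_growth_model(space$count_table, fit_range = c(3, 7))
model
#> <growth_model> log10(N) = -0.9196 + 0.8950 * n_heavy  (n = 5, R^2 = 0.9985)
extrapolate(model, c(11, 13))
#>   n_heavy    estimate order_of_magnitude
#> 1      11   843053354                  9
#> 2      13 51992201407                 11

coverage_percent(1e9, 1e22)   # a 10^9 library over a 10^22 space
#> [1] 1e-11

lib5 <- space$molecules[seq_len(space$count_table$cumulative[5])]
subs <- build_shelves(activate_library(lib5))
subs
#> <substituent_shelves> 13814 substituents in 48 shelves
```

The three molecules at one heavy atom are methane, ammonia and water; the
cumulative counts grow log-linearly (R² ≈ 0.999 over the fit range), which
is what makes order-of-magnitude extrapolation to larger sizes meaningful.
Counts are specific to this package's stability ruleset — published
exhaustive databases use richer exclusion rules and are smaller at the
same size.

Grow superstructures of benzene from a toy shelf:

```r
cfg <- activate_scaffold("c1ccccc1", "single")
nrow(cfg)                       # 12 symmetry-unique configurations
res <- generate_superstructures("c1ccccc1", 1, subs, mechanisms = "single")
head(res$molecules[[1]])        # toluene, phenol, aniline, ...
```

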