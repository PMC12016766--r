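# climvuln

Trait-based climate-change vulnerability assessment (TVA) for terrestrial
mammal faunas, with an audit of how the resulting vulnerability categories
are represented in general wildlife-disease surveillance.

General (scanning) surveillance of wildlife disease examines whatever
carcasses the public happens to find and submit, so it is unclear whether
the species most likely to be stressed by a changing climate — and hence
candidates for disease emergence — are being examined at all. `climvuln`
scores every species in a fauna on three dimensions and crosses the result
with the submission record:

* **Exposure** — the magnitude of climatic change inside the cells a species
  occupies. Per grid cell, climate novelty is the standardized Euclidean
  distance between a baseline and a recent period over six annual
  bioclimatic variables (BIO01, BIO05, BIO06, BIO12, BIO13, BIO14):

  $$\mathrm{SED} = \sum_{k=1}^{6} (b_k - a_k)^2 / s_k^2$$

  with $a_k$, $b_k$ the period means and $s_k$ the baseline interannual SD.
  Cells are terciled into classes 0/1/2; a species' raw exposure is
  $b + 2c$ with $b$, $c$ the percentages of its occupied cells in the middle
  and upper class, max–min rescaled to $[0,1]$ across species.
* **Sensitivity** — body mass, fossoriality, strict diurnality and habitat
  specialism, each scored 0–2 (2 most sensitive).
* **Adaptive capacity** — dispersal distance (migration class as proxy when
  absent), diet breadth, reproductive capacity
  $RC = (L_{\max}-L_{1r})\,LS\,LPY$, and generation length, each scored 0–2
  (2 lowest capacity).

Axis sums are rescaled and the top quartiles flagged; the three flags map to
eight discrete vulnerability categories (1 = highly vulnerable … 8 = low
vulnerability). Surveillance records are filtered by necropsy completeness,
coordinate validity, targeted-project status and date, then cross-tabulated
against orders and categories.

The package includes a synthetic-data generator reproducing the statistical
structure of the real inputs (gridded monthly climate with an optional
edge-localized trend, clustered presence-only occupancy, trait tables,
unequal per-order carcass submissions) and a packaged reference table
assigning 59 Dutch terrestrial mammal species to their vulnerability
categories.

## Worked example

Audit the packaged 59-species table (categories inverted to dimension flags
and re-tallied):

```r
library(climvuln)
fixture_audit()
```

```
Vulnerability audit of the packaged species table
  59 species: 15 exposed (25.4%), 14 sensitive (23.7%), 13 low adaptive capacity (22.0%)
  category tally:
 category                      label  n       pct
        1          highly vulnerable  2  3.389831
        2   biologically susceptible  5  8.474576
        3          potential adapter  3  5.084746
        4        potential persister  2  3.389831
        5               exposed only  8 13.559322
        6             sensitive only  4  6.779661
        7 low adaptive capacity only  4  6.779661
        8          low vulnerability 31 52.542373
  per-order flag counts:
           order n_species n_exposed n_sensitive n_low_ac
       Carnivora        10         1           0        0
 Cetartiodactyla         5         0           0        1
      Chiroptera        18         6          11        8
    Eulipotyphla         8         4           0        3
      Lagomorpha         2         0           0        0
        Rodentia        16         4           3        1
```

Read: of 59 species, 15 are highly exposed, 14 highly sensitive and 13
(22.0%) have low adaptive capacity; bats (Chiroptera) dominate the sensitive
and low-capacity flags, and over half the fauna (31 species) is in the
low-vulnerability category.

Run the full pipeline on synthetic data with a warming trend concentrated on
the eastern grid edge:

```r
cfg <- synthetic_config(seed = 11, trend_gradient = "east", n_species = 12)
run_pipeline(cfg)
```

```
Trait-based vulnerability assessment run
  400 cells, SED mean 3.938 (breaks 1.401 / 4.562)
  12 species: 4 exposed, 3 sensitive, 6 low adaptive capacity
  category tally:
 category                      label n       pct
        1          highly vulnerable 0  0.000000
        2   biologically susceptible 1  8.333333
        3          potential adapter 0  0.000000
        4        potential persister 2 16.666667
        5               exposed only 2 16.666667
        6             sensitive only 2 16.666667
        7 low adaptive capacity only 3 25.000000
        8          low vulnerability 2 16.666667
```

The per-cell SED field, per-species exposure table, trait scores,
assignments and surveillance cross-tabs are in the returned list (and are
written as CSVs when `out_dir` is given). A thin command-line wrapper lives
at `inst/scripts/tva.R` (`run --config run.yaml`, `fixture-audit`).

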