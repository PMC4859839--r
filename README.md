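# pocketEDA

Hydrogen-bond statistics and Hartree–Fock interaction-energy decomposition
for protein–ligand binding pockets.

## The problem

When a ligand sits in an enzyme pocket — the motivating system is a sirtuin
(Sir2-family NAD⁺-dependent deacetylase) active site occupied by the
carba-NAD⁺ analogue ADP-HPD — two questions drive the analysis:

1. **Which contacts hold it there, and how persistently?**  Answered from a
   trajectory: per-bond donor–H···acceptor distance distributions binned
   into 0.25 Å frequency tables, occupancy percentages, and ring–ring
   distances for stacking contacts; then one *representative frame* is
   chosen whose monitored distances all sit in the most-represented
   intervals of their distributions, with the smallest total hydrogen-bond
   length.
2. **What is the physical nature of each contact?**  Answered by
   decomposing the restricted Hartree–Fock interaction energy of each
   residue–ligand dimer:

   ΔE^HF = ε_el^(10) + ΔE_ex^HL + ΔE_del^HF

   — first-order electrostatics (Coulomb interaction of the unperturbed
   monomer charge distributions), Heitler–London exchange (Pauli
   repulsion), and delocalization (induction + charge transfer).  Every
   state is computed in the dimer-centered basis set (partner atoms as
   ghost centers), so all components are free of basis-set superposition
   error by construction.  Hydrogen bonds with a covalency ratio
   ΔE_del^HF/ε_el^(10) above 0.45 are flagged as partially covalent, and
   Spearman rank correlations (ρ = 1 − 6Σd²/(n(n²−1)), no tie correction)
   summarize how the components co-vary across the pocket.

The package is aimed at structural-bioinformatics / molecular-modeling work:
the Gaussian-integral engine (McMurchie–Davidson, Rcpp), the SCF solver and
the decomposition are implemented here — no external quantum-chemistry
program is needed.  A synthetic-trajectory module generates inputs with
prescribed distance statistics so that every stage is testable against
closed forms.

## Worked example

Decompose a hydrogen-bonded water dimer (O···O 3.0 Å, RHF/STO-3G):

```r
library(pocketEDA)
eda_decompose(water_dimer(3.0))
#> HF interaction energy decomposition: water-donor ... water-acceptor (sto-3g, 14 bf)
#>   dE^HL         -0.6083 kcal/mol
#>   e_el^(10)     -6.0526 kcal/mol
#>   dE_ex^HL       5.4442 kcal/mol
#>   dE_del^HF     -1.2387 kcal/mol
#>   dE^HF         -1.8470 kcal/mol
```

The sign pattern is the canonical hydrogen-bond one: attractive
electrostatics (−6.05) partly quenched by exchange repulsion (+5.44), with a
stabilizing delocalization term (−1.24) and a net attraction of
−1.85 kcal/mol; the five numbers satisfy both additivity identities exactly.

Statistics over a per-residue component table (kcal/mol, packaged fixture):

```r
tab <- read_component_table(system.file("extdata", "table2.csv",
                                        package = "pocketEDA"))
correlation_table(tab)   # ligand sub-fragment rows excluded by default
#> Spearman rank correlations (n = 15 complexes)
#>            e_hl e_el_10 e_ex_hl e_del_hf  e_hf
#> e_hl      1.000   0.143   0.586   -0.289 0.596
#> e_el_10   0.143   1.000  -0.514    0.761 0.664
#> e_ex_hl   0.586  -0.514   1.000   -0.811 0.025
#> e_del_hf -0.289   0.761  -0.811    1.000 0.386
#> e_hf      0.596   0.664   0.025    0.386 1.000

covalency_report(tab, labels = c("ILE117", "ALA33", "SER225"))[, -2]
#>    label   e_hf     ratio ratio_2dp     classification
#> 1 ILE117   0.32 0.3549488      0.35      electrostatic
#> 2  ALA33 -16.41 0.5832408      0.58 partially-covalent
#> 3 SER225  -3.80 0.9065534      0.91 partially-covalent
```

Electrostatics and delocalization rank together (ρ = 0.76): the
strongest-bound residues are stabilized by both.  ALA33 and SER225 cross the
0.45 covalency threshold — their hydrogen bonds have partial charge-transfer
character.

## The analysis pipeline

Five numbered drivers under `analysis/` run the whole chain and write their
tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_trajectory.R` | 10⁴-frame synthetic trajectory from the packaged frequency table |
| `02_trajectory_statistics.R` | binned frequency table, occupancies, ring fractions, RMSD |
| `03_select_frame.R` | representative frame (strict criteria + fallback), JSON report, PDB frame |
| `04_dimer_eda.R` | decomposition of water / formamide / salt-bridge model dimers and a water scan |
| `05_component_statistics.R` | correlation matrix and covalency report from the component tables |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_trajectory.R`.

## Package layout

- `R/`, `src/` — trajectory statistics, frame selection, fragment
  extraction, basis sets, SCF, decomposition, rank statistics; C++ integral
  engine.
- `inst/extdata/` — packaged fixtures: the per-residue component table, the
  binned hydrogen-bond frequency table, hydrogen-bond distances, residue
  charges.
- `vignettes/pocket-eda-methods.Rmd` — the model, conventions, numerical
  choices and limitations, in detail.
- `tests/testthat/` — unit, property and acceptance suites (closed-form
  integral oracles, a nonorthogonal-determinant oracle, exhaustive
  selector enumeration).
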