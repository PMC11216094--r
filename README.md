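# halogat

Bond dissociation energies (BDEs) of cyclic hypervalent halogen reagents:
a packaged DFT dataset, cross-halogen linear-dependence analysis, and a
from-scratch graph attention network (GAT) that predicts BDEs directly from
molecular structure.

## The problem

Cyclic hypervalent iodine(III) reagents (benziodoxolones, Togni-type
benziodoxoles, and relatives) are standard electrophilic group-transfer
reagents; their bromine(III) and chlorine(III) analogues are largely
unexplored because many are too unstable to isolate. Two quantities guide
the design of new reagents:

* the **homolytic BDE** of the bond between the halogen(III) center and the
  transfer group (gas phase, kcal/mol) — a proxy for thermal stability;
* the **heterolytic BDE** (acetonitrile, kcal/mol) — a proxy for
  group-transfer ability.

This package is for computational and synthetic chemists who want to
estimate these quantities for new reagents without running quantum
chemistry. It ships DFT-computed (M06-2X/def2-TZVPP) BDE tables for a
combinatorial space of five cyclic skeletons x twenty transfer groups x
three halogen centers: 300 homolytic and 209 heterolytic values.

Two estimation routes are implemented:

1. **Linear-equation (LE) route.** BDEs at different halogen centers of the
   same skeleton/group are linearly related. Ordinary least squares on
   matched pairs with iodine as predictor gives, for homolytic BDEs,

       BDE_Br = 0.89 * BDE_I − 13.85      (R² = 0.79, n = 100)
       BDE_Cl = 0.76 * BDE_I − 26.02      (R² = 0.57, n = 100)

   and for heterolytic BDEs the much tighter

       BDE_Br = 0.96 * BDE_I − 20.49      (R² = 0.997, n = 69)
       BDE_Cl = 0.92 * BDE_I − 29.38      (R² = 0.988, n = 69)

2. **GAT route.** A graph attention network — implemented from first
   principles in R, with hand-derived backpropagation and Adam — regresses
   min–max-scaled BDEs on molecular graphs whose node features are three
   atomic-descriptor blocks: element one-hot, empirical (Gasteiger) partial
   charge + formal charge, and neighborhood composition. One joint model per
   BDE type covers all three halogen centers; halogen identity enters only
   through the atom-level features.

See `vignettes/halogat-methods.Rmd` for the model, its assumptions, all
tunable parameters, and known limitations.

## Worked example

```r
library(halogat)

# Cross-halogen regression on the shipped homolytic table
hom <- bde_table("homolytic")
map <- fit_cross_halogen(hom, "Br")
map
#> <linear_map> homolytic BDE(Br) = 0.89 * BDE(I) -13.85  (R2 = 0.788, n = 100)

# LE estimate for a reagent outside the library: the CF2SO2Ph reagent on the
# benziodoxolone skeleton, whose DFT iodine BDE is 32.6 kcal/mol
predict_from_iodine(round(map, 2), 32.6)
#> [1] 15.164

# GAT: assemble structures, featurize, train on a 9:1 split, evaluate
data <- bde_task_data("homolytic")
sp <- split_dataset(data$records, 0.1, seed = 1)
model <- train_gat(data$graphs, data$targets, gat_config(seed = 1), sp)
evaluate_gat(model, data$graphs[sp$test], data$targets[sp$test])
#> <bde_metrics> R2 = 0.935, MAE = 3.86, RMSE = 4.77 kcal/mol

# Structure-only estimates for reagents outside the library: the fluoro
# reagent on the external sulfonate-bridged skeleton, all three centers
ext <- mol_graphs(c(assemble_smiles(6, "I", "a"), assemble_smiles(6, "Br", "a"),
                    assemble_smiles(6, "Cl", "a")))
round(predict_bde(model, ext), 1)
#> [1] 83.2 62.1 38.6
```

The LE value 15.16 (15.2 at one decimal) predicts that a hypervalent bromine
analogue of the CF2SO2Ph benziodoxolone sits well below the ~20 kcal/mol
isolability threshold. The held-out metrics (R² 0.935 on this split; mean
test R² ≈ 0.94 homolytic / ≈ 0.96 heterolytic over five seeds) describe
reagents drawn from the same skeleton-group space as the training data. For
the external skeleton the GAT reproduces the I > Br > Cl ordering and the
~20 kcal/mol spacing between centers but runs systematically high
(DFT: 68.3, 44.1, 26.2), so for scaffolds outside the library treat GAT
values as rankings and prefer the LE route whenever an iodine BDE is known
(see the vignette's limitations section).

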