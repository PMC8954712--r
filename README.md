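# fragminer

Privileged-fragment mining and imbalance-aware classification of kinase
inhibitor fingerprints.

## The problem

Medicinal chemists optimizing inhibitors of DYRK1A — a kinase target for
neurodegenerative disease — want to know *which substructures make a
compound potent*. Given a compound set with measured IC50 values and
precomputed binary molecular fingerprints (PubChem 881 bits, MACCS 166
bits, ...), `fragminer` provides the full qualitative
structure–activity workflow:

1. **Potency labeling.** pIC50 = 6 − log10(IC50 in μM); compounds with
   pIC50 ≥ 6.0 (IC50 ≤ 1 μM) are potent ("P"), the rest non-potent ("N").
2. **Stratified 3:1 train/test splitting**, seeded and reproducible.
3. **Class balancing** of the training set by SMOTE + Tomek-link
   (SMOTETL), implemented from scratch: synthetic minority rows
   `x_new = x_i + u·(x_nn − x_i)` (binarized at 0.5 to stay valid bit
   vectors), followed by removal of cross-class mutual-nearest-neighbor
   pairs.
4. **A 7-algorithm classifier grid** (SVM, LR, kNN, ANN, NB, RF with 20
   trees of depth 15, DT) under pooled stratified 5-fold
   cross-validation and held-out evaluation.
5. **The standard metric suite** from confusion counts:
   SE = TP/(TP+FN), SP = TN/(TN+FP), CA = (TP+TN)/n,
   MCC = (TP·TN − FP·FN)/√((TN+FN)(TN+FP)(TP+FN)(TP+FP)),
   BA = (SE+SP)/2, and ROC AUC both as Mann–Whitney concordance and as
   trapezoidal ROC integration.
6. **Privileged-fragment mining**: per-bit Shannon information gain
   (base 2) of the class given bit presence, and the class-frequency
   statistic

   ```
   freq(class) = (N_fragment_class × N_total) / (N_fragment_total × N_class)
   ```

   where values > 1 mark over-representation; bits are ranked by IG and
   labeled positive/negative by which class they enrich.
7. **Chemical-space characterization**: Euclidean distance heat
   matrices, descriptor screening (>80% modal value, |r| > 0.95),
   PCA projection, Lipinski rule-of-five profiles.
8. **A seeded synthetic-data generator** that emulates the shape of a
   curated DYRK1A dataset (117 compounds, 89:28 P:N imbalance, 881 bits
   with enriched / constant / correlated structure), so the entire
   pipeline runs and is testable at desk scale with no external data.

## Worked example

```r
library(fragminer)

sim   <- generate_fingerprint_dataset(generator_config(seed = 42))
split <- stratified_split(sim$activity, ratio = "3:1", seed = 42)
split$counts
#>        P  N
#> train 67 21
#> test  22  7

labels <- setNames(sim$activity$potency_class, sim$activity$compound_id)
bal <- smote_tomek(sim$fingerprints[split$train_ids, ],
                   labels[split$train_ids], seed = 42)
bal
#> SMOTE+Tomek resampling result: 134 rows
#>      provenance
#> class original synthetic
#>     N       21        46
#>     P       67         0
#> removed as Tomek-link members: 0

grid <- run_grid(list(SimFP = sim$fingerprints), labels,
                 specs = lapply(c("SVM", "RF", "NB"), algorithm_spec),
                 split = split, balance = TRUE, seed = 42)
rep <- render_tables(grid, head(rank_fragments(sim$fingerprints, labels), 5))
head(rep$models[rep$models$Split == "cv_train", ], 3)
#>     Split     Model   AUC    CA   MCC TP TN FP FN    SE    SP    BA
#>  cv_train  SimFP-RF 0.978 0.940 0.881 63 63  4  4 0.940 0.940 0.940
#>  cv_train  SimFP-NB 0.973 0.903 0.822 67 54 13  0 1.000 0.806 0.903
#>  cv_train SimFP-SVM 0.968 0.910 0.834 67 55 12  0 1.000 0.821 0.911
rep$fragments
#>    Bit    IG         FP        FN Polarity
#>  EB001 0.237 1.292 (58) 0.071 (1) positive
#>  EB007 0.110 1.315 (28) 0.000 (0) positive
#>  EB002 0.108 1.205 (55) 0.348 (5) positive
#>  EB005 0.107 1.279 (36) 0.113 (1) positive
#>  EB004 0.088 1.275 (32) 0.127 (1) positive
```

Reading the output: the 88-compound training set (67 P / 21 N) is
balanced to 67/67 by SMOTETL (46 synthetic non-potent rows, no Tomek
links found at this seed); the balanced random forest classifies the
pooled cross-validated training set with CA 0.940 and MCC 0.881; and the
generator's planted enriched bits are recovered at the top of the
fragment ranking — `EB001` is present in 58 potent vs 1 non-potent
compound, giving the largest information gain (0.237) and a potent-class
frequency of 1.292.

An end-to-end run (simulate → label → split → balance → train-eval →
mine → report, with a digest-stamped manifest) is one call:

```r
run_pipeline(list(seed = 1), out_dir = "run1")
```

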