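# selcarb

Selective prediction of protein carbonylation sites with cross-prediction
control.

Protein carbonylation is an oxidative post-translational modification of
lysine (K), arginine (R), proline (P) and threonine (T) residues.
Sequence predictors of carbonylation sites habitually confuse them with
**ligand interaction sites** — functional residues of the same four types
whose sequence neighbourhoods look far more like carbonylation sites than
nonfunctional residues do. `selcarb` is for bioinformaticians who need a
carbonylation-site predictor that is *selective* (low cross-prediction of
ligand sites), and for method developers who need an evaluation framework
in which cross-prediction is measured rather than hidden inside a pooled
false-positive rate.

The package provides:

* **Segment machinery** — per-residue three-way annotation I/O (FASTA +
  TSV), sliding-window extraction of 27-residue segments centred on
  K/P/R/T with `'X'` terminal padding, central cropping to any odd window,
  stratified seeded splits.
* **Feature channels** — 10 binary physicochemical properties per residue
  (editable TSV), PSSM windows from protein-level profiles, and per-residue
  embeddings through a pluggable provider with a two-layer reducer to 10
  dimensions.
* **Motif discovery** — wildcard patterns (length 4–10) filtered at a 5%
  occurrence threshold and ranked by information gain ratio
  `IGR = IG(true labels) / IG(permuted-label null)`, averaged over ten
  negative replicates; motifs categorised highly (IGR > 10), moderately
  (2–10) or marginally (1–2) favoured; a cumulative-IG motif scorer as a
  baseline predictor.
* **A two-module attention network** — a transformer block (3 layers,
  multihead self-attention) over the PSSM window plus CNN-1D/CNN-2D
  branches (kernel 2, batch norm, ReLU, max-pool, dropout 0.5) over the
  physicochemical window, in two structurally identical modules: a ligand
  interaction module pretrained with BCE and then **frozen**, and a
  carbonylation module, fused by a four-layer FCNN with sigmoid output.
  Pure base-R implementation with hand-derived, finite-difference-verified
  backpropagation and Adam.
* **A class-specific focal loss**
  `−(1−p)^r·l_c·log p − α·p^r·l_n·log(1−p) − β·p^r·l_i·log(1−p)`
  whose `β` term prices cross-prediction of ligand sites, with the printed
  grid-selection rule (max AUROC within 0.02 of the minimum AUCPC).
* **Cross-prediction-aware evaluation** — SN/SP/ACC/F1/MCC, CPR/OPR and
  their random-calibrated ratios, ROC/PR/CP/OP curves with AUROC, AUPRC,
  AUCPC and AUOPC, partial-AUC ratios (AULC, AULCratio) at low FPR,
  threshold optima, and a stratified-bootstrap significance protocol
  (Anderson–Darling-gated t / Wilcoxon rank-sum tests).
* **A seeded synthetic-data generator** for all of the above: realistic
  class imbalance, planted carbonylation motifs, an aromatic ligand halo,
  and a shared motif slice that makes the two positive classes confusable
  — so every stage is testable without any external database.

## Worked example

Simulate an annotated proteome, discover carbonylation motifs, and
evaluate the motif-based baseline with cross-prediction-aware metrics:

```r
library(selcarb)

cfg <- simulation_config(n_proteins = 120, seed = 7)  # ~2% carb / 5% ligand
proteins <- simulate_proteins(cfg)
segments <- extract_all_segments(proteins, "K", 27L)
table(segments$label)
#> carbonylation        ligand nonfunctional
#>            26            97          1624

model <- discover_motifs(segments, q = 10, seed = 7)
head(model$motifs, 5)
#>   pattern  ig_cs ig_ncs_mean   igr   category
#> 1    KRKM 0.0696     0.00570 12.21     highly
#> 2   KRKME 0.0778     0.00684 11.38     highly
#> 3    RKME 0.0668     0.00765  8.74 moderately
#> 4   LRTGK 0.0659     0.01641  4.02 moderately
#> 5    RTGK 0.0659     0.01641  4.02 moderately

scores <- motif_score(crop_segments(segments, 13L)$window, model)
report <- evaluation_report(scores, segments$label)
sprintf("AUROC %.3f  AUCPC %.3f  AUOPC %.3f",
        report$AUROC, report$AUCPC, report$AUOPC)
#> "AUROC 0.717  AUCPC 0.310  AUOPC 0.281"
report$aulc$FPR10$AULCratio
#> 8.61
```

The generator planted `RKME` and `LRTG` next to carbonylation sites; the
discovery stage recovers them (and close variants) as highly/moderately
favoured motifs. The motif baseline's AUROC of 0.72 comes almost entirely
from the minority of segments containing a motif — hence the AULCratio of
8.6: at low false-positive rates it is ~9× better than random. AUCPC ≈
0.3 (< 0.5) shows it cross-predicts ligand sites *less* than a random
scorer, since part of the motif vocabulary is shared.

The full network workflow is one call per stage:

```r
run_simulate(cfg, "data/")                       # FASTA + TSV + PSSMs + manifest
run_train("data/", "model/", residue_type = "K", # pretrain LISPM, freeze,
          lp = loss_params(r = 2, alpha = 2,     # train fused model under
                           beta = 12))           # the custom loss
run_predict("model/checkpoint.rds", "data/proteins.fasta",
            "preds.tsv", pssm_dir = "data/pssm")
run_evaluate("preds.tsv", "data/proteins.fasta", "data/annotations.tsv",
             "report.json")
```

`run_ablate()` retrains with one design element removed (`no-embedding`,
`fcnn-for-attention`, `no-transfer`, `bce-loss`, `l2-loss`);
`window_search()` and `loss_grid_search()` reproduce the window-size and
(α, β) selection harnesses. The same workflows are reachable from a shell
via `inst/cli/selcarb <command>`.

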