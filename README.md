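# rnadecoy

Detection of non-homologous contaminants ("decoys") in small sets of
putative homologous structured RNAs.

## The problem

Predicting a conserved RNA secondary structure from a set of homologs is
far more accurate than folding a single sequence — but it presumes the set
really is homologous. Early in the curation of an RNA family, when no
trusted covariance model exists yet, contaminant sequences picked up by
sequence scans, synteny or manual curation can slip in, degrade the
consensus prediction, and propagate into databases. `rnadecoy` is for
curators at exactly that stage: it takes a FASTA of 5–20 putative
homologs, runs an iterative consensus-folding analysis of the group, and
reports for every sequence the probability that it does not belong.

## The method

Each sequence is folded by an exact partition-function calculation under a
simplified per-pair energy model, giving base-pair probabilities P(i,j)
and the pairing-status marginals P<, P>, Po (partner 5', partner 3',
unpaired) per position. Pairwise alignments come from a pair-HMM whose
match emissions include the structural match score

    p(i,k) = a1 (P<m P<n + P>m P>n) + a2 (Pom Pon) + a3,
    a1 = 1.0, a2 = 0.8, a3 = 0.5.

Alignment posteriors π(i,k) carry pairing information between sequences as
*extrinsic information*,

    E(i,j) = mean over n ≠ m of Σ_{k<l} π(i,k) π(j,l) Pn(k,l),

which multiplies each pair's Boltzmann weight by (1 + γ·E(i,j)) in the
next folding round. After three such iterations a progressive multiple
alignment is built from consistency-transformed posteriors.

Six features per sequence feed a boosted-stump (AdaBoost-style)
classifier: the Kullback–Leibler divergence of the sequence's triangular
465-bin (PS, US) pairing/unpairing-score histogram from the mean histogram
of the others; the Z-score of its ensemble folding free energy; its mean
sequence Shannon entropy in the alignment; and its structural Shannon
entropy before and after consensus refinement plus the difference.
Homologs agree with the group on pairing status column by column — decoys
do not, and the features make that visible. ROC machinery (`roc_curve()`)
reports AUC and the sensitivity at a 5% false-positive rate, the
conventional operating point.

Because real curated families cannot ship with the package, a simulator
(`generate_family()`, `build_corpus()`) creates Rfam-like families —
random nested consensus structures, compensatory evolution at paired
positions, identities 0.5–0.8, lengths 40–120 nt — and assembles labeled
training/test corpora with shuffled and cross-family decoys, with train
and test families disjoint.

## Worked example

```r
library(rnadecoy)

# an Rfam-like family of 9, contaminated with one partially shuffled decoy
fam <- generate_family(length = 80, n_members = 10, target_identity = 0.65,
                       family_id = "demo", seed = 42)
dec <- shuffle_decoy(fam$seqs[10], keep_fraction = attr(fam, "mean_identity"),
                     id = fam$ids[10], seed = 42)
grp <- rna_group(c(fam$seqs[1:9], dec$seqs), ids = c(fam$ids[1:9], dec$ids))

res <- run_turbo(grp)          # iterative consensus folding, 3 iterations
feature_table(res)[, c("id", "kl_score", "z_score", "ss_delta")]
```

```
                  id  kl_score      z_score  ss_delta
1           demo_m01 0.1538366 -0.002351612 0.1996582
2           demo_m02 0.2425022  3.310942057 0.1789444
3           demo_m03 0.1473170 -0.109429262 0.2110658
4           demo_m04 0.1706357 -2.638359723 0.1668948
5           demo_m05 0.1686292  0.447297056 0.1907398
6           demo_m06 0.1310404  0.230225736 0.1863802
7           demo_m07 0.2361257 -0.342693284 0.1123902
8           demo_m08 0.1576344 -0.755979114 0.1350154
9           demo_m09 0.1809588 -0.523199923 0.2166441
10 demo_m10_shuffled 0.2920704  0.794322505 0.1862694
```

The shuffled decoy (`demo_m10_shuffled`) has the highest `kl_score` in the
group: its pairing-status histogram diverges most from the others'. No
single feature is decisive on its own — that is exactly why six of them
feed a trained classifier. With a
trained classifier, `classify_group(model, res)` turns these features
into a decoy probability per sequence and a verdict at the chosen
threshold (default 0.4971 — an operating point at 5% false positives that
should be re-derived for any retrained model), and `write_report()` saves
the table.

A command-line front end covers the same pipeline:

```sh
decoyscan simulate --out corpus --seed 1
decoyscan train    --corpus corpus --model model.tsv
decoyscan classify --in group.fasta --model model.tsv --out report.tsv
decoyscan evaluate --corpus corpus --model model.tsv
```

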