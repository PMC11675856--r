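# mitochar

Comparative characterization of animal mitochondrial genomes in R.

Mitogenome papers all report the same family of statistics: per-partition
base composition with AT/GC strand skews, codon usage and relative
synonymous codon usage (RSCU) under the vertebrate mitochondrial code,
a gene-by-gene ledger of intergenic spacers (IGS) and overlaps on the
circular molecule, control-region domain structure with its conserved
motifs (goose hairpin, ETAS, CSB), pairwise Ka/Ks to detect selection, and
distance-based phylogenies with clock-dated nodes. `mitochar` implements
that whole battery as composable, pipe-friendly functions returning
tibbles, so a full characterization — or a side-by-side comparison of two
genomes — is a few lines of code, and ships seeded synthetic-genome and
sequence-evolution generators so every stage can be tested against known
ground truth without downloading anything.

The core quantities, in the field's notation:

- AT skew = (A − T)/(A + T), GC skew = (G − C)/(G + C)
- IGS = downstream start − upstream end − 1 (negative = overlap), with
  circular closure Σ lengths + Σ IGS = genome length
- RSCU(c) = n(c) / (family total / family size), Leu and Ser split into
  their two mitochondrial families
- NG86 Ka/Ks: pathway-averaged Nd/Sd over stop-free mutational orderings,
  fractional site counts N + S = 3 × codons, Jukes–Cantor correction
  d = −(3/4)·ln(1 − 4p/3); ratio < 1 purifying, > 1 positive
- K2P distance d = −½·ln((1 − 2P − Q)·√(1 − 2Q)); NJ / UPGMA trees; strict
  clock: node age = depth / rate, rate fit to fossil calibrations

A 38-feature ring-necked pheasant (*Phasianus colchicus*) annotation and
its published per-partition composition ship as plain-text fixtures and
serve as the default template of the synthetic generator.

## Worked example

```r
library(mitochar)
library(dplyr)

# the bundled pheasant annotation: 38 features over 16,696 bp
g <- read_feature_table(pheasant_feature_table())
adjacency_ledger(g) |> filter(igs < 0 | igs > 5)
#>    upstream      downstream      igs overlap_motif
#>  1 tRNA-Phe      12S rRNA         -1 NA
#>  2 16S rRNA      tRNA-Leu(UUR)    -1 NA
#>  3 tRNA-Leu(UUR) ND1              11 NA
#>  4 tRNA-Ile      tRNA-Gln          6 NA
#>  5 tRNA-Gln      tRNA-Met         -1 NA
#>  6 COI           tRNA-Ser(UCN)    -9 NA
#>  7 ATP8          ATP6            -10 NA
#>  8 ATP6          COIII            -1 NA
#>  9 ND4L          ND4              -7 NA
#> 10 tRNA-Pro      ND6               6 NA
```

The ATP8/ATP6 and ND4L/ND4 rows are the two long overlaps characteristic
of pheasant-like mitogenomes (10 and 7 bp; motifs are extracted when a
sequence is attached). The whole-genome skews from the published
composition percentages:

```r
tab <- readr::read_tsv(pheasant_composition_table(), show_col_types = FALSE)
m <- tab[tab$partition == "Mitogenome", ]
round(skew(m$pct_a, m$pct_t), 4)  # 0.0958   (A-rich)
round(skew(m$pct_g, m$pct_c), 4)  # -0.3981  (strongly C-skewed)
```

A synthetic genome realizes the same layout with known truth, and the
codon machinery reproduces the published total of 3,796 codons for the 13
protein-coding genes:

```r
sim <- generate_genome(seed = 1)
pcg <- filter(sim$genome$features, type == "PCG")
cds <- vapply(seq_len(nrow(pcg)),
              function(i) extract_feature_sequence(sim$genome, pcg[i, ]),
              character(1))
usage <- rscu(codon_tally(cds))
sum(usage$count)
#> [1] 3796
```

Ka/Ks on a pair of sequences evolved with dN/dS = 0.2 recovers the
generating ratio:

```r
pair <- evolve_codon_pair(
  evolve_params(t = 0.3, kappa = 1, omega = 0.2, n_codons = 5000), seed = 1)
glance(ng86_kaks(pair$cds1, pair$cds2))
#>       ka    ks ratio class     n_codons
#>   0.0357 0.193 0.185 purifying     5000
```

`characterize_run(genome, out_dir)` writes the full report bundle
(annotation, ledger, composition, codon usage/RSCU, control-region
annotation, JSON summary, manifest); `compare_run()` produces the
side-by-side tables plus a per-gene Ka/Ks table for two genomes.
`plot_rscu()`, `plot_skew()`, and the `autoplot()`/`tidy()`/`glance()`
methods cover the usual figures and tidy summaries. The methods vignette
(`vignettes/mitochar-methods.Rmd`) documents the models, conventions, and
design choices.

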