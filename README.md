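# semvar

Corpus-based measures of lexical-semantic ambiguity from latent semantic
analysis, for psycholinguists and computational linguists who need
per-word ambiguity predictors (for naming / lexical-decision modelling)
or want to study how homonymy and polysemy differ distributionally.

Given a pre-segmented corpus (whitespace tokens; one document per line or
per file), `semvar` builds an LSA space and computes, per word:

- **CD** — contextual diversity: the number of ~150-token contexts the
  word occurs in, and its base-10 log;
- **SemD** — semantic diversity: `-log10` of the mean pairwise cosine
  between the word's context vectors (high = used in mutually dissimilar
  contexts);
- **SemVar** — semantic variability: the word's context vectors are
  clustered by spherical k-means, with the cluster count picked as the
  smallest k achieving 90% of the attainable SSE reduction, and SemVar is

  ```
  SemVar(w) = mean within-cluster cosine distance
              ------------------------------------
              mean between-centroid cosine distance
  ```

  Low SemVar = tight, well-separated context clusters (homonym-like);
  high SemVar = one diffuse overlapping cloud (polyseme-like). This is
  the substructure signal a plain similarity average cannot see: a
  two-cluster word and a diffuse-cloud word can have identical SemD.
- **SemVarRes** — the residual of SemVar after OLS on log CD, i.e. the
  clustering signal orthogonal to context count.

A seeded synthetic-corpus generator plants unambiguous, polysemous, and
homonymous words with known topic structure and matched expected CD, so
the full chain is testable without any licensed corpus.

## Worked example

```r
library(semvar)

# generate a topic-structured corpus with 30 planted homonyms,
# 30 polysemes, 15 unambiguous words; run the whole pipeline; evaluate
sim <- cmd_simulate(synthetic_spec(seed = 42))
sim$report
```

```
Homonym/polyseme separation report

Class means:
       class  n mean_semvar  mean_semd  mean_cd
     homonym 30  0.06678317 0.23590326 60.76667
    polyseme 30  0.11647700 0.09989548 62.06667
 unambiguous 15  0.04921359 0.05451802 29.00000

Rank-sum comparisons (homonym vs polyseme):
 measure statistic     p.value cohens_d rank_biserial
  semvar         0 1.50993e-11 3.992236    -1.0000000
    semd       880 1.07720e-10 2.680118     0.9555556

Stronger separating measure: semvar
```

Planted homonyms score reliably *lower* SemVar than planted polysemes
(two tight unrelated clusters vs one diffuse cloud), at matched mean CD
(~60 contexts each); here every homonym ranks below every polyseme
(rank-biserial −1). The one-sided rank-sum p-value is for the planted
direction. `sim$records` is the full per-word tibble (word, cd, log_cd,
semd, k_best, within, between, semvar, semvar_res, n_contexts_used,
missing_reason); `autoplot(sim$records)` shows the measure
distributions, and `plot_separation(sim$records, sim$truth)` the class
boxplots.

For a real corpus:

```r
corpus <- read_corpus("corpus.txt", layout = "lines") |> preprocess_corpus()
records <- ambiguity_measures(corpus)          # default 150-token chunks,
                                               # 300-dim space, k up to 200
```

or from a shell:

```sh
Rscript inst/cli/semvar.R measures --input corpus.txt --out outdir --seed 1
Rscript inst/cli/semvar.R simulate --out simdir --seed 1
```

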