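---
title: "SAGE tag quantification, fold-change screening and qPCR validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SAGE tag quantification, fold-change screening and qPCR validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagescope)
```

## The measurement model

Serial analysis of gene expression (SAGE) quantifies a transcriptome by
counting short cDNA tags anchored at a restriction site rather than by
shotgun sequencing of whole transcripts. NlaIII cuts at `CATG`; library
construction captures, for each polyadenylated transcript, the fragment
downstream of the **3'-most** `CATG`, so each transcript contributes one
tag species and a gene's tag count is proportional to its transcript
copy number. `sagescope` implements the full analysis chain for this
design:

1. **Virtual tag database** (`extract_virtual_tags`): for each reference
   transcript, locate the 3'-most `CATG` on the sense strand and take the
   anchor plus the next `tag_length - 4` bases. Transcripts with no
   anchor, with too little downstream sequence at the 3'-most anchor, or
   with an `N` inside the tag window contribute nothing and are tallied.
   Ambiguity is assessed at the *gene* level: a tag produced by several
   transcripts of one gene is a single unambiguous entry, while a tag
   shared across genes is flagged and later refused.
2. **Assignment** (`match_tag`, `count_library`): observed tags are first
   looked up exactly; exact misses are searched against the whole
   database within a Hamming-distance allowance (default 2 mismatches,
   the conventional tolerance for tag mapping). Among hits within the
   allowance, only minimal-distance hits vote on the gene; tags whose
   minimal-distance hits span several genes are discarded as ambiguous.
   An exact hit always beats any mismatch hit, so the hash-first search
   is exactly equivalent to a full scan.
3. **Normalization**: tags per million (TPM), computed over the total of
   *assigned* tags only — the denominator a study reports as "uniquely
   mapped" tags. Every non-empty profile satisfies
   $\sum_g \mathrm{TPM}_g = 10^6$.
4. **Differential expression** (`fold_change`, `select_de`): with one
   unreplicated library per condition there is no within-group variance,
   so genes are screened by fold change with an abundance floor, not by a
   p-value. The ratio is treated/control TPM; when a gene is unobserved
   in exactly one library, one tag is assumed to have been seen there, so
   the zero is replaced by `tpm(1, total)` of that library (0.2 TPM in a
   five-million-tag library) — a pseudo-count that scales with library
   depth rather than a fixed constant. Genes unobserved in both libraries
   have no defined ratio and are skipped. Defaults: TPM strictly greater
   than 10 in at least one library, fold magnitude $\max(FC, 1/FC) \ge 2$.
5. **Gene-set over-representation** (`fold_enrichment`, `hypergeom_p`,
   `enrich`): for a DE list of size $n$ from a background of $N$ genes,
   a set with $M$ background members and $m$ DE members has fold
   enrichment $(m/n)/(M/N)$ and an exact upper-tail hypergeometric
   p-value $P(X \ge m)$. Gene sets are user-supplied (GMT); no annotation
   database is bundled.
6. **qPCR validation** (`genorm_m`, `normalization_factor`, `ddct`,
   `validate_panel`): candidate reference genes are ranked by the classic
   geNorm stability value $M_j$ — the mean over partner genes $k$ of the
   standard deviation across samples of the pairwise log2 ratio of
   relative quantities $2^{-Ct}$. Normalization uses the geometric mean
   of the chosen references, equivalently the arithmetic mean of their Ct
   values on the log2 scale. A target's expression change in a treated
   sample is $-\Delta\Delta Ct = \overline{\Delta Ct}_{\mathrm{control}}
   - \Delta Ct_{\mathrm{sample}}$ with $\Delta Ct = Ct_{\mathrm{target}}
   - \overline{Ct}_{\mathrm{refs}}$, i.e. a log2 fold change under the
   assumption of perfect doubling per cycle. Panels are validated by
   counting individuals whose log2 fold change reaches a fold threshold,
   and compared across treatments by agglomerative clustering.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tag_length` | 27 nt | anchor (4) + 23 downstream bases, the long-tag scale of ligation-based sequencers; configurable because different SAGE chemistries produce 14–27 nt tags |
| `max_mismatch` | 2 | Hamming allowance for tag assignment |
| `tpm_min` | 10 TPM | abundance floor, roughly 3 transcript copies per cell; strictly `>` by default, `tpm_strict = FALSE` flips to `>=` |
| `fc_min` | 2 | fold-magnitude cutoff; `>=` by default, `fc_strict = TRUE` makes it strict |
| `alpha` | 0.05 | raw-p significance cutoff for enrichment; Benjamini–Hochberg behind `adjust = TRUE` |
| `fold_threshold`, `min_individuals` | 2, 5 | per-individual validation calls |
| qPCR efficiency | fixed 2.0 | implied by the pure $-\Delta\Delta Ct$ form |
| clustering | Pearson distance, average linkage | heatmap-viewer conventions; Euclidean available |

Three conventions were genuinely open and are package decisions rather
than inherited ones. First, a transcript whose 3'-most anchor leaves too
little downstream sequence contributes *no* tag rather than falling back
to an earlier anchor, because the physical library only captures the
3'-most fragment; `fallback = TRUE` restores the permissive behaviour.
Second, mismatch assignment resolves ties by minimal distance only, and
discards tags whose minimal-distance hits span genes — the bounded search
can create ambiguity that exact matching never sees, and silently picking
a winner would bias counts toward gene families. Third, the per-individual
validation call uses a fold cutoff (log2 FC at or above `log2(2)`)
rather than a per-gene t-test; both are available (`group_ttest`), and
the choice is recorded in the output rather than asserted as the only
reasonable one.

## What the simulators emulate — and what they do not

`simulation_manifest()` fixes the study conditions: 2,000 genes, two
libraries of $2\times10^6$ tags, a log-normal abundance spectrum with
`sdlog = 3.5` (about a tenth of genes above 100 TPM carrying the bulk of
the tag mass, the skew characteristic of liver transcriptomes), 50 genes
spiked 4-fold up and 50 spiked 4-fold down, uniform per-base substitution
errors at $10^{-3}$, and per-individual qPCR tables with 0.25-cycle noise
and 3 technical replicates. The scale is large enough for stable TPM
estimates yet runs in seconds on one CPU; `n_tags_per_library` raises it
to the tens-of-millions-of-tags scale of real libraries.

Spiked effects are planted only in genes at or below 5,000 TPM
(`de_tpm_cap`). TPM is a *relative* measure: multiplying a transcript
that already carries half the library by four does not produce a
four-fold TPM change — it produces a global renormalization in which
every other gene appears down-shifted. Such global mRNA-content shifts
are real biology but are unidentifiable from relative-abundance data,
so the generator keeps the planted truth inside the space the estimator
can represent. The truth table records both the spiked effect and the
TPM-scale fold change (`true_fc_tpm`), whose small residual difference
is the compositional shift the renormalization still induces.

The simulators deliberately omit several features of real data: no
indels (the matcher is Hamming-based, so substitutions are the relevant
error mode), no PCR duplication or amplification bias, no quality
scores, one transcript per gene (gene-level ambiguity is exercised by
explicit fixtures instead), and no biological covariance between genes.
Passing recovery tests therefore shows that the *estimator* is correct
under its own measurement model, not that the model captures every
artefact of a real sequencing run.

## Numerical choices and degenerate inputs

- TPM conservation is checked to relative $10^{-6}$; the pseudo-count is
  applied per library from that library's own total.
- `fold_change(0, 0, ...)` is `NA` and the gene is excluded from DE
  evaluation and from fold-change-versus-abundance plots.
- The hypergeometric tail is computed by `phyper(m − 1, ...)`, exact in
  double precision; the EASE-style conservative variant substitutes
  `m − 1` for `m`.
- Replicate Ct values are averaged on the Ct (log) scale before any
  ratio, the standard instrument-software behaviour; missing
  (gene, sample) cells are an error naming the gap rather than a silent
  `NA`.
- `group_ttest` reports the degenerate zero-variance case explicitly
  (p = 1 for identical constant groups) instead of erroring mid-panel.
- Tag iteration and output tables are sorted lexicographically so repeat
  runs are byte-identical; all simulators are deterministic given the
  manifest seed, with fixed per-stage seed offsets.

## Worked example

```{r example}
man <- simulation_manifest(seed = 11, n_genes = 300,
                           n_tags_per_library = 2e5,
                           n_de_up = 10, n_de_down = 10)
tr <- simulate_transcriptome(man)
ab <- simulate_abundances(man)
db <- extract_virtual_tags(tr$transcriptome, man$tag_length)
prof_c <- count_library(simulate_library(tr$truth, ab, man, "control")$tags,
                        db, 2, "control")
prof_t <- count_library(simulate_library(tr$truth, ab, man, "treated")$tags,
                        db, 2, "treated")
de <- select_de(prof_c, prof_t)
de
```

```{r qpcr}
fc <- c(frh3 = 2.5, mgst1 = 1.8, cmbl = 0.4)
sim <- simulate_ct(fc, references = c("rnf7", "rplp2", "rpl13a"),
                   n_individuals = 9, manifest = man)
panel <- panel_log2fc(sim$ct, names(fc), c("rnf7", "rplp2", "rpl13a"))
validate_panel(panel, fold_threshold = 2, min_individuals = 5)
```

## Known limitations

- Tag mapping is transcript-space only; tags spanning splice junctions
  absent from the reference, antisense tags, and genome-level mapping
  are out of scope.
- No replicate-aware DE statistics: the fold-change screen is the
  appropriate tool for single pooled libraries, and its false-call
  behaviour is characterized on simulations, but it cannot separate
  biological variability from treatment effect.
- The enrichment engine tests user-supplied sets only; results depend
  entirely on the supplied annotation and background, and no ortholog
  mapping is attempted.
- qPCR efficiency is fixed at 2.0; per-gene efficiency calibration would
  require standard-curve data the Ct table format does not carry.
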