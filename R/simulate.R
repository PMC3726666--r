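# Ground-truth simulators for every pipeline stage: transcriptomes with
# planted tags, tag libraries with a skewed abundance spectrum and
# substitution errors, gene sets with planted enrichment, and qPCR Ct
# tables with known fold changes. Every generator is deterministic given
# the manifest seed; sub-generators use fixed small offsets from it so the
# same manifest reproduces every byte.

#' Simulation manifest
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' emulate the study scale the pipeline targets: two SAGE libraries with a
#' heavily skewed log-normal abundance spectrum in which roughly a tenth of
#' genes sit above 100 TPM yet carry the bulk of all tags, spiked
#' differential effects of at least two-fold in both directions, uniform
#' per-base substitution errors within the matcher's tolerance, and
#' replicated per-individual Ct measurements for targets and references.
#' Library size defaults to 2e6 tags over 2,000 genes — a scale with stable
#' TPM estimates that runs in minutes on one CPU; `n_tags_per_library` can
#' be raised to the multi-million-tag scale of real libraries.
#'
#' @param seed integer seed; fully determines every generated byte.
#' @param n_genes number of genes (one transcript each).
#' @param transcript_length_range min/max transcript length in bases.
#' @param tag_length virtual tag length (anchor included).
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   relative abundance spectrum before renormalization to 1e6 TPM.
#'   The default sdlog 3.5 reproduces the skew described above.
#' @param n_de_up,n_de_down number of genes spiked up / down.
#' @param de_fold linear fold effect applied to spiked genes (up genes get
#'   `de_fold`, down genes `1/de_fold`).
#' @param de_tpm_cap spiked effects are planted only in genes at or below
#'   this control TPM, so the planted fold changes stay representable in
#'   relative-abundance units (see [simulate_abundances()]).
#' @param n_tags_per_library tags drawn per library.
#' @param per_base_error_rate uniform substitution rate per base.
#' @param ct_noise_sd qPCR measurement noise, in cycles.
#' @param ct_replicates technical replicates per (gene, sample).
#' @return list of class `sage_manifest`.
#' @export
simulation_manifest <- function(seed = 20130729L,
                                n_genes = 2000L,
                                transcript_length_range = c(300L, 2000L),
                                tag_length = 27L,
                                abundance_meanlog = 0,
                                abundance_sdlog = 3.5,
                                n_de_up = 50L, n_de_down = 50L,
                                de_fold = 4,
                                de_tpm_cap = 5000,
                                n_tags_per_library = 2e6,
                                per_base_error_rate = 0.001,
                                ct_noise_sd = 0.25,
                                ct_replicates = 3L) {
  stopifnot(n_genes >= 1, de_fold >= 1,
            per_base_error_rate >= 0, per_base_error_rate <= 1,
            ct_noise_sd >= 0, seed < 2^31 - 16)
  structure(as.list(environment()), class = "sage_manifest")
}

# fixed seed offsets per generator so stages are independently reproducible
manifest_seed <- function(manifest, stage) {
  offsets <- c(transcriptome = 0L, abundance = 1L, library_control = 2L,
               library_treated = 3L, gene_sets = 4L, ct = 5L, de = 6L)
  as.integer(manifest$seed) + offsets[[stage]]
}

random_dna <- function(n, len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, "")
}

#' Simulate a reference transcriptome with one planted tag per gene
#'
#' Each gene gets one transcript: a random body ending in a planted anchor
#' plus tail sized exactly for one tag, with the sequence rejection-sampled
#' so the planted anchor is the 3'-most `CATG` with sufficient downstream
#' bases — every record is guaranteed to yield exactly one virtual tag, and
#' the truth table records it.
#'
#' @param manifest a `sage_manifest`.
#' @return list with `transcriptome` (data.frame usable by
#'   [extract_virtual_tags()]) and `truth` (data.frame: `gene_id`,
#'   `true_tag`, `anchor_offset`).
#' @export
simulate_transcriptome <- function(manifest) {
  stopifnot(inherits(manifest, "sage_manifest"))
  set.seed(manifest_seed(manifest, "transcriptome"))
  n <- manifest$n_genes
  L <- manifest$tag_length
  lr <- manifest$transcript_length_range
  gene_ids <- sprintf("g%04d", seq_len(n))
  seqs <- character(n)
  tags <- character(n)
  offs <- integer(n)
  for (i in seq_len(n)) {
    body_len <- sample(seq(lr[1], lr[2]), 1) - L
    repeat {
      body <- random_dna(1, body_len)
      tail <- random_dna(1, L - 4L)
      s <- paste0(body, "CATG", tail)
      # accept only if the planted anchor is the 3'-most qualifying CATG
      hits <- gregexpr("CATG", s, fixed = TRUE)[[1]]
      if (max(hits) == body_len + 1L) break
    }
    seqs[i] <- s
    tags[i] <- paste0("CATG", tail)
    offs[i] <- body_len  # 0-based anchor offset
  }
  list(
    transcriptome = data.frame(
      transcript_id = paste0(gene_ids, ".t1"),
      gene_id = gene_ids, sequence = seqs, stringsAsFactors = FALSE),
    truth = data.frame(gene_id = gene_ids, true_tag = tags,
                       anchor_offset = offs, stringsAsFactors = FALSE))
}

#' True abundance spectrum and differential effects
#'
#' Draws per-gene relative abundances from the manifest's log-normal model,
#' renormalized to 1e6 TPM in the control condition, and assigns spiked
#' fold effects (`de_fold` up, `1/de_fold` down) to disjoint random gene
#' subsets. Treated TPM is the effect-scaled spectrum renormalized back to
#' 1e6, so the mild compositional shift real libraries show is present
#' too; spiking is restricted to genes at or below `de_tpm_cap` because a
#' several-fold change in a transcript that dominates the library would
#' amount to a global mRNA-content change, which TPM — a relative measure —
#' cannot represent, and would distort every other gene's apparent fold
#' change through renormalization alone.
#'
#' @param manifest a `sage_manifest`.
#' @return data.frame: `gene_id`, `effect` (spiked linear fold),
#'   `true_tpm_control`, `true_tpm_treated`, and `true_fc_tpm` (the
#'   TPM-scale fold change including the renormalization shift).
#' @export
simulate_abundances <- function(manifest) {
  stopifnot(inherits(manifest, "sage_manifest"))
  set.seed(manifest_seed(manifest, "abundance"))
  n <- manifest$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n))
  x <- rlnorm(n, manifest$abundance_meanlog, manifest$abundance_sdlog)
  tpm_control <- 1e6 * x / sum(x)
  effect <- rep(1, n)
  # spike only genes below the abundance cap: a multi-fold change in a
  # transcript carrying a large share of the library is a global
  # mRNA-content shift that relative-abundance (TPM) data cannot express
  eligible <- which(tpm_control <= manifest$de_tpm_cap)
  n_de <- manifest$n_de_up + manifest$n_de_down
  if (length(eligible) < n_de) eligible <- seq_len(n)
  de_idx <- sample(eligible, n_de)
  effect[de_idx[seq_len(manifest$n_de_up)]] <- manifest$de_fold
  if (manifest$n_de_down > 0) {
    effect[de_idx[manifest$n_de_up + seq_len(manifest$n_de_down)]] <-
      1 / manifest$de_fold
  }
  treated_raw <- tpm_control * effect
  tpm_treated <- 1e6 * treated_raw / sum(treated_raw)
  data.frame(gene_id = gene_ids, effect = effect,
             true_tpm_control = tpm_control,
             true_tpm_treated = tpm_treated,
             true_fc_tpm = tpm_treated / tpm_control,
             stringsAsFactors = FALSE)
}

#' Simulate one SAGE tag library
#'
#' Draws `n_tags_per_library` tags multinomially from the condition's true
#' abundance spectrum over the planted per-gene tags, then applies
#' independent uniform base substitutions at the manifest error rate (no
#' indels — the matcher is Hamming-based). Returns the tallied tag stream
#' and the per-gene truth.
#'
#' @param transcriptome_truth the `truth` component of
#'   [simulate_transcriptome()] (per-gene planted tags).
#' @param abundances data.frame from [simulate_abundances()].
#' @param manifest a `sage_manifest`.
#' @param condition `"control"` or `"treated"`.
#' @return list with `tags` (data.frame `tag_sequence`, `count`) and
#'   `truth` (abundances joined with the drawn per-gene read counts).
#' @export
simulate_library <- function(transcriptome_truth, abundances, manifest,
                             condition = c("control", "treated")) {
  condition <- match.arg(condition)
  stopifnot(inherits(manifest, "sage_manifest"),
            identical(transcriptome_truth$gene_id, abundances$gene_id))
  set.seed(manifest_seed(manifest, paste0("library_", condition)))
  tpm_col <- paste0("true_tpm_", condition)
  prob <- abundances[[tpm_col]] / 1e6
  n_tags <- manifest$n_tags_per_library
  counts <- as.vector(rmultinom(1, n_tags, prob))
  tag_of_gene <- transcriptome_truth$true_tag
  L <- manifest$tag_length
  p <- manifest$per_base_error_rate

  if (p > 0) {
    p_any <- 1 - (1 - p)^L
    n_err <- rbinom(length(counts), counts, p_any)
  } else {
    n_err <- integer(length(counts))
  }
  clean <- counts - n_err

  err_tags <- character(0)
  if (sum(n_err) > 0) {
    base_tags <- rep(tag_of_gene, n_err)
    err_tags <- mutate_tags(base_tags, L, p)
  }
  clean_df <- data.frame(tag_sequence = tag_of_gene[clean > 0],
                         count = clean[clean > 0],
                         stringsAsFactors = FALSE)
  if (length(err_tags) > 0) {
    tab <- table(err_tags)
    err_df <- data.frame(tag_sequence = names(tab),
                         count = as.integer(tab), stringsAsFactors = FALSE)
    all_df <- rbind(clean_df, err_df)
  } else {
    all_df <- clean_df
  }
  agg <- tapply(all_df$count, all_df$tag_sequence, sum)
  tags <- data.frame(tag_sequence = names(agg), count = as.integer(agg),
                     stringsAsFactors = FALSE)
  tags <- tags[order(tags$tag_sequence), , drop = FALSE]
  rownames(tags) <- NULL
  truth <- abundances
  truth$reads_drawn <- counts
  list(tags = tags, truth = truth)
}

# apply >=1 base substitutions to each tag, conditioned on the per-base
# error model; single-error reads (the vast majority) are vectorized
mutate_tags <- function(base_tags, L, p) {
  n <- length(base_tags)
  pk <- stats::dbinom(1:L, L, p)
  k <- sample.int(L, n, replace = TRUE, prob = pk / sum(pk))
  bases <- c("A", "C", "G", "T")
  one <- which(k == 1)
  if (length(one) > 0) {
    pos <- sample.int(L, length(one), replace = TRUE)
    orig <- substr(base_tags[one], pos, pos)
    shift <- sample.int(3, length(one), replace = TRUE)
    new <- bases[(match(orig, bases) - 1L + shift) %% 4L + 1L]
    substr(base_tags[one], pos, pos) <- new
  }
  for (i in which(k > 1)) {
    pos <- sample.int(L, k[i])
    s <- strsplit(base_tags[i], "")[[1]]
    s[pos] <- vapply(s[pos],
                     function(b) sample(setdiff(bases, b), 1), "")
    base_tags[i] <- paste(s, collapse = "")
  }
  base_tags
}

#' Simulate gene-set collections with planted enrichment
#'
#' Draws `n_sets` gene sets uniformly from the universe; sets named in
#' `planted` instead over-sample the DE list so their expected fold
#' enrichment equals the planted value.
#'
#' @param gene_universe character vector: the background.
#' @param n_sets number of unplanted (uniform) sets.
#' @param de_list the DE gene list enrichment is planted against.
#' @param planted named numeric vector: target fold enrichment per planted
#'   set (values >= 1; 1 means uniform).
#' @param set_size_range min/max set size.
#' @param seed integer seed.
#' @return list with `sets` (named list, GMT-ready) and `truth`
#'   (data.frame `set_id`, `planted_fold`).
#' @export
simulate_gene_sets <- function(gene_universe, n_sets = 20L, de_list,
                               planted = c(planted_4x = 4),
                               set_size_range = c(20L, 100L),
                               seed = 1L) {
  stopifnot(all(de_list %in% gene_universe), all(planted >= 1))
  set.seed(seed)
  N <- length(gene_universe)
  n <- length(de_list)
  non_de <- setdiff(gene_universe, de_list)
  sets <- list()
  for (i in seq_len(n_sets)) {
    M <- sample(seq(set_size_range[1], set_size_range[2]), 1)
    sets[[sprintf("set%03d", i)]] <- sample(gene_universe, M)
  }
  for (id in names(planted)) {
    f <- planted[[id]]
    M <- sample(seq(set_size_range[1], set_size_range[2]), 1)
    # expected DE members under fold enrichment f: m = f * M * n / N
    m <- min(round(f * M * n / N), M, n)
    sets[[id]] <- c(sample(de_list, m), sample(non_de, M - m))
  }
  truth <- data.frame(
    set_id = names(sets),
    planted_fold = c(rep(1, n_sets), unname(planted)),
    stringsAsFactors = FALSE)
  list(sets = sets, truth = truth)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Control individuals get per-gene baseline Ct values plus Gaussian
#' measurement noise per technical replicate; treated individuals get the
#' baseline shifted down by the gene's true log2 fold change (one cycle per
#' doubling). Reference genes are generated with true fold change 0.
#'
#' @param true_log2_fc named numeric vector: true log2 fold change per
#'   target gene.
#' @param references character vector of reference gene ids.
#' @param n_individuals individuals per group.
#' @param manifest a `sage_manifest` (uses `ct_noise_sd`, `ct_replicates`
#'   and the seed); pass `ct_noise_sd` to override the noise.
#' @param ct_noise_sd overrides the manifest noise if not `NULL`.
#' @param baseline_range uniform range for per-gene baseline Ct.
#' @return list with `ct` (long data.frame: `gene_id`, `sample_id`,
#'   `group`, `replicate`, `ct`) and `truth` (per-gene true log2 FC).
#' @export
simulate_ct <- function(true_log2_fc, references, n_individuals = 9L,
                        manifest = simulation_manifest(),
                        ct_noise_sd = NULL, baseline_range = c(18, 28)) {
  stopifnot(inherits(manifest, "sage_manifest"),
            !is.null(names(true_log2_fc)), length(references) >= 1)
  set.seed(manifest_seed(manifest, "ct"))
  sdv <- ct_noise_sd %||% manifest$ct_noise_sd
  reps <- manifest$ct_replicates
  genes <- c(names(true_log2_fc), references)
  fc <- c(true_log2_fc, setNames(rep(0, length(references)), references))
  baseline <- setNames(runif(length(genes), baseline_range[1],
                             baseline_range[2]), genes)
  samples <- c(paste0("C", seq_len(n_individuals)),
               paste0("S", seq_len(n_individuals)))
  groups <- rep(c("control", "treated"), each = n_individuals)
  grid <- expand.grid(gene_id = genes, sample_id = samples,
                      replicate = seq_len(reps), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$group <- groups[match(grid$sample_id, samples)]
  shift <- ifelse(grid$group == "treated", fc[grid$gene_id], 0)
  grid$ct <- baseline[grid$gene_id] - shift + rnorm(nrow(grid), 0, sdv)
  ct <- grid[order(grid$gene_id, grid$sample_id, grid$replicate),
             c("gene_id", "sample_id", "group", "replicate", "ct")]
  rownames(ct) <- NULL
  list(ct = ct,
       truth = data.frame(gene_id = names(fc), true_log2_fc = unname(fc),
                          is_reference = names(fc) %in% references,
                          stringsAsFactors = FALSE))
}

#' Write simulated reads or tag tallies to disk
#'
#' `write_tag_counts` writes the two-column tally; `write_library_fastq`
#' expands tallies into one read per tag occurrence with constant quality
#' (intended for small libraries — tallies are the compact interchange).
#'
#' @param tags data.frame (`tag_sequence`, `count`).
#' @param path destination.
#' @export
write_tag_counts <- function(tags, path) {
  write.table(tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_counts
#' @export
write_library_fastq <- function(tags, path) {
  reads <- rep(tags$tag_sequence, tags$count)
  ss <- Biostrings::DNAStringSet(reads)
  names(ss) <- sprintf("read%06d", seq_along(reads))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write a simulated transcriptome as FASTA
#'
#' Headers carry the gene id as a `gene=` token so [read_transcriptome()]
#' recovers it with the default pattern.
#'
#' @param transcriptome data.frame from [simulate_transcriptome()].
#' @param path destination.
#' @export
write_transcriptome_fasta <- function(transcriptome, path) {
  ss <- Biostrings::DNAStringSet(transcriptome$sequence)
  names(ss) <- sprintf("%s gene=%s", transcriptome$transcript_id,
                       transcriptome$gene_id)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
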