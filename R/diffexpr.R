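# Fold-change differential expression between two unreplicated SAGE
# libraries, with the one-tag pseudo-count for genes unobserved in one
# library, plus abundance-distribution profiling.

#' Fold change between two libraries with the one-tag pseudo-count
#'
#' The ratio of treated to control TPM. When a gene is unobserved in exactly
#' one library, one tag is assumed to have been observed there, i.e. the
#' zero TPM is replaced by `tpm(1, total)` of that library (0.2 TPM at a
#' five-million-tag library) before the ratio is taken. Genes unobserved in
#' both libraries have no defined fold change and return `NA`.
#'
#' @param tpm_treated,tpm_control per-gene TPM values (vectorized).
#' @param total_treated,total_control total mapped tags of each library,
#'   used to size the pseudo-count.
#' @return `tpm_treated / tpm_control` after zero-handling; `NA` where both
#'   inputs are zero.
#' @examples
#' fold_change(1.0, 0, 5e6, 5e6) # 1.0 / 0.2 = 5
#' @export
fold_change <- function(tpm_treated, tpm_control,
                        total_treated, total_control) {
  stopifnot(total_treated > 0, total_control > 0,
            all(tpm_treated >= 0), all(tpm_control >= 0))
  n <- max(length(tpm_treated), length(tpm_control))
  tpm_treated <- rep_len(tpm_treated, n)
  tpm_control <- rep_len(tpm_control, n)
  t_adj <- ifelse(tpm_treated == 0, tpm(1, total_treated), tpm_treated)
  c_adj <- ifelse(tpm_control == 0, tpm(1, total_control), tpm_control)
  fc <- t_adj / c_adj
  fc[tpm_treated == 0 & tpm_control == 0] <- NA_real_
  fc
}

#' Select differentially expressed genes between two libraries
#'
#' Evaluates the union of genes observed in either profile. A gene passes
#' the abundance filter when its TPM exceeds `tpm_min` in at least one
#' library, and the fold-change filter when `max(FC, 1/FC) >= fc_min` (with
#' FC from [fold_change()], pseudo-count applied per library). Only genes
#' passing both filters are returned. By default both comparisons mirror
#' the usual single-library SAGE screen: abundance strictly greater than
#' the cutoff, fold change at least the cutoff; `tpm_strict` and
#' `fc_strict` flip either convention.
#'
#' @param profile_control,profile_treated `sage_profile` objects.
#' @param tpm_min abundance cutoff in TPM (default 10).
#' @param fc_min fold-change cutoff (default 2).
#' @param tpm_strict if `TRUE` (default) the abundance test is `> tpm_min`,
#'   otherwise `>= tpm_min`.
#' @param fc_strict if `TRUE` the fold-change test is `> fc_min`; default
#'   `FALSE`, i.e. `>= fc_min`.
#' @param all_genes if `TRUE`, return every evaluated gene with its filter
#'   flags instead of only the selected ones.
#' @return data.frame of class `sage_de` with columns `gene_id`,
#'   `tpm_control`, `tpm_treated`, `fold_change` (treated/control),
#'   `direction` (`up` iff FC >= 1), `passes_tpm_filter`,
#'   `passes_fc_filter`; attributes `n_up` and `n_down` summarize the
#'   selected set.
#' @export
select_de <- function(profile_control, profile_treated,
                      tpm_min = 10, fc_min = 2,
                      tpm_strict = TRUE, fc_strict = FALSE,
                      all_genes = FALSE) {
  stopifnot(inherits(profile_control, "sage_profile"),
            inherits(profile_treated, "sage_profile"),
            profile_control$total_mapped > 0,
            profile_treated$total_mapped > 0)
  genes <- sort(union(names(profile_control$counts),
                      names(profile_treated$counts)))
  tc <- ifelse(genes %in% names(profile_control$tpm),
               profile_control$tpm[genes], 0)
  tt <- ifelse(genes %in% names(profile_treated$tpm),
               profile_treated$tpm[genes], 0)
  fc <- fold_change(tt, tc, profile_treated$total_mapped,
                    profile_control$total_mapped)
  defined <- !is.na(fc)
  genes <- genes[defined]; tc <- tc[defined]; tt <- tt[defined]
  fc <- fc[defined]

  pass_tpm <- if (tpm_strict) tc > tpm_min | tt > tpm_min
              else tc >= tpm_min | tt >= tpm_min
  mag <- pmax(fc, 1 / fc)
  pass_fc <- if (fc_strict) mag > fc_min else mag >= fc_min

  out <- data.frame(gene_id = genes,
                    tpm_control = unname(tc), tpm_treated = unname(tt),
                    fold_change = unname(fc),
                    direction = ifelse(fc >= 1, "up", "down"),
                    passes_tpm_filter = unname(pass_tpm),
                    passes_fc_filter = unname(pass_fc),
                    stringsAsFactors = FALSE)
  sel <- out$passes_tpm_filter & out$passes_fc_filter
  if (!all_genes) out <- out[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(sel & ifelse(is.na(fc), FALSE, fc >= 1))
  attr(out, "n_down") <- sum(sel & ifelse(is.na(fc), FALSE, fc < 1))
  class(out) <- c("sage_de", "data.frame")
  out
}

#' @export
print.sage_de <- function(x, ...) {
  cat(sprintf("Differentially expressed genes: %d up, %d down\n",
              attr(x, "n_up"), attr(x, "n_down")))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Abundance-category distribution of an expression profile
#'
#' Bins expressed genes by TPM and reports, per bin, the number of gene
#' entries and the fraction of all assigned tags they carry, plus cumulative
#' variants — the distribution that shows a small fraction of highly
#' abundant transcripts carrying most of the transcriptome.
#'
#' @param profile a `sage_profile`.
#' @param bin_edges strictly increasing upper TPM edges; the implied bins
#'   are `(0, e1], (e1, e2], ..., (ek, Inf)`. Default decade edges
#'   `c(0.2, 1, 10, 100, 1000, 1e4)`.
#' @return list of class `sage_abundance` with `bin_edges`,
#'   `entries_per_bin`, `tag_fraction_per_bin`, `cum_entries`,
#'   `cum_tag_fraction` and the underlying `tpm` vector.
#' @export
abundance_profile <- function(profile,
                              bin_edges = c(0.2, 1, 10, 100, 1000, 1e4)) {
  stopifnot(inherits(profile, "sage_profile"),
            all(diff(bin_edges) > 0), all(bin_edges > 0))
  tpm_v <- profile$tpm[profile$counts >= 1]
  cnt_v <- profile$counts[profile$counts >= 1]
  breaks <- c(0, bin_edges, Inf)
  bin <- cut(tpm_v, breaks = breaks, right = TRUE)
  entries <- as.integer(table(bin))
  frac <- as.numeric(tapply(cnt_v, bin, sum, default = 0)) / sum(cnt_v)
  structure(
    list(bin_edges = breaks, entries_per_bin = entries,
         tag_fraction_per_bin = frac,
         cum_entries = cumsum(entries),
         cum_tag_fraction = cumsum(frac),
         tpm = tpm_v),
    class = "sage_abundance")
}

#' Entries above an abundance threshold and the tag fraction they carry
#'
#' @param profile a `sage_profile`.
#' @param threshold TPM threshold `t`.
#' @return list with `n_entries` (genes with TPM > t), `pct_entries`
#'   (percentage of expressed genes), and `tag_fraction` (fraction of all
#'   assigned tags carried by those genes).
#' @export
abundance_above <- function(profile, threshold) {
  stopifnot(inherits(profile, "sage_profile"))
  expressed <- profile$counts >= 1
  above <- expressed & profile$tpm > threshold
  list(n_entries = sum(above),
       pct_entries = 100 * sum(above) / sum(expressed),
       tag_fraction = sum(profile$counts[above]) / sum(profile$counts))
}

#' Fold-change versus abundance scatter points
#'
#' One point per gene with a defined fold change: x is the log2 TPM of the
#' treated library (pseudo-count applied when zero), y the log2 fold change.
#'
#' @param de a `sage_de` table (use `all_genes = TRUE` in [select_de()] for
#'   the full transcriptome picture).
#' @param total_treated treated-library total, used to place the
#'   pseudo-count TPM of genes unobserved in the treated library.
#' @return data.frame with `gene_id`, `log2_tpm`, `log2_fc`.
#' @export
fc_vs_tpm_points <- function(de, total_treated) {
  stopifnot(inherits(de, "sage_de"))
  tt <- ifelse(de$tpm_treated == 0, tpm(1, total_treated), de$tpm_treated)
  data.frame(gene_id = de$gene_id,
             log2_tpm = log2(tt),
             log2_fc = log2(de$fold_change),
             stringsAsFactors = FALSE)
}

#' Write a DE table as tab-separated text with a summary header
#'
#' @param de a `sage_de` table.
#' @param path destination.
#' @export
de_write <- function(de, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sage_de n_up=%d n_down=%d",
                     attr(de, "n_up"), attr(de, "n_down")), con)
  write.table(as.data.frame(de), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
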