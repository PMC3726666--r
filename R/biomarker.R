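# RT-qPCR validation arm: reference-gene stability (geNorm M), geometric-
# mean normalization, minus-delta-delta-Ct fold changes, panel validation,
# dose dependence and hierarchical clustering of fold-change panels.

# A Ct table is long-format: gene_id, sample_id, group, replicate, ct.
check_ct_table <- function(ct_table) {
  stopifnot(is.data.frame(ct_table),
            all(c("gene_id", "sample_id", "group", "ct") %in%
                  names(ct_table)))
  if (any(!is.finite(ct_table$ct))) stop("non-finite Ct values")
  invisible(ct_table)
}

# technical replicates averaged on the Ct scale: genes x samples matrix
ct_matrix <- function(ct_table, genes = NULL, samples = NULL) {
  check_ct_table(ct_table)
  if (!is.null(genes)) ct_table <- ct_table[ct_table$gene_id %in% genes, ]
  if (!is.null(samples)) {
    ct_table <- ct_table[ct_table$sample_id %in% samples, ]
  }
  m <- tapply(ct_table$ct, list(ct_table$gene_id, ct_table$sample_id), mean)
  if (any(is.na(m))) {
    gap <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing Ct for gene '%s' in sample '%s'",
                 rownames(m)[gap[1]], colnames(m)[gap[2]]))
  }
  m
}

#' Reference-gene stability ranking (geNorm M-value)
#'
#' For each candidate reference gene j, the stability measure M_j is the
#' mean, over all other candidates k, of the standard deviation across
#' samples of the pairwise log2 expression ratio of j against k (relative
#' quantities `2^-Ct`, so the log2 ratio of j over k is `Ct_k - Ct_j`).
#' Lower M means more stable expression; genes are ranked ascending by M.
#' Technical replicates are averaged on the Ct scale first.
#'
#' @param ct_table long-format Ct table restricted to (or filtered by)
#'   the candidate reference genes.
#' @param candidates optional character vector naming the candidates; by
#'   default every gene in `ct_table`.
#' @return data.frame of class `sage_stability`: `gene_id`, `M_value`,
#'   `rank`, sorted by rank.
#' @export
genorm_m <- function(ct_table, candidates = NULL) {
  m <- ct_matrix(ct_table, genes = candidates)
  if (nrow(m) < 2) stop("geNorm needs at least 2 candidate genes")
  if (ncol(m) < 2) stop("geNorm needs at least 2 samples")
  genes <- rownames(m)
  M <- vapply(seq_along(genes), function(j) {
    others <- setdiff(seq_along(genes), j)
    # log2 ratio of gene j to gene k across samples is Ct_k - Ct_j
    mean(vapply(others, function(k) sd(m[k, ] - m[j, ]), numeric(1)))
  }, numeric(1))
  out <- data.frame(gene_id = genes, M_value = M,
                    rank = rank(M, ties.method = "first"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sage_stability", "data.frame")
  out
}

#' Per-sample normalization factor from reference genes
#'
#' The geometric mean of the reference genes' relative quantities `2^-Ct`
#' (equivalently `2^-mean(Ct)` across the references), with technical
#' replicates averaged on the Ct scale first.
#'
#' @param ct_table long-format Ct table.
#' @param reference_genes character vector of reference gene ids; all must
#'   be measured in every sample.
#' @return named numeric vector, one factor per sample.
#' @export
normalization_factor <- function(ct_table, reference_genes) {
  stopifnot(length(reference_genes) >= 1)
  m <- ct_matrix(ct_table, genes = reference_genes)
  if (!all(reference_genes %in% rownames(m))) {
    stop("reference gene(s) missing from the Ct table: ",
         paste(setdiff(reference_genes, rownames(m)), collapse = ", "))
  }
  2^(-colMeans(m[reference_genes, , drop = FALSE]))
}

#' Relative expression as minus-delta-delta-Ct
#'
#' Per sample, `dCt = Ct(target) - mean Ct(references)` (the log2-scale
#' counterpart of dividing by the geometric-mean normalization factor).
#' The returned log2 fold change for a treated sample is
#' `-ddCt = mean dCt(control group) - dCt(treated sample)`, assuming
#' perfect amplification efficiency (doubling per cycle).
#'
#' @param ct_table long-format Ct table with a `group` column.
#' @param target_gene gene to quantify.
#' @param reference_genes reference gene ids for normalization.
#' @param treated_samples sample ids to report; default all samples whose
#'   group is not `control_group`.
#' @param control_group group label of the calibrator samples
#'   (default `"control"`).
#' @return named numeric vector of log2 fold changes, one per treated
#'   sample.
#' @export
ddct <- function(ct_table, target_gene, reference_genes,
                 treated_samples = NULL, control_group = "control") {
  check_ct_table(ct_table)
  m <- ct_matrix(ct_table, genes = c(target_gene, reference_genes))
  if (!target_gene %in% rownames(m)) {
    stop("target gene not in Ct table: ", target_gene)
  }
  dct <- m[target_gene, ] - colMeans(m[reference_genes, , drop = FALSE])
  sample_group <- unique(ct_table[, c("sample_id", "group")])
  ctrl <- sample_group$sample_id[sample_group$group == control_group]
  ctrl <- intersect(colnames(m), ctrl)
  if (length(ctrl) == 0) stop("no control-group samples found")
  if (is.null(treated_samples)) {
    treated_samples <- setdiff(colnames(m), ctrl)
  }
  mean(dct[ctrl]) - dct[treated_samples]
}

#' Per-individual fold changes for a panel of target genes
#'
#' Convenience wrapper applying [ddct()] to each target gene, returning a
#' genes x individuals matrix of log2 fold changes.
#'
#' @inheritParams ddct
#' @param target_genes character vector of target gene ids.
#' @return numeric matrix, rows = target genes, columns = treated samples.
#' @export
panel_log2fc <- function(ct_table, target_genes, reference_genes,
                         control_group = "control") {
  rows <- t(vapply(target_genes, function(g) {
    ddct(ct_table, g, reference_genes, control_group = control_group)
  }, numeric(length(unique(
    ct_table$sample_id[ct_table$group != control_group])))))
  rownames(rows) <- target_genes
  rows
}

#' Validate biomarker candidates across individuals
#'
#' A gene is validated when its per-individual log2 fold change reaches the
#' fold threshold in at least `min_individuals` individuals — the
#' "confirmed in at least five individual fish" style of call.
#'
#' @param log2fc genes x individuals matrix of log2 fold changes.
#' @param fold_threshold linear fold-change threshold (default 2, i.e.
#'   log2 FC >= 1).
#' @param min_individuals minimum qualifying individuals (default 5).
#' @return data.frame: `gene_id`, `n_qualifying`, `validated`.
#' @export
validate_panel <- function(log2fc, fold_threshold = 2, min_individuals = 5) {
  stopifnot(is.matrix(log2fc), fold_threshold > 0)
  qual <- rowSums(log2fc >= log2(fold_threshold))
  data.frame(gene_id = rownames(log2fc) %||% seq_len(nrow(log2fc)),
             n_qualifying = as.integer(qual),
             validated = qual >= min_individuals,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dose-dependent response call
#'
#' Flags genes whose mean log2 fold change is strictly larger at the higher
#' dose — a qualitative monotonicity call, with no significance test.
#'
#' @param fc_low per-gene (mean) log2 fold change at the lower dose.
#' @param fc_high per-gene log2 fold change at the higher dose; names must
#'   match `fc_low` if both are named.
#' @return named logical vector.
#' @export
dose_dependence <- function(fc_low, fc_high) {
  if (!is.null(names(fc_low)) && !is.null(names(fc_high))) {
    stopifnot(setequal(names(fc_low), names(fc_high)))
    fc_high <- fc_high[names(fc_low)]
  }
  stopifnot(length(fc_low) == length(fc_high))
  fc_high > fc_low
}

#' Two-sample Student's t-test between treated and control values
#'
#' A thin wrapper around the classical equal-variance two-sided t-test,
#' handling the degenerate case of essentially constant data (p reported as
#' 1 when the groups are identical, 0 otherwise, flagged `degenerate`).
#'
#' @param values_treated,values_control numeric vectors, each of length
#'   at least 2.
#' @return list with `p_value`, `t`, `degenerate`.
#' @export
group_ttest <- function(values_treated, values_control) {
  stopifnot(length(values_treated) >= 2, length(values_control) >= 2)
  res <- tryCatch(
    t.test(values_treated, values_control, var.equal = TRUE),
    error = function(e) NULL)
  if (is.null(res)) {
    same <- isTRUE(all.equal(mean(values_treated), mean(values_control)))
    return(list(p_value = if (same) 1 else 0, t = if (same) 0 else Inf,
                degenerate = TRUE))
  }
  list(p_value = res$p.value, t = unname(res$statistic), degenerate = FALSE)
}

#' Hierarchical clustering of a biomarker fold-change panel
#'
#' Agglomerative clustering of both rows (genes) and columns (conditions)
#' of a log2 fold-change matrix, with Pearson-correlation distance
#' (`1 - r`) and average linkage by default — the conventions of the usual
#' expression-heatmap viewers — or Euclidean distance.
#'
#' @param mat numeric matrix of log2 fold changes, finite entries, at least
#'   2 rows and 2 columns.
#' @param distance `"pearson"` (default) or `"euclidean"`.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return list of class `sage_panel_clust`: the input `matrix` reordered
#'   by the trees, `row_tree` and `col_tree` (`hclust` objects), and
#'   `row_newick` / `col_newick` serializations.
#' @export
cluster_panel <- function(mat, distance = c("pearson", "euclidean"),
                          linkage = "average") {
  distance <- match.arg(distance)
  stopifnot(is.matrix(mat), nrow(mat) >= 2, ncol(mat) >= 2)
  if (any(!is.finite(mat))) stop("panel matrix contains non-finite entries")
  dfun <- function(x) {
    if (distance == "pearson") as.dist(1 - cor(t(x))) else dist(x)
  }
  row_tree <- hclust(dfun(mat), method = linkage)
  col_tree <- hclust(dfun(t(mat)), method = linkage)
  structure(
    list(matrix = mat[row_tree$order, col_tree$order, drop = FALSE],
         row_tree = row_tree, col_tree = col_tree,
         row_newick = hclust_newick(row_tree),
         col_newick = hclust_newick(col_tree)),
    class = "sage_panel_clust")
}

# serialize an hclust as Newick via ape
hclust_newick <- function(h) {
  ape::write.tree(ape::as.phylo(h))
}

#' @export
print.sage_panel_clust <- function(x, ...) {
  cat(sprintf("Clustered panel: %d genes x %d conditions\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  column tree:", x$col_newick, "\n")
  invisible(x)
}

#' Read a long-format Ct table from CSV
#'
#' Expected columns: `gene_id`, `sample_id`, `group`, `replicate`, `ct`.
#'
#' @param path CSV file.
#' @export
read_ct_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_ct_table(df)
  df
}
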