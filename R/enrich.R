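# Gene-set over-representation: fold enrichment (m/n)/(M/N) and the exact
# upper-tail hypergeometric p-value, plus gene-list intersection.

#' Fold enrichment of a gene set in a DE list
#'
#' `(m/n) / (M/N)` where `N` is the background size, `M` the background
#' genes in the set, `n` the DE genes, and `m` the DE genes in the set. A
#' value of 1 means the set is represented in the DE list exactly at its
#' background rate.
#'
#' @param m DE genes in the set.
#' @param n DE genes (in the background).
#' @param M background genes in the set.
#' @param N background size.
#' @return the fold enrichment (0 when `m == 0`).
#' @export
fold_enrichment <- function(m, n, M, N) {
  check_enrich_counts(m, n, M, N)
  (m / n) / (M / N)
}

check_enrich_counts <- function(m, n, M, N) {
  if (any(N <= 0) || any(M <= 0) || any(n <= 0) || any(m < 0) ||
      any(M > N) || any(n > N) || any(m > pmin(n, M))) {
    stop("inconsistent enrichment counts: need 0 <= m <= min(n, M), ",
         "0 < M <= N, 0 < n <= N")
  }
  invisible(TRUE)
}

#' Upper-tail hypergeometric p-value for over-representation
#'
#' `P(X >= m)` for `X ~ Hypergeometric(N, M, n)`: the probability that `n`
#' genes drawn without replacement from a background of `N` containing `M`
#' set members include at least `m` of them.
#'
#' @inheritParams fold_enrichment
#' @param ease if `TRUE`, compute the conservative EASE-style score: the
#'   same tail probability with one member removed from `m`.
#' @return p-value in (0, 1].
#' @export
hypergeom_p <- function(m, n, M, N, ease = FALSE) {
  check_enrich_counts(m, n, M, N)
  if (ease) m <- pmax(m - 1, 0)
  phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis of a DE gene list
#'
#' Harmonizes identifiers case-insensitively, drops (and counts) DE genes
#' absent from the background, and tests every gene set with at least one DE
#' member. Results are sorted by p-value; no multiple-testing correction is
#' applied by default, matching the conventional raw-p screening of
#' annotation tools, with Benjamini-Hochberg available behind a flag.
#'
#' @param de_genes character vector of DE gene ids.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]), or a data.frame with `set_id`, `name`, `members`.
#' @param background character vector: the gene universe.
#' @param alpha significance cutoff on the (possibly adjusted) p-value.
#' @param ease use the EASE-style conservative score (see [hypergeom_p()]).
#' @param adjust apply Benjamini-Hochberg adjustment before flagging
#'   significance (default `FALSE`).
#' @return data.frame of class `sage_enrichment`: `set_id`, `m`, `n`, `M`,
#'   `N`, `fold_enrichment`, `p_value`, `significant`; attribute
#'   `n_dropped` counts DE genes not found in the background.
#' @export
enrich <- function(de_genes, gene_sets, background, alpha = 0.05,
                   ease = FALSE, adjust = FALSE) {
  stopifnot(length(gene_sets) > 0, length(background) > 0)
  bg <- unique(tolower(background))
  de <- unique(tolower(de_genes))
  dropped <- setdiff(de, bg)
  if (length(dropped) > 0) {
    message(sprintf("%d DE gene(s) absent from the background were dropped",
                    length(dropped)))
  }
  de <- intersect(de, bg)
  N <- length(bg)
  n <- length(de)
  if (n == 0) stop("no DE genes remain after harmonization with background")

  rows <- lapply(names(gene_sets), function(id) {
    members <- intersect(unique(tolower(gene_sets[[id]])), bg)
    M <- length(members)
    if (M == 0) return(NULL)
    m <- length(intersect(de, members))
    if (m == 0) return(NULL)
    data.frame(set_id = id, m = m, n = n, M = M, N = N,
               fold_enrichment = fold_enrichment(m, n, M, N),
               p_value = hypergeom_p(m, n, M, N, ease = ease),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set_id = character(0), m = integer(0), n = integer(0),
                      M = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      significant = logical(0))
  } else {
    p <- if (adjust) stats::p.adjust(out$p_value, "BH") else out$p_value
    out$significant <- p < alpha
    out <- out[order(out$p_value), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_dropped") <- length(dropped)
  class(out) <- c("sage_enrichment", "data.frame")
  out
}

#' Intersect two gene lists (Venn partition)
#'
#' @param list_a,list_b character vectors; compared case-insensitively
#'   after deduplication.
#' @return list with `common`, `only_a`, `only_b` (three disjoint sets
#'   partitioning the union) and `sizes`.
#' @export
intersect_gene_lists <- function(list_a, list_b) {
  a <- unique(tolower(list_a))
  b <- unique(tolower(list_b))
  common <- intersect(a, b)
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  list(common = sort(common), only_a = sort(only_a), only_b = sort(only_b),
       sizes = c(common = length(common), only_a = length(only_a),
                 only_b = length(only_b)))
}

#' Read / write gene sets in GMT format
#'
#' One set per line: id, description, then member genes, tab-separated.
#' Reading is delegated to the fgsea parser.
#'
#' @param path GMT file.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of descriptions, recycled.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
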