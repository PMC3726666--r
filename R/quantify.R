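# Tag extraction from reads, bounded-mismatch assignment against the virtual
# tag database, and per-library gene quantification in tags per million.

#' Tags per million
#'
#' The SAGE normalization: a gene's tag count scaled by one million over the
#' library's total of assigned (uniquely mapped) tags. One observed tag in a
#' library of five million mapped tags is 0.2 TPM — the pseudo-count used by
#' [fold_change()] when a gene is unobserved in one library.
#'
#' @param count tag count(s), `0 <= count <= total_mapped`.
#' @param total_mapped total assigned tags in the library; must be positive.
#' @return `count * 1e6 / total_mapped`.
#' @examples
#' tpm(1, 5e6) # 0.2
#' @export
tpm <- function(count, total_mapped) {
  if (length(total_mapped) != 1 || is.na(total_mapped) || total_mapped <= 0) {
    stop("total_mapped must be a single positive count")
  }
  if (any(count < 0) || any(count > total_mapped)) {
    stop("counts must lie in [0, total_mapped]")
  }
  count * 1e6 / total_mapped
}

#' Extract the SAGE tag from a sequencing read
#'
#' Reads from the tag-sequencing protocol begin at the anchored tag: after an
#' optional fixed 5' trim, the first `tag_length` bases are the tag provided
#' they begin with the anchor. Returns `NA` for reads that are too short or
#' do not start with the anchor.
#'
#' @param read_sequence character vector of read sequences.
#' @param tag_length expected tag length (anchor included).
#' @param anchor anchor prefix, default `"CATG"`.
#' @param trim5 number of 5' bases to discard before the tag (default 0).
#' @return character vector of tags, `NA` where no tag could be extracted.
#' @export
extract_read_tag <- function(read_sequence, tag_length, anchor = "CATG",
                             trim5 = 0L) {
  s <- toupper(read_sequence)
  if (trim5 > 0) s <- substring(s, trim5 + 1L)
  out <- substr(s, 1L, tag_length)
  out[nchar(s) < tag_length | !startsWith(out, anchor)] <- NA_character_
  out
}

#' Assign a tag to a gene with a bounded-mismatch search
#'
#' Exact hits are resolved first by hash lookup (an exact hit always beats
#' any mismatch hit). On an exact miss, all database entries within Hamming
#' distance `max_mismatch` are found and only minimal-distance hits vote on
#' the gene: if they resolve to exactly one gene the tag is assigned with
#' status `"mismatch"`; if they span several genes (or the exact hit is an
#' ambiguous entry) the tag is discarded as `"ambiguous"`; with no hit it is
#' `"unassigned"`. Ambiguous tags are never counted, at any allowance.
#'
#' @param tag a single tag, or a character vector of tags, of length
#'   `db$tag_length`.
#' @param db a `sage_tagdb` from [extract_virtual_tags()].
#' @param max_mismatch maximum Hamming distance searched (default 2).
#' @return data.frame with one row per tag: `tag_sequence`, `status`
#'   (`exact`/`mismatch`/`ambiguous`/`unassigned`), `gene_id` (`NA` unless
#'   assigned), `n_mismatches` (`NA` unless assigned).
#' @export
match_tag <- function(tag, db, max_mismatch = 2L) {
  stopifnot(inherits(db, "sage_tagdb"), max_mismatch >= 0)
  if (any(nchar(tag) != db$tag_length)) {
    stop(sprintf("tag length must equal db tag_length (%d)", db$tag_length))
  }
  n <- length(tag)
  status <- rep("unassigned", n)
  gene <- rep(NA_character_, n)
  nmm <- rep(NA_integer_, n)
  gene_sets <- tagdb_gene_sets(db)

  hit <- match(tag, db$tags$tag_sequence)
  ex <- !is.na(hit)
  amb <- ex & db$tags$ambiguous[hit]
  status[amb] <- "ambiguous"
  uex <- ex & !amb
  status[uex] <- "exact"
  gene[uex] <- db$tags$gene_ids[hit[uex]]
  nmm[uex] <- 0L

  miss <- which(!ex)
  if (length(miss) > 0 && max_mismatch > 0 && nrow(db$tags) > 0) {
    res <- .hamming_min_hits(tag[miss], db$tags$tag_sequence,
                             as.integer(max_mismatch))
    for (k in seq_along(miss)) {
      i <- miss[k]
      idx <- res$hits[[k]]
      if (length(idx) == 0) next
      g <- unique(unlist(gene_sets[idx]))
      if (length(g) == 1) {
        status[i] <- "mismatch"
        gene[i] <- g
        nmm[i] <- res$distance[k]
      } else {
        status[i] <- "ambiguous"
      }
    }
  }
  data.frame(tag_sequence = tag, status = status, gene_id = gene,
             n_mismatches = nmm, stringsAsFactors = FALSE)
}

#' Quantify a tag library against the virtual tag database
#'
#' Aggregates assigned tags per gene, computes TPM over the total of assigned
#' tags only (the "uniquely mapped" denominator — ambiguous and unassigned
#' tags are excluded), and reports an assignment summary. Iteration is in
#' lexicographic tag order so summaries are byte-stable.
#'
#' @param tag_stream data.frame with columns `tag_sequence` and `count`
#'   (observed read tallies per distinct tag), e.g. from [read_tag_counts()]
#'   or [tally_reads()].
#' @param db a `sage_tagdb`.
#' @param max_mismatch maximum Hamming distance for assignment (default 2).
#' @param library_id label stored in the profile.
#' @param min_count drop observed tags with `count` below this before
#'   assignment (default 1, i.e. no filtering).
#' @return an object of class `sage_profile`: list with `library_id`,
#'   `counts` (named integer vector, genes with count >= 1), `total_mapped`,
#'   `tpm` (named numeric, sums to 1e6), and `summary` (tag tallies by
#'   assignment status plus `genes_detected`).
#' @export
count_library <- function(tag_stream, db, max_mismatch = 2L,
                          library_id = "library", min_count = 1L) {
  stopifnot(inherits(db, "sage_tagdb"), nrow(db$tags) > 0,
            all(c("tag_sequence", "count") %in% names(tag_stream)))
  tag_stream <- tag_stream[tag_stream$count >= min_count, , drop = FALSE]
  tag_stream <- tag_stream[order(tag_stream$tag_sequence), , drop = FALSE]

  empty_summary <- c(exact = 0, mismatch = 0, ambiguous = 0, unassigned = 0)
  if (nrow(tag_stream) == 0) {
    return(structure(list(library_id = library_id,
                          counts = integer(0), total_mapped = 0L,
                          tpm = numeric(0),
                          summary = c(empty_summary, genes_detected = 0)),
                     class = "sage_profile"))
  }
  asg <- match_tag(tag_stream$tag_sequence, db, max_mismatch)
  by_status <- tapply(tag_stream$count, factor(asg$status,
                                               levels = names(empty_summary)),
                      sum, default = 0)
  assigned <- asg$status %in% c("exact", "mismatch")
  if (any(assigned)) {
    counts_tab <- tapply(tag_stream$count[assigned],
                         asg$gene_id[assigned], sum)
    counts <- setNames(as.integer(counts_tab), names(counts_tab))
    counts <- counts[order(names(counts))]
  } else {
    counts <- integer(0)
  }
  total <- sum(counts)
  tpm_vec <- if (total > 0) tpm(counts, total) else numeric(0)
  tallies <- setNames(as.numeric(by_status), names(empty_summary))
  structure(
    list(library_id = library_id, counts = counts,
         total_mapped = as.integer(total), tpm = tpm_vec,
         summary = c(tallies, genes_detected = length(counts))),
    class = "sage_profile")
}

#' @export
print.sage_profile <- function(x, ...) {
  cat(sprintf("SAGE expression profile '%s'\n", x$library_id))
  cat(sprintf("  %d assigned tags over %d genes\n",
              x$total_mapped, length(x$counts)))
  cat("  assignment summary: ",
      paste(names(x$summary), format(x$summary, trim = TRUE),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tally tag observations from sequencing reads
#'
#' Reads a FASTQ or FASTA file (quality scores are ignored), extracts the
#' anchored tag from each read with [extract_read_tag()], and tallies
#' distinct tags. Reads without an extractable tag are counted and dropped.
#'
#' @param path FASTQ or FASTA file.
#' @param tag_length tag length to extract.
#' @param format `"fastq"` or `"fasta"`.
#' @param revcomp reverse-complement reads before extraction, for libraries
#'   sequenced from the opposite strand.
#' @inheritParams extract_read_tag
#' @return data.frame (`tag_sequence`, `count`), sorted by tag, with
#'   attributes `n_reads` and `n_no_tag`.
#' @export
tally_reads <- function(path, tag_length, format = c("fastq", "fasta"),
                        anchor = "CATG", trim5 = 0L, revcomp = FALSE) {
  format <- match.arg(format)
  ss <- Biostrings::readDNAStringSet(path, format = format)
  if (revcomp) ss <- Biostrings::reverseComplement(ss)
  tags <- extract_read_tag(as.character(ss), tag_length, anchor, trim5)
  n_no_tag <- sum(is.na(tags))
  tab <- table(tags[!is.na(tags)])
  out <- data.frame(tag_sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$tag_sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_reads") <- length(ss)
  attr(out, "n_no_tag") <- n_no_tag
  out
}

#' Read / write a pre-tallied tag count table
#'
#' Two-column tab-separated text: `tag_sequence`, `count`.
#'
#' @param path file path.
#' @export
read_tag_counts <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("tag_sequence", "count") %in% names(df)))
  df
}

#' Write a per-gene expression profile as tab-separated text
#'
#' @param profile a `sage_profile`.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
profile_write <- function(profile, path) {
  stopifnot(inherits(profile, "sage_profile"))
  df <- data.frame(gene_id = names(profile$counts),
                   raw_count = as.integer(profile$counts),
                   tpm = as.numeric(profile$tpm))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sage_profile library_id=%s total_mapped=%d",
                     profile$library_id, profile$total_mapped), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname profile_write
#' @export
profile_read <- function(path) {
  meta <- readLines(path, n = 1)
  if (!startsWith(meta, "# sage_profile")) {
    stop("not a sage_profile file: ", path)
  }
  df <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  counts <- setNames(as.integer(df$raw_count), df$gene_id)
  total <- as.integer(sub(".*total_mapped=([0-9]+).*", "\\1", meta))
  structure(
    list(library_id = sub(".*library_id=([^ ]+).*", "\\1", meta),
         counts = counts, total_mapped = total,
         tpm = if (total > 0) tpm(counts, total) else numeric(0),
         summary = NULL),
    class = "sage_profile")
}
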