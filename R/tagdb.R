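# Virtual SAGE tag database: one tag per transcript, anchored at the
# 3'-most NlaIII site (CATG) on the sense strand, read 5'->3' downstream.

#' Build a virtual SAGE tag database from a reference transcriptome
#'
#' For each transcript the 3'-most occurrence of the anchor (`CATG`, the
#' NlaIII recognition site) is located and the virtual tag is the anchor plus
#' the following `tag_length - 4` bases — the fragment a SAGE library would
#' actually capture. Transcripts with no anchor, or whose 3'-most anchor
#' leaves too few downstream bases, contribute no tag and are tallied in the
#' skip counters (an optional fallback to an earlier anchor is available but
#' off by default, since library construction only captures the 3'-most
#' fragment). Tag windows containing `N` are never emitted. Identical tags
#' from transcripts of the same gene are merged; tags shared across genes
#' are flagged ambiguous and are later refused by the matcher.
#'
#' @param transcriptome a data.frame with columns `transcript_id`, `gene_id`,
#'   `sequence` (A/C/G/T/N), e.g. from [read_transcriptome()].
#' @param tag_length total tag length in bases including the 4-base anchor;
#'   must be at least 5. Default 27 (anchor + 23 nt, SOLiD-SAGE scale).
#' @param anchor anchor sequence; `"CATG"` for NlaIII. Other enzymes are not
#'   modelled beyond substituting their recognition string.
#' @param fallback if `TRUE`, a transcript whose 3'-most anchor has
#'   insufficient downstream sequence falls back to the next anchor upstream.
#' @return an object of class `sage_tagdb`: a list with `tag_length`,
#'   `anchor`, `tags` (data.frame: `tag_sequence`, `gene_ids` comma-joined,
#'   `anchor_offset` 0-based, `ambiguous`), `n_genes_total`, and `skipped`
#'   counts (`no_anchor`, `too_short`, `ambiguous_base`, `bad_alphabet`).
#' @examples
#' tx <- data.frame(transcript_id = "t1", gene_id = "g1",
#'                  sequence = "TTCATGAAAACCCCGGGGCATGTGTGTGTGAAA")
#' db <- extract_virtual_tags(tx, tag_length = 10)
#' db$tags$tag_sequence # "CATGTGTGTG", from the 3'-most CATG
#' @export
extract_virtual_tags <- function(transcriptome, tag_length = 27L,
                                 anchor = "CATG", fallback = FALSE) {
  if (tag_length < 5L) {
    stop("tag_length must be >= 5 (anchor plus at least one base)")
  }
  stopifnot(is.data.frame(transcriptome), nrow(transcriptome) > 0,
            all(c("transcript_id", "gene_id", "sequence") %in%
                  names(transcriptome)))
  if (anyDuplicated(transcriptome$transcript_id)) {
    stop("duplicate transcript_id in transcriptome")
  }
  seqs <- toupper(transcriptome$sequence)
  ok <- nzchar(seqs) & is_dna(seqs)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("rejected %d record(s) with invalid alphabet: %s",
                    n_bad,
                    paste(head(transcriptome$transcript_id[!ok], 5),
                          collapse = ", ")))
  }

  tail_len <- tag_length - nchar(anchor)
  skipped <- c(no_anchor = 0L, too_short = 0L, ambiguous_base = 0L,
               bad_alphabet = n_bad)
  tag_seq <- character(0)
  tag_gene <- character(0)
  tag_off <- integer(0)

  for (i in which(ok)) {
    s <- seqs[i]
    hits <- gregexpr(anchor, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      skipped["no_anchor"] <- skipped["no_anchor"] + 1L
      next
    }
    # positions are 1-based starts; consider 3'-most first
    starts <- sort(as.integer(hits), decreasing = TRUE)
    if (!fallback) starts <- starts[1]
    emitted <- FALSE
    for (st in starts) {
      if (st + tag_length - 1L > nchar(s)) next  # insufficient downstream
      tg <- substr(s, st, st + tag_length - 1L)
      if (grepl("N", tg, fixed = TRUE)) {
        skipped["ambiguous_base"] <- skipped["ambiguous_base"] + 1L
        emitted <- TRUE  # consumed: N window is a terminal skip, no fallback
        break
      }
      tag_seq <- c(tag_seq, tg)
      tag_gene <- c(tag_gene, transcriptome$gene_id[i])
      tag_off <- c(tag_off, st - 1L)  # 0-based
      emitted <- TRUE
      break
    }
    if (!emitted) skipped["too_short"] <- skipped["too_short"] + 1L
  }

  entries <- merge_tag_entries(tag_seq, tag_gene, tag_off)
  structure(
    list(tag_length = as.integer(tag_length),
         anchor = anchor,
         tags = entries,
         n_genes_total = length(unique(transcriptome$gene_id[ok])),
         skipped = skipped),
    class = "sage_tagdb")
}

# collapse per-transcript tags into unique tag entries with gene sets
merge_tag_entries <- function(tag_seq, tag_gene, tag_off) {
  if (length(tag_seq) == 0) {
    return(data.frame(tag_sequence = character(0), gene_ids = character(0),
                      anchor_offset = integer(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE))
  }
  o <- order(tag_seq, tag_gene)
  tag_seq <- tag_seq[o]; tag_gene <- tag_gene[o]; tag_off <- tag_off[o]
  genes <- tapply(tag_gene, tag_seq, function(g) sort(unique(g)))
  offs <- tapply(tag_off, tag_seq, min)
  keys <- sort(names(genes))
  data.frame(
    tag_sequence = keys,
    gene_ids = vapply(genes[keys], paste, "", collapse = ","),
    anchor_offset = as.integer(offs[keys]),
    ambiguous = vapply(genes[keys], function(g) length(g) > 1, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.sage_tagdb <- function(x, ...) {
  cat(sprintf("Virtual SAGE tag database (anchor %s, tag length %d)\n",
              x$anchor, x$tag_length))
  cat(sprintf("  %d tag entries (%d ambiguous) from %d genes\n",
              nrow(x$tags), sum(x$tags$ambiguous), x$n_genes_total))
  cat(sprintf("  skipped transcripts: %s\n",
              paste(names(x$skipped), x$skipped, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Read a reference transcriptome from FASTA
#'
#' The gene identifier is parsed from each record's description line with a
#' configurable regular expression whose first capture group is the gene id;
#' records without a match fall back to the record id itself.
#'
#' @param path FASTA file.
#' @param gene_id_pattern regex with one capture group extracting the gene id
#'   from the full header line. Default captures the token after `gene=`.
#' @return data.frame with `transcript_id`, `gene_id`, `sequence`.
#' @export
read_transcriptome <- function(path, gene_id_pattern = "gene=([^ ]+)") {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  m <- regmatches(headers, regexec(gene_id_pattern, headers))
  gene <- vapply(seq_along(m), function(i) {
    if (length(m[[i]]) >= 2) m[[i]][2] else ids[i]
  }, "")
  data.frame(transcript_id = ids, gene_id = gene,
             sequence = as.character(ss), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write / read a virtual tag database as tab-separated text
#'
#' The file carries a metadata header line (`# sage_tagdb ...`) recording the
#' tag length, anchor and a digest of the tag entries, then a column header
#' and one line per tag. `db_read(db_write(db, f))` reproduces the database
#' exactly.
#'
#' @param db a `sage_tagdb`.
#' @param path destination / source file.
#' @return `db_write` returns `path` invisibly; `db_read` a `sage_tagdb`.
#' @export
db_write <- function(db, path) {
  stopifnot(inherits(db, "sage_tagdb"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# sage_tagdb tag_length=%d anchor=%s n_genes_total=%d digest=%s skipped=%s",
    db$tag_length, db$anchor, db$n_genes_total, tagdb_digest(db),
    paste(names(db$skipped), db$skipped, sep = ":", collapse = ",")), con)
  writeLines("tag_sequence\tgene_ids\tanchor_offset\tambiguous", con)
  if (nrow(db$tags) > 0) {
    writeLines(sprintf("%s\t%s\t%d\t%d", db$tags$tag_sequence,
                       db$tags$gene_ids, db$tags$anchor_offset,
                       as.integer(db$tags$ambiguous)), con)
  }
  invisible(path)
}

# digest over the entry table so a reread can be checked for integrity
tagdb_digest <- function(db) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(db$tags$tag_sequence, db$tags$gene_ids), tmp)
  unname(tools::md5sum(tmp))
}

#' @rdname db_write
#' @export
db_read <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "# sage_tagdb")) {
    stop("not a sage_tagdb file (missing metadata header): ", path)
  }
  meta <- lines[1]
  getf <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", meta)
  tag_length <- as.integer(getf("tag_length"))
  skip_kv <- strsplit(getf("skipped"), ",")[[1]]
  skipped <- as.integer(sub(".*:", "", skip_kv))
  names(skipped) <- sub(":.*", "", skip_kv)
  body <- lines[-(1:2)]
  if (length(body) == 0) {
    tags <- data.frame(tag_sequence = character(0), gene_ids = character(0),
                       anchor_offset = integer(0), ambiguous = logical(0),
                       stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 4)) {
      stop(sprintf("malformed tag database line %d: expected 4 fields, got %d",
                   which(nf != 4)[1] + 2L, nf[nf != 4][1]))
    }
    m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
    bad_len <- nchar(m[, 1]) != tag_length
    if (any(bad_len)) {
      stop(sprintf("tag of wrong length at line %d: '%s' (expected %d bases)",
                   which(bad_len)[1] + 2L, m[bad_len, 1][1], tag_length))
    }
    tags <- data.frame(tag_sequence = m[, 1], gene_ids = m[, 2],
                       anchor_offset = as.integer(m[, 3]),
                       ambiguous = as.logical(as.integer(m[, 4])),
                       stringsAsFactors = FALSE)
  }
  db <- structure(
    list(tag_length = tag_length, anchor = getf("anchor"), tags = tags,
         n_genes_total = as.integer(getf("n_genes_total")),
         skipped = skipped),
    class = "sage_tagdb")
  if (tagdb_digest(db) != getf("digest")) {
    stop("tag database digest mismatch: file corrupted? ", path)
  }
  db
}

# gene sets per entry, as a list of character vectors
tagdb_gene_sets <- function(db) {
  strsplit(db$tags$gene_ids, ",", fixed = TRUE)
}
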