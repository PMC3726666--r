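# Independent brute-force oracles and shared fixtures. These deliberately
# re-derive each quantity from first principles, without reusing the
# package's internals beyond plain data structures.

# Hamming distance between two equal-length strings
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# full-scan re-implementation of the assignment rule: exact beats all,
# minimal-distance hits vote on the gene, multi-gene votes are discarded
oracle_match <- function(tag, db, max_mismatch) {
  d <- vapply(db$tags$tag_sequence, oracle_hamming, numeric(1), a = tag)
  genes <- strsplit(db$tags$gene_ids, ",", fixed = TRUE)
  if (any(d == 0)) {
    i <- which(d == 0)
    if (length(genes[[i]]) == 1) {
      return(list(status = "exact", gene = genes[[i]], d = 0))
    }
    return(list(status = "ambiguous", gene = NA, d = NA))
  }
  within <- which(d <= max_mismatch)
  if (length(within) == 0) return(list(status = "unassigned", gene = NA, d = NA))
  dmin <- min(d[within])
  voters <- unique(unlist(genes[which(d == dmin)]))
  if (length(voters) == 1) {
    list(status = "mismatch", gene = voters, d = dmin)
  } else {
    list(status = "ambiguous", gene = NA, d = NA)
  }
}

# direct re-filter of a per-gene count table, mirroring the screening rule
oracle_select_de <- function(counts_control, counts_treated,
                             tpm_min = 10, fc_min = 2) {
  tot_c <- sum(counts_control); tot_t <- sum(counts_treated)
  genes <- union(names(counts_control)[counts_control > 0],
                 names(counts_treated)[counts_treated > 0])
  hits <- character(0)
  for (g in genes) {
    cc <- if (g %in% names(counts_control)) counts_control[[g]] else 0
    ct <- if (g %in% names(counts_treated)) counts_treated[[g]] else 0
    tc <- cc * 1e6 / tot_c
    tt <- ct * 1e6 / tot_t
    if (cc == 0 && ct == 0) next
    tcx <- if (tc == 0) 1e6 / tot_c else tc
    ttx <- if (tt == 0) 1e6 / tot_t else tt
    fc <- ttx / tcx
    if ((tc > tpm_min || tt > tpm_min) && max(fc, 1 / fc) >= fc_min) {
      hits <- c(hits, g)
    }
  }
  sort(hits)
}

# hypergeometric upper tail by enumerating every n-subset of the background
oracle_hyper_enum <- function(m, n, M, N) {
  marked <- seq_len(M)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(s) sum(s %in% marked) >= m))
}

# spreadsheet-style -ddCt: averages replicates, forms dCt against the
# plain mean of reference Cts, subtracts from the control-group mean dCt
oracle_ddct <- function(ct, target, refs, sample, control_group = "control") {
  avg <- function(g, s) mean(ct$ct[ct$gene_id == g & ct$sample_id == s])
  dct <- function(s) avg(target, s) - mean(vapply(refs, avg, 1, s = s))
  ctrl <- unique(ct$sample_id[ct$group == control_group])
  mean(vapply(ctrl, dct, 1)) - dct(sample)
}

# geNorm M by explicit pairwise log2-ratio SDs on relative quantities 2^-Ct
oracle_genorm <- function(ct, genes) {
  avg <- matrix(NA_real_, length(genes),
                length(unique(ct$sample_id)),
                dimnames = list(genes, sort(unique(ct$sample_id))))
  for (g in genes) for (s in colnames(avg)) {
    avg[g, s] <- mean(ct$ct[ct$gene_id == g & ct$sample_id == s])
  }
  q <- 2^(-avg)
  vapply(genes, function(j) {
    mean(vapply(setdiff(genes, j), function(k) {
      sd(log2(q[j, ] / q[k, ]))
    }, 1))
  }, 1)
}

# frozen 4-gene x 6-sample qPCR fixture: 2 references, 2 targets, values
# chosen by hand (replicated measurements with slight jitter)
qpcr_fixture <- function() {
  genes <- c("ref1", "ref2", "tgtA", "tgtB")
  base <- c(ref1 = 20, ref2 = 24, tgtA = 26, tgtB = 30)
  samples <- c("C1", "C2", "C3", "S1", "S2", "S3")
  groups <- rep(c("control", "treated"), each = 3)
  # treated shift: tgtA down 2 cycles (4-fold up), tgtB up 1 cycle (2-fold
  # down); references stable; deterministic jitter
  shift <- rbind(ref1 = c(0, 0, 0, 0, 0, 0),
                 ref2 = c(0, 0, 0, 0, 0, 0),
                 tgtA = c(0, 0, 0, -2, -2, -2),
                 tgtB = c(0, 0, 0, 1, 1, 1))
  jit <- c(-0.1, 0, 0.1)
  rows <- expand.grid(gene_id = genes, sample_id = samples,
                      replicate = 1:3, stringsAsFactors = FALSE)
  rows$group <- groups[match(rows$sample_id, samples)]
  rows$ct <- base[rows$gene_id] +
    shift[cbind(match(rows$gene_id, rownames(shift)),
                match(rows$sample_id, samples))] +
    jit[rows$replicate] + 0.05 * match(rows$sample_id, samples)
  rows[, c("gene_id", "sample_id", "group", "replicate", "ct")]
}

# tiny deterministic tag database fixture
toy_db <- function() {
  tx <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4", "t5"),
    gene_id = c("gA", "gB", "gC", "gD", "gD"),
    sequence = c(
      "AAAACATGAAAAAA",     # gA: CATGAAAAAA
      "CCCCCATGCCCCCC",     # gB: CATGCCCCCC
      "GGGGCATGGGGGGG",     # gC: CATGGGGGGG
      "TTTTCATGTTTTTT",     # gD: CATGTTTTTT
      "AGTCCATGTGTGTG"),    # gD: CATGTGTGTG (same gene, second transcript)
    stringsAsFactors = FALSE)
  extract_virtual_tags(tx, tag_length = 10)
}

random_tags <- function(n, L) {
  vapply(seq_len(n), function(i) {
    paste0("CATG", paste(sample(c("A", "C", "G", "T"), L - 4,
                                replace = TRUE), collapse = ""))
  }, "")
}

# a small profile built directly from per-gene counts
profile_from_counts <- function(counts, id = "lib") {
  counts <- counts[counts > 0]
  counts <- counts[order(names(counts))]
  structure(list(library_id = id, counts = counts,
                 total_mapped = as.integer(sum(counts)),
                 tpm = counts * 1e6 / sum(counts), summary = NULL),
            class = "sage_profile")
}
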