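test_that("tpm implements the tags-per-million normalization", {
  expect_identical(tpm(1, 5e6), 0.2)
  expect_identical(tpm(0, 1234), 0)
  expect_identical(tpm(1234, 1234), 1e6)
  expect_error(tpm(1, 0), "positive")
  expect_error(tpm(-1, 10), "counts")
  expect_error(tpm(11, 10), "counts")
})

test_that("read tags are the anchored prefix or nothing", {
  expect_equal(extract_read_tag("CATGTGTGTGAAAA", 10), "CATGTGTGTG")
  expect_true(is.na(extract_read_tag("TTTTTTTTTT", 10)))
  expect_true(is.na(extract_read_tag("CATGAA", 10)))  # too short
  expect_equal(extract_read_tag("GGCATGAAAAAA", 10, trim5 = 2),
               "CATGAAAAAA")
  expect_equal(extract_read_tag(c("CATGAAAAAAT", "AAAA", "CATGCCCCCCG"), 10),
               c("CATGAAAAAA", NA, "CATGCCCCCC"))
})

test_that("exact, mismatch, ambiguous and unassigned statuses follow the rule", {
  db <- toy_db()
  expect_equal(match_tag("CATGAAAAAA", db)$status, "exact")
  expect_equal(match_tag("CATGAAAAAA", db)$gene_id, "gA")
  # distance 1 from gA, >= 2 from everything else
  r <- match_tag("CATGAAAAAT", db)
  expect_equal(r$status, "mismatch")
  expect_equal(r$gene_id, "gA")
  expect_equal(r$n_mismatches, 1L)
  # distance 3+ from every entry
  expect_equal(match_tag("CATGACGTAC", db, 2)$status, "unassigned")
  # equidistant between two genes -> discarded
  tie <- match_tag("CATGAAACCC", db, 3)  # 3 from gA, 3 from gB
  expect_equal(tie$status, "ambiguous")
  expect_true(is.na(tie$gene_id))
  expect_error(match_tag("CATG", db), "length")
})

test_that("an exact hit on a multi-gene tag is refused", {
  tx <- data.frame(transcript_id = c("a", "b"), gene_id = c("gA", "gB"),
                   sequence = c("TTTTCATGAAAAAA", "GGGGCATGAAAAAA"))
  db <- extract_virtual_tags(tx, 10)
  expect_equal(match_tag("CATGAAAAAA", db)$status, "ambiguous")
  prof <- count_library(data.frame(tag_sequence = "CATGAAAAAA", count = 100),
                        db)
  expect_equal(prof$total_mapped, 0L)
  expect_equal(unname(prof$summary["ambiguous"]), 100)
})

test_that("match_tag agrees with a brute-force Hamming scan", {
  db <- toy_db()
  set.seed(7)
  tags <- unique(c(random_tags(150, 10), db$tags$tag_sequence))
  got <- match_tag(tags, db, 2)
  for (i in seq_along(tags)) {
    want <- oracle_match(tags[i], db, 2)
    expect_equal(got$status[i], want$status, info = tags[i])
    if (want$status %in% c("exact", "mismatch")) {
      expect_equal(got$gene_id[i], want$gene, info = tags[i])
      expect_equal(got$n_mismatches[i], want$d, info = tags[i])
    }
  }
})

test_that("the set of tags with any candidate hit grows with the allowance", {
  db <- toy_db()
  set.seed(8)
  tags <- random_tags(200, 10)
  with_candidate <- function(mm) {
    st <- match_tag(tags, db, mm)$status
    which(st != "unassigned")
  }
  prev <- with_candidate(0)
  for (mm in 1:3) {
    cur <- with_candidate(mm)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("count_library aggregates per gene over assigned tags only", {
  db <- toy_db()
  stream <- data.frame(
    tag_sequence = c("CATGAAAAAA", "CATGAAAAAA", "CATGAAAAAA"),
    count = c(2L, 3L, 5L))
  prof <- count_library(stream, db)
  expect_equal(unname(prof$counts["gA"]), 10L)
  expect_equal(prof$total_mapped, 10L)
  expect_equal(unname(prof$tpm["gA"]), 1e6)

  empty <- count_library(data.frame(tag_sequence = character(0),
                                    count = integer(0)), db)
  expect_equal(empty$total_mapped, 0L)
  expect_length(empty$tpm, 0)
})

test_that("TPM sums to one million and counting is additive over streams", {
  db <- toy_db()
  set.seed(9)
  s1 <- data.frame(tag_sequence = sample(db$tags$tag_sequence, 30, TRUE),
                   count = sample(1:50, 30, TRUE))
  s2 <- data.frame(tag_sequence = sample(db$tags$tag_sequence, 20, TRUE),
                   count = sample(1:50, 20, TRUE))
  p1 <- count_library(s1, db)
  p2 <- count_library(s2, db)
  p12 <- count_library(rbind(s1, s2), db)
  expect_equal(sum(p12$tpm), 1e6, tolerance = 1e-6)
  all_genes <- sort(union(names(p1$counts), names(p2$counts)))
  add <- function(p, g) if (g %in% names(p$counts)) p$counts[[g]] else 0L
  for (g in all_genes) {
    expect_equal(add(p12, g), add(p1, g) + add(p2, g))
  }
})

test_that("sampling a known mixture recovers per-gene TPM within 3 SE", {
  set.seed(10)
  n_genes <- 50
  tx <- data.frame(
    transcript_id = sprintf("t%02d", 1:n_genes),
    gene_id = sprintf("g%02d", 1:n_genes),
    sequence = vapply(1:n_genes, function(i) {
      repeat {
        s <- paste0(paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                          collapse = ""), "CATG",
                    paste(sample(c("A", "C", "G", "T"), 10, TRUE),
                          collapse = ""))
        if (max(gregexpr("CATG", s, fixed = TRUE)[[1]]) == 41) return(s)
      }
    }, ""), stringsAsFactors = FALSE)
  db <- extract_virtual_tags(tx, 14)
  tag_of <- setNames(db$tags$tag_sequence,
                     db$tags$gene_ids)
  prob <- runif(n_genes); prob <- prob / sum(prob)
  n <- 1e5
  draws <- as.vector(rmultinom(1, n, prob))
  stream <- data.frame(tag_sequence = unname(tag_of[sprintf("g%02d", 1:n_genes)]),
                       count = draws)
  prof <- count_library(stream[stream$count > 0, ], db, max_mismatch = 0)
  # per-gene 3 SE bound; across 50 simultaneous genes allow the ~0.3%
  # per-gene tail to fire at most twice
  outside <- vapply(which(draws > 0), function(i) {
    est <- prof$tpm[[sprintf("g%02d", i)]]
    se <- sqrt(prob[i] * (1 - prob[i]) / n) * 1e6
    abs(est - prob[i] * 1e6) >= 3 * se + 1e-9
  }, logical(1))
  expect_lte(sum(outside), 2)
})

test_that("profiles round-trip through the TSV format and reads tally", {
  db <- toy_db()
  stream <- data.frame(tag_sequence = db$tags$tag_sequence,
                       count = c(5L, 10L, 15L, 20L, 25L))
  prof <- count_library(stream, db, library_id = "libX")
  f <- withr::local_tempfile()
  profile_write(prof, f)
  back <- profile_read(f)
  expect_equal(back$counts, prof$counts)
  expect_equal(back$tpm, prof$tpm)
  expect_equal(back$library_id, "libX")

  fq <- withr::local_tempfile(fileext = ".fastq")
  write_library_fastq(stream, fq)
  tallied <- tally_reads(fq, 10, format = "fastq")
  expect_equal(tallied$tag_sequence, stream$tag_sequence)
  expect_equal(tallied$count, stream$count)
})
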