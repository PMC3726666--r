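test_that("perfectly covarying references have stability M of zero", {
  ct <- expand.grid(gene_id = c("r1", "r2"),
                    sample_id = paste0("s", 1:4),
                    replicate = 1L, stringsAsFactors = FALSE)
  ct$group <- "control"
  # r2 is always exactly 3 cycles above r1; sample-level shifts are shared
  base <- c(s1 = 20, s2 = 21, s3 = 19.5, s4 = 22)
  ct$ct <- base[ct$sample_id] + ifelse(ct$gene_id == "r2", 3, 0)
  st <- genorm_m(ct)
  expect_equal(st$M_value, c(0, 0))
})

test_that("geNorm M matches the pairwise log-ratio oracle and is invariant", {
  ct <- qpcr_fixture()
  genes <- c("ref1", "ref2", "tgtA")
  st <- genorm_m(ct, candidates = genes)
  want <- oracle_genorm(ct, genes)
  expect_equal(setNames(st$M_value, st$gene_id)[genes], want,
               tolerance = 1e-10)
  expect_equal(st$rank, seq_len(3))
  expect_true(all(diff(st$M_value) >= 0))

  # a constant added to every Ct of one sample cancels in all ratios
  shifted <- ct
  shifted$ct[shifted$sample_id == "S2"] <- shifted$ct[shifted$sample_id == "S2"] + 5
  st2 <- genorm_m(shifted, candidates = genes)
  expect_equal(st2$M_value, st$M_value, tolerance = 1e-10)

  # listing order of candidates does not matter
  st3 <- genorm_m(ct, candidates = rev(genes))
  expect_equal(setNames(st3$M_value, st3$gene_id)[genes],
               setNames(st$M_value, st$gene_id)[genes])
})

test_that("normalization factor is the geometric mean of reference quantities", {
  ct <- data.frame(gene_id = c("r1", "r2"), sample_id = "s1",
                   group = "control", replicate = 1L, ct = c(10, 20))
  expect_equal(unname(normalization_factor(ct, c("r1", "r2"))), 2^(-15))
  expect_equal(unname(normalization_factor(ct, "r1")), 2^(-10))

  fx <- qpcr_fixture()
  nf <- normalization_factor(fx, c("ref1", "ref2"))
  # brute force: product of 2^-Ct over references, cube^(1/k) root
  for (s in names(nf)) {
    cts <- vapply(c("ref1", "ref2"), function(g) {
      mean(fx$ct[fx$gene_id == g & fx$sample_id == s])
    }, 1)
    expect_equal(unname(nf[s]), prod(2^(-cts))^(1 / 2), tolerance = 1e-12)
  }
  expect_error(normalization_factor(fx, c("ref1", "nope")), "missing")
})

test_that("-ddCt recovers cycle shifts and cancels shared drift", {
  fx <- qpcr_fixture()
  # tgtA drops 2 cycles in every treated sample, references stable
  fcA <- ddct(fx, "tgtA", c("ref1", "ref2"))
  expect_equal(unname(fcA), rep(2, 3), tolerance = 1e-10)
  # tgtB rises 1 cycle: 2-fold down
  fcB <- ddct(fx, "tgtB", c("ref1", "ref2"))
  expect_equal(unname(fcB), rep(-1, 3), tolerance = 1e-10)

  # brute-force oracle agreement sample by sample
  for (s in c("S1", "S2", "S3")) {
    expect_equal(unname(fcA[s]),
                 oracle_ddct(fx, "tgtA", c("ref1", "ref2"), s),
                 tolerance = 1e-10)
  }

  # a global Ct shift applied to all genes of one sample cancels
  shifted <- fx
  pick <- shifted$sample_id == "S1"
  shifted$ct[pick] <- shifted$ct[pick] + 2.5
  expect_equal(ddct(shifted, "tgtA", c("ref1", "ref2"))[["S1"]],
               fcA[["S1"]], tolerance = 1e-10)
})

test_that("ddct validates its inputs", {
  fx <- qpcr_fixture()
  expect_error(ddct(fx, "nope", "ref1"), "missing Ct|not in Ct")
  only_treated <- fx[fx$group == "treated", ]
  expect_error(ddct(only_treated, "tgtA", "ref1"), "control")
})

test_that("panel validation counts qualifying individuals per gene", {
  m <- rbind(allup = rep(1.5, 9),
             few = c(rep(1.2, 4), rep(0, 5)),
             border = c(rep(1, 5), rep(0.9, 4)))
  v <- validate_panel(m, fold_threshold = 2, min_individuals = 5)
  expect_equal(v$validated, c(TRUE, FALSE, TRUE))
  expect_equal(v$n_qualifying, c(9L, 4L, 5L))

  # brute-force recount on a random matrix; monotone in both knobs
  set.seed(41)
  r <- matrix(rnorm(20 * 9, 0.8, 1), 20, 9,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  v1 <- validate_panel(r, 2, 5)
  expect_equal(v1$n_qualifying, unname(rowSums(r >= 1)))
  v_higher_fold <- validate_panel(r, 4, 5)
  expect_true(all(v_higher_fold$n_qualifying <= v1$n_qualifying))
  v_more_ind <- validate_panel(r, 2, 7)
  expect_true(all(v1$validated | !v_more_ind$validated))
})

test_that("dose dependence is a strict comparison of fold changes", {
  expect_false(dose_dependence(1.0, 1.0))
  expect_true(dose_dependence(1.0, 1.0 + 1e-9))
  set.seed(42)
  lo <- setNames(rnorm(20), sprintf("g%02d", 1:20))
  hi <- setNames(rnorm(20), sprintf("g%02d", 1:20))
  expect_equal(unname(dose_dependence(lo, hi)), unname(hi > lo))
  # name matching realigns permuted inputs
  expect_equal(dose_dependence(lo, hi[sample(names(hi))]),
               dose_dependence(lo, hi))
})

test_that("the group t-test behaves classically", {
  x <- c(1.1, 2.3, 0.9, 1.8)
  expect_equal(group_ttest(x, x)$p_value, 1, tolerance = 1e-12)
  a <- c(5.1, 4.9, 5.3, 5.2, 4.8)
  b <- c(4.1, 4.0, 4.4, 3.9, 4.2)
  res <- group_ttest(a, b)
  check <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$p_value, check$p.value)
  expect_equal(group_ttest(b, a)$p_value, res$p_value)  # symmetry
  deg <- group_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("clustering merges identical columns first and orders merges", {
  m <- cbind(x = c(1, 5, 9, 2), y = c(1, 5, 9, 2), z = c(9, 1, 2, 8))
  rownames(m) <- paste0("g", 1:4)
  cl <- cluster_panel(m, distance = "euclidean")
  expect_equal(cl$col_tree$height[1], 0)
  first <- sort(cl$col_tree$labels[-cl$col_tree$merge[1, ]])
  expect_equal(first, c("x", "y"))

  # 1-D toy {0, 1, 10} embedded so Euclidean row distance is |vi - vj|
  v <- c(p0 = 0, p1 = 1, p10 = 10) / sqrt(2)
  toy <- cbind(v, v)
  cl2 <- cluster_panel(toy, distance = "euclidean", linkage = "average")
  expect_equal(cl2$row_tree$height, c(1, 9.5), tolerance = 1e-10)
  expect_match(cl2$row_newick, "p10")
})

test_that("a strongly positive condition separates at the last merge", {
  set.seed(43)
  # one arsenic-like column of large positive fold changes against three
  # near-zero/negative conditions
  m <- cbind(arsenic = runif(14, 2, 5),
             e2 = rnorm(14, -0.2, 0.3),
             kt11 = rnorm(14, 0, 0.3),
             tcdd = rnorm(14, -0.5, 0.3))
  rownames(m) <- sprintf("bm%02d", 1:14)
  cl <- cluster_panel(m, distance = "euclidean", linkage = "average")
  last <- cl$col_tree$merge[nrow(cl$col_tree$merge), ]
  singleton <- last[last < 0]
  expect_equal(cl$col_tree$labels[-singleton], "arsenic")
  expect_error(cluster_panel(cbind(c(1, NA), c(2, 3))), "non-finite")
})

test_that("Ct tables round-trip through CSV", {
  fx <- qpcr_fixture()
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(fx, f, row.names = FALSE)
  back <- read_ct_table(f)
  expect_equal(back$ct, fx$ct)
  expect_equal(back$gene_id, fx$gene_id)
})
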