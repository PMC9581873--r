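test_that("read_fasta canonicalizes case, T->U and out-of-alphabet symbols", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">m1", "acgt", ">p2 some description", "AC", "GU"), tf)
  rec <- read_fasta(tf, "RNA")
  expect_equal(rec$id, c("m1", "p2"))
  expect_equal(rec$residues, c("ACGU", "ACGU"))
  expect_equal(rec$length, c(4L, 4L))

  writeLines(c(">p1", "MKV"), tf)
  prot <- read_fasta(tf, "PROTEIN")
  expect_equal(prot$length, 3L)

  writeLines(c(">x", "AC?G"), tf)
  expect_warning(rec <- read_fasta(tf, "RNA"), "rewritten")
  expect_equal(rec$residues, "ACNG")
})

test_that("read_fasta rejects malformed input with line diagnostics", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGU", ">x", "AC"), tf)
  expect_error(read_fasta(tf, "RNA"), "line 1")
  writeLines(c(">a", ">b", "ACG"), tf)
  expect_error(read_fasta(tf, "RNA"), "empty sequence.*'a'")
  writeLines(c(">a", "ACG", ">a", "GGG"), tf)
  expect_error(read_fasta(tf, "RNA"), "duplicate")
})

test_that("write_fasta / read_fasta round-trips canonicalized records", {
  recs <- records_tbl(random_rna(10, c(30, 200), seed = 5))
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, tf, width = 60)
  back <- read_fasta(tf, "RNA")
  expect_equal(back, recs)
})

test_that("load_pairs validates ids, labels and duplicates", {
  lnc <- records_tbl(random_rna(3, seed = 1), "L")
  par <- records_tbl(random_rna(3, c(17, 25), seed = 2), "M")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a_id\tb_id\tlabel", "L001\tM001\t1", "L002\tM002\t0",
               "L003\tM001\t1"), tf)
  pairs <- load_pairs(tf, lnc, par)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$label, c(1L, 0L, 1L))

  forced <- load_pairs(tf, lnc, par, positives_only = TRUE)
  expect_true(all(forced$label == 1L))

  writeLines(c("a_id\tb_id\tlabel", "zz\tM001\t1"), tf)
  expect_error(load_pairs(tf, lnc, par), "unknown id zz")
  writeLines(c("a_id\tb_id\tlabel", "L001\tM001\t1", "L001\tM001\t0"), tf)
  expect_error(load_pairs(tf, lnc, par), "duplicate pair")
})

test_that("Knuth-Durstenfeld shuffle is seeded, complete and uniform", {
  expect_equal(kd_shuffle(1:5, seed = 3), kd_shuffle(1:5, seed = 3))
  expect_equal(sort(kd_shuffle(1:50, n_shuffles = 10, seed = 1)), 1:50)

  # all 6 permutations of a 3-element list at uniform frequency
  # (chi-square against the exact uniform multinomial)
  draws <- vapply(1:6000, function(s) {
    paste(kd_shuffle(c("a", "b", "c"), seed = s), collapse = "")
  }, character(1))
  counts <- table(draws)
  expect_equal(length(counts), 6L)
  p <- stats::chisq.test(counts, p = rep(1 / 6, 6))$p.value
  expect_gt(p, 0.001)
})

test_that("generate_negatives avoids positives, duplicates and over-capacity", {
  lnc <- records_tbl(random_rna(2, seed = 1), "L")
  par <- records_tbl(random_rna(2, c(17, 25), seed = 2), "M")
  all_pairs <- tidyr::expand_grid(a_id = lnc$id, b_id = par$id)
  all_pairs$label <- 1L
  full <- paired_corpus(lnc, par, all_pairs)
  expect_error(generate_negatives(full, 1), "non-positive pairs")

  lnc3 <- records_tbl(random_rna(3, seed = 3), "L")
  par3 <- records_tbl(random_rna(3, c(17, 25), seed = 4), "M")
  pos <- tibble::tibble(a_id = c("L001", "L001", "L002", "L003"),
                        b_id = c("M001", "M002", "M001", "M003"),
                        label = 1L)
  corpus <- paired_corpus(lnc3, par3, pos)
  neg <- generate_negatives(corpus, 5, seed = 11)
  # exactly the 5 complementary cells of the 3x3 grid
  expect_setequal(paste(neg$a_id, neg$b_id),
                  c("L001 M003", "L002 M002", "L002 M003",
                    "L003 M001", "L003 M002"))
  expect_identical(neg, generate_negatives(corpus, 5, seed = 11))

  # property: disjoint from positives and duplicate-free for random corpora
  for (s in 1:10) {
    corp <- tiny_corpus(8, 0, seed = s)
    neg <- generate_negatives(corp, 12, seed = s + 100)
    expect_equal(nrow(dplyr::distinct(neg, a_id, b_id)), 12)
    expect_equal(nrow(dplyr::inner_join(
      neg, corp$pairs, by = c("a_id", "b_id"))), 0)
  }
})

test_that("split_folds stratifies folds and validation tags", {
  pairs <- tibble::tibble(a_id = sprintf("L%03d", 1:100),
                          b_id = sprintf("M%03d", 1:100),
                          label = rep(c(0L, 1L), 50))
  folds <- split_folds(pairs, n_folds = 5, val_fraction = 0.1, seed = 2)
  expect_equal(sort(unique(folds$fold)), 1:5)
  counts <- dplyr::count(folds, fold, label)
  expect_true(all(counts$n == 10)) # 20 per fold, 10 per class
  for (f in 1:5) {
    val <- folds[[paste0("val_f", f)]]
    expect_false(any(val & folds$fold == f)) # validation is inside training
    expect_equal(sum(val), 8)                # 10% of the 80 training pairs
    expect_equal(sum(val & folds$label == 1), 4)
  }
  expect_identical(folds, split_folds(pairs, 5, 0.1, seed = 2))
  expect_error(split_folds(pairs[1:3, ], n_folds = 5), "fewer pairs")
})
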