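test_that("protein alignment identity counts matches over all columns", {
  expect_equal(align_protein_pair("MKFW", "MKFW")$identity, 1.0)
  # one substitution, no gaps optimal
  al <- align_protein_pair("MKF", "MNF")
  expect_equal(al$identity, 2 / 3)
  expect_identical(nchar(al$aligned_a), 3L)
  expect_error(align_protein_pair("", "MKF"), "empty")
})

test_that("reciprocal best hits keep mutual argmax pairs only", {
  hits <- data.frame(
    query_id = c("A1", "A1", "A2", "A2"),
    subject_id = c("B1", "B2", "B2", "B1"),
    score = c(100, 50, 90, 40), identity = c(0.9, 0.5, 0.8, 0.4))
  rbh <- reciprocal_best_hits(hits)
  expect_equal(rbh$gene_a, c("A1", "A2"))
  expect_equal(rbh$gene_b, c("B1", "B2"))
  # A1 best is B1 but B1 best is A2 -> A1 unpaired
  hits2 <- data.frame(
    query_id = c("A1", "B1", "A2"), subject_id = c("B1", "A2", "B1"),
    score = c(50, 80, 80), identity = 0.5)
  rbh2 <- reciprocal_best_hits(hits2)
  expect_false("A1" %in% rbh2$gene_a)
  expect_identical(nrow(reciprocal_best_hits(hits[0, ])), 0L)
})

test_that("RBH agrees with an exhaustive oracle on random score tables", {
  set.seed(23)
  for (rep in 1:15) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    hits <- expand.grid(query_id = sprintf("A%d", 1:na),
                        subject_id = sprintf("B%d", 1:nb),
                        stringsAsFactors = FALSE)
    hits$score <- sample(1:1000, nrow(hits))
    hits$identity <- runif(nrow(hits))
    got <- reciprocal_best_hits(hits)
    expect_identical(sort(paste(got$gene_a, got$gene_b)), oracle_rbh(hits))
    # symmetric under swapping the genomes (directions flipped)
    flipped <- data.frame(query_id = hits$subject_id, subject_id = hits$query_id,
                          score = hits$score, identity = hits$identity)
    got2 <- reciprocal_best_hits(flipped)
    expect_identical(paste(got$gene_a, got$gene_b),
                     paste(got2$gene_a, got2$gene_b))
  }
})

test_that("chromosome homology resolves the worked 2x2 example", {
  counts <- matrix(c(30, 25, 2, 0), 2, 2,
                   dimnames = list(c("c1", "c2"), c("d1", "d2")))
  counts["c1", "d2"] <- 30; counts["c1", "d1"] <- 2; counts["c2", "d1"] <- 25
  counts["c2", "d2"] <- 0
  inst <- counts_to_rbh(counts)
  ch <- chromosome_homology(inst$rbh, inst$loc_a, inst$loc_b)
  expect_identical(ch$assignment[["c1"]], "d2")
  expect_identical(ch$assignment[["c2"]], "d1")
  # one chromosome per side pairs trivially
  one <- counts_to_rbh(matrix(5, 1, 1, dimnames = list("a1", "b1")))
  expect_identical(chromosome_homology(one$rbh, one$loc_a, one$loc_b)$assignment,
                   c(a1 = "b1"))
  # missing location errors
  expect_error(chromosome_homology(inst$rbh, inst$loc_a[-1], inst$loc_b),
               "location")
})

test_that("greedy assignment attains the brute-force optimum on small instances", {
  cases <- expand.grid(seed = 1:6, n_a = c(3, 5, 6), n_b = c(3, 6))
  for (i in seq_len(nrow(cases))) {
    counts <- random_homology_instance(cases$seed[i], cases$n_a[i], cases$n_b[i])
    inst <- counts_to_rbh(counts)
    ch <- chromosome_homology(inst$rbh, inst$loc_a, inst$loc_b)
    greedy_total <- sum(counts[cbind(match(names(ch$assignment), rownames(counts)),
                                     match(ch$assignment, colnames(counts)))])
    expect_equal(greedy_total, oracle_best_assignment(counts))
    # assignment is injective
    expect_false(any(duplicated(ch$assignment)))
  }
})

test_that("BLAST tabular reader converts percent identity to fractions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gA\tgB\t97.5\t200\t5\t0\t1\t200\t1\t200\t1e-50\t350.2",
               "gC\tgD\t88.0\t150\t18\t1\t1\t150\t3\t152\t1e-20\t180.0"), f)
  tab <- read_blast_tab(f)
  expect_equal(tab$identity, c(0.975, 0.88))
  expect_equal(tab$score, c(350.2, 180.0))
})

test_that("dot-plot anchors recover the diagonal, antidiagonal and nothing else", {
  s <- random_dna(3000, seed = 61)
  self <- kmer_anchor_dotplot(s, s)
  plus <- self[self$strand == "+", ]
  expect_true(all(plus$x_pos == plus$y_pos))
  expect_equal(nrow(plus), nchar(s) - 15 + 1)
  rc <- kmer_anchor_dotplot(s, revcomp(s))
  expect_true(all(rc$strand == "-"))
  expect_true(all(rc$x_pos + rc$y_pos == nchar(s) - 15))
  # unrelated sequences share no 15-mers
  expect_identical(nrow(kmer_anchor_dotplot(random_dna(2000, seed = 1),
                                            random_dna(2000, seed = 2))), 0L)
})

test_that("anchors are invariant under x/y exchange up to transposition", {
  x <- random_dna(2000, seed = 71)
  y <- paste0(substr(x, 501, 1500), random_dna(500, seed = 72))
  d1 <- kmer_anchor_dotplot(x, y)
  d2 <- kmer_anchor_dotplot(y, x)
  a <- d1[order(d1$x_pos, d1$y_pos), c("x_pos", "y_pos", "strand")]
  b <- d2[, c("y_pos", "x_pos", "strand")]
  names(b) <- c("x_pos", "y_pos", "strand")
  b <- b[order(b$x_pos, b$y_pos), ]
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("repeat-saturated k-mers are suppressed by the occurrence cap", {
  sat <- strrep("ACGTTGCAACGGTCA", 40)   # 15-bp motif repeated
  d <- kmer_anchor_dotplot(sat, sat, k = 15, max_occurrences = 10)
  expect_identical(nrow(d), 0L)
  # and N-containing k-mers never anchor
  s <- paste0(random_dna(100, seed = 3), strrep("N", 20), random_dna(100, seed = 4))
  d2 <- kmer_anchor_dotplot(s, s)
  expect_true(all(d2$x_pos < 86 | d2$x_pos >= 120))
})
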