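test_that("marker location finds exact and mutated planted copies", {
  set.seed(301)
  marker <- random_dna(600)
  left <- random_dna(2000); right <- random_dna(1500)
  contig <- genome_assembly("ctg1", paste0(left, marker, right))
  hit <- locate_marker(marker, contig)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$identity, 1.0)
  expect_equal(c(hit$begin, hit$end), c(2000L, 2600L))
  expect_identical(hit$strand, "+")
  # 2% substitutions: identity within 0.98 +/- 0.01
  chars <- strsplit(marker, "")[[1L]]
  idx <- sample(600, 12)
  for (i in idx) chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
  mut <- paste(chars, collapse = "")
  hit2 <- locate_marker(marker, genome_assembly("c", paste0(left, mut, right)))
  expect_lt(abs(hit2$identity - 0.98), 0.011)
  # reverse-strand copy reported in forward coordinates
  hit3 <- locate_marker(marker,
                        genome_assembly("c", paste0(left, revcomp(marker), right)))
  expect_identical(hit3$strand, "-")
  expect_equal(c(hit3$begin, hit3$end), c(2000L, 2600L))
  # absent marker: no hits; short marker errors
  expect_identical(nrow(locate_marker(marker, genome_assembly("c", left))), 0L)
  expect_error(locate_marker("ACGTACGTAC", contig), "shorter")
})

test_that("haplotype calls follow the diagnostic-deletion evidence", {
  set.seed(311)
  xref <- random_dna(2400)
  dg <- diagnostic_features(c("del_cds", "del_utr"), c("deletion", "deletion"),
                            c("CDS", "UTR3"), c(600L, 1800L), c(609L, 2041L))
  drop <- function(s, from, to) paste0(substr(s, 1, from), substring(s, to + 1))
  y_both <- drop(drop(xref, 1800, 2041), 600, 609)
  y_one <- drop(xref, 600, 609)
  expect_identical(classify_haplotype(xref, xref, dg)$call, "X")
  cy <- classify_haplotype(y_both, xref, dg)
  expect_identical(cy$call, "Y")
  expect_true(all(cy$evidence == "present"))
  expect_identical(classify_haplotype(y_one, xref, dg)$call, "ambiguous")
  # region truncated over a diagnostic: untestable, ambiguous
  trunc <- substr(xref, 1, 1500)
  ct <- classify_haplotype(trunc, xref, dg)
  expect_identical(unname(ct$evidence["del_utr"]), "untestable")
  expect_identical(ct$call, "ambiguous")
})

test_that("cds divergence matches hand-computed nucleotide and protein values", {
  d0 <- cds_divergence("ATGAAATTT", "ATGAAATTT")
  expect_equal(d0$nt_divergence, 0)
  expect_equal(d0$aa_divergence, 0)
  # one substitution: nt 1/9; MKF vs MNF: aa 1/3
  d1 <- cds_divergence("ATGAAATTT", "ATGAACTTT")
  expect_equal(d1$nt_divergence, 1 / 9)
  expect_equal(d1$aa_divergence, 1 / 3)
  expect_equal(d1$substitutions, 1L)
  expect_error(cds_divergence("", "ATG"), "empty")
  # synonymous third-position change leaves the protein identical
  d2 <- cds_divergence("ATGAAATTT", "ATGAAGTTT")
  expect_equal(d2$nt_divergence, 1 / 9)
  expect_equal(d2$aa_divergence, 0)
})

test_that("cds divergence is symmetric and indels stay out of the denominator", {
  set.seed(321)
  a <- paste0("ATG", random_dna(300), "TAA")
  chars <- strsplit(a, "")[[1L]]
  chars[50] <- setdiff(c("A", "C", "G", "T"), chars[50])[1]
  b <- paste(chars[-(100:108)], collapse = "")   # 1 substitution + 9-bp deletion
  dab <- cds_divergence(a, b)
  dba <- cds_divergence(b, a)
  expect_equal(dab$nt_divergence, dba$nt_divergence)
  expect_equal(dab$substitutions, 1L)
  expect_equal(dab$indel_events, 1L)
  expect_equal(dab$aligned_columns, nchar(b))
  expect_equal(dab$nt_divergence, 1 / nchar(b))
  # alignment-length denominator counts the gap columns
  dalt <- cds_divergence(a, b, denominator = "alignment")
  expect_equal(dalt$nt_divergence, 1 / nchar(a))
})

test_that("pseudogene scan flags lost start codons and missing exons", {
  set.seed(331)
  exons <- lapply(c(200, 150, 180, 120, 160, 140, 130), random_dna)
  exons[[1]] <- paste0("ATG", substring(exons[[1]], 4))
  intact <- paste0(random_dna(300), paste(unlist(exons), collapse = ""),
                   random_dna(300))
  ok <- pseudogene_scan(exons, intact)
  expect_false(ok$flagged)
  expect_identical(ok$exons_missing, 0L)
  expect_true(ok$start_codon_present)
  # ablate ATG and delete exons 3, 5, 7
  kept <- exons
  kept[[1]] <- paste0("GCG", substring(exons[[1]], 4))
  target <- paste0(random_dna(300),
                   paste(unlist(kept[c(1, 2, 4, 6)]), collapse = ""),
                   random_dna(300))
  bad <- pseudogene_scan(exons, target)
  expect_true(bad$flagged)
  expect_identical(bad$exons_missing, 3L)
  expect_false(bad$start_codon_present)
  # locus absent entirely
  gone <- pseudogene_scan(exons, random_dna(2000))
  expect_identical(gone$exons_missing, gone$exons_total)
  expect_true(gone$flagged)
})

test_that("per-gene divergence recovers planted substitution counts", {
  cfg <- sim_config(seed = 41, sex_region = list(n_genes = 5))
  sd <- simulate_diploid_sex_region(cfg)
  rg <- region_gene_divergence(sd$genes, sd$x_contig, sd$y_contig)
  expect_true(all(rg$found))
  x <- rg[rg$haplotype == "X", ]
  y <- rg[rg$haplotype == "Y", ]
  # X fragment is identical to the reference CDS set
  expect_true(all(x$nt_divergence == 0))
  # Y substitutions equal the planted counts gene by gene
  expect_equal(setNames(y$substitutions, y$gene_id),
               sd$truth$subst_count[y$gene_id])
})

test_that("diploid simulation yields correct X/Y calls and marker divergence", {
  sd <- simulate_diploid_sex_region(sim_config(seed = 43))
  for (hap in c("x", "y")) {
    ctg <- sd[[paste0(hap, "_contig")]]
    hit <- locate_marker(sd$marker$region, ctg)
    expect_identical(nrow(hit), 1L)
    region <- substr(ctg$residues[[1L]], hit$begin[1] + 1L, hit$end[1])
    call <- classify_haplotype(region, sd$marker$region, sd$diagnostics)
    expect_identical(call$call, unname(sd$truth$haplotype[ctg$id]))
  }
  # marker CDS divergence within 3 binomial SDs of the planted 1.6% rate
  hy <- locate_marker(sd$marker$cds, sd$y_contig)
  d <- cds_divergence(sd$marker$cds,
                      substr(sd$y_contig$residues[[1L]], hy$begin[1] + 1L, hy$end[1]))
  r <- 0.016; L <- nchar(sd$marker$cds)
  expect_lt(abs(d$nt_divergence - r), 3 * sqrt(r * (1 - r) / L))
  expect_gt(d$aa_divergence, d$nt_divergence)  # nonsynonymous load
})
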