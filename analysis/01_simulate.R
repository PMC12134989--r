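#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system.
#
# Emits, under results/sim/: a gapless contig-level genome with gene
# annotations and repeat annotations (FASTA + GFF3 + RepeatMasker-style
# .out), a scaffolded version with N-gaps, a diverged second genome for the
# synteny comparison, and a phased X/Y sex-region pair. Truth tables go to
# results/sim/truth_*.tsv so later stages can verify themselves.

suppressMessages(library(killistat))
seed <- 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed, gap_rate = 0)
pair <- simulate_genome_pair(cfg)
fs <- fragment_and_scaffold(pair$a$assembly, cfg)

write_fasta(fs$contigs, file.path(out, "genomeA_contigs.fa"))
write_fasta(fs$scaffolded, file.path(out, "genomeA_scaffolds.fa"))
write_gff3(pair$a$annotation, file.path(out, "genomeA.gff3"))
write_repeatmasker_out(pair$a$repeats, file.path(out, "genomeA_repeats.out"))
write_fasta(pair$b$assembly, file.path(out, "genomeB.fa"))
write_gff3(pair$b$annotation, file.path(out, "genomeB.gff3"))
write.table(fs$truth$gaps, file.path(out, "truth_scaffold_gaps.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_a = names(pair$truth$gene_map),
                       gene_b = unname(pair$truth$gene_map)),
            file.path(out, "truth_gene_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(chrom_a = names(pair$truth$chrom_map),
                       chrom_b = unname(pair$truth$chrom_map)),
            file.path(out, "truth_chrom_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# a second, gap-bearing genome for the gap-context stage
simg <- simulate_genome(sim_config(seed = seed + 1L))
write_fasta(simg$assembly, file.path(out, "genomeG_gapped.fa"))
write_gff3(simg$annotation, file.path(out, "genomeG.gff3"))
write.table(simg$truth$gene_context, file.path(out, "truth_gene_context.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# phased sex-region haplotypes
sd <- simulate_diploid_sex_region(sim_config(seed = seed))
write_fasta(sd$x_contig, file.path(out, "sex_hap1.fa"))
write_fasta(sd$y_contig, file.path(out, "sex_hap2.fa"))
write_fasta(genome_assembly(c("marker_cds", "marker_region"),
                            c(sd$marker$cds, sd$marker$region)),
            file.path(out, "sex_marker.fa"))
write_fasta(genome_assembly(names(sd$genes), unname(sd$genes)),
            file.path(out, "sex_gene_cds.fa"))
write.table(sd$diagnostics, file.path(out, "sex_diagnostics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = names(sd$truth$subst_count),
                       planted_substitutions = unname(sd$truth$subst_count),
                       cds_len = unname(sd$truth$cds_len)),
            file.path(out, "truth_sex_substitutions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated study system (seed", seed, "):\n")
cat("  genome A:", length(pair$a$assembly), "chromosomes,",
    sum(seq_lengths(pair$a$assembly)), "bp,",
    length(pair$a$annotation$genes), "genes\n")
cat("  contigs:", length(fs$contigs), " scaffold gaps:", nrow(fs$truth$gaps), "\n")
cat("  sex region:", length(sd$genes), "genes; Y carries",
    sum(sd$truth$subst_count), "planted substitutions and",
    nrow(sd$diagnostics), "diagnostic deletions\n")
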