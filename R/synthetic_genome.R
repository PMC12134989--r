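# Seeded generator of toy assemblies, annotations, repeat files and phased
# sex-region haplotypes, with complete truth tables. Every downstream stage
# is testable against the truth without any external download.
#
# Each simulate_* entry point seeds the stream once (set.seed(config$seed))
# and draws in a fixed documented order (chromosome by chromosome: target
# length, then per block intergenic/repeat/gene draws, then gap planting),
# so identical configs give byte-identical artifacts.

#' Simulation configuration with study-scale defaults
#'
#' Defaults emulate the statistical structure the analyses assume: a few
#' tens-of-kb chromosomes carrying strand-mixed multi-exon protein-coding
#' genes, classified repeat insertions in intergenic space, occasional
#' N-runs, and a diploid sex region whose Y haplotype carries per-gene
#' substitutions, two planted deletions (9 bp in the marker CDS, 241 bp in
#' its 3'-UTR) and a satellite expansion.
#'
#' @param seed integer seed; identical configs reproduce artifacts
#'   byte-for-byte.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length target chromosome length range (bp); chromosomes are
#'   padded with intergenic sequence up to a drawn target.
#' @param genes_per_chromosome protein-coding genes per chromosome.
#' @param exons_per_gene,exon_len,intron_len,intergenic_len ranges (min, max).
#' @param utr5_len,utr3_len UTR widths trimmed from the terminal exons.
#' @param gc_content G+C fraction of random sequence.
#' @param repeat_insertions_per_chrom expected repeat insertions per
#'   chromosome (placed in intergenic blocks).
#' @param gap_rate expected planted N-runs per bp; `gap_len` their length
#'   range.
#' @param ortholog_divergence substitution rate applied when deriving a
#'   second genome from the first (see [simulate_genome_pair()]).
#' @param sex_region list: `n_genes`, `cds_len` range, `nt_subst_rate`
#'   (scalar or per-gene vector), `intergenic_subst_rate`,
#'   `marker_subst_rate`, `marker_cds_len`, `marker_utr3_len`,
#'   `spacer_len` range, `satellite_expansion_bp`, `deletions`
#'   (a [diagnostic_features()] frame on the X marker region, CDS first).
#' @param fragmentation list: `n_breaks`, `min_contig_bp`, `gap_len` range.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       chrom_length = c(20000L, 30000L),
                       genes_per_chromosome = 8L,
                       exons_per_gene = c(2L, 5L),
                       exon_len = c(90L, 240L),
                       intron_len = c(80L, 400L),
                       intergenic_len = c(300L, 1200L),
                       utr5_len = 30L, utr3_len = 45L,
                       gc_content = 0.42,
                       repeat_insertions_per_chrom = 8L,
                       gap_rate = 1.5e-4, gap_len = c(50L, 300L),
                       ortholog_divergence = 0.02,
                       sex_region = list(),
                       fragmentation = list()) {
  sr_default <- list(
    n_genes = 20L, cds_len = c(900L, 1800L),
    nt_subst_rate = 0.005, intergenic_subst_rate = 0.005,
    marker_subst_rate = 0.016,
    marker_cds_len = 1371L, marker_utr3_len = 1000L,
    spacer_len = c(400L, 1200L),
    satellite_expansion_bp = 3000L,
    deletions = diagnostic_features(
      name = c("cds_del_9bp", "utr3_del_241bp"),
      kind = c("deletion", "deletion"),
      region = c("CDS", "UTR3"),
      ref_start = c(600L, 1371L + 300L),
      ref_end = c(609L, 1371L + 541L))
  )
  fr_default <- list(n_breaks = 12L, min_contig_bp = 2000L,
                     gap_len = c(50L, 300L))
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chrom_length = chrom_length,
              genes_per_chromosome = genes_per_chromosome,
              exons_per_gene = exons_per_gene, exon_len = exon_len,
              intron_len = intron_len, intergenic_len = intergenic_len,
              utr5_len = utr5_len, utr3_len = utr3_len,
              gc_content = gc_content,
              repeat_insertions_per_chrom = repeat_insertions_per_chrom,
              gap_rate = gap_rate, gap_len = gap_len,
              ortholog_divergence = ortholog_divergence,
              sex_region = {
                # the deletions frame is replaced wholesale, never merged
                sr <- utils::modifyList(
                  sr_default[setdiff(names(sr_default), "deletions")],
                  sex_region[setdiff(names(sex_region), "deletions")])
                sr$deletions <- if (is.null(sex_region$deletions))
                  sr_default$deletions else sex_region$deletions
                sr
              },
              fragmentation = utils::modifyList(fr_default, fragmentation),
              repeat_library = .default_repeat_library())
  stopifnot(cfg$gap_rate >= 0, cfg$gap_rate <= 1,
            all(cfg$exon_len > 0), all(cfg$intron_len > 0))
  structure(cfg, class = "sim_config")
}

.default_repeat_library <- function() {
  list(
    list(name = "L2-1_sim", class_family = "LINE/L2", length = 400L),
    list(name = "Gypsy7_sim", class_family = "LTR/Gypsy", length = 350L),
    list(name = "hAT3_sim", class_family = "DNA/hAT-Charlie", length = 250L),
    list(name = "Tc1-4_sim", class_family = "DNA/TcMar-Tc1", length = 220L),
    list(name = "SAT-21_sim", class_family = "Satellite", motif_len = 21L, copies = 20L),
    list(name = "(AT)n", class_family = "Simple_repeat", motif = "AT", copies = 30L),
    list(name = "Helitron1_sim", class_family = "RC/Helitron", length = 300L),
    list(name = "Unknown5_sim", class_family = "Unknown", length = 280L)
  )
}

.rand_seq <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.runif_int <- function(rng) {
  if (rng[1L] == rng[2L]) return(as.integer(rng[1L]))
  sample(seq(rng[1L], rng[2L]), 1L)
}

# random coding sequence: ATG start, sense codons, single stop at the end
.rand_cds <- function(len3) {
  stopifnot(len3 %% 3L == 0L, len3 >= 9L)
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1L, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_mid <- len3 / 3L - 2L
  paste0("ATG", paste(sample(sense, n_mid, replace = TRUE), collapse = ""), "TAA")
}

# substitute bases at `rate` (skipping Ns); returns sequence, count, positions
.mutate_seq <- function(s, rate, exclude = NULL) {
  if (rate <= 0 || !nzchar(s)) return(list(seq = s, n = 0L, pos = integer()))
  chars <- strsplit(s, "")[[1L]]
  eligible <- which(!chars %in% c("N", "n"))
  if (!is.null(exclude)) eligible <- setdiff(eligible, exclude)
  hit <- eligible[runif(length(eligible)) < rate]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), toupper(chars[i])), 1L)
  }
  list(seq = paste(chars, collapse = ""), n = length(hit), pos = hit)
}

.repeat_seq <- function(entry, gc) {
  if (!is.null(entry[["motif"]])) {
    paste(rep(entry[["motif"]], entry[["copies"]]), collapse = "")
  } else if (!is.null(entry[["motif_len"]])) {
    paste(rep(.rand_seq(entry[["motif_len"]], gc), entry[["copies"]]), collapse = "")
  } else {
    .rand_seq(entry[["length"]], gc)
  }
}

# ---- whole-genome simulation -------------------------------------------------

#' Simulate a toy annotated genome with truth tables
#'
#' Builds `n_chromosomes` sequences of alternating intergenic blocks (some
#' carrying repeat insertions) and multi-exon protein-coding genes on random
#' strands, then plants non-adjacent N-runs at `gap_rate`. Genes never
#' overlap. The emitted artifacts round-trip losslessly through the genome
#' I/O readers.
#'
#' @param config a [sim_config()].
#' @return list with `assembly` (`genome_assembly`), `annotation`
#'   (`annotation_set`), `repeats` (RepeatMasker-style hit frame) and
#'   `truth`: `gaps` (planted N-runs), `gene_context` (per-gene gap flags at
#'   10 kb flanks, strand-aware), `genes` (coordinate table), `repeats`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  gc <- config$gc_content
  chrom_ids <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  residues <- character(0)
  genes <- list()
  repeat_rows <- list()
  gap_rows <- list()
  gene_rows <- list()

  for (ci in seq_along(chrom_ids)) {
    cid <- chrom_ids[ci]
    target_len <- .runif_int(config$chrom_length)
    p_rep <- min(1, config$repeat_insertions_per_chrom /
                   (config$genes_per_chromosome + 1L))
    parts <- character()
    pos <- 0L
    add <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
    for (gi in seq_len(config$genes_per_chromosome)) {
      ig <- .rand_seq(.runif_int(config$intergenic_len), gc)
      if (runif(1) < p_rep) {
        entry <- config$repeat_library[[sample(length(config$repeat_library), 1L)]]
        rs <- .repeat_seq(entry, gc)
        at <- sample(nchar(ig), 1L)
        repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
          seq_id = cid, begin = pos + at, end = pos + at + nchar(rs),
          strand = sample(c("+", "-"), 1L), repeat_name = entry$name,
          class_family = entry$class_family,
          divergence_pct = round(runif(1, 0, 25), 1), stringsAsFactors = FALSE)
        ig <- paste0(substr(ig, 1L, at), rs, substr(ig, at + 1L, nchar(ig)))
      }
      add(ig)
      # gene: exons/introns; CDS = exons minus terminal UTRs, length % 3 == 0
      n_ex <- .runif_int(config$exons_per_gene)
      ex_len <- vapply(seq_len(n_ex), function(i) .runif_int(config$exon_len), 0L)
      in_len <- if (n_ex > 1L) {
        vapply(seq_len(n_ex - 1L), function(i) .runif_int(config$intron_len), 0L)
      } else integer()
      strand <- sample(c("+", "-"), 1L)
      g_start <- pos
      ex_iv <- matrix(0L, nrow = n_ex, ncol = 2L)
      p <- pos
      for (i in seq_len(n_ex)) {
        ex_iv[i, ] <- c(p, p + ex_len[i])
        p <- p + ex_len[i]
        if (i < n_ex) p <- p + in_len[i]
      }
      g_end <- p
      gene_seq <- .rand_seq(g_end - g_start, gc)
      add(gene_seq)
      # trim UTRs strand-aware; shave the 3' trim so CDS length is a codon multiple
      cds_iv <- ex_iv
      u5 <- config$utr5_len; u3 <- config$utr3_len
      if (strand == "+") {
        cds_iv[1L, 1L] <- cds_iv[1L, 1L] + u5
        cds_iv[n_ex, 2L] <- cds_iv[n_ex, 2L] - u3
        extra <- sum(cds_iv[, 2L] - cds_iv[, 1L]) %% 3L
        cds_iv[n_ex, 2L] <- cds_iv[n_ex, 2L] - extra
      } else {
        cds_iv[n_ex, 2L] <- cds_iv[n_ex, 2L] - u5
        cds_iv[1L, 1L] <- cds_iv[1L, 1L] + u3
        extra <- sum(cds_iv[, 2L] - cds_iv[, 1L]) %% 3L
        cds_iv[1L, 1L] <- cds_iv[1L, 1L] + extra
      }
      gid <- sprintf("%s_g%02d", cid, gi)
      tid <- paste0(gid, ".t1")
      genes[[gid]] <- list(
        gene_id = gid, seq_id = cid, strand = strand,
        start = g_start, end = g_end, biotype = "protein_coding",
        transcripts = setNames(list(list(exons = .iv_mat(ex_iv[, 1L], ex_iv[, 2L]),
                                         cds = .iv_mat(cds_iv[, 1L], cds_iv[, 2L]))),
                               tid))
      gene_rows[[gid]] <- data.frame(gene_id = gid, seq_id = cid, strand = strand,
                                     start = g_start, end = g_end,
                                     stringsAsFactors = FALSE)
    }
    add(.rand_seq(.runif_int(config$intergenic_len), gc))
    chrom <- paste(parts, collapse = "")
    if (nchar(chrom) < target_len) {
      chrom <- paste0(chrom, .rand_seq(target_len - nchar(chrom), gc))
    }
    # plant non-adjacent N-runs
    clen <- nchar(chrom)
    n_gaps <- rpois(1L, config$gap_rate * clen)
    placed <- matrix(0L, nrow = 0L, ncol = 2L)
    for (k in seq_len(n_gaps)) {
      glen <- .runif_int(config$gap_len)
      for (try in 1:50) {
        s <- sample(seq(2L, clen - glen - 1L), 1L)
        if (nrow(placed) == 0L ||
            all(s + glen + 1L < placed[, 1L] | s - 1L > placed[, 2L])) {
          placed <- rbind(placed, c(s, s + glen))
          chrom <- paste0(substr(chrom, 1L, s), strrep("N", glen),
                          substr(chrom, s + glen + 1L, clen))
          gap_rows[[length(gap_rows) + 1L]] <- data.frame(
            seq_id = cid, start = s, end = s + glen, stringsAsFactors = FALSE)
          break
        }
      }
    }
    residues[cid] <- chrom
  }

  assembly <- genome_assembly(chrom_ids, residues[chrom_ids])
  by_seq <- split(names(genes), vapply(genes, `[[`, "", "seq_id"))
  annotation <- structure(list(genes = genes, by_seq = by_seq),
                          class = "annotation_set")
  gaps <- if (length(gap_rows)) do.call(rbind, gap_rows) else
    data.frame(seq_id = character(), start = integer(), end = integer())
  gaps <- gaps[order(gaps$seq_id, gaps$start), , drop = FALSE]
  rownames(gaps) <- NULL
  repeats <- if (length(repeat_rows)) do.call(rbind, repeat_rows) else
    data.frame(seq_id = character(), begin = integer(), end = integer(),
               strand = character(), repeat_name = character(),
               class_family = character(), divergence_pct = numeric())
  rownames(repeats) <- NULL
  truth <- list(
    gaps = gaps,
    gene_context = .truth_gene_context(genes, gaps, seq_lengths(assembly)),
    genes = do.call(rbind, c(unname(gene_rows), make.row.names = FALSE)),
    repeats = repeats
  )
  list(assembly = assembly, annotation = annotation, repeats = repeats,
       truth = truth)
}

# Truth gap-context flags from planted coordinates: plain interval arithmetic,
# independent of the scanner's IRanges path.
.truth_gene_context <- function(genes, gaps, slens) {
  hit <- function(iv, g) {
    if (is.null(iv) || nrow(iv) == 0L || nrow(g) == 0L) return(FALSE)
    any(vapply(seq_len(nrow(iv)), function(i) {
      any(g$start < iv[i, 2L] & g$end > iv[i, 1L])
    }, TRUE))
  }
  rows <- lapply(genes, function(gm) {
    g <- gaps[gaps$seq_id == gm$seq_id, , drop = FALSE]
    slen <- slens[[gm$seq_id]]
    left <- cbind(max(0L, gm$start - 10000L), gm$start)
    right <- cbind(gm$end, min(slen, gm$end + 10000L))
    if (left[1L] >= left[2L]) left <- left[0L, , drop = FALSE]
    if (right[1L] >= right[2L]) right <- right[0L, , drop = FALSE]
    minus <- identical(gm$strand, "-")
    data.frame(gene_id = gm$gene_id,
               has_N_upstream = hit(if (minus) right else left, g),
               has_N_downstream = hit(if (minus) left else right, g),
               has_N_cds = hit(gene_cds(gm), g),
               has_N_intron = hit(gene_introns(gm), g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(unname(rows), make.row.names = FALSE))
  out[order(out$gene_id), , drop = FALSE]
}

#' Replace residues with Ns at a chosen position
#'
#' Utility for planting a single gap into an existing assembly (the
#' surrounding residues are unchanged, so coordinates are preserved).
#'
#' @param assembly a `genome_assembly`.
#' @param seq_id target sequence.
#' @param start 0-based start of the run.
#' @param length run length in bp.
#' @return The modified assembly.
#' @export
plant_gap <- function(assembly, seq_id, start, length) {
  s <- get_seq(assembly, seq_id)
  stopifnot(start >= 0L, start + length <= nchar(s))
  assembly$residues[[seq_id]] <- paste0(
    substr(s, 1L, start), strrep("N", length),
    substr(s, start + length + 1L, nchar(s)))
  assembly
}

#' Derive a diverged second genome and its ortholog truth
#'
#' Simulates genome A with [simulate_genome()], then derives genome B by
#' substituting bases at `ortholog_divergence` (Ns untouched), renaming and
#' reordering chromosomes. Gene structures and relative coordinates are
#' preserved, so every A gene has exactly one B ortholog; the truth records
#' the gene-to-gene and chromosome-to-chromosome maps.
#'
#' @param config a [sim_config()].
#' @return list with `a`, `b` (each as from [simulate_genome()]) and
#'   `truth`: `gene_map` (named character A -> B), `chrom_map` (A -> B).
#' @export
simulate_genome_pair <- function(config = sim_config()) {
  a <- simulate_genome(config)
  # continue the stream: derivation draws follow the genome draws
  perm <- sample(config$n_chromosomes)
  chrom_map <- setNames(sprintf("chrB%02d", perm), a$assembly$id)
  b_ids_in_order <- sprintf("chrB%02d", seq_len(config$n_chromosomes))
  residues <- character()
  for (cid in a$assembly$id) {
    residues[chrom_map[[cid]]] <-
      .mutate_seq(a$assembly$residues[[cid]], config$ortholog_divergence)$seq
  }
  genes_b <- list()
  gene_map <- character()
  for (gid in names(a$annotation$genes)) {
    g <- a$annotation$genes[[gid]]
    bid <- sub("^chr", "geneB_chr", gid)
    g$gene_id <- bid
    g$seq_id <- chrom_map[[g$seq_id]]
    names(g$transcripts) <- paste0(bid, ".t1")
    genes_b[[bid]] <- g
    gene_map[gid] <- bid
  }
  b_assembly <- genome_assembly(b_ids_in_order, residues[b_ids_in_order])
  b_annot <- structure(list(genes = genes_b,
                            by_seq = split(names(genes_b),
                                           vapply(genes_b, `[[`, "", "seq_id"))),
                       class = "annotation_set")
  list(a = a, b = list(assembly = b_assembly, annotation = b_annot),
       truth = list(gene_map = gene_map, chrom_map = chrom_map))
}

#' Extract the spliced coding sequence of a gene
#'
#' Concatenates the gene-level CDS union in genomic order and reverse
#' complements for minus-strand genes. Frame 1 of the result is the coding
#' frame.
#'
#' @param assembly a `genome_assembly`.
#' @param gene a gene model (from an `annotation_set`).
#' @return The CDS residue string.
#' @export
extract_cds <- function(assembly, gene) {
  iv <- gene_cds(gene)
  if (nrow(iv) == 0L) stop("gene has no CDS: ", gene$gene_id)
  s <- get_seq(assembly, gene$seq_id)
  parts <- vapply(seq_len(nrow(iv)), function(i) {
    substr(s, iv[i, 1L] + 1L, iv[i, 2L])
  }, "")
  out <- paste(parts, collapse = "")
  if (identical(gene$strand, "-")) out <- revcomp(out) else out
}

# ---- diploid sex region ------------------------------------------------------

#' Simulate a phased X/Y sex-region pair with truth
#'
#' The X contig carries `n_genes` coding sequences and a marker locus
#' (CDS + 3'-UTR) separated by spacers. The Y contig is derived from it by
#' per-gene substitutions at `nt_subst_rate`, marker substitutions at
#' `marker_subst_rate`, the planted diagnostic deletions (applied after
#' substitution, at recorded X-region coordinates), background spacer
#' substitutions, and a terminal satellite expansion block. The truth
#' records every edit.
#'
#' @param config a [sim_config()]; the `sex_region` element drives this
#'   generator.
#' @return list: `x_contig`, `y_contig` (single-sequence assemblies named
#'   like phased assembler output), `marker` (`cds`, `region` = CDS+UTR,
#'   `y_region`), `genes` (named X-haplotype CDS strings, the divergence
#'   references), `diagnostics`, and `truth` (`haplotype` per contig,
#'   per-gene `subst_count`/`cds_len`/rates, marker substitution count,
#'   gene coordinates on each contig).
#' @export
simulate_diploid_sex_region <- function(config = sim_config()) {
  set.seed(config$seed)
  sc <- config$sex_region
  gc <- config$gc_content
  marker_cds <- .rand_cds(sc$marker_cds_len - sc$marker_cds_len %% 3L)
  marker_utr3 <- .rand_seq(sc$marker_utr3_len, gc)
  marker_region <- paste0(marker_cds, marker_utr3)
  dg <- sc$deletions
  if (any(dg$ref_end > nchar(marker_region)) || any(dg$ref_start < 0L)) {
    stop("planted deletion coordinates fall outside the marker region")
  }
  n <- sc$n_genes
  rates <- rep(sc$nt_subst_rate, length.out = n)
  gene_len <- vapply(seq_len(n), function(i) {
    l <- .runif_int(sc$cds_len); l - l %% 3L
  }, 0L)
  genes <- setNames(lapply(gene_len, .rand_cds), sprintf("sexgene%02d", seq_len(n)))
  spacers <- lapply(seq_len(n + 1L), function(i) .rand_seq(.runif_int(sc$spacer_len), gc))
  marker_slot <- max(1L, n %/% 2L)

  # X contig assembly, recording coordinates
  x_parts <- list(); x_coords <- list(); xpos <- 0L
  push_x <- function(name, s) {
    x_parts[[length(x_parts) + 1L]] <<- s
    if (!is.null(name)) x_coords[[name]] <<- c(xpos, xpos + nchar(s))
    xpos <<- xpos + nchar(s)
  }
  for (i in seq_len(n)) {
    push_x(NULL, spacers[[i]])
    push_x(names(genes)[i], genes[[i]])
    if (i == marker_slot) push_x("marker", marker_region)
  }
  push_x(NULL, spacers[[n + 1L]])
  x_seq <- paste(unlist(x_parts), collapse = "")

  # Y contig: mutate per segment, then apply deletions to the marker region
  y_parts <- list(); y_coords <- list(); ypos <- 0L
  subst <- setNames(integer(n), names(genes))
  push_y <- function(name, s) {
    y_parts[[length(y_parts) + 1L]] <<- s
    if (!is.null(name)) y_coords[[name]] <<- c(ypos, ypos + nchar(s))
    ypos <<- ypos + nchar(s)
  }
  # marker edits: substitutions outside the to-be-deleted spans, then deletion
  del_sites <- unlist(lapply(seq_len(nrow(dg)), function(i) {
    seq(dg$ref_start[i] + 1L, dg$ref_end[i])
  }))
  mk <- .mutate_seq(marker_region, sc$marker_subst_rate, exclude = del_sites)
  y_marker <- mk$seq
  for (i in order(dg$ref_start, decreasing = TRUE)) {
    y_marker <- paste0(substr(y_marker, 1L, dg$ref_start[i]),
                       substr(y_marker, dg$ref_end[i] + 1L, nchar(y_marker)))
  }
  for (i in seq_len(n)) {
    push_y(NULL, .mutate_seq(spacers[[i]], sc$intergenic_subst_rate)$seq)
    m <- .mutate_seq(genes[[i]], rates[i])
    subst[i] <- m$n
    push_y(names(genes)[i], m$seq)
    if (i == marker_slot) push_y("marker", y_marker)
  }
  push_y(NULL, .mutate_seq(spacers[[n + 1L]], sc$intergenic_subst_rate)$seq)
  if (sc$satellite_expansion_bp > 0L) {
    motif <- .rand_seq(21L, gc)
    copies <- ceiling(sc$satellite_expansion_bp / 21L)
    sat <- substr(paste(rep(motif, copies), collapse = ""), 1L,
                  sc$satellite_expansion_bp)
    push_y("satellite_expansion", sat)
  }
  y_seq <- paste(unlist(y_parts), collapse = "")

  x_contig <- genome_assembly("h1tg000299l", x_seq)
  y_contig <- genome_assembly("h2tg000474l", y_seq)
  coords_df <- function(cl) {
    do.call(rbind, lapply(names(cl), function(nm) {
      data.frame(feature = nm, start = cl[[nm]][1L], end = cl[[nm]][2L],
                 stringsAsFactors = FALSE)
    }))
  }
  list(
    x_contig = x_contig, y_contig = y_contig,
    marker = list(cds = marker_cds, region = marker_region, y_region = y_marker),
    genes = vapply(genes, identity, ""),
    diagnostics = dg,
    truth = list(
      haplotype = c(h1tg000299l = "X", h2tg000474l = "Y"),
      subst_count = subst,
      cds_len = setNames(gene_len, names(genes)),
      nt_subst_rate = setNames(rates, names(genes)),
      marker_subst_count = mk$n,
      marker_cds_subst_count = sum(mk$pos <= nchar(marker_cds)),
      x_coords = coords_df(x_coords), y_coords = coords_df(y_coords)
    )
  )
}

# ---- fragmentation and scaffolding -------------------------------------------

#' Break an assembly into contigs and re-scaffold with N gaps
#'
#' Draws `n_breaks` break points across the assembly (each at least
#' `min_contig_bp` from sequence ends and from other breaks on the same
#' sequence), emits the resulting contigs, and rejoins the contigs of each
#' input sequence with N-runs of drawn lengths. Scaffolded total length
#' equals contig total plus the sum of gap lengths.
#'
#' @param assembly a `genome_assembly`.
#' @param config a [sim_config()]; `fragmentation` drives break count,
#'   minimum contig size and gap length range; draws are seeded from
#'   `config$seed`.
#' @return list: `contigs` (assembly of contigs), `scaffolded` (assembly
#'   with inserted N-runs), `truth` (`breaks` per sequence, `gaps` inserted
#'   with scaffold coordinates).
#' @export
fragment_and_scaffold <- function(assembly, config = sim_config()) {
  set.seed(config$seed)
  fr <- config$fragmentation
  lens <- seq_lengths(assembly)
  contigs_id <- character(); contigs_seq <- character()
  scaff_seq <- character()
  gap_rows <- list(); break_rows <- list()
  n_breaks_per <- if (fr$n_breaks > 0L) {
    tabulate(sample(seq_along(assembly$id), fr$n_breaks, replace = TRUE,
                    prob = pmax(0, lens - 2L * fr$min_contig_bp)),
             nbins = length(assembly$id))
  } else rep(0L, length(assembly$id))
  for (ci in seq_along(assembly$id)) {
    cid <- assembly$id[ci]
    s <- assembly$residues[[cid]]
    L <- nchar(s)
    nb <- n_breaks_per[ci]
    breaks <- integer()
    for (k in seq_len(nb)) {
      for (try in 1:50) {
        b <- sample(seq(fr$min_contig_bp, L - fr$min_contig_bp), 1L)
        if (!length(breaks) || all(abs(b - breaks) >= fr$min_contig_bp)) {
          breaks <- c(breaks, b); break
        }
      }
    }
    breaks <- sort(breaks)
    bounds <- c(0L, breaks, L)
    pieces <- vapply(seq_len(length(bounds) - 1L), function(i) {
      substr(s, bounds[i] + 1L, bounds[i + 1L])
    }, "")
    pids <- sprintf("%s.ctg%d", cid, seq_along(pieces))
    contigs_id <- c(contigs_id, pids)
    contigs_seq <- c(contigs_seq, setNames(pieces, pids))
    if (length(breaks)) {
      break_rows[[cid]] <- data.frame(seq_id = cid, pos = breaks,
                                      stringsAsFactors = FALSE)
    }
    glens <- if (length(pieces) > 1L) {
      vapply(seq_len(length(pieces) - 1L), function(i) .runif_int(fr$gap_len), 0L)
    } else integer()
    scaf <- pieces[1L]
    at <- nchar(pieces[1L])
    for (i in seq_along(glens)) {
      gap_rows[[paste(cid, i)]] <- data.frame(
        seq_id = cid, start = at, end = at + glens[i], stringsAsFactors = FALSE)
      scaf <- paste0(scaf, strrep("N", glens[i]), pieces[i + 1L])
      at <- at + glens[i] + nchar(pieces[i + 1L])
    }
    scaff_seq[cid] <- scaf
  }
  gaps <- if (length(gap_rows)) do.call(rbind, c(unname(gap_rows), make.row.names = FALSE)) else
    data.frame(seq_id = character(), start = integer(), end = integer())
  list(
    contigs = genome_assembly(contigs_id, contigs_seq[contigs_id]),
    scaffolded = genome_assembly(assembly$id, scaff_seq[assembly$id]),
    truth = list(
      breaks = if (length(break_rows)) do.call(rbind, c(unname(break_rows), make.row.names = FALSE)) else
        data.frame(seq_id = character(), pos = integer()),
      gaps = gaps
    )
  )
}
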