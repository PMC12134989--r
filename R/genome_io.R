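#' @importFrom stats rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# ---- assembly container ------------------------------------------------------

#' Construct a genome assembly from parallel vectors
#'
#' An assembly is an ordered set of named nucleotide sequences. Order is
#' significant (it is preserved from the source FASTA) and ids must be unique.
#' Residues are stored case-preserving; analyses are case-insensitive.
#'
#' @param ids character vector of unique, non-empty sequence ids.
#' @param residues character vector of sequences (A/C/G/T/N plus IUPAC codes).
#' @param descriptions free-text descriptions (header text after the first
#'   whitespace); recycled to `""` when missing.
#' @return An object of class `genome_assembly`: a list with elements `id`,
#'   `description` and `residues` (named by id).
#' @export
genome_assembly <- function(ids, residues, descriptions = NULL) {
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("assembly must contain at least one sequence")
  if (any(!nzchar(ids))) stop("sequence ids must be non-empty")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (length(residues) != length(ids)) stop("ids and residues differ in length")
  if (is.null(descriptions)) descriptions <- rep("", length(ids))
  residues <- as.character(residues)
  names(residues) <- ids
  structure(
    list(id = ids, description = setNames(as.character(descriptions), ids),
         residues = residues),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly: %d sequence(s), %s bp total\n",
              length(x$id), format(sum(seq_lengths(x)), big.mark = ",")))
  show <- head(x$id, 6L)
  for (id in show) cat(sprintf("  %s  %s bp\n", id, format(nchar(x$residues[[id]]), big.mark = ",")))
  if (length(x$id) > 6L) cat(sprintf("  ... and %d more\n", length(x$id) - 6L))
  invisible(x)
}

#' @export
length.genome_assembly <- function(x) length(x$id)

#' Sequence lengths of an assembly
#' @param assembly a `genome_assembly`.
#' @return Named integer vector of lengths in bp, in file order.
#' @export
seq_lengths <- function(assembly) {
  setNames(nchar(assembly$residues), assembly$id)
}

#' Fetch one sequence from an assembly by id
#' @param assembly a `genome_assembly`.
#' @param id sequence id.
#' @return The residue string.
#' @export
get_seq <- function(assembly, id) {
  if (!id %in% assembly$id) stop("unknown sequence id: ", id)
  assembly$residues[[id]]
}

# ---- FASTA -------------------------------------------------------------------

#' Read a multi-record FASTA file
#'
#' Records are returned in file order; whitespace is stripped from sequence
#' lines; the description is the header text after the first whitespace.
#' Case (soft-masking) is preserved.
#'
#' @param path path to a FASTA file.
#' @return A `genome_assembly`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  headers <- vapply(recs, function(r) sub("^>", "", attr(r, "Annot")), "")
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(recs, function(r) gsub("\\s", "", as.character(r)[1]), "")
  genome_assembly(ids, seqs, desc)
}

#' Write an assembly to FASTA
#' @param assembly a `genome_assembly`.
#' @param path output path.
#' @param width line width for wrapped sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  nm <- ifelse(nzchar(assembly$description),
               paste(assembly$id, assembly$description), assembly$id)
  seqinr::write.fasta(as.list(unname(assembly$residues)), names = nm,
                      file.out = path, nbchar = width, as.string = TRUE)
  invisible(path)
}

# ---- GFF3 --------------------------------------------------------------------

# Internal coordinates are 0-based half-open everywhere; conversion to/from the
# 1-based inclusive convention of GFF3 happens only here.

.iv_mat <- function(start0, end0) {
  m <- cbind(start = as.integer(start0), end = as.integer(end0))
  m[order(m[, 1L]), , drop = FALSE]
}

#' Read a GFF3 annotation into gene models
#'
#' Understands the RefSeq dialect attributes `ID`, `Parent` and
#' `gene_biotype`. Coordinates are converted from 1-based inclusive to
#' internal 0-based half-open. A gene with no `gene_biotype` is inferred
#' protein_coding when any of its transcripts carries a CDS, else noncoding.
#'
#' @param path path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @return An `annotation_set`: list with `genes` (named list of gene models)
#'   and `by_seq` (seq_id -> gene ids). Each gene model has `gene_id`,
#'   `seq_id`, `strand`, `start`, `end` (0-based half-open span), `biotype`
#'   and `transcripts`, a named list of `list(exons =, cds =)` two-column
#'   interval matrices sorted by start.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(g, stringsAsFactors = FALSE)
  if (any(df$end < df$start)) {
    bad <- which(df$end < df$start)[1L]
    stop("feature with end < start at row ", bad)
  }
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  df$parent1 <- vapply(as.list(g$Parent), function(p) if (length(p)) p[[1L]] else NA_character_, "")
  ftype <- as.character(df$type)

  is_gene <- ftype %in% c("gene", "pseudogene")
  gene_rows <- which(is_gene)
  gene_ids <- df$ID[gene_rows]
  # transcript-level features: anything whose Parent is a gene
  is_tx <- !is_gene & !is.na(df$parent1) & df$parent1 %in% gene_ids &
    !ftype %in% c("exon", "CDS")
  tx_rows <- which(is_tx)
  tx_ids <- df$ID[tx_rows]
  tx_gene <- setNames(df$parent1[tx_rows], tx_ids)

  child_rows <- which(ftype %in% c("exon", "CDS"))
  if (length(child_rows)) {
    orphan <- !(df$parent1[child_rows] %in% c(tx_ids, gene_ids))
    if (any(orphan)) {
      stop("unresolvable Parent for feature(s): ",
           paste(head(df$ID[child_rows][orphan], 3L), collapse = ", "))
    }
  }

  genes <- vector("list", length(gene_rows))
  names(genes) <- gene_ids
  for (i in seq_along(gene_rows)) {
    r <- gene_rows[i]
    gid <- gene_ids[i]
    my_tx <- tx_ids[tx_gene == gid]
    tx_list <- list()
    for (tid in my_tx) {
      kid <- child_rows[df$parent1[child_rows] == tid]
      ex <- kid[ftype[kid] == "exon"]
      cd <- kid[ftype[kid] == "CDS"]
      tx_list[[tid]] <- list(
        exons = .iv_mat(df$start0[ex], df$end0[ex]),
        cds = .iv_mat(df$start0[cd], df$end0[cd])
      )
    }
    # exon/CDS features hanging directly off the gene (annotation shortcuts)
    kid <- child_rows[df$parent1[child_rows] == gid]
    if (length(kid)) {
      ex <- kid[ftype[kid] == "exon"]
      cd <- kid[ftype[kid] == "CDS"]
      tx_list[[paste0(gid, ".direct")]] <- list(
        exons = .iv_mat(df$start0[ex], df$end0[ex]),
        cds = .iv_mat(df$start0[cd], df$end0[cd])
      )
    }
    has_cds <- any(vapply(tx_list, function(t) nrow(t$cds) > 0L, TRUE))
    biotype <- df$gene_biotype[r]
    if (is.null(biotype) || is.na(biotype)) {
      biotype <- if (identical(ftype[r], "pseudogene")) "pseudogene"
                 else if (has_cds) "protein_coding" else "noncoding"
    }
    genes[[gid]] <- list(
      gene_id = gid, seq_id = as.character(df$seqnames[r]),
      strand = as.character(df$strand[r]),
      start = df$start0[r], end = df$end0[r],
      biotype = biotype, transcripts = tx_list
    )
  }
  by_seq <- split(gene_ids, vapply(genes, `[[`, "", "seq_id"))
  structure(list(genes = genes, by_seq = by_seq), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  bt <- table(vapply(x$genes, `[[`, "", "biotype"))
  cat(sprintf("annotation_set: %d gene(s) on %d sequence(s)\n",
              length(x$genes), length(x$by_seq)))
  cat("  ", paste(names(bt), as.integer(bt), collapse = ", "), "\n")
  invisible(x)
}

# union of intervals across transcripts, as a sorted non-overlapping matrix
.union_ivs <- function(mats) {
  mats <- mats[vapply(mats, nrow, 0L) > 0L]
  if (!length(mats)) return(.iv_mat(integer(), integer()))
  m <- do.call(rbind, mats)
  ir <- IRanges::reduce(IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L]))
  .iv_mat(IRanges::start(ir) - 1L, IRanges::end(ir))
}

#' Gene-level exon union across transcripts
#' @param gene a gene model from [read_gff3()].
#' @return Two-column matrix of 0-based half-open intervals.
#' @export
gene_exons <- function(gene) .union_ivs(lapply(gene$transcripts, `[[`, "exons"))

#' Gene-level CDS union across transcripts
#' @rdname gene_exons
#' @export
gene_cds <- function(gene) .union_ivs(lapply(gene$transcripts, `[[`, "cds"))

#' Introns of a gene: span minus exon union
#' @rdname gene_exons
#' @export
gene_introns <- function(gene) {
  ex <- gene_exons(gene)
  if (nrow(ex) == 0L) return(.iv_mat(integer(), integer()))
  exr <- IRanges::reduce(IRanges::IRanges(start = ex[, 1L] + 1L, end = ex[, 2L]))
  gaps <- IRanges::gaps(exr, start = gene$start + 1L, end = gene$end)
  .iv_mat(IRanges::start(gaps) - 1L, IRanges::end(gaps))
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS rows with ID/Parent/gene_biotype attributes,
#' converting internal 0-based half-open coordinates back to 1-based
#' inclusive.
#'
#' @param annotation an `annotation_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  rows <- character()
  fmt <- function(seq_id, type, s0, e0, strand, attrs) {
    sprintf("%s\tkillistat\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seq_id, type, s0 + 1L, e0, strand, attrs)
  }
  for (g in annotation$genes) {
    rows <- c(rows, fmt(g$seq_id, if (g$biotype == "pseudogene") "pseudogene" else "gene",
                        g$start, g$end, g$strand,
                        sprintf("ID=%s;gene_biotype=%s", g$gene_id, g$biotype)))
    for (tid in names(g$transcripts)) {
      tx <- g$transcripts[[tid]]
      ts <- if (nrow(tx$exons)) min(tx$exons[, 1L]) else g$start
      te <- if (nrow(tx$exons)) max(tx$exons[, 2L]) else g$end
      rows <- c(rows, fmt(g$seq_id, "mRNA", ts, te, g$strand,
                          sprintf("ID=%s;Parent=%s", tid, g$gene_id)))
      if (nrow(tx$exons)) {
        for (i in seq_len(nrow(tx$exons))) {
          rows <- c(rows, fmt(g$seq_id, "exon", tx$exons[i, 1L], tx$exons[i, 2L],
                              g$strand, sprintf("ID=%s.e%d;Parent=%s", tid, i, tid)))
        }
      }
      if (nrow(tx$cds)) {
        for (i in seq_len(nrow(tx$cds))) {
          rows <- c(rows, fmt(g$seq_id, "CDS", tx$cds[i, 1L], tx$cds[i, 2L],
                              g$strand, sprintf("ID=%s.c;Parent=%s", tid, tid)))
        }
      }
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

# ---- RepeatMasker .out -------------------------------------------------------

#' Read a RepeatMasker .out annotation file
#'
#' Expects the standard layout: two header lines plus a blank line, then
#' whitespace-delimited annotation rows. Query begin/end are converted from
#' 1-based inclusive to 0-based half-open.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return data.frame with columns `seq_id`, `begin`, `end` (0-based
#'   half-open), `strand` (`+`/`-`; RepeatMasker's `C` maps to `-`),
#'   `repeat_name`, `class_family`, `divergence_pct`.
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("RepeatMasker .out file not found: ", path)
  lines <- readLines(path)
  body <- if (length(lines) > 3L) lines[-seq_len(3L)] else character()
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_ln <- (3L + seq_along(keep))[keep]
  if (!length(body)) {
    return(data.frame(seq_id = character(), begin = integer(), end = integer(),
                      strand = character(), repeat_name = character(),
                      class_family = character(), divergence_pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(body), "\\s+")
  parse_row <- function(f, ln) {
    if (length(f) < 11L) stop("malformed RepeatMasker row at line ", ln)
    b <- suppressWarnings(as.integer(f[6L])); e <- suppressWarnings(as.integer(f[7L]))
    div <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(b) || is.na(e)) stop("non-numeric coordinates at line ", ln)
    if (e < b) stop("end < begin at line ", ln)
    data.frame(seq_id = f[5L], begin = b - 1L, end = e,
               strand = if (identical(f[9L], "C")) "-" else "+",
               repeat_name = f[10L], class_family = f[11L],
               divergence_pct = div, stringsAsFactors = FALSE)
  }
  do.call(rbind, Map(parse_row, fields, body_ln))
}

#' Write repeat hits in RepeatMasker .out layout
#' @param hits data.frame as returned by [read_repeatmasker_out()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(hits, path) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    ""
  )
  rows <- sprintf(" 1000 %5.1f  0.0  0.0  %s %8d %8d (0) %s  %-14s %-18s 1 100 (0) %d",
                  hits$divergence_pct, hits$seq_id, hits$begin + 1L, hits$end,
                  ifelse(hits$strand == "-", "C", "+"),
                  hits$repeat_name, hits$class_family, seq_len(nrow(hits)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
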