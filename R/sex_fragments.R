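# Phased X/Y fragment analysis: locate a marker locus in haplotype contigs,
# call X vs Y from diagnostic indels, compute per-gene gametolog divergence,
# and flag pseudogenization.

.kmer_starts <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, 1:(n - k + 1L), k:n)
}

# Seed-and-extend search of `query` against one residue string, one strand.
# Returns hits in subject coordinates (0-based half-open).
.search_one <- function(query, subject, k, band, pad, min_identity) {
  qk <- .kmer_starts(query, k)
  sk <- .kmer_starts(subject, k)
  valid <- function(km) !grepl("N", km, fixed = TRUE)
  shared <- intersect(qk[valid(qk)], sk[valid(sk)])
  if (!length(shared)) return(NULL)
  qi <- which(qk %in% shared)
  si <- which(sk %in% shared)
  qpos <- split(qi - 1L, qk[qi])
  spos <- split(si - 1L, sk[si])
  seeds <- do.call(rbind, lapply(shared, function(km) {
    qp <- qpos[[km]]; sp <- spos[[km]]
    if (length(qp) * length(sp) > 100L) return(NULL)  # repeat-saturated k-mer
    expand.grid(q = qp, s = sp)
  }))
  if (is.null(seeds) || nrow(seeds) == 0L) return(NULL)
  seeds$diag <- seeds$s - seeds$q
  seeds <- seeds[order(seeds$diag), , drop = FALSE]
  grp <- cumsum(c(1L, diff(seeds$diag) > band))
  qlen <- nchar(query); slen <- nchar(subject)
  hits <- lapply(split(seeds, grp), function(cl) {
    ws <- max(0L, min(cl$s) - min(cl$q) - pad)
    we <- min(slen, max(cl$s) + k + (qlen - max(cl$q) - k) + pad)
    if (we - ws < k) return(NULL)
    window <- substr(subject, ws + 1L, we)
    al <- .align_nt_global(query, window, type = "global-local")
    st <- .aln_columns(al$a, al$b)
    # identity over aligned (non-gap) columns, so an indel-bearing copy of
    # the locus is not rejected on gap columns alone
    ident <- st$matches / st$aligned_columns
    if (ident < min_identity) return(NULL)
    rng <- Biostrings::subject(al$pa)
    data.frame(begin = ws + BiocGenerics::start(rng) - 1L,
               end = ws + BiocGenerics::end(rng),
               identity = ident, score = al$score, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  hits
}

#' Locate a marker locus in assembly contigs
#'
#' Seed-and-extend search: exact k-mer seeds are clustered by diagonal and
#' each cluster is extended by aligning the whole marker into a padded
#' subject window (affine-gap alignment, BLAST-like scores). Both strands
#' are searched; overlapping hits on a contig are merged by keeping the
#' highest-scoring one.
#'
#' @param marker the marker sequence (residue string).
#' @param contigs a `genome_assembly` of contigs to search.
#' @param min_identity minimum alignment identity to report (default 0.9).
#' @param k seed k-mer size (default 15).
#' @param band diagonal clustering bandwidth in bp (default 400; at least
#'   the largest indel expected between marker and target).
#' @param pad window padding in bp.
#' @return data.frame of hits sorted by decreasing score: `contig_id`,
#'   `begin`, `end` (0-based half-open, forward-strand coordinates),
#'   `strand`, `identity`, `score`.
#' @export
locate_marker <- function(marker, contigs, min_identity = 0.9, k = 15L,
                          band = 400L, pad = 100L) {
  if (nchar(marker) < k) stop("marker shorter than seed size k = ", k)
  empty <- data.frame(contig_id = character(), begin = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  out <- list()
  for (id in contigs$id) {
    subj <- contigs$residues[[id]]
    clen <- nchar(subj)
    fwd <- .search_one(marker, subj, k, band, pad, min_identity)
    if (!is.null(fwd) && nrow(fwd)) {
      fwd$strand <- "+"
    }
    rev_ <- .search_one(marker, revcomp(subj), k, band, pad, min_identity)
    if (!is.null(rev_) && nrow(rev_)) {
      b <- clen - rev_$end; e <- clen - rev_$begin
      rev_$begin <- b; rev_$end <- e
      rev_$strand <- "-"
    }
    h <- rbind(fwd, rev_)
    if (is.null(h) || nrow(h) == 0L) next
    h$contig_id <- id
    # greedy merge: keep best-scoring hit, drop others overlapping it
    h <- h[order(-h$score), , drop = FALSE]
    kept <- h[0L, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      if (nrow(kept) == 0L ||
          all(h$begin[i] >= kept$end | h$end[i] <= kept$begin)) {
        kept <- rbind(kept, h[i, , drop = FALSE])
      }
    }
    out[[id]] <- kept
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, unname(out))
  res <- res[order(-res$score), c("contig_id", "begin", "end", "strand",
                                  "identity", "score")]
  rownames(res) <- NULL
  res
}

#' Build a table of diagnostic features
#'
#' Convenience constructor for the features that distinguish the Y-linked
#' copy of a locus from the X-linked reference (e.g. a 9-bp deletion in the
#' coding sequence and a 241-bp deletion in the 3'-UTR).
#'
#' @param name feature names.
#' @param kind `"deletion"`, `"insertion"` or `"substitution"`.
#' @param region `"CDS"`, `"UTR3"`, `"UTR5"` or `"other"`.
#' @param ref_start,ref_end 0-based half-open interval on the X-reference
#'   marker sequence.
#' @return data.frame of diagnostics with a `length` column.
#' @export
diagnostic_features <- function(name, kind, region, ref_start, ref_end) {
  stopifnot(all(kind %in% c("deletion", "insertion", "substitution")),
            all(ref_end > ref_start))
  data.frame(name = name, kind = kind, region = region,
             length = as.integer(ref_end - ref_start),
             ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
             stringsAsFactors = FALSE)
}

#' Call X or Y haplotype from diagnostic features
#'
#' Globally aligns the hit region to the X-reference marker and scores each
#' diagnostic: a deletion is "present" when the region shows a gap of length
#' within `tol` bp at the feature's reference coordinates (start within
#' `tol`). The call is Y iff all diagnostics are present, X iff all are
#' absent, otherwise ambiguous. A region that does not cover a diagnostic's
#' coordinates (terminal truncation) scores that feature "untestable" and
#' forces an ambiguous call.
#'
#' @param region_seq sequence of the candidate region (forward orientation
#'   relative to the reference).
#' @param x_reference the X-linked reference marker sequence.
#' @param diagnostics data.frame from [diagnostic_features()].
#' @param tol positional/length tolerance in bp (default 1).
#' @param contig_id optional id recorded in the result.
#' @return list with `contig_id`, `call` (`"X"`, `"Y"` or `"ambiguous"`) and
#'   `evidence` (named character: present/absent/untestable per feature).
#' @export
classify_haplotype <- function(region_seq, x_reference, diagnostics,
                               tol = 1L, contig_id = NA_character_) {
  al <- .align_nt_global(x_reference, region_seq)
  rc <- strsplit(toupper(al$a), "")[[1L]]   # reference, gapped
  tc <- strsplit(toupper(al$b), "")[[1L]]   # region, gapped
  ncol_ <- length(rc)
  ref_pos <- cumsum(rc != "-") - 1L         # ref coord per column (-1 before first)
  # terminal gaps in the region mark reference coords it does not cover
  lead <- if (tc[1L] == "-") rle(tc == "-")$lengths[1L] else 0L
  tr <- rle(rev(tc) == "-")
  trail <- if (tr$values[1L]) tr$lengths[1L] else 0L
  covered_lo <- if (lead > 0L) ref_pos[lead] + 1L else 0L
  covered_hi <- if (trail > 0L) ref_pos[ncol_ - trail] + 1L else sum(rc != "-")
  # non-terminal columns (terminal gaps are truncation, not deletion)
  internal <- seq_len(ncol_) > lead & seq_len(ncol_) <= ncol_ - trail
  evidence <- character(nrow(diagnostics))
  names(evidence) <- diagnostics$name
  pad <- max(tol, 10L)  # positional slack; long gaps can be split by the aligner
  for (i in seq_len(nrow(diagnostics))) {
    d <- diagnostics[i, ]
    if (d$ref_start < covered_lo || d$ref_end > covered_hi) {
      evidence[i] <- "untestable"
      next
    }
    in_window <- ref_pos >= d$ref_start - pad & ref_pos < d$ref_end + pad
    present <- switch(
      d$kind,
      deletion = {
        # net reference bases absent from the region near the feature coords
        n_del <- sum(in_window & internal & rc != "-" & tc == "-")
        abs(n_del - d$length) <= tol
      },
      insertion = {
        n_ins <- sum(in_window & internal & rc == "-" & tc != "-")
        abs(n_ins - d$length) <= tol
      },
      substitution = {
        cols <- which(ref_pos >= d$ref_start & ref_pos < d$ref_end &
                        rc != "-" & tc != "-")
        length(cols) > 0L && all(tc[cols] != rc[cols])
      }
    )
    evidence[i] <- if (present) "present" else "absent"
  }
  call <- if (any(evidence == "untestable")) "ambiguous"
          else if (all(evidence == "present")) "Y"
          else if (all(evidence == "absent")) "X"
          else "ambiguous"
  list(contig_id = contig_id, call = call, evidence = evidence)
}

#' Nucleotide and amino-acid divergence between two coding sequences
#'
#' Globally aligns the nucleotide sequences; nucleotide divergence is
#' substitutions over aligned non-gap columns (indels excluded from the
#' proportion by default, so a deletion does not inflate divergence; set
#' `denominator = "alignment"` to divide by all alignment columns instead).
#' Both inputs are then translated in frame 1 with the standard genetic code
#' (trailing partial codons dropped) and the proteins aligned the same way
#' for the amino-acid divergence.
#'
#' @param cds_a,cds_b coding sequences (length >= 3).
#' @param gene_id optional id carried into the record.
#' @param denominator `"nongap"` (default) or `"alignment"`.
#' @return list: `gene_id`, `nt_divergence`, `aa_divergence`,
#'   `aligned_columns`, `substitutions`, `indel_events`, plus
#'   `aa_aligned_columns` and `aa_substitutions` from the protein alignment.
#' @export
cds_divergence <- function(cds_a, cds_b, gene_id = NA_character_,
                           denominator = c("nongap", "alignment")) {
  denominator <- match.arg(denominator)
  if (!nzchar(cds_a) || !nzchar(cds_b)) stop("empty coding sequence")
  if (nchar(cds_a) < 3L || nchar(cds_b) < 3L) stop("coding sequence shorter than one codon")
  al <- .align_nt_global(cds_a, cds_b)
  st <- .aln_columns(al$a, al$b)
  denom <- if (denominator == "nongap") st$aligned_columns else st$columns
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  alp <- align_protein_pair(pa, pb)
  stp <- .aln_columns(alp$aligned_a, alp$aligned_b)
  denom_p <- if (denominator == "nongap") stp$aligned_columns else stp$columns
  list(gene_id = gene_id,
       nt_divergence = st$substitutions / denom,
       aa_divergence = stp$substitutions / denom_p,
       aligned_columns = st$aligned_columns,
       substitutions = st$substitutions,
       indel_events = st$indel_events,
       aa_aligned_columns = stp$aligned_columns,
       aa_substitutions = stp$substitutions)
}

#' Scan a target for pseudogenization of a reference gene
#'
#' Each reference exon is searched in the target (both strands). An exon is
#' missing when its best alignment identity falls below `min_exon_identity`.
#' The start codon is checked by reading the target residues homologous to
#' the first three bases of the first exon. A locus is flagged when the
#' start codon is absent or at least one exon is missing.
#'
#' @param reference_exons list/vector of exon sequences in gene order; the
#'   first exon must begin at the annotated ATG.
#' @param target a residue string or single-sequence `genome_assembly`.
#' @param min_exon_identity identity threshold per exon (default 0.8).
#' @return list: `start_codon_present`, `exons_total`, `exons_missing`,
#'   `flagged`, and `per_exon` (identity per exon; NA when no alignment).
#' @export
pseudogene_scan <- function(reference_exons, target, min_exon_identity = 0.8) {
  if (length(reference_exons) == 0L) stop("need at least one reference exon")
  if (inherits(target, "genome_assembly")) target <- target$residues[[1L]]
  best_aln <- function(exon) {
    cand <- list(list(seq = target, strand = "+"),
                 list(seq = revcomp(target), strand = "-"))
    best <- NULL
    for (cd in cand) {
      if (nchar(cd$seq) < nchar(exon)) next
      al <- .align_nt_global(exon, cd$seq, type = "global-local")
      st <- .aln_columns(al$a, al$b)
      ident <- st$matches / st$columns
      if (is.null(best) || ident > best$ident) best <- list(al = al, ident = ident)
    }
    best
  }
  per_exon <- numeric(length(reference_exons))
  alns <- vector("list", length(reference_exons))
  for (i in seq_along(reference_exons)) {
    b <- best_aln(as.character(reference_exons[[i]]))
    per_exon[i] <- if (is.null(b)) NA_real_ else b$ident
    alns[[i]] <- b
  }
  missing <- is.na(per_exon) | per_exon < min_exon_identity
  start_ok <- FALSE
  if (!missing[1L]) {
    al <- alns[[1L]]$al
    ec <- strsplit(toupper(al$a), "")[[1L]]
    tc <- strsplit(toupper(al$b), "")[[1L]]
    first3 <- which(cumsum(ec != "-") %in% 1:3 & ec != "-")
    start_ok <- length(first3) == 3L && identical(paste(tc[first3], collapse = ""), "ATG")
  }
  list(start_codon_present = start_ok,
       exons_total = length(reference_exons),
       exons_missing = sum(missing),
       flagged = !start_ok || any(missing),
       per_exon = per_exon)
}

#' Per-gene divergence of X and Y fragments against reference CDSs
#'
#' For each reference coding sequence, finds its best hit in the X fragment
#' and in the Y fragment ([locate_marker()]), extracts the hit region
#' (reverse-complemented for minus-strand hits) and computes
#' [cds_divergence()] against the reference. Genes with no hit at
#' `min_identity` are reported with `found = FALSE`.
#'
#' @param gene_set named list/vector of reference CDS strings.
#' @param x_fragment,y_fragment residue strings (or single-sequence
#'   assemblies) for the two haplotype fragments.
#' @param min_identity hit acceptance threshold (default 0.8).
#' @return data.frame with one row per gene and haplotype: `gene_id`,
#'   `haplotype`, `found`, `nt_divergence`, `aa_divergence`,
#'   `aligned_columns`, `substitutions`, `indel_events`.
#' @export
region_gene_divergence <- function(gene_set, x_fragment, y_fragment,
                                   min_identity = 0.8) {
  frag_of <- function(x, nm) {
    if (inherits(x, "genome_assembly")) x else genome_assembly(nm, x)
  }
  frags <- list(X = frag_of(x_fragment, "X"), Y = frag_of(y_fragment, "Y"))
  rows <- list()
  for (gid in names(gene_set)) {
    ref <- as.character(gene_set[[gid]])
    for (hap in names(frags)) {
      hits <- locate_marker(ref, frags[[hap]], min_identity = min_identity)
      if (nrow(hits) == 0L) {
        rows[[paste(gid, hap)]] <- data.frame(
          gene_id = gid, haplotype = hap, found = FALSE,
          nt_divergence = NA_real_, aa_divergence = NA_real_,
          aligned_columns = NA_integer_, substitutions = NA_integer_,
          indel_events = NA_integer_, stringsAsFactors = FALSE)
        next
      }
      h <- hits[1L, ]
      region <- substr(frags[[hap]]$residues[[h$contig_id]], h$begin + 1L, h$end)
      if (h$strand == "-") region <- revcomp(region)
      d <- cds_divergence(ref, region, gene_id = gid)
      rows[[paste(gid, hap)]] <- data.frame(
        gene_id = gid, haplotype = hap, found = TRUE,
        nt_divergence = d$nt_divergence, aa_divergence = d$aa_divergence,
        aligned_columns = d$aligned_columns, substitutions = d$substitutions,
        indel_events = d$indel_events, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(unname(rows), make.row.names = FALSE))
  res[order(res$gene_id, res$haplotype), , drop = FALSE]
}
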