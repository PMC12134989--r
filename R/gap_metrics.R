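# Contiguity and gap statistics: maximal N-run detection, Nx values with
# their rank, and whole-assembly reports with placed/unplaced accounting.

#' Find maximal runs of N in a sequence
#'
#' A gap is a maximal run of `N`/`n` characters (minimum length 1 by
#' default). Other IUPAC ambiguity codes are not gaps.
#'
#' @param residues a residue string, or a `genome_assembly` (then all
#'   sequences are scanned).
#' @param seq_id id to record when `residues` is a plain string.
#' @param min_length minimum run length to report.
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), sorted by `start` within each sequence.
#' @export
find_gap_runs <- function(residues, seq_id = "seq", min_length = 1L) {
  if (inherits(residues, "genome_assembly")) {
    runs <- lapply(residues$id, function(id) {
      find_gap_runs(residues$residues[[id]], seq_id = id, min_length = min_length)
    })
    return(do.call(rbind, runs))
  }
  m <- gregexpr("[Nn]+", residues)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  keep <- len >= min_length
  data.frame(seq_id = rep(seq_id, sum(keep)),
             start = as.integer(m[keep]) - 1L,
             end = as.integer(m[keep]) - 1L + len[keep],
             stringsAsFactors = FALSE)
}

#' Nx statistic of a set of sequence lengths
#'
#' Sorts lengths descending and returns the length at which the cumulative
#' sum first reaches `level`% of the total, together with its 1-based rank
#' (the "n" conventionally reported next to N50/N90: the number of sequences
#' at least that long contributing to the threshold).
#'
#' @param lengths positive sequence lengths in bp.
#' @param level percentage in (0, 100].
#' @return list with `level`, `value` (bp) and `rank`.
#' @export
nx <- function(lengths, level = 50) {
  if (length(lengths) == 0L) stop("nx() needs a non-empty length vector")
  if (any(lengths <= 0)) stop("all lengths must be positive")
  if (level <= 0 || level > 100) stop("level must be in (0, 100]")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  i <- which(cum >= level / 100 * sum(s))[1L]
  list(level = level, value = s[i], rank = i)
}

#' Whole-assembly contiguity report
#'
#' Computes total length, sequence count, N50/N90 with ranks, gap counts,
#' total N bases, and (when `chromosome_ids` is given) placed/unplaced
#' accounting. Records listed in `exclude_ids` (e.g. the mitochondrial
#' record) are left out of the placed/unplaced split but still count toward
#' the assembly totals.
#'
#' @param assembly a `genome_assembly`.
#' @param chromosome_ids ids of chromosome-scale records, or NULL.
#' @param exclude_ids ids excluded from placed/unplaced accounting.
#' @param min_gap_length minimum N-run length counted as a gap.
#' @return An `assembly_report` list: `total_length`, `num_sequences`, `n50`,
#'   `n90`, `total_N`, `num_gaps`, `per_seq_lengths`, and when applicable
#'   `placed_length`, `unplaced_count`, `unplaced_length`.
#' @export
assembly_report <- function(assembly, chromosome_ids = NULL, exclude_ids = NULL,
                            min_gap_length = 1L) {
  lens <- seq_lengths(assembly)
  gaps <- find_gap_runs(assembly, min_length = min_gap_length)
  rep <- list(
    total_length = sum(as.numeric(lens)),
    num_sequences = length(lens),
    n50 = nx(lens, 50), n90 = nx(lens, 90),
    total_N = if (nrow(gaps)) sum(as.numeric(gaps$end - gaps$start)) else 0,
    num_gaps = nrow(gaps),
    per_seq_lengths = lens
  )
  if (!is.null(chromosome_ids)) {
    unknown <- setdiff(chromosome_ids, assembly$id)
    if (length(unknown)) stop("unknown chromosome id(s): ", paste(unknown, collapse = ", "))
    unplaced <- setdiff(assembly$id, c(chromosome_ids, exclude_ids))
    rep$placed_length <- sum(as.numeric(lens[chromosome_ids]))
    rep$unplaced_count <- length(unplaced)
    rep$unplaced_length <- sum(as.numeric(lens[unplaced]))
  }
  structure(rep, class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("assembly_report: %s bp in %d sequence(s)\n",
              format(x$total_length, big.mark = ","), x$num_sequences))
  cat(sprintf("  N50 %s (n = %d); N90 %s (n = %d)\n",
              format(x$n50$value, big.mark = ","), x$n50$rank,
              format(x$n90$value, big.mark = ","), x$n90$rank))
  cat(sprintf("  gaps: %d run(s) of N totalling %s bp\n",
              x$num_gaps, format(x$total_N, big.mark = ",")))
  if (!is.null(x$placed_length)) {
    cat(sprintf("  placed %s bp; %d unplaced sequence(s), %s bp\n",
                format(x$placed_length, big.mark = ","), x$unplaced_count,
                format(x$unplaced_length, big.mark = ",")))
  }
  invisible(x)
}

#' One-row data.frame view of an assembly report
#' @param x an `assembly_report`.
#' @param ... unused.
#' @return data.frame with the report's scalar columns.
#' @export
as.data.frame.assembly_report <- function(x, ...) {
  data.frame(total_length = x$total_length, num_sequences = x$num_sequences,
             n50 = x$n50$value, n50_rank = x$n50$rank,
             n90 = x$n90$value, n90_rank = x$n90$rank,
             total_N = x$total_N, num_gaps = x$num_gaps,
             placed_length = if (is.null(x$placed_length)) NA_real_ else x$placed_length,
             unplaced_count = if (is.null(x$unplaced_count)) NA_integer_ else x$unplaced_count,
             unplaced_length = if (is.null(x$unplaced_length)) NA_real_ else x$unplaced_length,
             stringsAsFactors = FALSE)
}
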