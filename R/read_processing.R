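#' Quality-weighted poly(A) tail trimming
#'
#' 3'-biased RNA-seq reads frequently run into the mRNA poly(A) tail. For
#' every candidate number of kept bases i (0 = trim everything, read length
#' = trim nothing) a score is computed over the removed suffix:
#' the sum of the quality scores of each A after position i minus three
#' times the sum of the quality scores of each non-A after position i
#' (s = 0 when nothing is removed). All bases after the highest-scoring
#' position are removed, but only if that removes at least `min_trim` bases;
#' ties in the maximum are broken toward keeping more bases. N bases count
#' as non-A.
#'
#' @param bases character scalar over A/C/G/T/N.
#' @param qualities integer vector of Phred scores, one per base.
#' @param min_trim minimum number of bases a trim must remove to be applied.
#' @return list with `bases`, `qualities`, and `trimmed` (bases removed).
#' @export
trim_polya <- function(bases, qualities, min_trim = 3) {
  stopifnot(is.character(bases), length(bases) == 1, nchar(bases) > 0)
  b <- strsplit(bases, "", fixed = TRUE)[[1]]
  if (length(qualities) != length(b)) {
    stop("bases and qualities differ in length")
  }
  if (any(qualities < 0)) stop("negative quality score")
  s <- polya_trim_scores(b, qualities)
  keep <- max(which(s == max(s))) - 1L # index i = bases kept; prefer longest
  n <- length(b)
  if (n - keep >= min_trim) {
    list(bases = substr(bases, 1L, keep),
         qualities = qualities[seq_len(keep)],
         trimmed = n - keep)
  } else {
    list(bases = bases, qualities = qualities, trimmed = 0L)
  }
}

# suffix scores s_i for i = 0..n kept bases: contribution of each removed
# base is +Q for A, -3Q otherwise
polya_trim_scores <- function(b, q) {
  contrib <- ifelse(b == "A", q, -3 * q)
  c(rev(cumsum(rev(contrib))), 0)
}

#' Trim poly(A) tails from a FASTQ file
#'
#' Applies [trim_polya()] to every record of an (uncompressed) FASTQ file.
#' An optional fixed-window pre-trim (`clip_start`/`clip_end`) harmonizes
#' read lengths across sequencing platforms before tail trimming.
#'
#' @param infile,outfile paths to uncompressed FASTQ files.
#' @param min_trim see [trim_polya()].
#' @param clip_start,clip_end bases clipped unconditionally from read ends
#'   before tail trimming.
#' @param phred_offset ASCII offset of the quality encoding (33 = Sanger).
#' @return invisibly, the number of reads written.
#' @export
trim_polya_fastq <- function(infile, outfile, min_trim = 3,
                             clip_start = 0L, clip_end = 0L,
                             phred_offset = 33L) {
  lines <- readLines(infile)
  stopifnot(length(lines) %% 4 == 0)
  out <- character(length(lines))
  for (i in seq(1, length(lines), by = 4)) {
    seqs <- lines[i + 1L]
    qstr <- lines[i + 3L]
    n <- nchar(seqs)
    lo <- clip_start + 1L
    hi <- n - clip_end
    seqs <- substr(seqs, lo, hi)
    qstr <- substr(qstr, lo, hi)
    q <- utf8ToInt(qstr) - phred_offset
    tr <- trim_polya(seqs, q, min_trim = min_trim)
    out[i] <- lines[i]
    out[i + 1L] <- tr$bases
    out[i + 2L] <- lines[i + 2L]
    out[i + 3L] <- intToUtf8(tr$qualities + phred_offset)
  }
  writeLines(out, outfile)
  invisible(length(lines) / 4)
}

#' Filter ambiguous alignments of a single read
#'
#' Given the candidate alignments of one read (edit distance: 1 per
#' mismatch, 2 per indel), the read is discarded when the difference in edit
#' distance between its best and second-best alignment is within `margin`,
#' or when equally-best alignments map to more than one distinct genomic
#' position. Equal-best candidates at the same `genomic_key` (the canonical
#' genome coordinate after projecting transcriptome hits through splice
#' gaps) are consolidated into a single alignment, so a read hitting both a
#' genomic locus and a spliced transcript of the same locus survives.
#'
#' @param candidates data frame with columns `reference`, `position`,
#'   `strand`, `edit_distance`, `genomic_key`; all rows belong to one read.
#'   May be empty (unmapped read).
#' @param margin minimum edit-distance advantage the best alignment must
#'   have over the runner-up at a different position.
#' @return a one-row data frame (the consolidated best alignment) or `NULL`
#'   if the read is unmapped or discarded as ambiguous.
#' @export
filter_ambiguous <- function(candidates, margin = 3) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  stopifnot(all(candidates$edit_distance >= 0))
  best <- min(candidates$edit_distance)
  at_best <- candidates[candidates$edit_distance == best, , drop = FALSE]
  if (length(unique(at_best$genomic_key)) > 1) return(NULL)
  others <- candidates$edit_distance[candidates$genomic_key !=
                                       at_best$genomic_key[1]]
  if (length(others) && min(others) - best <= margin) return(NULL)
  out <- at_best[order(at_best$position), , drop = FALSE][1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a table of candidate alignments, read by read
#'
#' @param candidates data frame as in [filter_ambiguous()] plus a `read_id`
#'   column.
#' @param margin see [filter_ambiguous()].
#' @return list with `kept` (data frame of consolidated alignments, one row
#'   per surviving read) and `filtered_read_ids` (reads discarded as
#'   ambiguous, as opposed to unmapped).
#' @export
filter_alignments <- function(candidates, margin = 3) {
  pieces <- split(candidates, candidates$read_id)
  kept <- list()
  dropped <- character(0)
  for (rid in names(pieces)) {
    res <- filter_ambiguous(pieces[[rid]], margin = margin)
    if (is.null(res)) {
      dropped <- c(dropped, rid)
    } else {
      res$read_id <- rid
      kept[[rid]] <- res
    }
  }
  kept <- if (length(kept)) do.call(rbind, kept) else NULL
  list(kept = kept, filtered_read_ids = dropped)
}
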