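# Segment universe: in-silico digestion and fragment merging.

#' Digest chromosome sequences at a restriction motif
#'
#' Cuts every chromosome at each occurrence of `motif`, placing the cut at the
#' motif start (the blunt 5' cut of DpnII at GATC). Fragments tile each
#' chromosome without gaps or overlaps.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param motif Recognition motif, e.g. `"GATC"` for DpnII.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), one row per restriction fragment. A chromosome without any
#'   motif occurrence yields a single fragment spanning it; an empty sequence
#'   yields no fragments.
#' @examples
#' digest_genome(c(chr1 = "AAAAGATCAAAA"), "GATC")
#' @export
digest_genome <- function(sequences, motif = "GATC") {
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (is.null(names(sequences)) || anyNA(names(sequences))) {
    stop("sequences must be named by chromosome")
  }
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  out <- lapply(seq_along(sequences), function(i) {
    seq_i <- sequences[[i]]
    len <- length(seq_i)
    if (len == 0L) return(NULL)
    hits <- Biostrings::matchPattern(motif, seq_i)
    cuts <- BiocGenerics::start(hits) - 1L  # 0-based motif starts
    cuts <- cuts[cuts > 0L]                 # a cut at 0 is the chromosome start
    bounds <- c(0L, cuts, len)
    data.frame(
      chrom = names(sequences)[i],
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      stringsAsFactors = FALSE
    )
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Merge restriction fragments into segments
#'
#' Greedy left-to-right merging: consecutive fragments are accumulated until
#' the running length reaches `min_len`, at which point a segment is emitted.
#' A trailing remainder shorter than `min_len` is absorbed into the previously
#' emitted segment. A single fragment already longer than `min_len` forms its
#' own segment and is never split, so segments longer than 1 kb can occur.
#'
#' The fragment-end count `n_ends` of a segment built from m fragments is
#' m + 1 (its two boundaries plus the m - 1 interior restriction sites).
#'
#' @param fragments data.frame from [digest_genome()]; must tile each
#'   chromosome (sorted, gap-free).
#' @param min_len Minimum segment length in bp (default 500).
#' @return A data.frame of segments with columns `chrom`, `start`, `end`,
#'   `id` (ordinal over the whole genome), `length`, `n_ends`, `center`
#'   (floor of the midpoint).
#' @export
merge_fragments <- function(fragments, min_len = 500) {
  .assert_df_cols(fragments, c("chrom", "start", "end"), "fragments")
  if (any(fragments$end <= fragments$start)) stop("malformed fragments: end <= start")
  parts <- split(fragments, factor(fragments$chrom, levels = unique(fragments$chrom)))
  segs <- lapply(parts, function(fr) {
    fr <- fr[order(fr$start), , drop = FALSE]
    if (any(fr$start[-1L] != fr$end[-nrow(fr)])) {
      stop("fragments do not tile chromosome ", fr$chrom[1L],
           ": malformed digestion input")
    }
    n <- nrow(fr)
    starts <- integer(0); ends <- integer(0); nfrag <- integer(0)
    i <- 1L
    while (i <= n) {
      j <- i
      acc <- fr$end[j] - fr$start[i]
      while (acc < min_len && j < n) {
        j <- j + 1L
        acc <- fr$end[j] - fr$start[i]
      }
      if (acc < min_len && length(starts)) {
        # trailing remainder: absorb into the previous segment
        ends[length(ends)] <- fr$end[j]
        nfrag[length(nfrag)] <- nfrag[length(nfrag)] + (j - i + 1L)
      } else {
        starts <- c(starts, fr$start[i])
        ends <- c(ends, fr$end[j])
        nfrag <- c(nfrag, j - i + 1L)
      }
      i <- j + 1L
    }
    data.frame(chrom = fr$chrom[1L], start = starts, end = ends,
               n_frag = nfrag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(segs, list(make.row.names = FALSE)))
  out$id <- seq_len(nrow(out))
  out$length <- out$end - out$start
  out$n_ends <- out$n_frag + 1L
  out$n_frag <- NULL
  out$center <- (out$start + out$end) %/% 2L
  out[, c("chrom", "start", "end", "id", "length", "n_ends", "center")]
}

#' Center-to-center distance between two segments
#'
#' @param a,b Single-row segment data.frames (or rows of the segment table).
#' @return Genomic distance in bp between segment centers.
#' @export
segment_distance <- function(a, b) {
  if (a$chrom != b$chrom) {
    stop("segments lie on different chromosomes; inter-chromosomal pairs are not supported")
  }
  abs(a$center - b$center)
}

#' Promoter regions around TSSs
#'
#' @param genes data.frame with columns `id`, `chrom`, `strand`, `tss`, `tts`.
#' @param flank Half-width in bp (default 500, i.e. TSS +/- 500 bp).
#' @param chrom_sizes Named vector of chromosome lengths for clipping.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `clipped` (TRUE when
#'   the region was truncated at a chromosome edge).
#' @export
promoter_regions <- function(genes, flank = 500, chrom_sizes = NULL) {
  .assert_df_cols(genes, c("id", "chrom", "tss"), "genes")
  start <- genes$tss - flank
  end <- genes$tss + flank
  clipped <- start < 0L
  start <- pmax(start, 0L)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[genes$chrom])
    clipped <- clipped | end > lim
    end <- pmin(end, lim)
  }
  data.frame(gene_id = genes$id, chrom = genes$chrom,
             start = start, end = end, clipped = clipped,
             stringsAsFactors = FALSE)
}

#' Tag segments overlapping centromeric intervals
#'
#' Any overlap with a masked interval marks the segment as centromeric;
#' downstream filtering drops every contact touching a tagged segment.
#'
#' @param segments Segment table from [merge_fragments()].
#' @param mask data.frame `chrom`, `start`, `end` of excluded intervals, or
#'   NULL for no mask.
#' @return `segments` with a logical `centromeric` column added.
#' @export
tag_centromeric <- function(segments, mask = NULL) {
  .assert_segments(segments)
  segments$centromeric <- FALSE
  if (is.null(mask) || nrow(mask) == 0L) return(segments)
  hits <- GenomicRanges::findOverlaps(.as_granges(segments), .as_granges(mask))
  segments$centromeric[unique(S4Vectors::queryHits(hits))] <- TRUE
  segments
}
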