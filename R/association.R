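# Feature-overlap flags and shift-coordinate / neighbor-reassignment
# permutation nulls for enrichment analyses.

#' Flag promoters covered by peaks
#'
#' A promoter is flagged when at least `min_overlap_frac` of its bases is
#' covered by the union of the peak intervals.
#'
#' @param promoters data.frame from [promoter_regions()].
#' @param peaks data.frame `chrom`, `start`, `end` of peak intervals
#'   (overlapping peaks are merged internally).
#' @param min_overlap_frac Minimum covered fraction (default 0.3, inclusive).
#' @return Logical vector, one flag per promoter row.
#' @export
flag_promoters <- function(promoters, peaks, min_overlap_frac = 0.3) {
  .assert_df_cols(promoters, c("chrom", "start", "end"), "promoters")
  if (nrow(peaks) == 0L) return(rep(FALSE, nrow(promoters)))
  pg <- .as_granges(promoters)
  kg <- GenomicRanges::reduce(.as_granges(peaks))
  cov <- numeric(nrow(promoters))
  hits <- GenomicRanges::findOverlaps(pg, kg)
  if (length(hits)) {
    inter <- IRanges::pintersect(pg[S4Vectors::queryHits(hits)],
                                 kg[S4Vectors::subjectHits(hits)])
    w <- BiocGenerics::width(inter)
    agg <- rowsum(w, S4Vectors::queryHits(hits))
    cov[as.integer(rownames(agg))] <- agg[, 1L]
  }
  cov >= min_overlap_frac * (promoters$end - promoters$start)
}

# map each segment id to the overlapping promoter row with maximal overlap;
# ties broken by nearest TSS (promoter midpoint). Returns promoter row index
# or NA.
.segment_to_promoter <- function(seg_ids, segments, promoters) {
  segs <- segments[match(seg_ids, segments$id), , drop = FALSE]
  sg <- .as_granges(segs)
  pg <- .as_granges(promoters)
  hits <- GenomicRanges::findOverlaps(sg, pg)
  out <- rep(NA_integer_, length(seg_ids))
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- BiocGenerics::width(IRanges::pintersect(sg[q], pg[s]))
  tss <- (promoters$start + promoters$end) / 2
  dist_tss <- abs(segs$center[q] - tss[s])
  ord <- order(q, -ov, dist_tss)
  q <- q[ord]; s <- s[ord]
  first <- !duplicated(q)
  out[q[first]] <- s[first]
  out
}

#' Promoter-pair interactions among called loops
#'
#' A promoter-pair interaction is a significant loop of span at least
#' `min_span` whose two segments each overlap (>= 1 bp) a distinct promoter.
#' Segments overlapping several promoters are assigned to the promoter with
#' maximal overlap (ties to the nearest TSS). Convergent, divergent and
#' tandem orientations all count.
#'
#' @param loops Significant loops (or a `loop_calls` object; only
#'   `significant` rows are used when the column is present).
#' @param segments Segment table.
#' @param promoters Promoter table ([promoter_regions()]).
#' @param flags Logical vector of promoter flags ([flag_promoters()]).
#' @param min_span Minimum loop span in bp (default 6000, inclusive).
#' @return list `n_pairs`, `n_dual_flagged`, and `pairs` (data.frame with the
#'   promoter row indices and flags of each interaction).
#' @export
promoter_pair_interactions <- function(loops, segments, promoters, flags,
                                       min_span = 6000) {
  if ("significant" %in% names(loops)) {
    loops <- loops[loops$significant, , drop = FALSE]
  }
  loops <- loops[loops$D >= min_span, , drop = FALSE]
  if (!nrow(loops)) {
    return(list(n_pairs = 0L, n_dual_flagged = 0L,
                pairs = data.frame(prom_a = integer(0), prom_b = integer(0),
                                   dual_flagged = logical(0))))
  }
  pa <- .segment_to_promoter(loops$seg_a, segments, promoters)
  pb <- .segment_to_promoter(loops$seg_b, segments, promoters)
  ok <- !is.na(pa) & !is.na(pb) & pa != pb
  pairs <- data.frame(prom_a = pa[ok], prom_b = pb[ok])
  pairs$dual_flagged <- flags[pairs$prom_a] & flags[pairs$prom_b]
  list(n_pairs = nrow(pairs), n_dual_flagged = sum(pairs$dual_flagged),
       pairs = pairs)
}

#' Shift a feature track along each chromosome with circular wrap
#'
#' Every interval is translated by `offset` bp; intervals running past a
#' chromosome end wrap around to its start, so feature count and total
#' covered length are conserved exactly. Wrapped features are represented by
#' two rows sharing the same `feature_id`; shifting back by `-offset`
#' restores the original track (rows are kept in canonical chromosome/start
#' order).
#'
#' @param track data.frame `chrom`, `start`, `end` (+ optional extra columns
#'   and a `feature_id` column from a previous shift).
#' @param offset Signed shift in bp.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return Shifted track with a `feature_id` column.
#' @export
shift_features <- function(track, offset, chrom_sizes) {
  .assert_df_cols(track, c("chrom", "start", "end"), "track")
  if (any(abs(offset) >= chrom_sizes[unique(track$chrom)])) {
    stop("|offset| must be smaller than every chromosome length")
  }
  if (!"feature_id" %in% names(track)) {
    track$feature_id <- seq_len(nrow(track))
  }
  feats <- .canonical_features(track, chrom_sizes)
  L <- unname(chrom_sizes[feats$chrom])
  s <- (feats$start + offset) %% L
  len <- feats$len
  wraps <- s + len > L
  main <- data.frame(chrom = feats$chrom, start = s,
                     end = pmin(s + len, L), feature_id = feats$feature_id,
                     stringsAsFactors = FALSE)
  if (any(wraps)) {
    extra <- data.frame(chrom = feats$chrom[wraps], start = 0,
                        end = (s + len - L)[wraps],
                        feature_id = feats$feature_id[wraps],
                        stringsAsFactors = FALSE)
    main <- rbind(main, extra)
  }
  main <- main[main$end > main$start, , drop = FALSE]
  main <- main[order(main$chrom, main$start, main$feature_id), , drop = FALSE]
  rownames(main) <- NULL
  main
}

# collapse wrapped pieces (same feature_id) back into circular-start + length
.canonical_features <- function(track, chrom_sizes) {
  parts <- split(track, track$feature_id)
  rows <- lapply(parts, function(p) {
    if (nrow(p) == 1L) {
      return(data.frame(chrom = p$chrom, start = p$start,
                        len = p$end - p$start, feature_id = p$feature_id,
                        stringsAsFactors = FALSE))
    }
    # wrapped feature: the piece not touching position 0 holds the start
    L <- unname(chrom_sizes[p$chrom[1L]])
    tail_piece <- p[p$start != 0, , drop = FALSE][1L, ]
    data.frame(chrom = p$chrom[1L], start = tail_piece$start,
               len = sum(p$end - p$start), feature_id = p$feature_id[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$feature_id), , drop = FALSE]
}

#' Empirical enrichment p-value against permutation nulls
#'
#' Uses the add-one estimator `p = (1 + #\{null >= observed\}) / (1 + #null)`.
#'
#' @param observed Observed statistic (single number).
#' @param nulls Vector of null statistics (one per shift/permutation).
#' @return list `observed`, `nulls`, `p`.
#' @export
empirical_enrichment <- function(observed, nulls) {
  if (!length(nulls)) stop("at least one null value is required")
  p <- (1 + sum(nulls >= observed)) / (1 + length(nulls))
  list(observed = observed, nulls = nulls, p = p)
}

#' Reassign expression levels from lagged neighbors along the chromosome
#'
#' Gene i receives the expression level of gene i + lag (direction "down")
#' or i - lag ("up") in chromosome order, wrapping within each chromosome.
#' The multiset of levels per chromosome is preserved exactly.
#'
#' @param genes Gene table with `expression`.
#' @param lag Neighbor offset (default 20; the companion scale is 50).
#' @param direction `"down"` (i + lag) or `"up"` (i - lag).
#' @return `genes` with a reassigned `expression` column.
#' @export
expression_shuffle <- function(genes, lag = 20, direction = c("down", "up")) {
  direction <- match.arg(direction)
  .assert_df_cols(genes, c("chrom", "tss", "expression"), "genes")
  shift <- if (direction == "down") lag else -lag
  for (ch in unique(genes$chrom)) {
    sel <- which(genes$chrom == ch)
    sel <- sel[order(pmin(genes$tss[sel], genes$tts[sel] %||% genes$tss[sel]))]
    n <- length(sel)
    src <- ((seq_len(n) - 1L + shift) %% n) + 1L
    genes$expression[sel] <- genes$expression[sel][src]
  }
  genes
}

#' Per-segment log signal/control coverage ratio
#'
#' Natural logarithm of the ratio between (optionally depth-normalized)
#' signal and control coverage per segment, with a pseudocount added to both
#' numerator and denominator.
#'
#' @param signal,control Numeric per-segment coverage vectors (same order as
#'   `segments`).
#' @param pseudocount Read-equivalent added to both tracks (default 1).
#' @param normalize Scale both tracks to equal totals before the ratio
#'   (default TRUE).
#' @return Numeric vector of log-ratios; a segment is "enriched" when its
#'   value exceeds 0 (signal/control ratio > 1).
#' @export
signal_ratio <- function(signal, control, pseudocount = 1, normalize = TRUE) {
  if (length(signal) != length(control)) stop("tracks must have equal length")
  if (pseudocount <= 0 && any(control == 0)) {
    stop("zero control coverage requires a positive pseudocount")
  }
  s <- signal + pseudocount
  cc <- control + pseudocount
  if (normalize) {
    tot <- (sum(s) + sum(cc)) / 2
    s <- s / sum(s) * tot
    cc <- cc / sum(cc) * tot
  }
  log(s / cc)
}

#' Count dual-enriched loops in a log-ratio window
#'
#' Generic count-in-region statistic over a per-segment log-ratio track:
#' counts loops whose two segments both have log-ratios inside `[lo, hi]`.
#' With the defaults this is the "strong signal on both partners" count.
#'
#' @param loops Loop pairs (significant rows used if flagged).
#' @param ratios Named numeric vector of per-segment log-ratios (names =
#'   segment ids) or a vector aligned to segment id.
#' @param lo,hi Window bounds (default `lo = 0`, `hi = Inf`).
#' @return Integer count.
#' @export
count_dual_enriched <- function(loops, ratios, lo = 0, hi = Inf) {
  if ("significant" %in% names(loops)) {
    loops <- loops[loops$significant, , drop = FALSE]
  }
  ra <- .ratio_lookup(ratios, loops$seg_a)
  rb <- .ratio_lookup(ratios, loops$seg_b)
  sum(!is.na(ra) & !is.na(rb) & ra >= lo & ra <= hi & rb >= lo & rb <= hi)
}

.ratio_lookup <- function(ratios, ids) {
  if (!is.null(names(ratios))) {
    ratios[as.character(ids)]
  } else {
    ratios[ids]
  }
}

#' Within-gene versus between-gene classification of short loops
#'
#' Among loops shorter than `max_span` whose two segments both overlap gene
#' bodies (maximal-overlap assignment when a segment overlaps several genes),
#' counts loops connecting two positions of the same gene ("within-gene")
#' versus two different genes ("between-gene"). Optionally restricted to
#' loops whose two segments both carry an enrichment flag.
#'
#' @param loops Loop pairs (significant rows used if flagged).
#' @param segments Segment table.
#' @param genes Gene table.
#' @param max_span Maximum loop span in bp, exclusive (default 6000).
#' @param flags Optional per-segment logical (named by segment id or aligned
#'   to id) restricting to dual-flagged loops.
#' @return list `n_within_gene`, `n_between_gene`.
#' @export
classify_gene_pair_loops <- function(loops, segments, genes, max_span = 6000,
                                     flags = NULL) {
  if ("significant" %in% names(loops)) {
    loops <- loops[loops$significant, , drop = FALSE]
  }
  loops <- loops[loops$D < max_span, , drop = FALSE]
  if (!is.null(flags) && nrow(loops)) {
    fa <- .ratio_lookup(flags, loops$seg_a)
    fb <- .ratio_lookup(flags, loops$seg_b)
    loops <- loops[!is.na(fa) & !is.na(fb) & fa & fb, , drop = FALSE]
  }
  if (!nrow(loops)) return(list(n_within_gene = 0L, n_between_gene = 0L))
  bodies <- data.frame(chrom = genes$chrom,
                       start = pmin(genes$tss, genes$tts),
                       end = pmax(genes$tss, genes$tts),
                       stringsAsFactors = FALSE)
  ga <- .segment_to_gene(loops$seg_a, segments, bodies)
  gb <- .segment_to_gene(loops$seg_b, segments, bodies)
  ok <- !is.na(ga) & !is.na(gb)
  list(n_within_gene = sum(ok & ga == gb),
       n_between_gene = sum(ok & ga != gb))
}

# maximal-overlap gene assignment (ties -> first in table order)
.segment_to_gene <- function(seg_ids, segments, bodies) {
  segs <- segments[match(seg_ids, segments$id), , drop = FALSE]
  sg <- .as_granges(segs)
  gg <- .as_granges(bodies)
  hits <- GenomicRanges::findOverlaps(sg, gg)
  out <- rep(NA_integer_, length(seg_ids))
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- BiocGenerics::width(IRanges::pintersect(sg[q], gg[s]))
  ord <- order(q, -ov, s)
  q <- q[ord]; s <- s[ord]
  first <- !duplicated(q)
  out[q[first]] <- s[first]
  out
}
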