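# Contact ingestion: mapped pair records -> segment-pair counts -> filters.

#' Assign mapped Hi-C pair records to segments and aggregate counts
#'
#' Each mate's 5' mapped position is assigned to the segment containing it;
#' each pair increments the unordered segment-pair count by one. Pairs whose
#' mates fall in the same segment carry no inter-segment information and are
#' counted separately; pairs with a position outside the segment universe are
#' skipped with a warning count.
#'
#' @param pairs data.frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (strand columns, if present, are ignored). Positions 0-based.
#' @param segments Segment table from [merge_fragments()].
#' @return A contacts data.frame `seg_a`, `seg_b` (segment ids, `seg_a <
#'   seg_b`), `chrom`, `k` (read count), `D` (center-to-center distance), with
#'   attributes `n_input`, `n_skipped`, `n_intra`, `n_inter_chrom`.
#' @export
assign_pairs <- function(pairs, segments) {
  .assert_df_cols(pairs, c("chrom1", "pos1", "chrom2", "pos2"), "pairs")
  .assert_segments(segments)
  seg1 <- .locate_positions(pairs$chrom1, pairs$pos1, segments)
  seg2 <- .locate_positions(pairs$chrom2, pairs$pos2, segments)
  ok <- !is.na(seg1) & !is.na(seg2)
  n_skipped <- sum(!ok)
  if (n_skipped) warning(n_skipped, " pair(s) with a position outside the segment universe were skipped")
  seg1 <- seg1[ok]; seg2 <- seg2[ok]
  same_chrom <- segments$chrom[seg1] == segments$chrom[seg2]
  n_inter <- sum(!same_chrom)
  seg1 <- seg1[same_chrom]; seg2 <- seg2[same_chrom]
  intra <- seg1 == seg2
  n_intra <- sum(intra)
  a <- pmin(seg1[!intra], seg2[!intra])
  b <- pmax(seg1[!intra], seg2[!intra])
  if (length(a)) {
    key <- paste0(a, "_", b)
    tab <- rowsum(rep(1L, length(key)), key)
    ab <- matrix(as.integer(unlist(strsplit(rownames(tab), "_", fixed = TRUE))),
                 ncol = 2, byrow = TRUE)
    out <- data.frame(
      seg_a = segments$id[ab[, 1L]],
      seg_b = segments$id[ab[, 2L]],
      chrom = segments$chrom[ab[, 1L]],
      k = as.integer(tab[, 1L]),
      D = abs(segments$center[ab[, 1L]] - segments$center[ab[, 2L]]),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$seg_a, out$seg_b), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(seg_a = integer(0), seg_b = integer(0),
                      chrom = character(0), k = integer(0), D = integer(0))
  }
  attr(out, "n_input") <- nrow(pairs)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_intra") <- n_intra
  attr(out, "n_inter_chrom") <- n_inter
  out
}

# row index in `segments` containing each (chrom, pos), NA when outside
.locate_positions <- function(chrom, pos, segments) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    seg_rows <- which(segments$chrom == ch)
    sel <- which(chrom == ch)
    if (!length(seg_rows)) next
    starts <- segments$start[seg_rows]
    ends <- segments$end[seg_rows]
    j <- findInterval(pos[sel], starts)
    inside <- j >= 1L & pos[sel] < ends[pmax(j, 1L)] & pos[sel] >= 0
    idx[sel[inside]] <- seg_rows[j[inside]]
  }
  idx
}

#' Filter contacts by distance window and centromere mask
#'
#' Keeps contacts with `d_min <= D <= d_max` (both bounds inclusive) whose two
#' segments both lie outside centromeric intervals. Idempotent.
#'
#' @param contacts Contacts data.frame from [assign_pairs()].
#' @param segments Segment table; if it lacks a `centromeric` column and
#'   `mask` is given, segments are tagged first.
#' @param d_min,d_max Distance window in bp (defaults 2000 and 25000).
#' @param mask Optional centromere mask data.frame (`chrom`, `start`, `end`).
#' @return Filtered contacts data.frame.
#' @export
filter_contacts <- function(contacts, segments, d_min = 2000, d_max = 25000,
                            mask = NULL) {
  .assert_df_cols(contacts, c("seg_a", "seg_b", "k", "D"), "contacts")
  if (!is.null(mask) || !"centromeric" %in% names(segments)) {
    segments <- tag_centromeric(segments, mask)
  }
  cen <- segments$id[segments$centromeric]
  keep <- contacts$D >= d_min & contacts$D <= d_max &
    !(contacts$seg_a %in% cen) & !(contacts$seg_b %in% cen)
  out <- contacts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all same-chromosome segment pairs with center distance in [d_min, d_max];
# restricted to `usable` ids when given. Returns data.frame(seg_a, seg_b, D)
# with seg_a < seg_b.
.enumerate_window_pairs <- function(segments, d_min = 2000, d_max = 25000,
                                    usable = NULL) {
  segs <- segments
  if (!is.null(usable)) segs <- segs[segs$id %in% usable, , drop = FALSE]
  if ("centromeric" %in% names(segs)) segs <- segs[!segs$centromeric, , drop = FALSE]
  parts <- split(segs, factor(segs$chrom, levels = unique(segs$chrom)))
  res <- lapply(parts, function(s) {
    s <- s[order(s$center), , drop = FALSE]
    centers <- s$center
    n <- length(centers)
    if (n < 2L) return(NULL)
    lo <- findInterval(centers + d_min - 1L, centers) + 1L
    hi <- findInterval(centers + d_max, centers)
    cnt <- pmax(hi - lo + 1L, 0L)
    ii <- rep.int(seq_len(n), cnt)
    jj <- unlist(lapply(seq_len(n), function(i) if (cnt[i] > 0L) seq.int(lo[i], hi[i]) else integer(0)))
    if (!length(ii)) return(NULL)
    data.frame(seg_a = s$id[ii], seg_b = s$id[jj],
               D = centers[jj] - centers[ii], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(seg_a = integer(0), seg_b = integer(0), D = integer(0))
  }
  out
}
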