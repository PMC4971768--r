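# Gene self-loop classification from TSS-anchored focal points, and
# directionality-bias scans upstream of genes.

#' Genes eligible for self-loop calling
#'
#' A gene is a candidate when the search radius of its TSS focal point
#' (the distance from TSS to TTS, i.e. the gene length) is at least the
#' minimum callable loop span, so that at least one partner can exist within
#' the radius.
#'
#' @param genes Gene table (`id`, `chrom`, `strand`, `tss`, `tts`).
#' @param min_loop_distance Minimum loop span in bp (default 2000).
#' @return The candidate subset of `genes`.
#' @export
candidate_genes <- function(genes, min_loop_distance = 2000) {
  .assert_df_cols(genes, c("id", "chrom", "strand", "tss", "tts"), "genes")
  genes[abs(genes$tts - genes$tss) >= min_loop_distance, , drop = FALSE]
}

# focal points of one gene: TSS and +400/+800 bp downstream if inside the body
.gene_focal_points <- function(tss, tts, strand, offsets = c(0L, 400L, 800L)) {
  dir <- if (strand == "+") 1L else -1L
  fp <- tss + dir * offsets
  len <- abs(tts - tss)
  fp[offsets < len]  # strictly inside the gene body (TSS itself included)
}

#' Classify one gene's self-loop conformation
#'
#' Focal points are placed at the TSS and 400/800 bp downstream (skipped
#' individually when outside the gene body). Each focal point is assigned to
#' the segment containing it; significant loop partners of that segment whose
#' centers lie within the search radius R (the distance from the focal point
#' to the TTS, inclusive) are collected and classified as 3' (downstream, in
#' the direction of transcription) or 5' (upstream). A partner centered
#' exactly on the focal point counts as neither. The gene's category
#' aggregates partners over all focal points: `"none"`, `"5'only"`,
#' `"3'only"`, or `"both"`; a gene "has a gene loop" iff at least one 3'
#' partner exists.
#'
#' @param gene One-row gene data.frame.
#' @param loops Significant loop pairs (data.frame with `seg_a`, `seg_b`);
#'   pass e.g. `subset(calls, significant)`.
#' @param segments Segment table.
#' @return list `id`, `category`, `n_3prime`, `n_5prime`, `partners`
#'   (segment ids of supporting partners).
#' @export
classify_gene <- function(gene, loops, segments) {
  fps <- .gene_focal_points(gene$tss, gene$tts, gene$strand)
  dir <- if (gene$strand == "+") 1L else -1L
  segs_chr <- segments[segments$chrom == gene$chrom, , drop = FALSE]
  n3 <- 0L; n5 <- 0L; sup <- integer(0)
  for (fp in fps) {
    row <- which(segs_chr$start <= fp & fp < segs_chr$end)
    if (!length(row)) next
    fseg <- segs_chr$id[row[1L]]
    if (isTRUE(segs_chr$centromeric[row[1L]])) next
    R <- abs(gene$tts - fp)
    sel <- loops$seg_a == fseg | loops$seg_b == fseg
    if (!any(sel)) next
    partner <- ifelse(loops$seg_a[sel] == fseg, loops$seg_b[sel], loops$seg_a[sel])
    pc <- segments$center[match(partner, segments$id)]
    within <- abs(pc - fp) <= R
    side <- sign(pc - fp) * dir
    n3 <- n3 + sum(within & side > 0)
    n5 <- n5 + sum(within & side < 0)
    sup <- c(sup, partner[within & side != 0])
  }
  category <- if (n3 > 0 && n5 > 0) "both" else if (n3 > 0) "3'only" else
    if (n5 > 0) "5'only" else "none"
  list(id = gene$id, category = category, n_3prime = n3, n_5prime = n5,
       partners = unique(sup))
}

#' Classify all candidate genes by self-loop conformation
#'
#' @param genes Gene table; non-candidates (see [candidate_genes()]) are
#'   classified too but flagged.
#' @param loops A `loop_calls` object or data.frame of loop pairs; only rows
#'   with `significant == TRUE` are used when the column is present.
#' @param segments Segment table.
#' @param min_loop_distance Candidate rule threshold (default 2000).
#' @return data.frame `id`, `category`, `n_3prime`, `n_5prime`, `candidate`,
#'   `partners` (comma-separated supporting segment ids).
#' @export
classify_gene_loops <- function(genes, loops, segments, min_loop_distance = 2000) {
  if ("significant" %in% names(loops)) {
    loops <- loops[loops$significant, , drop = FALSE]
  }
  cand_ids <- candidate_genes(genes, min_loop_distance)$id
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    cl <- classify_gene(genes[i, ], loops, segments)
    data.frame(id = cl$id, category = cl$category, n_3prime = cl$n_3prime,
               n_5prime = cl$n_5prime,
               candidate = cl$id %in% cand_ids,
               partners = paste(cl$partners, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Directionality bias of loop partners around gene starts
#'
#' For a series of focal points upstream of each TSS, counts the significant
#' loop partners of the focal segment on the 5' side (further upstream of the
#' gene) versus the 3' side (toward or over the gene), per focal offset and
#' per expression group.
#'
#' @param genes Gene table with an `expression` column (ordinal 0-9).
#' @param loops Significant loops (or a `loop_calls` object).
#' @param segments Segment table.
#' @param upstream_offsets Offsets upstream of the TSS in bp
#'   (default `c(5000, 2000, 1000, 500, 0)`).
#' @param expression_groups Named list of expression-level vectors defining
#'   the groups (default silent 0-2 / medium 3-6 / high 7-9).
#' @return data.frame `offset`, `group`, `n_3prime`, `n_5prime`, `frac_3prime`,
#'   `frac_5prime` (NA when a group has no partners).
#' @export
direction_bias <- function(genes, loops, segments,
                           upstream_offsets = c(5000, 2000, 1000, 500, 0),
                           expression_groups = list(silent = 0:2, medium = 3:6,
                                                    high = 7:9)) {
  .assert_df_cols(genes, c("id", "chrom", "strand", "tss", "expression"), "genes")
  if ("significant" %in% names(loops)) {
    loops <- loops[loops$significant, , drop = FALSE]
  }
  out <- list()
  for (off in upstream_offsets) {
    for (g in names(expression_groups)) {
      sub <- genes[genes$expression %in% expression_groups[[g]], , drop = FALSE]
      n3 <- 0L; n5 <- 0L
      for (i in seq_len(nrow(sub))) {
        dir <- if (sub$strand[i] == "+") 1L else -1L
        fp <- sub$tss[i] - dir * off
        segs_chr <- segments[segments$chrom == sub$chrom[i], , drop = FALSE]
        row <- which(segs_chr$start <= fp & fp < segs_chr$end)
        if (!length(row)) next
        fseg <- segs_chr$id[row[1L]]
        sel <- loops$seg_a == fseg | loops$seg_b == fseg
        if (!any(sel)) next
        partner <- ifelse(loops$seg_a[sel] == fseg, loops$seg_b[sel],
                          loops$seg_a[sel])
        pc <- segments$center[match(partner, segments$id)]
        side <- sign(pc - fp) * dir
        n3 <- n3 + sum(side > 0)
        n5 <- n5 + sum(side < 0)
      }
      tot <- n3 + n5
      out[[length(out) + 1L]] <- data.frame(
        offset = off, group = g, n_3prime = n3, n_5prime = n5,
        frac_3prime = if (tot > 0) n3 / tot else NA_real_,
        frac_5prime = if (tot > 0) n5 / tot else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
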