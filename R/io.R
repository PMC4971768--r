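# Readers and writers for the standard plain-text formats used by the
# pipeline. All internal coordinates are 0-based half-open; GFF3 (1-based
# closed) is converted at this boundary.

#' Read chromosome sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write chromosome sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 rows with feature type `gene` are used; BED uses every row. 1-based
#' GFF3 coordinates are converted to the internal 0-based half-open
#' convention. TSS/TTS are derived from the strand.
#'
#' @param path Input file.
#' @param format `"gff3"` or `"bed"`; guessed from the extension by default.
#' @return Gene table `id`, `chrom`, `strand`, `start`, `end`, `tss`, `tts`.
#' @export
read_genes <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (format == "gff3") {
    gr <- gr[gr$type == "gene"]
    ids <- gr$ID %||% gr$Name
  } else {
    ids <- gr$name
  }
  if (is.null(ids) || anyNA(ids)) ids <- paste0("gene", seq_along(gr))
  start <- BiocGenerics::start(gr) - 1L
  end <- BiocGenerics::end(gr)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  data.frame(
    id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand, start = start, end = end,
    tss = ifelse(strand == "+", start, end),
    tts = ifelse(strand == "+", end, start),
    stringsAsFactors = FALSE
  )
}

#' Write gene models as GFF3
#'
#' @param genes Gene table.
#' @param path Output file.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write segments as BED4
#'
#' @param segments Segment table.
#' @param path Output file.
#' @export
write_segments_bed <- function(segments, path) {
  write.table(segments[, c("chrom", "start", "end", "id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read mapped pair records from a pairs text file
#'
#' Tab-separated, optional `#` comment/header lines. Accepts 4 columns
#' (chrom1 pos1 chrom2 pos2) or 6 (chrom1 pos1 strand1 chrom2 pos2 strand2);
#' strand columns are ignored.
#'
#' @param path Input file.
#' @return data.frame `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) >= 6L) {
    df <- df[, c(1L, 2L, 4L, 5L)]
  } else if (ncol(df) != 4L) {
    stop("pairs file must have 4 or 6 tab-separated columns")
  }
  stats::setNames(df, c("chrom1", "pos1", "chrom2", "pos2"))
}

#' Write / read aggregated segment-pair contacts (TSV)
#'
#' Five columns: chrom, seg_a, seg_b, k, D.
#'
#' @param contacts Contacts data.frame.
#' @param path File path.
#' @export
write_contacts <- function(contacts, path) {
  write.table(contacts[, c("chrom", "seg_a", "seg_b", "k", "D")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  .assert_df_cols(df, c("chrom", "seg_a", "seg_b", "k", "D"), "contacts file")
  df[, c("seg_a", "seg_b", "chrom", "k", "D")]
}

#' Write loop calls as a BEDPE-like TSV
#'
#' Standard BEDPE columns for the two segments followed by the test columns
#' (k, p_ab, p_ba, a_hat, b_hat, p_value, q_value, significant).
#'
#' @param calls A `loop_calls` object.
#' @param segments Segment table (for coordinates).
#' @param path Output file.
#' @export
write_loops <- function(calls, segments, path) {
  ma <- match(calls$seg_a, segments$id)
  mb <- match(calls$seg_b, segments$id)
  out <- data.frame(
    chrom1 = segments$chrom[ma], start1 = segments$start[ma],
    end1 = segments$end[ma],
    chrom2 = segments$chrom[mb], start2 = segments$start[mb],
    end2 = segments$end[mb],
    k = calls$k, D = calls$D,
    p_ab = signif(calls$p_ab, 8), p_ba = signif(calls$p_ba, 8),
    a_hat = signif(calls$a_hat, 8), b_hat = signif(calls$b_hat, 8),
    p_value = signif(calls$p_value, 8), q_value = signif(calls$q_value, 8),
    significant = calls$significant
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a decay model as TSV
#'
#' Knot table (distance, fitted log-intensity) with metadata header lines.
#'
#' @param model A `decay_model`.
#' @param path File path.
#' @export
write_decay <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# decay_model df=%.6g spar=%.6g", model$df, model$spar), con)
  writeLines("distance\tlog_intensity", con)
  write.table(data.frame(distance = signif(exp(model$log_d), 10),
                         log_intensity = signif(model$log_c, 10)),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  structure(
    list(log_d = log(df$distance), log_c = df$log_intensity,
         domain = range(df$distance), df = NA_real_, spar = NA_real_,
         n_bins = nrow(df)),
    class = "decay_model"
  )
}

#' Read a BED file of intervals
#'
#' @param path BED file (0-based half-open, as BED).
#' @return data.frame `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  stats::setNames(df[, 1:3], c("chrom", "start", "end"))
}

#' Read a two-column expression TSV (gene id, level 0-9)
#'
#' @param path Input file.
#' @return data.frame `id`, `expression`.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df[, 1:2], c("id", "expression"))
}
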