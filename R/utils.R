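# Internal helpers shared across modules. All coordinates 0-based half-open.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_df_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  invisible(df)
}

# segments data.frame contract: chrom, start, end, id, length, n_ends, center
.assert_segments <- function(segments) {
  .assert_df_cols(segments, c("chrom", "start", "end", "id", "length", "n_ends", "center"),
                  "segments")
}

# unordered pair key, stable across orientations
.pair_key <- function(a, b) {
  paste0(pmin(a, b), "_", pmax(a, b))
}

# GRanges from a 0-based half-open data.frame
.as_granges <- function(df, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(
    seqnames = df[[chrom]],
    ranges = IRanges::IRanges(start = df[[start]] + 1L, end = df[[end]])
  )
}

# draw n integers to use as child seeds without disturbing determinism
.child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
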