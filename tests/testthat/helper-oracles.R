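# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the package's own code paths.

# regex-scan digestion oracle: cut at every motif start
oracle_digest <- function(seq, motif) {
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
  cuts <- hits[hits > 1L] - 1L  # 0-based cut positions, drop a cut at 0
  bounds <- c(0L, cuts, nchar(seq))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

# brute-force double-loop NB convolution p-value using stats::dnbinom
# (dnbinom's prob is the complement of the count probability p)
oracle_conv_pvalue <- function(k, A, B, pab, pba) {
  if (k == 0) return(1)
  dx <- function(i, r, p) {
    if (r == 0) as.numeric(i == 0) else stats::dnbinom(i, size = r, prob = 1 - p)
  }
  s <- 0
  for (j in 0:(k - 1L)) {
    for (i in 0:j) {
      s <- s + dx(i, A, pab) * dx(j - i, B, pba)
    }
  }
  max(0, 1 - s)
}

# base-by-base promoter coverage oracle
oracle_flag_promoter <- function(prom_start, prom_end, peaks, frac) {
  covered <- logical(prom_end - prom_start)
  for (r in seq_len(nrow(peaks))) {
    lo <- max(peaks$start[r], prom_start)
    hi <- min(peaks$end[r], prom_end)
    if (hi > lo) covered[(lo - prom_start + 1L):(hi - prom_start)] <- TRUE
  }
  sum(covered) >= frac * (prom_end - prom_start)
}

# explicit coordinate-arithmetic gene self-loop classifier
oracle_classify_gene <- function(gene, loops, segments) {
  dir <- if (gene$strand == "+") 1L else -1L
  len <- abs(gene$tts - gene$tss)
  fps <- gene$tss + dir * c(0L, 400L, 800L)
  fps <- fps[c(0L, 400L, 800L) < len]
  n3 <- 0L; n5 <- 0L
  for (fp in fps) {
    fseg <- NA_integer_
    for (s in seq_len(nrow(segments))) {
      if (segments$chrom[s] == gene$chrom &&
          segments$start[s] <= fp && fp < segments$end[s]) {
        fseg <- segments$id[s]; break
      }
    }
    if (is.na(fseg)) next
    R <- abs(gene$tts - fp)
    for (l in seq_len(nrow(loops))) {
      partner <- if (loops$seg_a[l] == fseg) loops$seg_b[l] else
        if (loops$seg_b[l] == fseg) loops$seg_a[l] else next
      pc <- segments$center[segments$id == partner]
      if (abs(pc - fp) > R) next
      side <- sign(pc - fp) * dir
      if (side > 0) n3 <- n3 + 1L
      if (side < 0) n5 <- n5 + 1L
    }
  }
  if (n3 > 0 && n5 > 0) "both" else if (n3 > 0) "3'only" else
    if (n5 > 0) "5'only" else "none"
}

# simple tiling segment table: n segments of width w on one chromosome
make_segments <- function(n, w = 1000, chrom = "chr1", n_ends = 3L) {
  starts <- (seq_len(n) - 1L) * w
  data.frame(chrom = chrom, start = starts, end = starts + w,
             id = seq_len(n), length = w, n_ends = n_ends,
             center = starts + w %/% 2L, stringsAsFactors = FALSE)
}

# flat decay model: f(D) constant over [dmin, dmax]
make_flat_decay <- function(dmin = 2000, dmax = 25000, value = 1) {
  structure(list(log_d = log(c(dmin, dmax)), log_c = log(c(value, value)),
                 domain = c(dmin, dmax), df = NA_real_, spar = NA_real_,
                 n_bins = 2L), class = "decay_model")
}

# decay bins sampled exactly from a power law C = c0 * D^alpha
make_powerlaw_bins <- function(alpha, n = 50, c0 = 1, dmin = 2000, dmax = 25000) {
  D <- exp(seq(log(dmin), log(dmax), length.out = n))
  data.frame(bin = seq_len(n), a = D, b = D, n_reads = 100,
             C = c0 * D^alpha, D = D)
}
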