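# Synthetic Hi-C study generator: genome, genes, biased contacts with
# planted loops, ChIP peaks, expression and resequencing coverage, all with
# known ground truth and fully seeded.

#' Configuration for a synthetic Hi-C study
#'
#' Defaults describe the study conditions emulated throughout the package: a
#' DpnII-digestible genome (motif GATC at mean 256 bp spacing, the 4-mer
#' expectation), segments merged at 500 bp, power-law contact decay with
#' exponent -1 over the 2-25 kb window, log-normal per-segment sequencing
#' bias, a square-root fragment-end-density effect, and planted gene-scale
#' loops of 2-8 kb at 10-fold enrichment. Counts are Poisson given the
#' factor-model rate (`dispersion = 0`); a positive `dispersion` switches to
#' negative binomial with size `1/dispersion`.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param motif Restriction motif (default `"GATC"`).
#' @param motif_spacing Mean distance between motif starts (bp).
#' @param min_segment_len Fragment-merging threshold (bp).
#' @param alpha Decay exponent (contact intensity ~ D^-alpha).
#' @param total_contacts Expected total read-pair count in the 2-25 kb window.
#' @param dispersion Per-pair count over-dispersion (0 = Poisson).
#' @param beta_sigma Log-normal sigma of the per-segment sequencing bias.
#' @param end_exponent Exponent of the fragment-end-density effect
#'   (depth multiplier ~ E^exponent).
#' @param n_loops Number of planted generic loops.
#' @param loop_fold Enrichment fold of planted loops (>= 1).
#' @param loop_span Span range (bp) from which planted loops are drawn.
#' @param gene_length,gene_gap Uniform ranges (bp) for gene length and
#'   intergenic gap when placing genes.
#' @param n_genes Maximum number of genes per chromosome (NULL fills the
#'   chromosome).
#' @param self_loop_fraction Fraction of eligible genes given a planted
#'   5'-3' self-loop (TSS segment to TTS segment).
#' @param self_loop_fold Enrichment fold of planted self-loops.
#' @param n_promoter_loops Planted promoter-promoter loops (TSS segment to
#'   TSS segment, span >= 6 kb).
#' @param promoter_loop_fold Their enrichment fold.
#' @param peak_coupling Probability that each promoter of a planted
#'   promoter-pair loop receives a ChIP peak.
#' @param peak_background Probability that any other promoter receives a peak.
#' @param reseq_reads_per_bp Mean resequencing coverage in reads per bp
#'   (0.3 ~ 30x with 100 bp reads).
#' @param d_min,d_max Analysis window (bp).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 1, chrom_length = 1e6, motif = "GATC",
                       motif_spacing = 256, min_segment_len = 500,
                       alpha = 1, total_contacts = 5e5, dispersion = 0,
                       beta_sigma = 0.25, end_exponent = 0.5,
                       n_loops = 0, loop_fold = 10, loop_span = c(2000, 8000),
                       gene_length = c(1500, 4500), gene_gap = c(300, 1500),
                       n_genes = NULL,
                       self_loop_fraction = 0, self_loop_fold = 10,
                       n_promoter_loops = 0, promoter_loop_fold = 10,
                       peak_coupling = 1, peak_background = 0.05,
                       reseq_reads_per_bp = 0.3,
                       d_min = 2000, d_max = 25000) {
  cfg <- as.list(environment())
  stopifnot(cfg$motif_spacing > nchar(cfg$motif), cfg$alpha > 0,
            cfg$total_contacts > 0, cfg$dispersion >= 0,
            cfg$loop_fold >= 1, cfg$self_loop_fold >= 1,
            cfg$promoter_loop_fold >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic Hi-C study: %d chromosome(s) x %.2g bp, %.2g contacts, alpha %.2f\n",
              x$n_chrom, x$chrom_length, x$total_contacts, x$alpha))
  cat(sprintf("  planted: %d generic loops (fold %g), self-loop fraction %.2f, %d promoter loops\n",
              x$n_loops, x$loop_fold, x$self_loop_fraction, x$n_promoter_loops))
  invisible(x)
}

#' Simulate a genome with controlled restriction-site spacing, plus genes
#'
#' Chromosome sequences are assembled as random inter-motif gaps (geometric,
#' mean `motif_spacing` between motif starts) separated by motif copies;
#' accidental motif occurrences inside gaps are destroyed, so digestion
#' recovers the configured spacing. Genes are placed left to right,
#' non-overlapping, with uniform lengths and gaps and random strands.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the output is deterministic given (config, seed).
#' @return list with `sequences` (named character), `chrom_sizes`, `genes`
#'   (data.frame `id`, `chrom`, `strand`, `start`, `end`, `tss`, `tts`).
#' @export
simulate_genome <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  sequences <- vapply(chroms, function(ch) {
    .sim_chrom_sequence(config$chrom_length, config$motif, config$motif_spacing)
  }, character(1))
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    .sim_place_genes(ch, config$chrom_length, config$gene_length,
                     config$gene_gap, config$n_genes)
  }))
  rownames(genes) <- NULL
  genes$id <- sprintf("g%05d", seq_len(nrow(genes)))
  list(sequences = sequences,
       chrom_sizes = stats::setNames(rep(config$chrom_length, length(chroms)), chroms),
       genes = genes[, c("id", "chrom", "strand", "start", "end", "tss", "tts")])
}

.sim_chrom_sequence <- function(len, motif, spacing) {
  codes <- utf8ToInt("ACGT")
  m <- utf8ToInt(motif)
  mlen <- length(m)
  n_sites <- ceiling(len / spacing * 1.3) + 10
  gaps <- stats::rgeom(n_sites, prob = 1 / (spacing - mlen + 1))
  total <- sum(gaps) + mlen * n_sites
  if (total < len) {
    extra <- len - total
    gaps[n_sites] <- gaps[n_sites] + extra
    total <- total + extra
  }
  starts <- cumsum(gaps + mlen) - mlen + 1L  # 1-based motif starts
  motif_pos <- rep(starts, each = mlen) + seq_len(mlen) - 1L
  seq_int <- integer(total)
  seq_int[motif_pos] <- rep(m, n_sites)
  seq_int[-motif_pos] <- sample(codes, total - length(motif_pos), replace = TRUE)
  seq_int <- seq_int[seq_len(len)]
  intended <- starts[starts + mlen - 1L <= len]
  # destroy accidental motif occurrences: replace the second motif base with
  # the first (for GATC this provably creates no new site)
  for (pass in 1:25) {
    ok <- rep(TRUE, len - mlen + 1L)
    for (j in seq_len(mlen)) {
      ok <- ok & seq_int[seq_len(len - mlen + 1L) + j - 1L] == m[j]
    }
    bad <- setdiff(which(ok), intended)
    if (!length(bad)) break
    seq_int[bad + 1L] <- m[1L]
  }
  intToUtf8(seq_int)
}

.sim_place_genes <- function(chrom, chrom_length, gene_length, gene_gap, n_genes) {
  pos <- 500
  rows <- list()
  while (pos < chrom_length - max(gene_length) - 500 &&
         (is.null(n_genes) || length(rows) < n_genes)) {
    gap <- round(stats::runif(1, gene_gap[1], gene_gap[2]))
    len <- round(stats::runif(1, gene_length[1], gene_length[2]))
    start <- pos + gap
    end <- start + len
    strand <- sample(c("+", "-"), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, strand = strand, start = start, end = end,
      tss = if (strand == "+") start else end,
      tts = if (strand == "+") end else start,
      stringsAsFactors = FALSE
    )
    pos <- end
  }
  do.call(rbind, rows)
}

#' Simulate per-segment sequencing biases
#'
#' @param segments Segment table.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Numeric vector of true beta values (log-normal, mean 1), aligned
#'   to `segments` rows.
#' @export
simulate_biases <- function(segments, config, seed) {
  set.seed(seed)
  s <- config$beta_sigma
  stats::rlnorm(nrow(segments), meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate segment-pair Hi-C contacts with planted loops
#'
#' Expected counts follow the generative mirror of the caller's factor
#' model: `lambda ~ D^-alpha * (E_a E_b)^gamma * l_a l_b * beta_a beta_b`,
#' restricted to the analysis window and scaled to `total_contacts`; planted
#' pairs are multiplied by their enrichment fold. Counts are Poisson (or NB
#' when `dispersion > 0`).
#'
#' @param segments Segment table.
#' @param config A [sim_config()].
#' @param beta_true Per-segment bias vector from [simulate_biases()].
#' @param seed Integer seed.
#' @param genes Optional gene table; required when self-loops or
#'   promoter-pair loops are planted.
#' @return list with `contacts` (data.frame `seg_a`, `seg_b`, `chrom`, `k`,
#'   `D`, observed pairs only) and `truth` (data.frame `seg_a`, `seg_b`,
#'   `type`, `fold`, `gene_a`, `gene_b` of planted pairs).
#' @export
simulate_contacts <- function(segments, config, beta_true, seed, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  pairs <- .enumerate_window_pairs(segments, config$d_min, config$d_max)
  if (!nrow(pairs)) stop("no segment pairs in the analysis window")
  ia <- match(pairs$seg_a, segments$id)
  ib <- match(pairs$seg_b, segments$id)
  w <- pairs$D^(-config$alpha) *
    (segments$n_ends[ia] * segments$n_ends[ib])^config$end_exponent *
    segments$length[ia] * segments$length[ib] *
    beta_true[ia] * beta_true[ib]
  if (sum(w) <= 0) stop("total expected contact count is zero")
  lam <- w / sum(w) * config$total_contacts

  truth <- .plant_loops(pairs, segments, config, genes)
  if (nrow(truth)) {
    key <- .pair_key(pairs$seg_a, pairs$seg_b)
    m <- match(.pair_key(truth$seg_a, truth$seg_b), key)
    lam[m] <- lam[m] * truth$fold
  }
  k <- if (config$dispersion > 0) {
    stats::rnbinom(length(lam), mu = lam, size = 1 / config$dispersion)
  } else {
    stats::rpois(length(lam), lam)
  }
  obs <- k >= 1L
  contacts <- data.frame(
    seg_a = pairs$seg_a[obs], seg_b = pairs$seg_b[obs],
    chrom = segments$chrom[ia[obs]], k = k[obs], D = pairs$D[obs],
    stringsAsFactors = FALSE
  )
  list(contacts = contacts, truth = truth)
}

# choose planted pairs (generic loops, gene self-loops, promoter-pair loops)
.plant_loops <- function(pairs, segments, config, genes) {
  key <- .pair_key(pairs$seg_a, pairs$seg_b)
  taken <- character(0)
  out <- list()

  seg_of <- function(chrom, pos) {
    row <- .locate_positions(chrom, pos, segments)
    ifelse(is.na(row), NA_integer_, segments$id[row])
  }

  if (config$n_loops > 0) {
    cand <- which(pairs$D >= config$loop_span[1] & pairs$D <= config$loop_span[2])
    pick <- sample(cand, min(config$n_loops, length(cand)))
    out[[length(out) + 1L]] <- data.frame(
      seg_a = pairs$seg_a[pick], seg_b = pairs$seg_b[pick],
      type = "loop", fold = config$loop_fold,
      gene_a = NA_character_, gene_b = NA_character_,
      stringsAsFactors = FALSE
    )
    taken <- c(taken, key[pick])
  }

  if (config$self_loop_fraction > 0 && !is.null(genes)) {
    elig <- genes[abs(genes$tts - genes$tss) >= config$d_min &
                    abs(genes$tts - genes$tss) <= config$d_max, , drop = FALSE]
    if (nrow(elig)) {
      n_pick <- max(1L, round(config$self_loop_fraction * nrow(elig)))
      pick <- elig[sample(nrow(elig), min(n_pick, nrow(elig))), , drop = FALSE]
      # 5' anchor at the TSS; 3' anchor at the 3' end of the transcribed
      # region (500 bp inside the gene body), so the partner segment's center
      # stays on the gene side of the TTS
      dir3 <- ifelse(pick$strand == "+", -1L, 1L)
      sa <- seg_of(pick$chrom, pick$tss)
      sb <- seg_of(pick$chrom, pick$tts + 500L * dir3)
      ok <- !is.na(sa) & !is.na(sb) & sa != sb
      kk <- .pair_key(sa[ok], sb[ok])
      valid <- kk %in% key & !kk %in% taken
      if (any(valid)) {
        out[[length(out) + 1L]] <- data.frame(
          seg_a = pmin(sa[ok], sb[ok])[valid], seg_b = pmax(sa[ok], sb[ok])[valid],
          type = "self_loop", fold = config$self_loop_fold,
          gene_a = pick$id[ok][valid], gene_b = pick$id[ok][valid],
          stringsAsFactors = FALSE
        )
        taken <- c(taken, kk[valid])
      }
    }
  }

  if (config$n_promoter_loops > 0 && !is.null(genes)) {
    tss_seg <- seg_of(genes$chrom, genes$tss)
    gi <- which(!is.na(tss_seg))
    cand <- list()
    for (a in gi) {
      same <- gi[genes$chrom[gi] == genes$chrom[a] & gi > a]
      if (!length(same)) next
      da <- abs(segments$center[match(tss_seg[same], segments$id)] -
                  segments$center[match(tss_seg[a], segments$id)])
      okd <- same[da >= 6000 & da <= config$d_max]
      if (length(okd)) cand[[length(cand) + 1L]] <- cbind(a, okd)
    }
    cand <- do.call(rbind, cand)
    if (!is.null(cand) && nrow(cand)) {
      kk <- .pair_key(tss_seg[cand[, 1L]], tss_seg[cand[, 2L]])
      usable <- which(kk %in% key & !kk %in% taken & !duplicated(kk))
      pick <- usable[sample(length(usable), min(config$n_promoter_loops, length(usable)))]
      if (length(pick)) {
        sa <- tss_seg[cand[pick, 1L]]; sb <- tss_seg[cand[pick, 2L]]
        out[[length(out) + 1L]] <- data.frame(
          seg_a = pmin(sa, sb), seg_b = pmax(sa, sb),
          type = "promoter_pair", fold = config$promoter_loop_fold,
          gene_a = genes$id[cand[pick, 1L]], gene_b = genes$id[cand[pick, 2L]],
          stringsAsFactors = FALSE
        )
      }
    }
  }

  if (!length(out)) {
    return(data.frame(seg_a = integer(0), seg_b = integer(0),
                      type = character(0), fold = numeric(0),
                      gene_a = character(0), gene_b = character(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate ChIP peaks, expression levels and resequencing coverage
#'
#' Peaks are placed over the promoters of planted promoter-pair loop genes
#' with probability `peak_coupling` and over other promoters with probability
#' `peak_background`; each peak fully covers its promoter. Expression levels
#' are uniform on 0-9. Resequencing depth per segment is Poisson with mean
#' `beta * length * reseq_reads_per_bp`.
#'
#' @param genes Gene table.
#' @param segments Segment table.
#' @param config A [sim_config()].
#' @param beta_true Per-segment bias vector.
#' @param seed Integer seed.
#' @param truth Planted-loop truth table (for peak coupling).
#' @param chrom_sizes Named chromosome lengths (for clipping peaks).
#' @return list with `expression` (data.frame `id`, `expression`), `reseq`
#'   (data.frame `id`, `depth`), `peaks` (data.frame `chrom`, `start`,
#'   `end`), and `flagged_genes` (ids of peak-covered genes).
#' @export
simulate_tracks <- function(genes, segments, config, beta_true, seed,
                            truth = NULL, chrom_sizes = NULL) {
  set.seed(seed)
  expression <- data.frame(id = genes$id,
                           expression = sample(0:9, nrow(genes), replace = TRUE),
                           stringsAsFactors = FALSE)
  depth <- stats::rpois(nrow(segments),
                        beta_true * segments$length * config$reseq_reads_per_bp)
  reseq <- data.frame(id = segments$id, depth = depth)

  coupled <- character(0)
  if (!is.null(truth) && nrow(truth)) {
    pp <- truth[truth$type == "promoter_pair", , drop = FALSE]
    coupled <- unique(c(pp$gene_a, pp$gene_b))
  }
  p_peak <- ifelse(genes$id %in% coupled, config$peak_coupling,
                   config$peak_background)
  has_peak <- stats::runif(nrow(genes)) < p_peak
  peaks <- data.frame(chrom = genes$chrom[has_peak],
                      start = pmax(genes$tss[has_peak] - 600, 0),
                      end = genes$tss[has_peak] + 600,
                      stringsAsFactors = FALSE)
  if (!is.null(chrom_sizes) && nrow(peaks)) {
    peaks$end <- pmin(peaks$end, unname(chrom_sizes[peaks$chrom]))
  }
  list(expression = expression, reseq = reseq, peaks = peaks,
       flagged_genes = genes$id[has_peak])
}

#' Simulate a complete synthetic Hi-C study
#'
#' Runs [simulate_genome()], digestion/merging, [simulate_biases()],
#' [simulate_contacts()] and [simulate_tracks()] under one master seed.
#' Identical (config, seed) give identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return An object of class `hic_sim`: list with `config`, `seed`,
#'   `sequences`, `chrom_sizes`, `genes` (with expression merged in),
#'   `segments`, `beta_true`, `contacts`, `truth`, `reseq`, `peaks`,
#'   `flagged_genes`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  seeds <- .child_seeds(seed, 4L)
  genome <- simulate_genome(config, seeds[1L])
  fragments <- digest_genome(genome$sequences, config$motif)
  segments <- merge_fragments(fragments, config$min_segment_len)
  beta_true <- simulate_biases(segments, config, seeds[2L])
  sim <- simulate_contacts(segments, config, beta_true, seeds[3L],
                           genes = genome$genes)
  tracks <- simulate_tracks(genome$genes, segments, config, beta_true,
                            seeds[4L], truth = sim$truth,
                            chrom_sizes = genome$chrom_sizes)
  genes <- genome$genes
  genes$expression <- tracks$expression$expression[match(genes$id, tracks$expression$id)]
  structure(
    list(config = config, seed = seed, sequences = genome$sequences,
         chrom_sizes = genome$chrom_sizes, genes = genes, segments = segments,
         beta_true = beta_true, contacts = sim$contacts, truth = sim$truth,
         reseq = tracks$reseq, peaks = tracks$peaks,
         flagged_genes = tracks$flagged_genes),
    class = "hic_sim"
  )
}

#' @export
print.hic_sim <- function(x, ...) {
  cat(sprintf("Synthetic Hi-C study (seed %d)\n", x$seed))
  cat(sprintf("  %d segment(s) on %d chromosome(s); %d observed pairs, %.0f reads\n",
              nrow(x$segments), length(x$chrom_sizes), nrow(x$contacts),
              sum(x$contacts$k)))
  cat(sprintf("  %d gene(s); %d planted pair(s)\n", nrow(x$genes), nrow(x$truth)))
  invisible(x)
}

#' Expand segment-pair contacts into synthetic mate-pair records
#'
#' Draws `k` read-pair records for each contact, with each mate position
#' uniform within its segment; useful for exercising [assign_pairs()] on
#' data with known placement.
#'
#' @param contacts Contacts data.frame.
#' @param segments Segment table.
#' @param seed Integer seed.
#' @return data.frame `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @export
simulate_pair_records <- function(contacts, segments, seed) {
  set.seed(seed)
  ia <- match(rep(contacts$seg_a, contacts$k), segments$id)
  ib <- match(rep(contacts$seg_b, contacts$k), segments$id)
  data.frame(
    chrom1 = segments$chrom[ia],
    pos1 = segments$start[ia] +
      floor(stats::runif(length(ia)) * segments$length[ia]),
    chrom2 = segments$chrom[ib],
    pos2 = segments$start[ib] +
      floor(stats::runif(length(ib)) * segments$length[ib]),
    stringsAsFactors = FALSE
  )
}
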