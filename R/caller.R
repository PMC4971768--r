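# Negative-binomial convolution significance test and loop calling.

#' Negative binomial probability mass function (count parameterization)
#'
#' `f(k, r, p) = C(k + r - 1, k) p^k (1 - p)^r`, generalized to non-integer
#' `r` through the gamma function and computed in log space. `p` is the
#' per-trial probability of the counted event, so the mean is
#' `r p / (1 - p)`. The degenerate case `r = 0` is a point mass at 0.
#'
#' @param k Non-negative integer counts (vectorized).
#' @param r Positive "failed trials" parameter (a single value).
#' @param p Event probability in (0, 1) (a single value).
#' @return P(X = k).
#' @export
nb_pmf <- function(k, r, p) {
  if (any(k < 0)) stop("k must be non-negative")
  if (r < 0) stop("r must be non-negative")
  if (r == 0) return(as.numeric(k == 0))
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  exp(lgamma(k + r) - lgamma(r) - lfactorial(k) + k * log(p) + r * log1p(-p))
}

#' Convolution p-value for an observed pair count
#'
#' The observed count of a segment pair is modeled as `AB = X + Y` with
#' `X ~ NB(A_hat, p_AB)` and `Y ~ NB(B_hat, p_BA)`, one term per anchoring of
#' the pair. The pmf of AB is the exact convolution
#' `P(AB = j) = sum_i P(X = i) P(Y = j - i)` and the p-value is the upper
#' tail `1 - sum_{j < k} P(AB = j)`, floored at 0 against rounding.
#'
#' @param k Observed read count (single non-negative integer).
#' @param A_hat,B_hat Background ("failed trials") parameters of the two
#'   anchorings; non-negative, 0 meaning a point mass at 0.
#' @param p_AB,p_BA Adjusted contact probabilities of the pair under each
#'   anchoring.
#' @return The p-value in [0, 1]; `k = 0` gives 1 (empty sum).
#' @export
convolution_pvalue <- function(k, A_hat, B_hat, p_AB, p_BA) {
  stopifnot(length(k) == 1L, k >= 0, is.finite(A_hat), is.finite(B_hat))
  if (k == 0) return(1)
  j <- 0:(k - 1L)
  px <- nb_pmf(j, A_hat, p_AB)
  py <- nb_pmf(j, B_hat, p_BA)
  # sum over i + i' <= k - 1 of px[i] py[i'] via the reversed cumulative sum
  cpy <- cumsum(py)
  s <- sum(px * cpy[k:1L])
  max(0, 1 - s)
}

# vectorized convolution p-values, grouped by distinct k internally.
# All arguments same length; returns p-values. NA where probabilities are
# not in (0,1) (no alternative partner) -- callers drop those pairs.
.conv_pvalue_batch <- function(k, A_hat, B_hat, p_AB, p_BA) {
  n <- length(k)
  out <- rep(NA_real_, n)
  valid <- p_AB > 0 & p_AB < 1 & p_BA > 0 & p_BA < 1 &
    is.finite(A_hat) & is.finite(B_hat) & A_hat >= 0 & B_hat >= 0
  out[valid & k == 0] <- 1
  for (kk in sort(unique(k[valid & k > 0]))) {
    sel <- which(valid & k == kk)
    j <- 0:(kk - 1L)
    px <- .nb_pmf_matrix(j, A_hat[sel], p_AB[sel])
    py <- .nb_pmf_matrix(j, B_hat[sel], p_BA[sel])
    # row-wise cumulative sums of py, reversed column order
    if (kk == 1L) {
      s <- px[, 1L] * py[, 1L]
    } else {
      cpy <- py %*% upper.tri(diag(kk), diag = TRUE)
      s <- rowSums(px * cpy[, kk:1L, drop = FALSE])
    }
    out[sel] <- pmax(0, 1 - s)
  }
  out
}

# matrix of NB pmfs: rows = parameter vectors (r_i, p_i), cols = counts j
.nb_pmf_matrix <- function(j, r, p) {
  n <- length(r)
  lp <- matrix(0, n, length(j))
  pos <- r > 0
  if (any(pos)) {
    rr <- r[pos]; pp <- p[pos]
    lp[pos, ] <- outer(rr, j, function(r0, j0) lgamma(j0 + r0)) -
      lgamma(rr) - matrix(lfactorial(j), sum(pos), length(j), byrow = TRUE) +
      outer(log(pp), j, `*`) + rr * log1p(-pp)
    lp[pos, ] <- exp(lp[pos, , drop = FALSE])
  }
  if (any(!pos)) {
    lp[!pos, ] <- matrix(as.numeric(j == 0), sum(!pos), length(j), byrow = TRUE)
  }
  lp
}

#' Background estimate for one anchor segment
#'
#' Implements the anchored background model: for each observed partner i of
#' anchor A, `r_i = (A_total - C_Ai) / ((A_total - C_Ai) + (i_total - C_Ai))`
#' (0.5 when the denominator is 0) and `A_hat = sum_i C_Ai * r_i`. Depths
#' `A_total` and `i_total` are each segment's total read count within the
#' analysis window.
#'
#' @param anchor Segment id.
#' @param contacts Filtered contacts data.frame.
#' @return list with `anchor`, `A_hat`, and `components` (data.frame
#'   `partner`, `C`, `r`, `term`).
#' @export
estimate_background <- function(anchor, contacts) {
  depth <- segment_depths(contacts)
  a_tot <- depth$depth[match(anchor, depth$id)]
  if (is.na(a_tot)) {
    return(list(anchor = anchor, A_hat = 0,
                components = data.frame(partner = integer(0), C = numeric(0),
                                        r = numeric(0), term = numeric(0))))
  }
  sel <- contacts$seg_a == anchor | contacts$seg_b == anchor
  partner <- ifelse(contacts$seg_a[sel] == anchor, contacts$seg_b[sel],
                    contacts$seg_a[sel])
  C <- contacts$k[sel]
  i_tot <- depth$depth[match(partner, depth$id)]
  num <- a_tot - C
  den <- (a_tot - C) + (i_tot - C)
  if (any(num < 0 | i_tot - C < 0)) stop("negative depth difference: depth bookkeeping error")
  r <- ifelse(den == 0, 0.5, num / den)
  term <- C * r
  list(anchor = anchor, A_hat = sum(term),
       components = data.frame(partner = partner, C = C, r = r, term = term))
}

#' Per-segment read depth within the analysis window
#'
#' @param contacts Filtered contacts data.frame.
#' @return data.frame `id`, `depth` (sum of pair counts touching the segment).
#' @export
segment_depths <- function(contacts) {
  ids <- c(contacts$seg_a, contacts$seg_b)
  kk <- c(contacts$k, contacts$k)
  tab <- rowsum(as.numeric(kk), ids)
  data.frame(id = as.numeric(rownames(tab)), depth = tab[, 1L])
}

#' Call chromatin loops with the negative-binomial convolution test
#'
#' For every observed, filtered contact the pair is tested under both
#' anchorings: adjusted probabilities `p_AB` / `p_BA` come from the
#' decay-bias factor model over each anchor's full usable partner set, and
#' the background parameters come from the anchored background estimate with
#' the tested pair's own contribution excluded
#' (`A = A_hat_A - C_AB * r_B`). p-values from the exact NB convolution are
#' corrected with Benjamini-Hochberg over the family of all tested pairs
#' (observed `k >= 1` passing all filters); loops are pairs with
#' `q < q_threshold`.
#'
#' @param contacts Filtered contacts data.frame ([filter_contacts()]).
#' @param segments Segment table.
#' @param decay A `decay_model`; fitted from `contacts` when NULL.
#' @param biases Optional bias table ([estimate_beta()]); when given, the
#'   beta filter is applied and unusable segments are excluded from anchor
#'   and partner sets.
#' @param end_model Optional `end_density_model`; fitted from the contact
#'   marginals when `fit_end = TRUE` and `end_model` is NULL.
#' @param q_threshold Significance threshold on BH q-values (default 0.01).
#' @param d_min,d_max Analysis window in bp.
#' @param fit_end Fit the fragment-end-density model from the data when no
#'   `end_model` is supplied (default TRUE).
#' @return An object of class `loop_calls`: a data.frame with one row per
#'   tested pair (`seg_a`, `seg_b`, `chrom`, `D`, `k`, `p_ab`, `p_ba`,
#'   `a_hat`, `b_hat`, `p_value`, `q_value`, `significant`) ordered by
#'   q-value, with attributes `n_tested`, `n_skipped`, `q_threshold`.
#' @export
call_loops <- function(contacts, segments, decay = NULL, biases = NULL,
                       end_model = NULL, q_threshold = 0.01,
                       d_min = 2000, d_max = 25000, fit_end = TRUE) {
  .assert_segments(segments)
  if (!is.null(biases)) contacts <- apply_beta_filter(contacts, biases)
  if (!nrow(contacts)) stop("no contacts to test")
  if (is.null(decay)) decay <- fit_decay(equal_occupancy_bins(contacts))
  if (is.null(end_model) && fit_end) {
    end_model <- fit_end_density(stats::setNames(segment_depths(contacts),
                                                 c("id", "depth")), segments)
  }

  usable <- .usable_ids(segments, biases)
  allp <- .enumerate_window_pairs(segments, d_min, d_max, usable = usable)
  # denominator of the adjusted probabilities, per anchor (both directions)
  anchor <- c(allp$seg_a, allp$seg_b)
  partner <- c(allp$seg_b, allp$seg_a)
  wd <- .partner_weights(partner, c(allp$D, allp$D), segments, decay, biases,
                         end_model)
  denom_tab <- rowsum(wd, anchor)
  denom <- function(ids) denom_tab[match(as.character(ids), rownames(denom_tab)), 1L]

  # windowed depths and anchored backgrounds from the observed contacts
  depth_tab <- segment_depths(contacts)
  depth <- function(ids) {
    d <- depth_tab$depth[match(ids, depth_tab$id)]
    d[is.na(d)] <- 0
    d
  }
  a_tot <- depth(contacts$seg_a)
  b_tot <- depth(contacts$seg_b)
  kk <- contacts$k
  r_ab <- .background_ratio(a_tot, b_tot, kk)  # anchor = seg_a, partner = seg_b
  r_ba <- .background_ratio(b_tot, a_tot, kk)
  term_ab <- kk * r_ab
  term_ba <- kk * r_ba
  ahat_tab <- rowsum(c(term_ab, term_ba), c(contacts$seg_a, contacts$seg_b))
  ahat <- function(ids) ahat_tab[match(as.character(ids), rownames(ahat_tab)), 1L]
  a_param <- pmax(0, ahat(contacts$seg_a) - term_ab)
  b_param <- pmax(0, ahat(contacts$seg_b) - term_ba)

  # adjusted probabilities of the observed pairs under both anchorings
  w_b_as_partner <- .partner_weights(contacts$seg_b, contacts$D, segments,
                                     decay, biases, end_model)
  w_a_as_partner <- .partner_weights(contacts$seg_a, contacts$D, segments,
                                     decay, biases, end_model)
  p_ab <- w_b_as_partner / denom(contacts$seg_a)
  p_ba <- w_a_as_partner / denom(contacts$seg_b)

  testable <- is.finite(p_ab) & is.finite(p_ba) &
    p_ab > 0 & p_ab < 1 & p_ba > 0 & p_ba < 1
  n_skipped <- sum(!testable)
  res <- contacts[testable, c("seg_a", "seg_b", "chrom", "D", "k")]
  res$p_ab <- p_ab[testable]
  res$p_ba <- p_ba[testable]
  res$a_hat <- a_param[testable]
  res$b_hat <- b_param[testable]
  res$p_value <- .conv_pvalue_batch(res$k, res$a_hat, res$b_hat,
                                    res$p_ab, res$p_ba)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < q_threshold
  res <- res[order(res$q_value, res$p_value, res$seg_a, res$seg_b), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("loop_calls", "data.frame"),
            n_tested = nrow(res), n_skipped = n_skipped,
            q_threshold = q_threshold)
}

.background_ratio <- function(anchor_tot, partner_tot, C) {
  num <- anchor_tot - C
  den <- (anchor_tot - C) + (partner_tot - C)
  if (any(num < -1e-9 | partner_tot - C < -1e-9)) {
    stop("negative depth difference: depth bookkeeping error")
  }
  ifelse(den <= 0, 0.5, num / den)
}

#' @export
print.loop_calls <- function(x, ...) {
  cat(sprintf("Loop calls: %d tested pairs, %d significant at q < %g\n",
              attr(x, "n_tested"), sum(x$significant), attr(x, "q_threshold")))
  if (attr(x, "n_skipped") > 0) {
    cat(sprintf("  (%d pairs skipped: no usable alternative partners)\n",
                attr(x, "n_skipped")))
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
summary.loop_calls <- function(object, ...) {
  sig <- object[object$significant, , drop = FALSE]
  out <- list(
    n_tested = attr(object, "n_tested"),
    n_significant = nrow(sig),
    q_threshold = attr(object, "q_threshold"),
    span_quartiles = if (nrow(sig)) stats::quantile(sig$D, c(.25, .5, .75)) else NULL
  )
  class(out) <- "summary.loop_calls"
  out
}

#' @export
print.summary.loop_calls <- function(x, ...) {
  cat(sprintf("%d of %d tested pairs significant at q < %g\n",
              x$n_significant, x$n_tested, x$q_threshold))
  if (!is.null(x$span_quartiles)) {
    cat("loop span quartiles (bp):",
        paste(round(x$span_quartiles), collapse = " / "), "\n")
  }
  invisible(x)
}
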