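# Per-segment sequencing bias (beta), fragment-end-density effect f(E),
# and bias-adjusted contact probabilities.

#' Estimate per-segment sequencing bias from resequencing coverage
#'
#' beta is the ratio of a segment's length-normalized coverage to the
#' genome-wide mean of that quantity, so mean(beta) = 1 by construction.
#' Multiple resequencing data sets are pooled by summing depth per segment
#' before taking the ratio.
#'
#' @param coverage data.frame with columns `id` (segment id) and `depth`
#'   (read count assigned to the segment); several rows per id (one per data
#'   set) are summed.
#' @param segments Segment table.
#' @param lo,hi Usability bounds on beta (inclusive; defaults 0.05 and 20).
#' @return data.frame `id`, `beta`, `usable`.
#' @export
estimate_beta <- function(coverage, segments, lo = 0.05, hi = 20) {
  .assert_df_cols(coverage, c("id", "depth"), "coverage")
  .assert_segments(segments)
  depth <- rowsum(as.numeric(coverage$depth), coverage$id)
  total <- numeric(nrow(segments))
  m <- match(segments$id, as.numeric(rownames(depth)))
  total[!is.na(m)] <- depth[m[!is.na(m)], 1L]
  if (sum(total) <= 0) stop("zero total coverage; cannot estimate beta")
  norm <- total / segments$length
  beta <- norm / mean(norm)
  data.frame(id = segments$id, beta = beta,
             usable = beta >= lo & beta <= hi)
}

#' Remove contacts involving segments with extreme sequencing bias
#'
#' A contact is retained only when both of its segments have
#' `lo <= beta <= hi` (bounds inclusive). Contacts touching a segment with no
#' bias estimate are dropped with a warning.
#'
#' @param contacts Contacts data.frame.
#' @param biases Bias table from [estimate_beta()] (or a per-segment table
#'   with columns `id`, `beta`).
#' @param lo,hi Retention bounds on beta.
#' @return Filtered contacts data.frame.
#' @export
apply_beta_filter <- function(contacts, biases, lo = 0.05, hi = 20) {
  .assert_df_cols(biases, c("id", "beta"), "biases")
  ba <- biases$beta[match(contacts$seg_a, biases$id)]
  bb <- biases$beta[match(contacts$seg_b, biases$id)]
  missing <- is.na(ba) | is.na(bb)
  if (any(missing)) {
    warning(sum(missing), " contact(s) dropped: no bias estimate for a segment")
  }
  keep <- !missing & ba >= lo & ba <= hi & bb >= lo & bb <= hi
  out <- contacts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the fragment-end-density effect f(E)
#'
#' Least-squares fit of log(Hi-C depth) on log(fragment-end count) across
#' segments, returning a multiplicative model rescaled so the mean multiplier
#' over the observed segments is 1. If fewer than two distinct end counts
#' with positive depth are present, the model degenerates to a constant
#' multiplier of 1.
#'
#' @param hic_depth data.frame `id`, `depth`: total Hi-C reads assigned to
#'   each segment (within the analysis window).
#' @param segments Segment table (supplies `n_ends` per id).
#' @return An object of class `end_density_model`.
#' @export
fit_end_density <- function(hic_depth, segments) {
  .assert_df_cols(hic_depth, c("id", "depth"), "hic_depth")
  .assert_segments(segments)
  e <- segments$n_ends[match(hic_depth$id, segments$id)]
  ok <- !is.na(e) & hic_depth$depth > 0
  e_obs <- e[ok]; d_obs <- hic_depth$depth[ok]
  if (length(unique(e_obs)) < 2L) {
    model <- structure(list(slope = 0, intercept = 0, norm = 1,
                            constant = TRUE), class = "end_density_model")
    return(model)
  }
  fit <- stats::lm(log(d_obs) ~ log(e_obs))
  cf <- stats::coef(fit)
  raw <- exp(cf[1L] + cf[2L] * log(e_obs))
  structure(
    list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
         norm = mean(raw), constant = FALSE),
    class = "end_density_model"
  )
}

#' Evaluate the fragment-end-density multiplier
#'
#' @param model An `end_density_model` from [fit_end_density()].
#' @param E Fragment-end counts.
#' @return Positive multipliers with mean 1 over the segments the model was
#'   fitted on.
#' @export
evaluate_end_density <- function(model, E) {
  stopifnot(inherits(model, "end_density_model"))
  if (model$constant) return(rep(1, length(E)))
  exp(model$intercept + model$slope * log(E)) / model$norm
}

#' @export
predict.end_density_model <- function(object, E, ...) evaluate_end_density(object, E)

#' @export
print.end_density_model <- function(x, ...) {
  if (x$constant) {
    cat("Fragment-end-density model: constant (multiplier 1)\n")
  } else {
    cat(sprintf("Fragment-end-density model: log-linear, slope %.3f\n", x$slope))
  }
  invisible(x)
}

#' Bias-adjusted contact probabilities for one anchor segment
#'
#' For an anchor segment, the contact probability with each partner B within
#' the distance window is proportional to
#' `f(D_B) * f_E(E_B) * l_B * beta_B`, normalized over the partner set so the
#' probabilities sum to one. Segments failing the bias filter are excluded
#' both as anchors and from partner (denominator) sets.
#'
#' @param anchor Segment id of the anchor.
#' @param segments Segment table.
#' @param decay A `decay_model`.
#' @param biases Optional bias table (`id`, `beta`, `usable`); NULL treats
#'   all segments as usable with beta 1.
#' @param end_model Optional `end_density_model`; NULL means multiplier 1.
#' @param d_min,d_max Distance window (defaults 2000, 25000).
#' @return list with `anchor`, `partners` (ids), `D`, `p` (probabilities
#'   summing to 1), or an object with `error = "no usable partners"` /
#'   `"anchor unusable"`.
#' @export
adjusted_probabilities <- function(anchor, segments, decay, biases = NULL,
                                   end_model = NULL, d_min = 2000, d_max = 25000) {
  .assert_segments(segments)
  usable <- .usable_ids(segments, biases)
  if (!anchor %in% usable) {
    return(list(anchor = anchor, error = "anchor unusable"))
  }
  arow <- segments[segments$id == anchor, ]
  part <- segments[segments$id %in% usable & segments$chrom == arow$chrom &
                     segments$id != anchor, , drop = FALSE]
  D <- abs(part$center - arow$center)
  sel <- D >= d_min & D <= d_max
  part <- part[sel, , drop = FALSE]; D <- D[sel]
  if (!nrow(part)) {
    return(list(anchor = anchor, error = "no usable partners"))
  }
  w <- .partner_weights(part$id, D, segments, decay, biases, end_model)
  list(anchor = anchor, partners = part$id, D = D, p = w / sum(w))
}

# ids of usable segments: non-centromeric (if tagged) and passing beta bounds
.usable_ids <- function(segments, biases) {
  ids <- segments$id
  if ("centromeric" %in% names(segments)) ids <- ids[!segments$centromeric]
  if (!is.null(biases)) {
    ok <- biases$id[biases$usable]
    ids <- ids[ids %in% ok]
  }
  ids
}

# unnormalized partner weight f(D)*f_E(E)*l*beta for partner ids
.partner_weights <- function(ids, D, segments, decay, biases, end_model) {
  m <- match(ids, segments$id)
  w <- evaluate_decay(decay, D) * segments$length[m]
  if (!is.null(end_model)) {
    w <- w * evaluate_end_density(end_model, segments$n_ends[m])
  }
  if (!is.null(biases)) {
    w <- w * biases$beta[match(ids, biases$id)]
  }
  w
}
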