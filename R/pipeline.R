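# End-to-end pipeline driver over a synthetic study (or pre-loaded inputs).

#' Run the full loop-calling pipeline on a synthetic study
#'
#' Simulates a study, estimates per-segment bias from the simulated
#' resequencing coverage, fits the decay and fragment-end models, calls
#' loops, classifies gene self-loops, and (optionally) writes all results as
#' plain-text tables. Deterministic: the same (config, seed) produce
#' byte-identical output files.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @param q_threshold Loop significance threshold (default 0.01).
#' @return Invisibly, a list with `sim`, `biases`, `decay`, `end_model`,
#'   `calls`, `gene_classes`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1, out_dir = NULL,
                         q_threshold = 0.01) {
  sim <- simulate_study(config, seed)
  segments <- sim$segments
  contacts <- filter_contacts(sim$contacts, segments,
                              d_min = config$d_min, d_max = config$d_max)
  biases <- estimate_beta(sim$reseq, segments)
  contacts <- apply_beta_filter(contacts, biases)
  decay <- fit_decay(equal_occupancy_bins(contacts))
  end_model <- fit_end_density(
    stats::setNames(segment_depths(contacts), c("id", "depth")), segments)
  calls <- call_loops(contacts, segments, decay = decay, biases = biases,
                      end_model = end_model, q_threshold = q_threshold,
                      d_min = config$d_min, d_max = config$d_max)
  gene_classes <- classify_gene_loops(sim$genes, calls, segments)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_segments_bed(segments, file.path(out_dir, "segments.bed"))
    write_contacts(contacts, file.path(out_dir, "contacts.tsv"))
    write_decay(decay, file.path(out_dir, "decay.tsv"))
    write_loops(calls, segments, file.path(out_dir, "loops.tsv"))
    write.table(gene_classes, file.path(out_dir, "gene_loops.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(sim = sim, biases = biases, decay = decay,
                 end_model = end_model, calls = calls,
                 gene_classes = gene_classes))
}
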