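#' End-to-end enhancer-candidate prediction
#'
#' Chains the stages of the framework for one gene list: threshold
#' clustering, 1 Mb locus expansion, intersection with a conservation
#' track broadened by 150 bp, sequence extraction, and the two-round
#' PSWM screen. Stage counts (loci, segments, hits, retained, accepted)
#' are recorded for logging.
#'
#' @param genes a sorted gene list ([build_gene_list()]).
#' @param threshold intergenic cutoff in bp, default 1 Mb.
#' @param track conservation features (data.frame chrom/start/end).
#' @param genome [Biostrings::DNAStringSet] or FASTA path.
#' @param matrices list of `pswm`.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param flank locus expansion in bp, default 1 Mb.
#' @param pad segment broadening in bp, default 150.
#' @param config a [scan_config()].
#' @param source_track label for the track ("GERP", "EPO", ...).
#' @param run_label provenance label for the candidates.
#' @return list with `architecture`, `segments` (data.frame), `seqs`
#'   ([Biostrings::DNAStringSet]), `candidates` (a `candidate_set`),
#'   `counts`.
#' @export
predict_elements <- function(genes, threshold = 1e6, track, genome,
                             matrices, chrom_sizes, flank = 1e6, pad = 150,
                             config = scan_config(),
                             source_track = "other",
                             run_label = NA_character_) {
  arch <- cluster_by_threshold(genes, threshold)
  expanded <- expand_loci(arch, flank = flank, chrom_sizes = chrom_sizes)
  segments <- intersect_and_broaden(expanded, track, pad = pad,
                                    chrom_sizes = chrom_sizes,
                                    source_track = source_track)
  seqs <- extract_segment_seqs(segments, genome)
  cands <- two_round_select(seqs, matrices, config, run_label = run_label)
  counts <- c(genes = nrow(as.data.frame(genes)),
              loci = nrow(arch$loci),
              segments = nrow(segments),
              round1_hits = nrow(cands$round1_hits),
              retained = sum(cands$candidates$retained),
              accepted = sum(cands$candidates$accepted))
  list(architecture = arch, segments = segments, seqs = seqs,
       candidates = cands, counts = counts)
}

#' Write a run manifest
#'
#' Records the run label, input-file MD5 digests, the parameter snapshot
#' and the output paths, sufficient to reproduce the run.
#'
#' @param path output JSON file.
#' @param run_label free-text label.
#' @param inputs named character vector of input file paths.
#' @param params named list of parameters (threshold, alpha, flank, pad,
#'   bins, matrix ids, ...).
#' @param outputs named character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, run_label, inputs = character(),
                           params = list(), outputs = character()) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(unname(inputs)))
  } else list()
  names(digests) <- names(inputs)
  jsonlite::write_json(
    list(run_label = run_label,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         inputs = as.list(inputs), input_md5 = digests,
         params = params, outputs = as.list(outputs)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
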