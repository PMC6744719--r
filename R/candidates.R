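#' Two-round enhancer-candidate selection
#'
#' Round 1 scans all segments with all matrices and converts p-values to
#' q-values pooled over the whole run; segments with at least one
#' significant hit are retained. Round 2 re-scans the retained segments
#' only (all matrices, same alpha) — a smaller pool, so q-values
#' legitimately change, which is what makes the second round meaningful.
#' A retained segment is *accepted* as a putative element iff its
#' round-1 significant hits include at least one core matrix. Accepted
#' candidates are numbered by chromosomal location within the run; the
#' reported interval is the whole conserved (broadened) segment, not the
#' hit window.
#'
#' @param segments named [Biostrings::DNAStringSet]; coordinate-string
#'   names (see [extract_segment_seqs()]) enable chromosomal numbering.
#' @param matrices list of `pswm` with `core` flags.
#' @param config a [scan_config()].
#' @param run_label provenance label recorded on the candidates (the
#'   list/genome letter codes of a multi-run report).
#' @return object of class `candidate_set`: list with `candidates`
#'   (data.frame: segment_id, chrom, start, end, retained, accepted,
#'   enhancer_number, round1_matrices, round2_matrices, run_label),
#'   `round1_hits`, `round2_hits`, `n_scanned`.
#' @export
two_round_select <- function(segments, matrices, config = scan_config(),
                             run_label = NA_character_) {
  if (length(matrices) == 0) stop("two_round_select: empty matrix set")
  r1 <- significant(bh_qvalues(scan_segments(segments, matrices, config)),
                    config)
  retained_ids <- unique(r1$segment_id)
  r2 <- if (length(retained_ids)) {
    significant(bh_qvalues(scan_segments(segments[retained_ids], matrices,
                                         config)), config)
  } else r1[0, , drop = FALSE]
  core_ids <- vapply(Filter(function(m) isTRUE(m$core), matrices),
                     function(m) as.character(m$id), "")
  coords <- parse_segment_headers(names(segments))
  cand <- data.frame(
    segment_id = names(segments),
    chrom = coords$chrom, start = coords$start, end = coords$end,
    retained = names(segments) %in% retained_ids,
    stringsAsFactors = FALSE)
  cand$round1_matrices <- vapply(cand$segment_id, function(id)
    matrix_id_set(r1$matrix_id[r1$segment_id == id]), "")
  cand$round2_matrices <- vapply(cand$segment_id, function(id)
    matrix_id_set(r2$matrix_id[r2$segment_id == id]), "")
  cand$accepted <- vapply(cand$segment_id, function(id)
    any(as.character(r1$matrix_id[r1$segment_id == id]) %in% core_ids),
    TRUE)
  # number accepted candidates by chromosomal location (header coords when
  # parseable, otherwise input order)
  ord <- if (all(!is.na(cand$chrom))) {
    order(chrom_rank(cand$chrom), cand$start)
  } else seq_len(nrow(cand))
  cand$enhancer_number <- NA_integer_
  acc_in_order <- ord[cand$accepted[ord]]
  cand$enhancer_number[acc_in_order] <- seq_along(acc_in_order)
  cand$run_label <- run_label
  structure(list(candidates = cand, round1_hits = r1, round2_hits = r2,
                 n_scanned = length(segments), config = config),
            class = "candidate_set")
}

matrix_id_set <- function(ids) {
  ids <- unique(as.character(ids))
  if (!length(ids)) return("")
  num <- suppressWarnings(as.numeric(ids))
  ids <- if (anyNA(num)) sort(ids) else ids[order(num)]
  paste(ids, collapse = ",")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "candidate_set: %d segments scanned, %d retained, %d accepted\n",
    x$n_scanned, sum(x$candidates$retained), sum(x$candidates$accepted)))
  invisible(x)
}

#' Configuration of the H/P-only 13-mer pipeline variant
#'
#' @param query the core 13-mer, default [core_motif_13()].
#' @param top_n best-matching subjects kept per database, default 100.
#' @param allowed_matrices ids whose significant hits qualify a segment
#'   for retention (matrices free of post-2014/J sequence information),
#'   default c(1, 2, 3, 8).
#' @return list of class `variant_config`.
#' @export
variant_config <- function(query = core_motif_13(), top_n = 100,
                           allowed_matrices = c(1, 2, 3, 8)) {
  stopifnot(top_n >= 1, length(allowed_matrices) >= 1)
  structure(list(query = query, top_n = top_n,
                 allowed_matrices = as.character(allowed_matrices)),
            class = "variant_config")
}

# best ungapped local-alignment score of a short query against a subject
# (both strands); match +1 / mismatch -3, gaps prohibited — exact and
# deterministic for a 13 bp query
ungapped_local_score <- function(query, subject) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3)
  best <- -Inf
  q <- Biostrings::DNAString(query)
  for (subj in list(subject, Biostrings::reverseComplement(subject))) {
    sc <- Biostrings::pairwiseAlignment(
      q, subj, type = "local", substitutionMatrix = submat,
      gapOpening = 1e6, gapExtension = 1e6, scoreOnly = TRUE)
    best <- max(best, sc)
  }
  best
}

#' H/P-only variant: 13-mer pre-filter then two-round screen
#'
#' For each database of conserved segments, every segment is ranked by
#' the best ungapped local-alignment score of the 13-bp core query
#' (match +1, mismatch -3, both strands; ties broken by segment
#' coordinate) and the `top_n` best subjects are kept. A first-round
#' scan uses all matrices, but only segments with a significant hit for
#' one of the `allowed_matrices` are retained; a second round re-scans
#' the retained segments with all matrices. Per candidate, the matrix-id
#' sets with at least one significant hit in each round are reported.
#'
#' @param databases named list of [Biostrings::DNAStringSet] (e.g. GERP-
#'   and EPO-derived segment sets).
#' @param matrices list of `pswm`.
#' @param config a [variant_config()].
#' @param scan a [scan_config()].
#' @return data.frame: `database`, `segment_id`, `chrom`, `start`, `end`,
#'   `best_13mer_score`, `retained`, `round1_matrices`, `round2_matrices`.
#' @export
variant_core_motif_search <- function(databases, matrices,
                                      config = variant_config(),
                                      scan = scan_config()) {
  stopifnot(is.list(databases), length(databases) > 0)
  out <- lapply(names(databases), function(db_name) {
    db <- databases[[db_name]]
    if (length(db) < config$top_n) {
      message("database '", db_name, "' has ", length(db),
              " segments (< top_n = ", config$top_n, "); keeping all")
    }
    scores <- vapply(seq_along(db), function(i)
      ungapped_local_score(config$query, db[[i]]), 0)
    coords <- parse_segment_headers(names(db))
    tie <- if (all(!is.na(coords$chrom))) {
      order(-scores, chrom_rank(coords$chrom), coords$start)
    } else order(-scores, seq_along(db))
    keep <- head(tie, config$top_n)
    top <- db[keep]

    r1 <- significant(bh_qvalues(scan_segments(top, matrices, scan)), scan)
    retained_ids <- unique(
      r1$segment_id[as.character(r1$matrix_id) %in% config$allowed_matrices])
    r2 <- if (length(retained_ids)) {
      significant(bh_qvalues(scan_segments(top[retained_ids], matrices,
                                           scan)), scan)
    } else r1[0, , drop = FALSE]

    cc <- parse_segment_headers(names(top))
    data.frame(
      database = db_name,
      segment_id = names(top),
      chrom = cc$chrom, start = cc$start, end = cc$end,
      best_13mer_score = scores[keep],
      retained = names(top) %in% retained_ids,
      round1_matrices = vapply(names(top), function(id)
        matrix_id_set(r1$matrix_id[r1$segment_id == id]), "",
        USE.NAMES = FALSE),
      round2_matrices = vapply(names(top), function(id)
        matrix_id_set(r2$matrix_id[r2$segment_id == id]), "",
        USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Label candidates against known elements
#'
#' Candidates sharing genomic overlap with a known element (when
#' coordinates are on the same assembly) — or, lacking coordinates, a
#' local-alignment match to its sequence — are labeled
#' `"overlaps <element>"`; all others are `"novel"`. A candidate whose
#' significant matrices all derive from the overlapped element itself is
#' additionally flagged `derived_from_own_matrix`: such a rediscovery is
#' not self-supporting evidence.
#'
#' @param candidates candidate data.frame (needs `chrom`, `start`, `end`,
#'   `round1_matrices`; e.g. `two_round_select(...)$candidates`).
#' @param known_coords optional data.frame of known-element intervals
#'   (`chrom`, `start`, `end`, `name`, 0-based half-open).
#' @param known_seqs optional named [Biostrings::DNAStringSet] of
#'   known-element sequences (used when coordinates are unavailable).
#' @param candidate_seqs named [Biostrings::DNAStringSet] of candidate
#'   sequences, required with `known_seqs`.
#' @param matrix_provenance named list mapping matrix id to the element
#'   names its training block derives from.
#' @param min_identity,min_coverage sequence-match thresholds, as in
#'   [known_element_retention()].
#' @return `candidates` with `label` and `derived_from_own_matrix`
#'   columns.
#' @export
rediscovery_check <- function(candidates, known_coords = NULL,
                              known_seqs = NULL, candidate_seqs = NULL,
                              matrix_provenance = list(),
                              min_identity = 0.8, min_coverage = 0.5) {
  labels <- rep("novel", nrow(candidates))
  matched_el <- rep(NA_character_, nrow(candidates))
  if (!is.null(known_coords) && nrow(known_coords) > 0) {
    for (i in seq_len(nrow(candidates))) {
      if (is.na(candidates$chrom[i])) next
      ov <- known_coords$chrom == candidates$chrom[i] &
        known_coords$start < candidates$end[i] &
        known_coords$end > candidates$start[i]
      if (any(ov)) {
        matched_el[i] <- known_coords$name[which(ov)[1]]
        labels[i] <- paste0("overlaps ", matched_el[i])
      }
    }
  }
  if (!is.null(known_seqs) && !is.null(candidate_seqs)) {
    todo <- which(labels == "novel" &
                    candidates$segment_id %in% names(candidate_seqs))
    for (i in todo) {
      ret <- known_element_retention(
        known_seqs,
        candidate_seqs[candidates$segment_id[i]],
        min_identity = min_identity, min_coverage = min_coverage)
      hit <- ret$table$element[ret$table$retained]
      if (length(hit)) {
        matched_el[i] <- hit[1]
        labels[i] <- paste0("overlaps ", hit[1])
      }
    }
  }
  derived <- rep(FALSE, nrow(candidates))
  if (length(matrix_provenance)) {
    for (i in seq_len(nrow(candidates))) {
      if (is.na(matched_el[i])) next
      ids <- strsplit(candidates$round1_matrices[i], ",")[[1]]
      ids <- ids[nzchar(ids)]
      if (!length(ids)) next
      own <- vapply(ids, function(id)
        matched_el[i] %in% (matrix_provenance[[id]] %||% character()), TRUE)
      derived[i] <- all(own)
    }
  }
  candidates$label <- labels
  candidates$derived_from_own_matrix <- derived
  candidates
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write accepted candidates as a BED track
#'
#' @param cs a `candidate_set` (or its `candidates` data.frame).
#' @param path output `.bed` file.
#' @return `path`, invisibly.
#' @export
write_candidate_bed <- function(cs, path) {
  cand <- if (inherits(cs, "candidate_set")) cs$candidates else cs
  acc <- cand[cand$accepted & !is.na(cand$chrom), , drop = FALSE]
  bed <- data.frame(chrom = acc$chrom, start = acc$start, end = acc$end,
                    name = paste0("enhancer", acc$enhancer_number),
                    score = 0, strand = "+", stringsAsFactors = FALSE)
  bed <- bed[order_genomic(bed), , drop = FALSE]
  write_bed6(bed, path)
}
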