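# Interval helpers: the package stores genomic intervals as plain
# data.frames (chrom, start, end) in 0-based half-open coordinates and
# converts to 1-based GRanges only at the GenomicRanges/rtracklayer
# boundary.

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a BED file into 0-based half-open intervals
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file '", path,
                                          "': ", conditionMessage(e)))
  out <- granges_to_intervals(gr)
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' Expand locus spans by a flank
#'
#' Each locus span of the architecture grows by `flank` bp on both sides,
#' clamped to the chromosome bounds. Expanded intervals that overlap each
#' other are all kept (no merging), so conserved features shared between
#' neighboring loci are harvested for each of them.
#'
#' @param arch an `architecture`.
#' @param flank bp added on each side, default 1 Mb.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return data.frame of intervals with a `locus_id` column.
#' @export
expand_loci <- function(arch, flank = 1e6, chrom_sizes) {
  loci <- arch$loci
  unknown <- setdiff(unique(loci$chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop("chromosome(s) absent from chrom.sizes: ",
         paste(unknown, collapse = ", "))
  }
  data.frame(chrom = loci$chrom,
             start = pmax(0, loci$span_start - flank),
             end = pmin(unname(chrom_sizes[loci$chrom]), loci$span_end + flank),
             locus_id = loci$locus_id,
             stringsAsFactors = FALSE)
}

#' Intersect expanded loci with a conservation track and broaden
#'
#' Every positive-width overlap between a track feature and an expanded
#' interval becomes one segment, padded by `pad` bp on each side and
#' clamped to the chromosome. Exact duplicate segments are removed;
#' overlapping non-identical segments are retained separately (no
#' merging), mirroring how independently conserved stretches are listed.
#'
#' @param expanded intervals from [expand_loci()].
#' @param track conservation features (data.frame chrom/start/end, e.g.
#'   from [read_bed()]).
#' @param pad broadening in bp, default 150.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param source_track label recorded on the output ("GERP", "EPO", ...).
#' @return data.frame of segments with `chrom`, `start`, `end`,
#'   `source_track`, `segment_id` (coordinate string).
#' @export
intersect_and_broaden <- function(expanded, track, pad = 150, chrom_sizes,
                                  source_track = "other") {
  stopifnot(pad >= 0)
  if (nrow(expanded) == 0 || nrow(track) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), source_track = character(),
                      segment_id = character(), stringsAsFactors = FALSE))
  }
  gr_e <- intervals_to_granges(expanded)
  gr_t <- intervals_to_granges(track)
  ov <- GenomicRanges::findOverlaps(gr_t, gr_e, minoverlap = 1)
  if (length(ov) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), source_track = character(),
                      segment_id = character(), stringsAsFactors = FALSE))
  }
  pieces <- IRanges::pintersect(gr_t[S4Vectors::queryHits(ov)],
                                gr_e[S4Vectors::subjectHits(ov)])
  seg <- granges_to_intervals(pieces)
  seg$start <- pmax(0, seg$start - pad)
  seg$end <- pmin(unname(chrom_sizes[seg$chrom]), seg$end + pad)
  seg$source_track <- source_track
  seg <- unique(seg)
  seg <- seg[order_genomic(seg), , drop = FALSE]
  rownames(seg) <- NULL
  seg$segment_id <- coord_string(seg$chrom, seg$start, seg$end)
  seg
}

#' Extract segment sequences from a genome
#'
#' One FASTA record per segment, named with the 1-based inclusive
#' coordinate string `chrom:start-end` so the header parses back to the
#' interval ([parse_segment_headers()]). Sequences are uppercased.
#'
#' @param segments data.frame of intervals (0-based half-open).
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome, or the
#'   path of a FASTA file.
#' @return named [Biostrings::DNAStringSet].
#' @export
extract_segment_seqs <- function(segments, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  missing_chr <- setdiff(unique(segments$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  if (nrow(segments) == 0) return(Biostrings::DNAStringSet())
  lens <- setNames(Biostrings::width(genome), names(genome))
  beyond <- segments$end > lens[segments$chrom] | segments$start < 0
  if (any(beyond)) {
    stop("segment(s) beyond chromosome bounds: ",
         paste(head(coord_string(segments$chrom[beyond],
                                 segments$start[beyond],
                                 segments$end[beyond]), 5), collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(segments)), function(i) {
    toupper(as.character(Biostrings::subseq(genome[[segments$chrom[i]]],
                                            start = segments$start[i] + 1,
                                            end = segments$end[i])))
  }, ""))
  names(seqs) <- coord_string(segments$chrom, segments$start, segments$end)
  seqs
}

#' Parse coordinate-string FASTA headers back to intervals
#'
#' Inverse of the headers written by [extract_segment_seqs()].
#'
#' @param headers character vector like `"chr1:951-1350"` (1-based
#'   inclusive).
#' @return data.frame of 0-based half-open intervals; unparsable headers
#'   yield NA coordinates.
#' @export
parse_segment_headers <- function(headers) {
  m <- regmatches(headers, regexec("^(.+):([0-9]+)-([0-9]+)$", headers))
  ok <- lengths(m) == 4
  data.frame(
    chrom = ifelse(ok, vapply(m, function(x) if (length(x) == 4) x[2] else NA_character_, ""), NA_character_),
    start = ifelse(ok, vapply(m, function(x) if (length(x) == 4) as.numeric(x[3]) - 1 else NA_real_, 0), NA_real_),
    end = ifelse(ok, vapply(m, function(x) if (length(x) == 4) as.numeric(x[4]) else NA_real_, 0), NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Known-element retention quality control
#'
#' Checks, by local pairwise alignment on both strands, whether each known
#' element sequence is retained in a set of conserved segments: an element
#' is retained iff some segment carries a local alignment with identity
#' `>= min_identity` spanning `>= min_coverage` of the element length.
#'
#' @param known named [Biostrings::DNAStringSet] of element sequences.
#' @param segments named [Biostrings::DNAStringSet] of conserved segments.
#' @param min_identity fraction, default 0.8.
#' @param min_coverage fraction of the element length, default 0.5.
#' @return list with `table` (per-element element, retained, best_identity,
#'   best_coverage, best_segment) and `fraction` retained.
#' @export
known_element_retention <- function(known, segments, min_identity = 0.8,
                                    min_coverage = 0.5) {
  if (length(known) == 0 || length(segments) == 0) {
    stop("known_element_retention: empty input")
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  rows <- lapply(seq_along(known), function(i) {
    el <- known[[i]]
    len <- length(el)
    best <- list(id = 0, cov = 0, seg = NA_character_)
    for (j in seq_along(segments)) {
      for (subject in list(segments[[j]],
                           Biostrings::reverseComplement(segments[[j]]))) {
        aln <- Biostrings::pairwiseAlignment(
          el, subject, type = "local", substitutionMatrix = submat,
          gapOpening = 2, gapExtension = 1)
        idf <- Biostrings::pid(aln, type = "PID1") / 100
        pat <- Biostrings::pattern(aln)
        cov <- (IRanges::end(pat) - IRanges::start(pat) + 1) / len
        if (idf * cov > best$id * best$cov ||
            (idf >= min_identity && cov >= min_coverage)) {
          best <- list(id = idf, cov = cov, seg = names(segments)[j])
        }
        if (idf >= min_identity && cov >= min_coverage) break
      }
      if (best$id >= min_identity && best$cov >= min_coverage) break
    }
    data.frame(element = names(known)[i],
               retained = best$id >= min_identity && best$cov >= min_coverage,
               best_identity = best$id, best_coverage = best$cov,
               best_segment = best$seg, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, fraction = mean(tab$retained))
}
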