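#' Scan configuration
#'
#' @param alpha significance level for p- and q-values, default 0.05.
#' @param bins discretization resolution of the score grid used by the
#'   dynamic-programming p-values, default 1000 (>= 100 enforced).
#' @param background `"segments"` (zero-order frequencies estimated from
#'   the scanned segment set, the default), `"uniform"`, or a numeric
#'   vector of 4 probabilities over A,C,G,T.
#' @param filter which significance filter [significant()] applies:
#'   `"both"` (p <= alpha and q <= alpha, the default), `"p"` or `"q"`.
#' @param max_n_fraction segments whose sequence is more than this
#'   fraction N are skipped with a message, default 0.5.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(alpha = 0.05, bins = 1000, background = "segments",
                        filter = c("both", "p", "q"), max_n_fraction = 0.5) {
  stopifnot(alpha > 0, alpha < 1, bins >= 100)
  structure(list(alpha = alpha, bins = bins, background = background,
                 filter = match.arg(filter),
                 max_n_fraction = max_n_fraction),
            class = "scan_config")
}

# zero-order background from a DNAStringSet (N and other codes ignored)
estimate_background <- function(segments) {
  counts <- colSums(Biostrings::letterFrequency(segments, DNA_LETTERS))
  if (sum(counts) == 0) return(rep(0.25, 4))
  freqs <- pmax(counts / sum(counts), 1e-3)   # keep log-odds finite
  unname(freqs / sum(freqs))
}

resolve_background <- function(config, segments) {
  bg <- config$background
  if (is.numeric(bg)) return(validate_background(bg))
  if (identical(bg, "uniform")) return(rep(0.25, 4))
  estimate_background(segments)
}

#' Exact score-to-p-value table for a PSWM
#'
#' Discretizes the per-column log-odds scores onto an integer grid of
#' about `bins` steps spanning the attainable score range, then obtains
#' the exact distribution of the window score under the zero-order
#' background by column-wise convolution. The window score used by the
#' scanner lives on the same grid, so `p(s) = P(score >= s)` is exact for
#' the discretized matrix; discretization moves any p-value by at most
#' the mass near one grid bin per column. p is non-increasing in s and
#' equals 1 at the minimum attainable score.
#'
#' @param pswm a `pswm`.
#' @param background zero-order probabilities over A,C,G,T.
#' @param bins grid resolution, default 1000.
#' @return object of class `pvalue_table`: list with `lod` (real
#'   log-odds, bits), `imat` (integer grid scores), `scale`, `offset`
#'   (real score at integer 0), `tail` (`tail[s + 1] = P(S_int >= s)`),
#'   `width`.
#' @export
pvalue_table <- function(pswm, background = rep(0.25, 4), bins = 1000) {
  background <- validate_background(background)
  lod <- log_odds(pswm, background)
  w <- nrow(lod)
  colmin <- apply(lod, 1, min)
  colmax <- apply(lod, 1, max)
  total_range <- sum(colmax - colmin)
  scale <- if (total_range > 0) bins / total_range else 1
  imat <- round(sweep(lod, 1, colmin, "-") * scale)
  storage.mode(imat) <- "integer"
  pmf <- 1
  for (j in seq_len(w)) {
    newlen <- length(pmf) + max(imat[j, ])
    new <- numeric(newlen)
    for (a in 1:4) {
      idx <- imat[j, a]
      new[(idx + 1):(idx + length(pmf))] <-
        new[(idx + 1):(idx + length(pmf))] + background[a] * pmf
    }
    pmf <- new
  }
  tail <- rev(cumsum(rev(pmf)))
  tail <- pmin(tail, 1)
  structure(list(lod = lod, imat = imat, scale = scale,
                 offset = sum(colmin), tail = tail, width = w),
            class = "pvalue_table")
}

#' Look up p-values for real-valued window scores
#' @param table a `pvalue_table`.
#' @param score numeric vector of window log-odds scores (bits).
#' @return numeric vector of p-values.
#' @export
pvalue_lookup <- function(table, score) {
  s_int <- pmax(0L, pmin(length(table$tail) - 1L,
                         as.integer(round((score - table$offset) * table$scale))))
  table$tail[s_int + 1L]
}

encode_dna <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], DNA_LETTERS)
  codes
}

# score every window of `codes` (integer 1..4, NA for ambiguous) against
# an integer/real score matrix pair; returns int scores, real scores and
# a validity mask
score_windows <- function(codes, imat, lod) {
  w <- nrow(imat)
  n <- length(codes) - w + 1L
  if (n < 1) {
    return(list(s_int = integer(0), bits = numeric(0), ok = logical(0)))
  }
  s_int <- integer(n)
  bits <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    bad <- is.na(cj)
    ok <- ok & !bad
    cj[bad] <- 1L
    s_int <- s_int + imat[j, cj]
    bits <- bits + lod[j, cj]
  }
  list(s_int = s_int, bits = bits, ok = ok)
}

#' Scan segments with PSWMs on both strands
#'
#' Every window of every segment is scored on the forward and
#' reverse-complement strands; windows reaching `p <= alpha` are emitted
#' as hits (pre-q-value filter), with reverse-strand coordinates reported
#' on the forward strand and 0-based half-open within-segment positions.
#' Output order is (segment, start, matrix, strand) and the scan is fully
#' deterministic. The total number of scanned windows is recorded in the
#' `n_tests` attribute and is the Benjamini-Hochberg pool size used by
#' [bh_qvalues()] for this run.
#'
#' @param segments named [Biostrings::DNAStringSet].
#' @param matrices list of `pswm`.
#' @param config a [scan_config()].
#' @return data.frame of hits: `matrix_id`, `segment_id`, `start`,
#'   `stop`, `strand`, `score` (bits), `p_value`, `q_value` (NA until
#'   [bh_qvalues()]), `matched_seq`; attributes `n_tests`, `background`,
#'   `config`.
#' @export
scan_segments <- function(segments, matrices, config = scan_config()) {
  if (length(matrices) == 0) stop("scan_segments: empty matrix set")
  if (is.null(names(segments)) && length(segments) > 0) {
    names(segments) <- paste0("segment", seq_along(segments))
  }
  background <- resolve_background(config, segments)
  tables <- lapply(matrices, pvalue_table, background = background,
                   bins = config$bins)
  seq_chars <- as.character(segments)
  n_frac <- if (length(segments)) {
    as.numeric(Biostrings::letterFrequency(segments, "N")) /
      pmax(1, Biostrings::width(segments))
  } else numeric(0)
  skip <- n_frac > config$max_n_fraction
  if (any(skip)) {
    message("skipping ", sum(skip), " segment(s) with > ",
            config$max_n_fraction * 100, "% N")
  }
  hits <- list()
  n_tests <- 0
  for (si in seq_along(segments)) {
    if (skip[si]) next
    codes_f <- encode_dna(seq_chars[si])
    L <- length(codes_f)
    codes_r <- rev(5L - codes_f)     # reverse complement, NA preserved
    for (mi in seq_along(matrices)) {
      tab <- tables[[mi]]
      w <- tab$width
      for (strand in c("+", "-")) {
        codes <- if (strand == "+") codes_f else codes_r
        sw <- score_windows(codes, tab$imat, tab$lod)
        valid <- which(sw$ok)
        n_tests <- n_tests + length(valid)
        if (!length(valid)) next
        p <- tab$tail[sw$s_int[valid] + 1L]
        emit <- valid[p <= config$alpha]
        if (!length(emit)) next
        p_emit <- tab$tail[sw$s_int[emit] + 1L]
        start0 <- if (strand == "+") emit - 1L else L - (emit - 1L) - w
        strand_seq <- paste(c("A", "C", "G", "T", "N")[
          ifelse(is.na(codes), 5L, codes)], collapse = "")
        matched <- substring(strand_seq, emit, emit + w - 1L)
        hits[[length(hits) + 1L]] <- data.frame(
          matrix_id = rep(matrices[[mi]]$id, length(emit)),
          segment_id = names(segments)[si],
          start = start0, stop = start0 + w,
          strand = strand,
          score = sw$bits[emit],
          p_value = p_emit,
          q_value = NA_real_,
          matched_seq = matched,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    matrix_id = character(), segment_id = character(), start = integer(),
    stop = integer(), strand = character(), score = numeric(),
    p_value = numeric(), q_value = numeric(), matched_seq = character(),
    stringsAsFactors = FALSE)
  if (nrow(out)) {
    seg_rank <- match(out$segment_id, names(segments))
    mat_rank <- match(out$matrix_id, vapply(matrices, function(m)
      as.character(m$id), ""))
    out <- out[order(seg_rank, out$start, mat_rank, out$strand), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_tests") <- n_tests
  attr(out, "background") <- background
  attr(out, "config") <- config
  out
}

#' Benjamini-Hochberg q-values for motif hits
#'
#' The q-value of a hit is the minimal false discovery rate at which it
#' is called significant: for the i-th smallest p-value,
#' `q(i) = min over j >= i of (m p(j) / j)`, capped at 1. The pool size
#' `m` defaults to the number of tests performed by the scan that
#' produced the hits (the `n_tests` attribute set by [scan_segments()]:
#' all matrices, segments and strands of one run); for a bare table of
#' p-values it is the number of rows.
#'
#' @param hits hit data.frame with `p_value`.
#' @param m pool size override.
#' @return `hits` with `q_value` filled in.
#' @export
bh_qvalues <- function(hits, m = NULL) {
  if (nrow(hits) == 0) return(hits)
  if (is.null(m)) {
    m <- attr(hits, "n_tests")
    if (is.null(m)) m <- nrow(hits)
  }
  hits$q_value <- p.adjust(hits$p_value, method = "BH", n = max(m, nrow(hits)))
  hits
}

#' Filter hits for significance and annotate q-level stars
#'
#' Default keeps hits with `p <= alpha` and `q <= alpha` and annotates
#' the reporting level: `*` for q < 0.05, `**` for q < 0.01, `***` for
#' q < 0.001.
#'
#' @param hits hit data.frame with q-values set.
#' @param config a [scan_config()] (alpha and filter mode).
#' @return filtered hits with a `q_level` column.
#' @export
significant <- function(hits, config = scan_config()) {
  if (nrow(hits) == 0) {
    hits$q_level <- character(0)
    return(hits)
  }
  keep <- switch(config$filter,
    both = hits$p_value <= config$alpha & hits$q_value <= config$alpha,
    p = hits$p_value <= config$alpha,
    q = hits$q_value <= config$alpha)
  out <- hits[keep, , drop = FALSE]
  out$q_level <- ifelse(out$q_value < 0.001, "***",
                        ifelse(out$q_value < 0.01, "**",
                               ifelse(out$q_value < 0.05, "*", "")))
  rownames(out) <- NULL
  out
}

#' Write a hit table as TSV
#' @param hits hit data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
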