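DNA_LETTERS <- c("A", "C", "G", "T")

#' The 13-bp core motif shared by the H and P elements
#'
#' A perfect 13-bp match (5'-TCATTAAAAAGTT-3') exists among the H element,
#' the P element and the promoter of *Olfr713*; it is the query of the
#' H/P-only pipeline variant ([variant_core_motif_search()]).
#'
#' @return character scalar of length-13 DNA.
#' @export
core_motif_13 <- function() "TCATTAAAAAGTT"

#' Construct a position-specific weight matrix (PSWM)
#'
#' Builds column probabilities from an ungapped block of equal-length
#' DNA sequences with a background-distributed pseudocount:
#' `p[i, a] = (count[i, a] + alpha_p * bg[a]) / (nsites + alpha_p)`.
#'
#' @param block character vector or [Biostrings::DNAStringSet] of
#'   equal-length ACGT sequences (ambiguity codes rejected).
#' @param id matrix identifier (the published set is numbered 1-12).
#' @param pseudocount total pseudocount `alpha_p` distributed by the
#'   background, default 0.1.
#' @param background zero-order probabilities over A,C,G,T, default
#'   uniform.
#' @param core is this a core matrix (element/homeodomain signature)?
#'   Conventionally true for ids 1-8.
#' @param variant_safe built without sequence information from the
#'   post-2014 element set or J (usable by the H/P-only variant)?
#' @param provenance character vector of element names the block derives
#'   from (used by [rediscovery_check()]).
#' @return object of class `pswm`: list with `id`, `probs` (w x 4 matrix,
#'   columns A,C,G,T), `nsites`, `core`, `variant_safe`, `provenance`.
#' @export
build_pswm <- function(block, id = NA_integer_, pseudocount = 0.1,
                       background = rep(0.25, 4), core = FALSE,
                       variant_safe = FALSE, provenance = character()) {
  block <- as.character(block)
  if (length(block) == 0) stop("build_pswm: empty block")
  w <- unique(nchar(block))
  if (length(w) != 1) stop("build_pswm: ragged block (unequal lengths)")
  if (w < 1) stop("build_pswm: zero-width block")
  block <- toupper(block)
  if (any(grepl("[^ACGT]", block))) {
    stop("build_pswm: non-ACGT character in block (ambiguity codes rejected)")
  }
  background <- validate_background(background)
  chars <- matrix(unlist(strsplit(block, "")), nrow = length(block),
                  byrow = TRUE)
  counts <- t(apply(chars, 2, function(col) {
    tabulate(match(col, DNA_LETTERS), nbins = 4)
  }))
  if (w == 1) counts <- matrix(counts, nrow = 1)
  probs <- sweep(counts, 2, pseudocount * background, "+") /
    (length(block) + pseudocount)
  colnames(probs) <- DNA_LETTERS
  new_pswm(probs, id = id, nsites = length(block), core = core,
           variant_safe = variant_safe, provenance = provenance)
}

new_pswm <- function(probs, id = NA_integer_, nsites = NA_integer_,
                     core = FALSE, variant_safe = FALSE,
                     provenance = character()) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4)
  colnames(probs) <- DNA_LETTERS
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-6)) {
    probs <- probs / sums          # renormalize printed-precision input
  }
  structure(list(id = id, probs = probs, nsites = nsites, core = core,
                 variant_safe = variant_safe, provenance = provenance),
            class = "pswm")
}

validate_background <- function(background) {
  stopifnot(length(background) == 4, all(background > 0))
  background / sum(background)
}

#' @export
print.pswm <- function(x, ...) {
  cat(sprintf("PSWM %s: width %d, nsites %s%s%s\n consensus %s\n",
              x$id, pswm_width(x), x$nsites,
              if (isTRUE(x$core)) ", core" else "",
              if (isTRUE(x$variant_safe)) ", variant-safe" else "",
              pswm_consensus(x)))
  invisible(x)
}

#' PSWM width (number of columns)
#' @param pswm a `pswm`.
#' @return integer width.
#' @export
pswm_width <- function(pswm) nrow(pswm$probs)

#' Consensus sequence of a PSWM
#' @param pswm a `pswm`.
#' @return character scalar.
#' @export
pswm_consensus <- function(pswm) {
  paste(DNA_LETTERS[apply(pswm$probs, 1, which.max)], collapse = "")
}

#' Per-column information content of a PSWM (bits)
#' @param pswm a `pswm`.
#' @return numeric vector in `[0, 2]`.
#' @export
pswm_information <- function(pswm) {
  apply(pswm$probs, 1, function(p) 2 + sum(p * log2(p)))
}

#' Reverse-complement a PSWM
#' @param pswm a `pswm`.
#' @return a `pswm` with columns reversed and letters complemented.
#' @export
pswm_revcomp <- function(pswm) {
  probs <- pswm$probs[rev(seq_len(pswm_width(pswm))), c("T", "G", "C", "A"),
                      drop = FALSE]
  colnames(probs) <- DNA_LETTERS
  out <- pswm
  out$probs <- probs
  out
}

#' Log-odds score matrix of a PSWM (bits)
#'
#' `score[i, a] = log2(p[i, a] / bg[a])`. Zero probabilities (possible
#' only with a zero pseudocount) are floored with a warning.
#'
#' @param pswm a `pswm`.
#' @param background zero-order probabilities over A,C,G,T.
#' @param prob_floor floor applied to zero probabilities, default 1e-4.
#' @return w x 4 numeric matrix.
#' @export
log_odds <- function(pswm, background = rep(0.25, 4), prob_floor = 1e-4) {
  background <- validate_background(background)
  probs <- pswm$probs
  if (any(probs == 0)) {
    warning("PSWM ", pswm$id, " has zero probabilities; flooring at ",
            prob_floor)
    probs[probs == 0] <- prob_floor
  }
  log2(sweep(probs, 2, background, "/"))
}

#' Read PSWMs from a MEME minimal motif file
#'
#' Supports the minimal format: a `MEME version` line, an optional
#' `ALPHABET= ACGT` line (4-letter DNA only), an optional
#' `Background letter frequencies` block, and per-motif
#' `MOTIF <name>` / `letter-probability matrix: alength= 4 w= ...`
#' sections. Motif order is preserved.
#'
#' @param path file path.
#' @param core_ids numeric ids flagged as core matrices, default 1-8.
#' @param variant_safe_ids ids usable by the H/P-only variant, default
#'   c(1, 2, 3, 8).
#' @return list with `matrices` (list of `pswm`) and `background`.
#' @export
read_meme <- function(path, core_ids = 1:8,
                      variant_safe_ids = c(1, 2, 3, 8)) {
  lines <- readLines(path)
  if (!any(grepl("^\\s*MEME version", lines))) {
    stop("not a MEME motif file (missing 'MEME version' line): ", path)
  }
  alpha_line <- grep("^\\s*ALPHABET\\s*=", lines, value = TRUE)
  if (length(alpha_line)) {
    alpha <- gsub("\\s", "", sub("^\\s*ALPHABET\\s*=", "", alpha_line[1]))
    if (toupper(alpha) != "ACGT") {
      stop("unsupported alphabet '", alpha, "' (DNA ACGT only)")
    }
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^\\s*Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    if (length(toks) >= 8) {
      freqs <- as.numeric(toks[seq(2, 8, by = 2)])
      names(freqs) <- toupper(toks[seq(1, 7, by = 2)])
      background <- unname(freqs[DNA_LETTERS])
    }
  }
  motif_at <- grep("^\\s*MOTIF\\b", lines)
  matrices <- lapply(motif_at, function(at) {
    name <- strsplit(trimws(lines[at]), "\\s+")[[1]][2]
    hdr_at <- at + grep("letter-probability matrix",
                        lines[(at + 1):length(lines)])[1]
    hdr <- lines[hdr_at]
    alength <- as.integer(sub(".*alength=\\s*([0-9]+).*", "\\1", hdr))
    if (is.na(alength) || alength != 4) {
      stop("motif '", name, "': alength= ", alength, " unsupported (must be 4)")
    }
    w <- as.integer(sub(".*\\bw=\\s*([0-9]+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.integer(sub(".*nsites=\\s*([0-9]+).*", "\\1", hdr))
    } else NA_integer_
    rows <- lines[(hdr_at + 1):(hdr_at + w)]
    probs <- t(vapply(rows, function(r) {
      v <- as.numeric(strsplit(trimws(r), "\\s+")[[1]])
      if (length(v) != 4) {
        stop("motif '", name, "': matrix row with ", length(v),
             " columns (expected 4)")
      }
      v
    }, numeric(4)))
    rownames(probs) <- NULL
    id <- suppressWarnings(as.numeric(name))
    if (is.na(id)) id <- name
    new_pswm(probs, id = id, nsites = nsites,
             core = is.numeric(id) && id %in% core_ids,
             variant_safe = is.numeric(id) && id %in% variant_safe_ids)
  })
  list(matrices = matrices, background = background)
}

#' Write PSWMs as a MEME minimal motif file
#'
#' @param matrices list of `pswm`.
#' @param path output file.
#' @param background zero-order probabilities written to the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(matrices, path, background = rep(0.25, 4)) {
  background <- validate_background(background)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_LETTERS, background),
                     collapse = " "), ""), con)
  for (m in matrices) {
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      pswm_width(m), if (is.na(m$nsites)) 20L else as.integer(m$nsites)), con)
    for (i in seq_len(pswm_width(m))) {
      writeLines(paste(sprintf("%.6f", m$probs[i, ]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
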