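#' Read a chromosome-sizes table
#'
#' Two whitespace-separated columns, name and length in bp, as produced by
#' `samtools faidx` (first two columns) or UCSC `chrom.sizes` files.
#'
#' @param path file path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom.sizes file must have two columns (name, length)")
  len <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(len)) stop("non-numeric chromosome length in ", path)
  setNames(len, as.character(df[[1]]))
}

#' Natural chromosome ordering rank
#'
#' Numeric chromosome names sort numerically, then X, then Y, then MT;
#' any other (unplaced/alternative) name sorts last, alphabetically.
#' A leading "chr" prefix is ignored.
#'
#' @param chrom character vector of chromosome names.
#' @return Numeric rank usable in `order()`.
#' @export
chrom_rank <- function(chrom) {
  base <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(base))
  rank <- num
  rank[base %in% c("X", "x")] <- 1e6
  rank[base %in% c("Y", "y")] <- 1e6 + 1
  rank[base %in% c("MT", "M", "mt")] <- 1e6 + 2
  other <- is.na(rank)
  if (any(other)) {
    # unplaced scaffolds: stable alphabetical order after everything else
    rank[other] <- 2e6 + xtfrm(base[other])
  }
  rank
}

#' Order gene/interval rows by (natural chromosome order, start, end)
#' @param df data.frame with `chrom`, `start`, `end` columns.
#' @return Integer permutation.
#' @keywords internal
order_genomic <- function(df) {
  order(chrom_rank(df$chrom), df$start, df$end)
}

# render 0-based half-open internal coordinates as the 1-based inclusive
# "chrN:start-end" strings used in reports
coord_string <- function(chrom, start0, end0) {
  sprintf("%s:%d-%d", chrom, as.integer(start0) + 1L, as.integer(end0))
}
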