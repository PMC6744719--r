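#' Intergenic distance between two genes
#'
#' The inner gap between gene bodies (end of the upstream gene to start of
#' the downstream gene), clamped at 0 for overlapping or abutting genes.
#' Arguments may be given in either order; both genes must lie on the same
#' chromosome.
#'
#' @param a,b one-row gene records (or lists with `chrom`, `start`, `end`).
#' @return gap in bp.
#' @export
intergenic_distance <- function(a, b) {
  if (a$chrom != b$chrom) {
    stop("intergenic_distance: genes on different chromosomes (",
         a$chrom, " vs ", b$chrom, ")")
  }
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  max(0, b$start - a$end)
}

#' Relative orientation of a neighboring gene pair
#'
#' With `a` upstream of `b`: same strand is head-to-tail, (+,-) is
#' tail-to-tail (3' ends facing), (-,+) is head-to-head (5' ends facing).
#'
#' @param a,b one-row gene records, `a` upstream of `b`.
#' @return "head_to_tail", "tail_to_tail" or "head_to_head".
#' @export
pair_orientation <- function(a, b) {
  if (a$chrom != b$chrom) {
    stop("pair_orientation: genes on different chromosomes")
  }
  if (a$strand == b$strand) "head_to_tail"
  else if (a$strand == "+") "tail_to_tail"
  else "head_to_head"
}

# consecutive same-chromosome gaps of a sorted gene table:
# returns list(gap = numeric gaps between row i and i+1, same_chrom = logical)
consecutive_gaps <- function(genes) {
  n <- nrow(genes)
  if (n < 2) return(list(gap = numeric(0), same_chrom = logical(0)))
  i <- seq_len(n - 1)
  same <- genes$chrom[i] == genes$chrom[i + 1]
  gap <- pmax(0, genes$start[i + 1] - genes$end[i])
  gap[!same] <- NA_real_
  list(gap = gap, same_chrom = same)
}

#' Partition a gene list into loci at a cutoff distance
#'
#' A single left-to-right pass per chromosome: a new locus starts whenever
#' the intergenic distance to the previous gene exceeds the threshold
#' `t` (a pair at gap exactly `t` is co-clustered). Loci with >= 3 members
#' are clusters, pairs are miniclusters, single genes are solitary.
#'
#' @param genes a sorted gene list ([build_gene_list()]).
#' @param t cutoff distance in bp (> 0).
#' @return An object of class `architecture`: list with `threshold_bp`,
#'   `loci` (data.frame: locus_id, chrom, span_start, span_end, n_members,
#'   kind, mean_intergenic_bp, cluster_number), `members` (gene records
#'   with a `locus_id` column), counts `n_clusters` (loci with >= 2
#'   members, miniclusters included), `n_solitary`, and the source
#'   descriptor.
#' @export
cluster_by_threshold <- function(genes, t) {
  stopifnot(t > 0)
  src <- list(species = attr(genes, "species"),
              list_type = attr(genes, "list_type"),
              include_pseudo = attr(genes, "include_pseudo"))
  genes <- as.data.frame(genes)
  n <- nrow(genes)
  if (n == 0) {
    return(new_architecture(t, empty_loci(), cbind(empty_gene_records(),
           data.frame(locus_id = integer())), src))
  }
  genes <- genes[order_genomic(genes), , drop = FALSE]
  cg <- consecutive_gaps(genes)
  newlocus <- c(TRUE, !cg$same_chrom | cg$gap > t)
  locus_id <- cumsum(newlocus)
  genes$locus_id <- locus_id

  loci <- do.call(rbind, lapply(split(seq_len(n), locus_id), function(idx) {
    g <- genes[idx, , drop = FALSE]
    m <- length(idx)
    gaps <- if (m >= 2) pmax(0, g$start[-1] - g$end[-m]) else numeric(0)
    data.frame(
      locus_id = g$locus_id[1],
      chrom = g$chrom[1],
      span_start = min(g$start),
      span_end = max(g$end),
      n_members = m,
      kind = if (m == 1) "solitary" else if (m == 2) "minicluster" else "cluster",
      mean_intergenic_bp = if (m >= 2) mean(gaps) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(loci) <- NULL
  # cluster numbering by chromosomal location, counted over non-solitary loci
  is_cl <- loci$kind != "solitary"
  loci$cluster_number <- NA_integer_
  loci$cluster_number[is_cl] <- seq_len(sum(is_cl))
  new_architecture(t, loci, genes, src)
}

new_architecture <- function(t, loci, members, source = NULL,
                             method = "threshold") {
  structure(list(threshold_bp = t, loci = loci, members = members,
                 n_clusters = sum(loci$n_members >= 2),
                 n_solitary = sum(loci$n_members == 1),
                 source = source, method = method),
            class = "architecture")
}

empty_loci <- function() {
  data.frame(locus_id = integer(), chrom = character(),
             span_start = numeric(), span_end = numeric(),
             n_members = integer(), kind = character(),
             mean_intergenic_bp = numeric(), cluster_number = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.architecture <- function(x, ...) {
  thr <- if (is.na(x$threshold_bp)) x$method else
    sprintf("t = %g Mb", x$threshold_bp / 1e6)
  cat(sprintf("architecture (%s): %d loci (%d clusters incl. %d miniclusters, %d solitary)\n",
              thr, nrow(x$loci), x$n_clusters,
              sum(x$loci$kind == "minicluster"), x$n_solitary))
  invisible(x)
}

#' Count intact (non-pseudogene) solitary genes of an architecture
#' @param arch an `architecture`.
#' @return integer count.
#' @export
n_intact_solitary <- function(arch) {
  m <- arch$members
  sol <- arch$loci$locus_id[arch$loci$n_members == 1]
  sum(m$locus_id %in% sol & !m$pseudogene)
}

#' Sweep the cutoff distance across a grid
#'
#' The grid runs from `step` to the length of the widest chromosome
#' (rounded up to the next multiple of `step`) in increments of `step`.
#' For each grid value the number of clusters (>= 2 members) and solitary
#' genes is recorded; the total locus count is non-increasing in the
#' threshold.
#'
#' @param genes a sorted gene list.
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param step grid increment in bp, default 0.1 Mb.
#' @return data.frame with `threshold_bp`, `n_clusters`, `n_solitary`,
#'   `n_loci`.
#' @export
sweep_thresholds <- function(genes, chrom_sizes, step = 1e5) {
  if (missing(chrom_sizes) || is.null(chrom_sizes)) {
    stop("sweep_thresholds needs chromosome sizes to bound the grid")
  }
  grid <- seq(step, ceiling(max(chrom_sizes) / step) * step, by = step)
  genes <- as.data.frame(genes)
  genes <- genes[order_genomic(genes), , drop = FALSE]
  cg <- consecutive_gaps(genes)
  res <- lapply(grid, function(t) {
    newlocus <- c(TRUE, !cg$same_chrom | cg$gap > t)
    sizes <- tabulate(cumsum(newlocus))
    c(n_clusters = sum(sizes >= 2), n_solitary = sum(sizes == 1))
  })
  res <- do.call(rbind, res)
  data.frame(threshold_bp = grid,
             n_clusters = res[, "n_clusters"],
             n_solitary = res[, "n_solitary"],
             n_loci = res[, "n_clusters"] + res[, "n_solitary"])
}

#' Tabular and BED descriptions of an architecture
#'
#' The report lists clusters richest-first (member count, then
#' chromosomal order) followed by solitary genes, with 1-based inclusive
#' coordinate strings, mean intergenic distances rounded half-up to the
#' nearest Kb, minicluster orientations and solitary-gene strands. The
#' BED table uses 0-based half-open intervals, name `locusN|symbol`,
#' score = member count and strand "." for multi-gene loci.
#'
#' @param arch an `architecture`.
#' @return list with `report` and `bed` data.frames.
#' @export
describe_architecture <- function(arch) {
  loci <- arch$loci
  members <- arch$members
  if (nrow(loci) == 0) {
    return(list(report = data.frame(), bed = data.frame()))
  }
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    g <- members[members$locus_id == l$locus_id, , drop = FALSE]
    orientation <- if (l$kind == "minicluster")
      pair_orientation(g[1, ], g[2, ]) else NA_character_
    data.frame(
      label = if (l$kind == "solitary") g$symbol[1]
              else paste0("cluster", l$cluster_number),
      kind = l$kind,
      coords = coord_string(l$chrom, l$span_start, l$span_end),
      n_members = l$n_members,
      mean_intergenic_kb = if (is.na(l$mean_intergenic_bp)) NA_real_
                           else floor(l$mean_intergenic_bp / 1000 + 0.5),
      orientation = orientation,
      strand = if (l$kind == "solitary") g$strand[1] else ".",
      genes = paste(g$symbol, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  is_cl <- report$kind != "solitary"
  report <- rbind(
    report[is_cl, ][order(-report$n_members[is_cl]), , drop = FALSE],
    report[!is_cl, , drop = FALSE]
  )
  rownames(report) <- NULL

  bed_name <- vapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    if (l$kind == "solitary") {
      g <- members[members$locus_id == l$locus_id, ]
      paste0("locus", l$locus_id, "|", g$symbol[1])
    } else paste0("locus", l$locus_id, "|cluster", l$cluster_number)
  }, "")
  bed_strand <- vapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    if (l$kind == "solitary")
      members$strand[members$locus_id == l$locus_id][1] else "."
  }, "")
  bed <- data.frame(chrom = loci$chrom, start = loci$span_start,
                    end = loci$span_end, name = bed_name,
                    score = loci$n_members, strand = bed_strand,
                    stringsAsFactors = FALSE)
  list(report = report, bed = bed)
}

#' Write an architecture's loci as a 6-column BED track
#'
#' @param arch an `architecture`.
#' @param path output `.bed` file.
#' @return `path`, invisibly.
#' @export
write_architecture_bed <- function(arch, path) {
  bed <- describe_architecture(arch)$bed
  write_bed6(bed, path)
}

# rtracklayer-backed 6-column BED writer; `bed` has 0-based half-open
# chrom/start/end plus name, score, strand ("." rendered as "*")
write_bed6 <- function(bed, path) {
  if (nrow(bed) == 0) {
    file.create(path)
    return(invisible(path))
  }
  strand <- bed$strand
  strand[!(strand %in% c("+", "-"))] <- "*"
  gr <- GenomicRanges::GRanges(
    bed$chrom,
    IRanges::IRanges(start = bed$start + 1, end = bed$end),
    strand = strand
  )
  gr$name <- bed$name
  gr$score <- bed$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
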