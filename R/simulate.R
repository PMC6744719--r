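#' Synthetic-fixture configuration
#'
#' Defines a desk-scale genome whose planted cluster architecture is
#' recoverable by construction: the minimum inter-locus gap exceeds the
#' maximum intra-cluster gap, so any threshold in between recovers the
#' truth exactly. Defaults emulate the study conditions: intra-cluster
#' gaps of 4-175 Kb (the observed range of mean within-cluster
#' distances), AT-rich background (A+T = 0.6, elements and OR promoters
#' being AT-rich sequences), ~10 Mb of total sequence.
#'
#' @param seed RNG seed (mandatory; one stream per fixture).
#' @param n_chrom number of chromosomes, default 3.
#' @param chrom_len chromosome length in bp, default 3.5e6.
#' @param loci_per_chrom planted loci per chromosome, default 2.
#' @param locus_sizes candidate gene counts per locus (sampled
#'   uniformly), default 1:5 so solitary genes, miniclusters and clusters
#'   all occur.
#' @param gene_len range of gene lengths, default c(1000, 2000).
#' @param intra_gap range of within-locus intergenic gaps in bp, default
#'   c(4e3, 1.75e5).
#' @param inter_gap_min minimum between-locus gap in bp, default 1.2e6
#'   (must exceed `max(intra_gap)`).
#' @param families named probabilities of family membership, default
#'   c(OR = 0.8, TAAR = 0.2).
#' @param pseudogene_rate fraction of genes flagged as pseudogenes,
#'   default 0.15.
#' @param at_richness background A+T fraction, default 0.6.
#' @param conserved_per_locus conserved features planted near each locus,
#'   default 2.
#' @param conserved_len range of conserved feature lengths, default
#'   c(250, 450).
#' @param decoys_per_chrom conservation features planted > `decoy_dist`
#'   from every locus (the pipeline must ignore them), default 1.
#' @param decoy_dist minimum distance of decoys from any locus span,
#'   default 1.05e6 (just beyond the 1 Mb expansion).
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(seed, n_chrom = 3, chrom_len = 3.5e6,
                           loci_per_chrom = 2, locus_sizes = 1:5,
                           gene_len = c(1000, 2000),
                           intra_gap = c(4e3, 1.75e5),
                           inter_gap_min = 1.2e6,
                           families = c(OR = 0.8, TAAR = 0.2),
                           pseudogene_rate = 0.15, at_richness = 0.6,
                           conserved_per_locus = 2,
                           conserved_len = c(250, 450),
                           decoys_per_chrom = 1, decoy_dist = 1.05e6) {
  if (missing(seed)) stop("fixture_config: seed is mandatory")
  if (inter_gap_min <= max(intra_gap)) {
    stop("inter_gap_min must exceed max(intra_gap) so the planted ",
         "architecture is recoverable at intermediate thresholds")
  }
  stopifnot(at_richness > 0, at_richness < 1)
  structure(as.list(environment()), class = "fixture_config")
}

#' Simulate a BioMart-style annotation table with ground truth
#'
#' Lays the planted loci left to right on each chromosome: genes within a
#' locus are separated by gaps drawn from `intra_gap`, loci by gaps of at
#' least `inter_gap_min`. An alternative-scaffold decoy gene is appended
#' to exercise scaffold pruning. Reproducible for a fixed seed.
#'
#' @param config a [fixture_config()].
#' @return list with `gene_table` (BioMart convention: 1-based inclusive,
#'   strand 1/-1), `chrom_sizes`, `truth` (data.frame gene_id ->
#'   locus, n_members) and `truth_loci` (per-locus chrom, span, size).
#' @export
simulate_annotation <- function(config) {
  withr::with_seed(config$seed, {
    rows <- list(); truth <- list()
    gene_i <- 0L; locus_i <- 0L
    fam_names <- names(config$families)
    fam_prob <- config$families / sum(config$families)
    for (ci in seq_len(config$n_chrom)) {
      chrom <- paste0("chr", ci)
      pos <- runif(1, 2e4, 5e4)
      for (li in seq_len(config$loci_per_chrom)) {
        locus_i <- locus_i + 1L
        size <- sample(config$locus_sizes, 1)
        for (gi in seq_len(size)) {
          gene_i <- gene_i + 1L
          len <- round(runif(1, config$gene_len[1], config$gene_len[2]))
          fam <- sample(fam_names, 1, prob = fam_prob)
          pseudo <- runif(1) < config$pseudogene_rate
          symbol <- paste0(if (fam == "OR") "Olfr" else "Taar", gene_i,
                           if (pseudo) "-ps1" else "")
          rows[[gene_i]] <- data.frame(
            gene_id = sprintf("SIMG%05d", gene_i), symbol = symbol,
            chrom = chrom, start = round(pos) + 1, end = round(pos) + len,
            strand = sample(c(1, -1), 1),
            biotype = if (pseudo) "processed_pseudogene" else "protein_coding",
            stringsAsFactors = FALSE)
          truth[[gene_i]] <- data.frame(
            gene_id = sprintf("SIMG%05d", gene_i), chrom = chrom,
            locus = locus_i, n_members = size, stringsAsFactors = FALSE)
          pos <- pos + len
          if (gi < size) {
            pos <- pos + runif(1, config$intra_gap[1], config$intra_gap[2])
          }
        }
        if (pos > config$chrom_len) {
          stop("simulate_annotation: infeasible packing; genes exceed ",
               "chromosome length (need ", round(pos), " bp, have ",
               config$chrom_len, ")")
        }
        pos <- pos + config$inter_gap_min + runif(1, 0, 2e5)
      }
    }
    gene_table <- do.call(rbind, rows)
    # alternative-scaffold decoy entry (pruned by build_gene_list)
    gene_table <- rbind(gene_table, data.frame(
      gene_id = "SIMGALT1", symbol = "Olfr9999", chrom = "CHR_SIM_PATCH",
      start = 1001, end = 2000, strand = 1, biotype = "protein_coding",
      stringsAsFactors = FALSE))
    truth <- do.call(rbind, truth)
    truth_loci <- do.call(rbind, lapply(split(truth, truth$locus),
                                        function(tr) {
      g <- gene_table[match(tr$gene_id, gene_table$gene_id), ]
      data.frame(locus = tr$locus[1], chrom = tr$chrom[1],
                 span_start = min(g$start) - 1, span_end = max(g$end),
                 n_members = nrow(tr), stringsAsFactors = FALSE)
    }))
    rownames(truth_loci) <- NULL
    sizes <- setNames(rep(config$chrom_len, config$n_chrom),
                      paste0("chr", seq_len(config$n_chrom)))
    list(gene_table = gene_table, chrom_sizes = sizes, truth = truth,
         truth_loci = truth_loci, config = config)
  })
}

random_dna <- function(n, at_richness) {
  p <- c(A = at_richness / 2, C = (1 - at_richness) / 2,
         G = (1 - at_richness) / 2, T = at_richness / 2)
  paste(sample(DNA_LETTERS, n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate genome sequence and a conservation track for a fixture
#'
#' Background sequence is drawn i.i.d. with the configured AT richness.
#' Conserved features are planted inside each truth locus's neighborhood
#' (within the locus span, where the 1 Mb expansion is guaranteed to
#' find them) plus decoy features placed at least `decoy_dist` from
#' every locus, which the conservation harvest must ignore.
#'
#' @param config a [fixture_config()].
#' @param sim output of [simulate_annotation()] for the same config.
#' @return list with `genome` ([Biostrings::DNAStringSet]),
#'   `conservation` (BED-style data.frame with `name`), `decoy_names`.
#' @export
simulate_genome_and_conservation <- function(config, sim) {
  withr::with_seed(config$seed + 1L, {
    genome <- Biostrings::DNAStringSet(vapply(
      seq_len(config$n_chrom), function(i)
        random_dna(config$chrom_len, config$at_richness), ""))
    names(genome) <- paste0("chr", seq_len(config$n_chrom))
    feats <- list(); decoys <- character()
    fi <- 0L
    for (li in seq_len(nrow(sim$truth_loci))) {
      l <- sim$truth_loci[li, ]
      for (k in seq_len(config$conserved_per_locus)) {
        fi <- fi + 1L
        len <- round(runif(1, config$conserved_len[1], config$conserved_len[2]))
        lo <- max(0, l$span_start - 2e4)
        hi <- min(config$chrom_len - len, l$span_end + 2e4)
        s <- round(runif(1, lo, hi))
        feats[[fi]] <- data.frame(chrom = l$chrom, start = s, end = s + len,
                                  name = sprintf("cons_locus%d_%d", l$locus, k),
                                  stringsAsFactors = FALSE)
      }
    }
    # decoys: far from every locus span on the same chromosome
    for (ci in seq_len(config$n_chrom)) {
      chrom <- paste0("chr", ci)
      spans <- sim$truth_loci[sim$truth_loci$chrom == chrom, ]
      placed <- 0L; tries <- 0L
      while (placed < config$decoys_per_chrom && tries < 200L) {
        tries <- tries + 1L
        len <- round(runif(1, config$conserved_len[1], config$conserved_len[2]))
        s <- round(runif(1, 0, config$chrom_len - len))
        dist <- min(abs(c(s - spans$span_end, spans$span_start - (s + len))))
        far <- all(s + len <= spans$span_start - config$decoy_dist |
                     s >= spans$span_end + config$decoy_dist)
        if (far) {
          placed <- placed + 1L; fi <- fi + 1L
          nm <- sprintf("decoy_%s_%d", chrom, placed)
          feats[[fi]] <- data.frame(chrom = chrom, start = s, end = s + len,
                                    name = nm, stringsAsFactors = FALSE)
          decoys <- c(decoys, nm)
        }
      }
    }
    conservation <- do.call(rbind, feats)
    conservation <- conservation[order_genomic(conservation), , drop = FALSE]
    rownames(conservation) <- NULL
    list(genome = genome, conservation = conservation, decoy_names = decoys)
  })
}

#' Plant motif instances into segments, recording the truth
#'
#' Writes an instance of each planned matrix into the segment sequence at
#' a recorded offset and strand, either the consensus or a sample from
#' the column probabilities. Instances longer than the segment are
#' skipped with a warning.
#'
#' @param segments named [Biostrings::DNAStringSet].
#' @param matrices list of `pswm`.
#' @param plan data.frame with `segment_id`, `matrix_id` and optionally
#'   `offset` (0-based; random if absent/NA), `strand` (random if
#'   absent), `mode` ("consensus" or "sample", default consensus).
#' @param seed RNG seed for random offsets/strands/samples.
#' @return list with `segments` (modified) and `truth` (data.frame
#'   segment_id, matrix_id, start, stop, strand, seq).
#' @export
plant_motif_instances <- function(segments, matrices, plan, seed = 1) {
  mat_by_id <- setNames(matrices, vapply(matrices, function(m)
    as.character(m$id), ""))
  seqs <- as.character(segments)
  truth <- list()
  withr::with_seed(seed, {
    for (i in seq_len(nrow(plan))) {
      sid <- plan$segment_id[i]
      m <- mat_by_id[[as.character(plan$matrix_id[i])]]
      w <- pswm_width(m)
      L <- nchar(seqs[[sid]])
      if (w > L) {
        warning("planted instance wider than segment ", sid, "; skipped")
        next
      }
      offset <- if (!is.null(plan$offset) && !is.na(plan$offset[i])) {
        plan$offset[i]
      } else sample.int(L - w + 1L, 1) - 1L
      strand <- if (!is.null(plan$strand) && !is.na(plan$strand[i])) {
        plan$strand[i]
      } else sample(c("+", "-"), 1)
      mode <- if (!is.null(plan$mode) && !is.na(plan$mode[i])) {
        plan$mode[i]
      } else "consensus"
      inst <- if (mode == "sample") {
        paste(vapply(seq_len(w), function(j)
          sample(DNA_LETTERS, 1, prob = m$probs[j, ]), ""), collapse = "")
      } else pswm_consensus(m)
      placed <- if (strand == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(inst)))
      } else inst
      substr(seqs[[sid]], offset + 1L, offset + w) <- placed
      truth[[length(truth) + 1L]] <- data.frame(
        segment_id = sid, matrix_id = m$id, start = offset,
        stop = offset + w, strand = strand, seq = inst,
        stringsAsFactors = FALSE)
    }
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(segments)
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    segment_id = character(), matrix_id = character(), start = integer(),
    stop = integer(), strand = character(), seq = character(),
    stringsAsFactors = FALSE)
  list(segments = out, truth = truth)
}

#' Write all fixture files to a directory
#'
#' Emits the mutually consistent file set a real run would consume: gene
#' TSV, chrom.sizes, genome FASTA, conservation BED, plus a flat
#' JSON sidecar with the ground truth (per-gene locus assignment, locus
#' spans, decoy feature names).
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if needed).
#' @return invisible list of written paths.
#' @export
write_fixture <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_annotation(config)
  gc <- simulate_genome_and_conservation(config, sim)
  paths <- list(
    genes = file.path(dir, "genes.tsv"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    genome = file.path(dir, "genome.fa"),
    conservation = file.path(dir, "conservation.bed"),
    truth = file.path(dir, "truth.json"))
  write.table(sim$gene_table, paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(names(sim$chrom_sizes), unname(sim$chrom_sizes)),
              paths$chrom_sizes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  Biostrings::writeXStringSet(gc$genome, paths$genome)
  write_bed6(data.frame(chrom = gc$conservation$chrom,
                        start = gc$conservation$start,
                        end = gc$conservation$end,
                        name = gc$conservation$name, score = 0,
                        strand = "."), paths$conservation)
  jsonlite::write_json(
    list(seed = config$seed,
         gene_locus = sim$truth[, c("gene_id", "chrom", "locus")],
         truth_loci = sim$truth_loci,
         decoys = gc$decoy_names),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
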