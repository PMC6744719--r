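# shared constructors and independent oracles

# quick gene-record table in internal 0-based half-open coordinates
make_genes <- function(chrom, start, end, strand = "+",
                       symbol = sprintf("Olfr%d", seq_along(start)),
                       pseudogene = FALSE) {
  n <- length(start)
  data.frame(gene_id = sprintf("G%03d", seq_len(n)),
             symbol = symbol, chrom = rep_len(chrom, n),
             start = start, end = end,
             strand = rep_len(strand, n),
             pseudogene = rep_len(pseudogene, n),
             on_alt_scaffold = rep_len(FALSE, n),
             biotype = rep_len("protein_coding", n),
             family = rep_len("OR", n), stringsAsFactors = FALSE)
}

# planted fixture shared by candidate and acceptance tests: two planted
# segments (core + non-core) over an AT-rich background
planted_fixture <- function(seed = 71, n_background = 4) {
  withr::with_seed(seed, {
    core <- sharp_pswm("TCATTAAAAAGTTCA", id = 1, core = TRUE)
    oe <- sharp_pswm("TCCCTAGGGAGT", id = 9, core = FALSE)
    segs <- random_segments(2 + n_background, 350)
    pl <- orenhance::plant_motif_instances(
      segs, list(core, oe),
      data.frame(segment_id = names(segs)[1:2], matrix_id = c(1, 9)),
      seed = seed + 1)
    list(segments = pl$segments, core = core, oe = oe, truth = pl$truth)
  })
}

# random gene set on a handful of chromosomes
random_genes <- function(n, n_chrom = 3, max_pos = 5e6) {
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
  start <- round(runif(n, 0, max_pos))
  len <- round(runif(n, 500, 3000))
  g <- make_genes(chrom, start, start + len,
                  strand = sample(c("+", "-"), n, replace = TRUE))
  g[order(orenhance::chrom_rank(g$chrom), g$start), ]
}

# oracle: connected components of the "gap <= t" adjacency graph
bf_cluster_sizes <- function(genes, t) {
  genes <- genes[order(orenhance::chrom_rank(genes$chrom), genes$start), ]
  unlist(lapply(split(genes, genes$chrom), function(g) {
    n <- nrow(g)
    if (n == 0) return(integer(0))
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j) {
        gap <- max(0, max(g$start[i], g$start[j]) -
                     min(g$end[i], g$end[j]))
        # neighbors in sorted order only, as the pass is linear
        if (abs(i - j) == 1) adj[i, j] <- gap <= t
      }
    }
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    as.integer(table(comp))
  }), use.names = FALSE)
}

# oracle: minimum WCSS over all contiguous k-partitions by enumeration
bf_min_wcss <- function(x, k) {
  x <- sort(x); n <- length(x)
  wss <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(wss(x))
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (c in seq_len(ncol(splits))) {
    bounds <- c(0, splits[, c], n)
    tot <- 0
    for (q in seq_len(k)) tot <- tot + wss(x[(bounds[q] + 1):bounds[q + 1]])
    best <- min(best, tot)
  }
  best
}

# oracle: exact p-values by enumeration of all 4^w words
bf_pvalues <- function(pswm, background) {
  lod <- log_odds(pswm, background)
  w <- nrow(lod)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(words)); probs <- numeric(nrow(words))
  for (r in seq_len(nrow(words))) {
    idx <- words[r, ]
    scores[r] <- sum(lod[cbind(seq_len(w), idx)])
    probs[r] <- prod(background[idx])
  }
  list(scores = scores, probs = probs,
       p_of = function(s) sum(probs[scores >= s - 1e-12]))
}

# sharp synthetic matrix around a consensus string
sharp_pswm <- function(consensus, id = 1, core = FALSE, major = 0.97) {
  letters4 <- c("A", "C", "G", "T")
  chars <- strsplit(consensus, "")[[1]]
  probs <- t(vapply(chars, function(ch) {
    p <- rep((1 - major) / 3, 4); p[match(ch, letters4)] <- major; p
  }, numeric(4)))
  rownames(probs) <- NULL
  orenhance:::new_pswm(probs, id = id, nsites = 20, core = core)
}

# AT-rich random segments as a DNAStringSet
random_segments <- function(n, len, at = 0.6, chrom = "chr1",
                            start0 = seq(0, by = len + 10, length.out = n)) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = ""), "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("%s:%d-%d", chrom, start0 + 1, start0 + len)
  out
}

# write (possibly modified) segment sequences back into a genome, using
# their coordinate-string names
patch_genome <- function(genome, segments) {
  seqs <- as.character(genome)
  coords <- orenhance::parse_segment_headers(names(segments))
  for (i in seq_along(segments)) {
    substr(seqs[[coords$chrom[i]]], coords$start[i] + 1, coords$end[i]) <-
      as.character(segments[[i]])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(genome)
  out
}

# direct evaluation of the BH step-up transform (independent of p.adjust)
bf_bh <- function(p, m = length(p)) {
  o <- order(p)
  q_sorted <- numeric(length(p))
  ps <- p[o]
  running <- 1
  for (i in rev(seq_along(ps))) {
    running <- min(running, m * ps[i] / i)
    q_sorted[i] <- running
  }
  q <- numeric(length(p)); q[o] <- q_sorted
  pmin(q, 1)
}
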