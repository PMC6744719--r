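#' Collapse genes of one chromosome to central coordinates
#'
#' Each gene's start and end are collapsed to a single midpoint,
#' `floor((start + end) / 2)` in the internal 0-based convention, and the
#' midpoints returned sorted ascending.
#'
#' @param genes gene records.
#' @param chrom chromosome name.
#' @return sorted numeric vector of midpoints (bp).
#' @export
collapse_midpoints <- function(genes, chrom) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) stop("no genes on chromosome ", chrom)
  sort(floor((g$start + g$end) / 2))
}

#' Optimal univariate k-means by dynamic programming
#'
#' Finds the contiguous partition of the sorted points into `k` runs that
#' globally minimizes the within-cluster sum of squares. Unlike Lloyd-type
#' iteration this is exact and deterministic: in one dimension the optimal
#' clusters are contiguous in sorted order, so a dynamic program over
#' split positions reaches the global optimum.
#'
#' @param x numeric points (sorted internally).
#' @param k number of clusters, `1 <= k <= length(x)`.
#' @return list with `points` (sorted), `k`, `cluster` (assignment per
#'   sorted point, 1..k), `boundaries` (start index of each run),
#'   `centers`, `size`, `wcss`.
#' @export
optimal_partition <- function(x, k) {
  n <- length(x)
  if (n == 0) stop("optimal_partition: no points")
  if (k < 1 || k > n) stop("optimal_partition: k must be in 1..n (k=", k,
                           ", n=", n, ")")
  x <- sort(as.numeric(x))
  s1 <- cumsum(x); s2 <- cumsum(x^2)
  ssq <- function(i, j) {           # within-SS of x[i..j]
    s <- s1[j] - if (i > 1) s1[i - 1] else 0
    q <- s2[j] - if (i > 1) s2[i - 1] else 0
    max(0, q - s^2 / (j - i + 1))
  }
  # D[q, j]: min WCSS of x[1..j] in q clusters; B[q, j]: first index of last run
  D <- matrix(Inf, k, n); B <- matrix(1L, k, n)
  for (j in 1:n) { D[1, j] <- ssq(1, j); B[1, j] <- 1L }
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        best <- Inf; arg <- q
        for (m in q:j) {
          v <- D[q - 1, m - 1] + ssq(m, j)
          if (v < best) { best <- v; arg <- m }
        }
        D[q, j] <- best; B[q, j] <- as.integer(arg)
      }
    }
  }
  bounds <- integer(k); j <- n
  for (q in k:1) { bounds[q] <- B[q, j]; j <- bounds[q] - 1L }
  cluster <- rep(seq_len(k), times = diff(c(bounds, n + 1L)))
  list(points = x, k = k, cluster = cluster, boundaries = bounds,
       centers = as.numeric(tapply(x, cluster, mean)),
       size = as.integer(table(cluster)),
       wcss = D[k, n])
}

#' Select the number of 1-D clusters by BIC
#'
#' For each candidate `k` the optimal contiguous partition is fitted and
#' scored as a Gaussian mixture with cluster-specific means and variances
#' (mixing weights `n_c / n`); `BIC = 2 loglik - (3k - 1) log(n)`.
#' Variances are floored at `var_floor_frac` of the squared data range so
#' singleton or degenerate clusters stay finite. The chosen `k_star`
#' maximizes BIC; ties go to the smallest `k`.
#'
#' @param x numeric points.
#' @param k_max largest candidate `k`, default `min(n, 50)`.
#' @param var_floor_frac variance floor as a fraction of `range(x)^2`,
#'   default `1e-6`.
#' @return list with the chosen partition fields (as
#'   [optimal_partition()]) plus `bic_curve` (length `k_max`), `k_star`
#'   and `n`.
#' @export
select_k_by_bic <- function(x, k_max = min(length(x), 50),
                            var_floor_frac = 1e-6) {
  n <- length(x)
  if (n == 0) stop("select_k_by_bic: no points")
  if (k_max > n) stop("select_k_by_bic: k_max > n")
  x <- sort(as.numeric(x))
  rng <- diff(range(x))
  floor_var <- max(var_floor_frac * max(rng, 1)^2, .Machine$double.eps)
  fits <- vector("list", k_max)
  bic <- numeric(k_max)
  for (k in seq_len(k_max)) {
    fit <- optimal_partition(x, k)
    ll <- 0
    for (c in seq_len(k)) {
      xi <- x[fit$cluster == c]
      mu <- mean(xi)
      v <- max(mean((xi - mu)^2), floor_var)
      ll <- ll + sum(log(length(xi) / n) + dnorm(xi, mu, sqrt(v), log = TRUE))
    }
    bic[k] <- 2 * ll - (3 * k - 1) * log(n)
    fits[[k]] <- fit
  }
  k_star <- which.max(bic)            # which.max returns smallest index on ties
  out <- fits[[k_star]]
  out$bic_curve <- bic
  out$k_star <- k_star
  out$n <- n
  out
}

#' k-means-based genomic architecture
#'
#' Runs per-chromosome midpoint collapsing, BIC-selected optimal 1-D
#' k-means, and merges the single-chromosome partitions into an
#' architecture whose locus spans come from the member gene extents.
#'
#' @param genes a sorted gene list.
#' @param k_max per-chromosome cap on candidate `k`, default 50.
#' @return An `architecture` (method `"kmeans1d"`, `threshold_bp = NA`)
#'   plus a `bic` element: per-chromosome data.frame of `k`, `bic`,
#'   `bic_over_n` (the BIC/n curve), `k_star`.
#' @export
kmeans_architecture <- function(genes, k_max = 50) {
  src <- list(species = attr(genes, "species"),
              list_type = attr(genes, "list_type"),
              include_pseudo = attr(genes, "include_pseudo"))
  genes <- as.data.frame(genes)
  genes <- genes[order_genomic(genes), , drop = FALSE]
  chroms <- unique(genes$chrom)
  members <- NULL; loci <- NULL; bic_tabs <- list()
  next_id <- 0L
  for (ch in chroms) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    mids <- floor((g$start + g$end) / 2)
    ord <- order(mids)
    g <- g[ord, , drop = FALSE]
    fit <- select_k_by_bic(sort(mids), k_max = min(k_max, nrow(g)))
    g$locus_id <- next_id + fit$cluster
    next_id <- next_id + fit$k_star
    members <- rbind(members, g)
    bic_tabs[[ch]] <- data.frame(
      chrom = ch, k = seq_along(fit$bic_curve), bic = fit$bic_curve,
      bic_over_n = fit$bic_curve / fit$n, k_star = fit$k_star,
      stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, lapply(split(seq_len(nrow(members)),
                                      members$locus_id), function(idx) {
    g <- members[idx, , drop = FALSE]
    m <- length(idx)
    gaps <- if (m >= 2) pmax(0, g$start[-1] - g$end[-m]) else numeric(0)
    data.frame(locus_id = g$locus_id[1], chrom = g$chrom[1],
               span_start = min(g$start), span_end = max(g$end),
               n_members = m,
               kind = if (m == 1) "solitary" else if (m == 2) "minicluster"
                      else "cluster",
               mean_intergenic_bp = if (m >= 2) mean(gaps) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(loci) <- NULL
  is_cl <- loci$kind != "solitary"
  loci$cluster_number <- NA_integer_
  loci$cluster_number[is_cl] <- seq_len(sum(is_cl))
  arch <- new_architecture(NA_real_, loci, members, src, method = "kmeans1d")
  arch$bic <- do.call(rbind, bic_tabs)
  rownames(arch$bic) <- NULL
  arch
}

#' Write the per-chromosome BIC curves as TSV
#' @param arch output of [kmeans_architecture()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bic_curves <- function(arch, path) {
  stopifnot(!is.null(arch$bic))
  write.table(arch$bic, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
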