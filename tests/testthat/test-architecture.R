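test_that("intergenic distance is the clamped inner gap", {
  g <- make_genes("chr1", c(100, 500), c(200, 600))
  expect_equal(intergenic_distance(g[1, ], g[2, ]), 300)
  expect_equal(intergenic_distance(g[2, ], g[1, ]), 300)   # order-free
  o <- make_genes("chr1", c(100, 300), c(400, 600))
  expect_equal(intergenic_distance(o[1, ], o[2, ]), 0)     # overlap
  a <- make_genes("chr1", c(100, 200), c(200, 300))
  expect_equal(intergenic_distance(a[1, ], a[2, ]), 0)     # abutting
  d <- make_genes(c("chr1", "chr2"), c(1, 1), c(10, 10))
  expect_error(intergenic_distance(d[1, ], d[2, ]), "chromosome")
})

test_that("pair orientation follows strand combination", {
  g <- function(s1, s2) make_genes("chr1", c(0, 1000), c(100, 1100),
                                   strand = c(s1, s2))
  expect_equal(pair_orientation(g("+", "+")[1, ], g("+", "+")[2, ]),
               "head_to_tail")
  expect_equal(pair_orientation(g("-", "-")[1, ], g("-", "-")[2, ]),
               "head_to_tail")
  expect_equal(pair_orientation(g("+", "-")[1, ], g("+", "-")[2, ]),
               "tail_to_tail")
  expect_equal(pair_orientation(g("-", "+")[1, ], g("-", "+")[2, ]),
               "head_to_head")
})

test_that("toy gene list partitions into cluster, minicluster, solitary", {
  # consecutive gaps 10, 10, 500, 10, 2000 kb; t = 100 kb
  len <- 1000
  gaps <- c(10, 10, 500, 10, 2000) * 1000
  starts <- cumsum(c(0, gaps + len))
  g <- make_genes("chr1", starts, starts + len)
  arch <- cluster_by_threshold(g, 1e5)
  expect_equal(sort(arch$loci$n_members), c(1, 2, 3))
  expect_equal(arch$loci$kind[order(arch$loci$n_members)],
               c("solitary", "minicluster", "cluster"))
  expect_equal(arch$n_clusters, 2)
  expect_equal(arch$n_solitary, 1)
})

test_that("a gap exactly t joins; t + 1 bp splits", {
  g <- make_genes("chr1", c(0, 1100), c(100, 1200))   # gap 1000
  expect_equal(nrow(cluster_by_threshold(g, 1000)$loci), 1)
  expect_equal(nrow(cluster_by_threshold(g, 999)$loci), 2)
})

test_that("huge threshold gives one locus per occupied chromosome", {
  withr::with_seed(8, g <- random_genes(30, n_chrom = 3))
  arch <- cluster_by_threshold(g, 1e10)
  expect_equal(nrow(arch$loci), length(unique(g$chrom)))
})

test_that("empty list gives an empty architecture", {
  arch <- cluster_by_threshold(make_genes(character(), numeric(),
                                          numeric()), 1e5)
  expect_equal(nrow(arch$loci), 0)
  expect_equal(arch$n_clusters + arch$n_solitary, 0)
})

test_that("threshold clustering equals the connected-components oracle", {
  withr::with_seed(101, {
    for (rep in 1:30) {
      g <- random_genes(sample(2:50, 1))
      t <- 10^runif(1, 3, 6.5)
      arch <- cluster_by_threshold(g, t)
      expect_equal(sort(arch$loci$n_members), sort(bf_cluster_sizes(g, t)))
      # partition property: every gene in exactly one locus
      expect_equal(sort(arch$members$gene_id), sort(g$gene_id))
      expect_equal(sum(arch$loci$n_members), nrow(g))
    }
  })
})

test_that("sweep grid covers the widest chromosome and is monotone", {
  g <- make_genes("chr1", c(0, 5e4, 2e5), c(1e3, 5.1e4, 2.01e5))
  sw <- sweep_thresholds(g, c(chr1 = 3e5), step = 1e5)
  expect_equal(sw$threshold_bp, c(1e5, 2e5, 3e5))
  withr::with_seed(21, g2 <- random_genes(40))
  sw2 <- sweep_thresholds(g2, c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6))
  expect_true(all(diff(sw2$n_loci) <= 0))
  # below the minimum gap every gene is solitary
  expect_equal(sw2$n_loci[1] <= nrow(g2), TRUE)
  # below the minimum positive gap every gene is solitary
  g3 <- make_genes("chr1", c(0, 1e4, 5e4), c(1e3, 1.1e4, 5.1e4))
  sw3 <- sweep_thresholds(g3, c(chr1 = 1e5), step = 1e3)
  expect_equal(sw3$n_solitary[1], 3)
  expect_error(sweep_thresholds(g2, NULL), "sizes")
})

test_that("architecture reports render coordinates, Kb means, orientations", {
  g <- make_genes("chr1", c(0, 15000), c(1000, 16000), strand = c("+", "-"))
  arch <- cluster_by_threshold(g, 1e5)
  rep1 <- describe_architecture(arch)$report
  expect_equal(rep1$kind, "minicluster")
  expect_equal(rep1$mean_intergenic_kb, 14)
  expect_equal(rep1$orientation, "tail_to_tail")
  expect_equal(rep1$coords, "chr1:1-16000")

  # solitary row carries the gene's strand; clusters sort richest-first
  g2 <- make_genes("chr1",
                   c(0, 10e3, 20e3, 100e6, 200e6, 200.01e6),
                   c(1e3, 11e3, 21e3, 100.001e6, 200.001e6, 200.011e6),
                   strand = c("+", "+", "+", "-", "+", "+"))
  arch2 <- cluster_by_threshold(g2, 1e5)
  rep2 <- describe_architecture(arch2)$report
  expect_equal(rep2$kind, c("cluster", "minicluster", "solitary"))
  expect_equal(rep2$strand[3], "-")
  expect_equal(rep2$mean_intergenic_kb[1], 9)   # constant 9 kb gaps
  bed <- describe_architecture(arch2)$bed
  expect_equal(bed$start[1], 0)                 # BED stays 0-based
  expect_equal(bed$score, arch2$loci$n_members)
})

test_that("intact solitary count excludes pseudogene-flagged solitaries", {
  g <- make_genes("chr1", c(0, 5e6, 10e6), c(1e3, 5.001e6, 10.001e6),
                  pseudogene = c(FALSE, TRUE, FALSE))
  arch <- cluster_by_threshold(g, 1e5)
  expect_equal(arch$n_solitary, 3)
  expect_equal(n_intact_solitary(arch), 2)
})

test_that("BED track round-trips through rtracklayer", {
  withr::with_seed(9, g <- random_genes(20))
  arch <- cluster_by_threshold(g, 5e5)
  path <- withr::local_tempfile(fileext = ".bed")
  write_architecture_bed(arch, path)
  back <- read_bed(path)
  expect_equal(nrow(back), nrow(arch$loci))
  expect_setequal(back$start, arch$loci$span_start)
  expect_setequal(back$end, arch$loci$span_end)
})
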