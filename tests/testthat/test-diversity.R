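toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tv1\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tv2\tG\tC\t.\tPASS\t.\tGT\t./.\t0/0\t0/1",
    "1\t300\tv3\tA\tC,T\t.\tPASS\t.\tGT\t0/1\t0/2\t1/1"), path)
  path
}

test_that("VCF genotypes load as dosages, skipping multiallelic records", {
  path <- toy_vcf(tempfile(fileext = ".vcf"))
  expect_message(G <- read_vcf(path), "1 multiallelic")
  expect_equal(dim(G$calls), c(3L, 2L))
  expect_equal(unname(G$calls["s1", ]), c(0L, NA))
  expect_equal(unname(G$calls["s2", ]), c(1L, 0L))
  expect_equal(unname(G$calls["s3", ]), c(2L, 1L))
  expect_error(read_vcf(tempfile()), "no such file")
})

test_that("variant filters apply the missingness and MAF rules exactly", {
  G <- planted_filter_genotypes()
  Gf <- filter_variants(G)
  rep <- attr(Gf, "filter_report")
  expect_equal(rep$n_removed_missing, 12)
  expect_equal(rep$n_removed_maf, 9)
  expect_equal(rep$n_retained, 79)
  expect_equal(ncol(Gf$calls), 79)
  # idempotent
  Gff <- filter_variants(Gf)
  expect_equal(Gff$calls, Gf$calls)
  # boundary: exactly 10% missing is kept, 11% is removed
  G2 <- genotype_matrix(cbind(c(rep(NA, 10), rep(0:1, 45)),
                              c(rep(NA, 11), rep(0:1, length.out = 89))))
  G2f <- filter_variants(G2)
  expect_equal(ncol(G2f$calls), 1)
  # monomorphic variant has MAF 0 and is removed
  G3 <- genotype_matrix(cbind(rep(0L, 100), rep(0:1, 50)))
  expect_equal(colnames(filter_variants(G3)$calls), "V2")
})

test_that("IBS distances behave as a normalized allele-sharing metric", {
  G <- genotype_matrix(rbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L),
                             c = c(2L, 1L, 0L)))
  D <- ibs_distance(G)
  expect_equal(D["a", "b"], 0)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_equal(D, t(D))
  G2 <- genotype_matrix(rbind(a = rep(0L, 4), b = rep(2L, 4)))
  expect_equal(ibs_distance(G2)["a", "b"], 1)
  G3 <- genotype_matrix(rbind(a = 0L, b = 1L))
  expect_equal(ibs_distance(G3)["a", "b"], 0.5)
  # invariant under sample reordering
  set.seed(71)
  X <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 6, 10)
  X[, 1] <- 1L                                 # no all-missing pair
  Ga <- genotype_matrix(X)
  perm <- sample(6)
  Gb <- genotype_matrix(X[perm, ])
  expect_equal(unname(ibs_distance(Gb)), unname(ibs_distance(Ga)[perm, perm]))
  expect_true(all(ibs_distance(Ga) >= 0 & ibs_distance(Ga) <= 1))
  # all-missing pair is an error
  Gbad <- genotype_matrix(rbind(a = c(0L, NA), b = c(NA, 1L)))
  expect_error(ibs_distance(Gbad), "no non-missing")
})

test_that("classical MDS reproduces Euclidean configurations", {
  set.seed(81)
  pts <- cbind(stats::rnorm(12), stats::rnorm(12))
  D <- as.matrix(stats::dist(pts))
  fit <- classical_mds(D, k = 2)
  X <- as.matrix(fit$coordinates[, c("C1", "C2")])
  expect_lt(procrustes_rms(X, pts), 1e-8)
  # pairwise coordinate distances reproduce D
  expect_equal(as.matrix(stats::dist(X)), D, ignore_attr = TRUE,
               tolerance = 1e-8)
  # eigenvalues non-increasing, coordinates centered
  eig <- fit$eigenvalues
  expect_true(all(diff(eig) <= 1e-8))
  expect_equal(colSums(X), c(C1 = 0, C2 = 0), tolerance = 1e-10)

  # three points at mutual distance 1: an equilateral triangle of side 1
  D3 <- matrix(1, 3, 3) - diag(3)
  X3 <- as.matrix(classical_mds(D3, k = 2)$coordinates[, c("C1", "C2")])
  expect_equal(as.vector(stats::dist(X3)), rep(1, 3), tolerance = 1e-10)

  # duplicated samples land on identical coordinates
  D4 <- as.matrix(stats::dist(pts[c(1, 1, 2, 3), ]))
  X4 <- as.matrix(classical_mds(D4, k = 2)$coordinates[, c("C1", "C2")])
  expect_equal(X4[1, ], X4[2, ], tolerance = 1e-10)

  expect_error(classical_mds(D3, k = 3), "smaller")
})

test_that("group assignment recovers simulated population structure", {
  sim <- simulate_genotypes(n_groups = 3, n_per_group = 10, n_snps = 300,
                            fst = 0.3, seed = 91)
  D <- ibs_distance(sim$genotypes)
  mds <- classical_mds(D, k = 2)
  grp <- assign_groups(mds, 3, seed = 1)
  expect_equal(mclust::adjustedRandIndex(grp$group, sim$labels$group), 1)
  expect_equal(unique(assign_groups(mds, 1)$group), 1L)
  n <- nrow(mds$coordinates)
  expect_equal(sort(assign_groups(mds, n)$group), seq_len(n))
  expect_error(assign_groups(mds, n + 1), "between")
  expect_s3_class(ggplot2::ggplot_build(autoplot(mds, groups = grp))$plot,
                  "ggplot")
})
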