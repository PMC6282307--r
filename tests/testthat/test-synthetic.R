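test_that("noise-free gene families are congruent with the species network", {
  sys <- toy_system()
  fams <- simulate_gene_families(sys$net, 3, 0, 0, seed = 1)
  mul <- network_to_multree(sys$net)
  for (fam in fams) {
    # every polyploid species carries exactly two homeolog copies
    counts <- table(fam$leaf_to_species)
    expect_true(all(counts[c("H1", "H2")] == 2))
    expect_true(all(counts[setdiff(names(counts), c("H1", "H2"))] == 1))
    expect_equal(mul_reconcile(fam, mul)$total_cost, 0)
    truth <- attr(fam, "truth")
    expect_equal(truth$n_duplications, 0L)
    expect_equal(truth$n_losses, 0L)
  }
  # a tree-shaped network yields species-tree-congruent single-copy families
  net0 <- parse_enewick(write_newick(sys$pruned))
  fam0 <- simulate_gene_families(net0, 1, 0, 0, seed = 2)[[1]]
  expect_equal(lca_reconcile(fam0, network_to_multree(net0))$total_cost, 0)
})

test_that("generators are deterministic given the seed", {
  sys <- toy_system()
  f1 <- simulate_gene_families(sys$net, 2, 0.3, 0.2, seed = 10)
  f2 <- simulate_gene_families(sys$net, 2, 0.3, 0.2, seed = 10)
  expect_identical(lapply(f1, function(f) write_newick(f$tree)),
                   lapply(f2, function(f) write_newick(f$tree)))
  f3 <- simulate_gene_families(sys$net, 2, 0.3, 0.2, seed = 11)
  expect_false(identical(lapply(f1, function(f) write_newick(f$tree)),
                         lapply(f3, function(f) write_newick(f$tree))))

  s1 <- simulate_genotypes(n_snps = 50, n_per_group = 4, seed = 3)
  s2 <- simulate_genotypes(n_snps = 50, n_per_group = 4, seed = 3)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)

  t1 <- simulate_trait(tree5(), mk_model(c("0", "1"), rate = 1), seed = 4)
  t2 <- simulate_trait(tree5(), mk_model(c("0", "1"), rate = 1), seed = 4)
  expect_identical(t1$data, t2$data)
})

test_that("copy growth under pure duplication matches the branching process", {
  # on a two-taxon tree with unit branches and no losses, copies per
  # species follow a Yule process: E[N] = exp(lambda * t)
  net <- parse_enewick("(A:1,B:1);")
  lambda <- 0.3
  set.seed(17)
  fams <- simulate_gene_families(net, 400, lambda, 0)
  nA <- vapply(fams, function(f) sum(f$leaf_to_species == "A"), numeric(1))
  expect_equal(length(nA), 400)
  se <- stats::sd(nA) / sqrt(length(nA))
  expect_lt(abs(mean(nA) - exp(lambda)), 3 * se + 1e-9)
})

test_that("simulated trait histories have the expected change intensity", {
  tr <- tree5()
  q <- 0.8
  m <- mk_model(c("0", "1"), rate = q)
  set.seed(19)
  changes <- vapply(seq_len(1000), function(i)
    simulate_trait(tr, m)$history$n_changes, numeric(1))
  expected <- q * sum(tr$edge.length)   # leaving rate q per unit length
  se <- stats::sd(changes) / sqrt(length(changes))
  expect_lt(abs(mean(changes) - expected), 3 * se)
  # zero rates: all tips inherit the root state, no changes
  sim0 <- simulate_trait(tr, mk_model(c("0", "1"), rate = 0), seed = 5)
  expect_equal(sim0$history$n_changes, 0L)
  expect_equal(length(unique(sim0$data$state)), 1L)
})

test_that("simulated VCFs reparse to the generated dosage matrix", {
  path <- tempfile(fileext = ".vcf")
  sim <- simulate_genotypes(n_groups = 2, n_per_group = 5, n_snps = 40,
                            fst = 0.2, missing_rate = 0.15,
                            vcf_path = path, seed = 23)
  G <- read_vcf(path)
  expect_equal(unname(G$calls), unname(sim$genotypes$calls))
  expect_equal(rownames(G$calls), rownames(sim$genotypes$calls))
})

test_that("missingness and panmixia behave as configured", {
  set.seed(29)
  sim <- simulate_genotypes(n_groups = 1, n_per_group = 100, n_snps = 60,
                            fst = 0, missing_rate = 0.5)
  miss <- mean(is.na(sim$genotypes$calls))
  expect_lt(abs(miss - 0.5), 0.05)
  # at 50% missingness essentially every variant fails the 10% filter
  suppressWarnings(Gf <- filter_variants(sim$genotypes))
  expect_lt(ncol(Gf$calls) / 60, 0.02)

  # panmictic genotypes show no dominant MDS axis
  fracs <- vapply(1:20, function(s) {
    sim <- simulate_genotypes(n_groups = 3, n_per_group = 20, n_snps = 500,
                              fst = 0, seed = 1000 + s)
    eig <- classical_mds(ibs_distance(sim$genotypes), k = 2)$eigenvalues
    pos <- eig[eig > 0]
    pos[1] / sum(pos)
  }, numeric(1))
  expect_true(all(fracs < 0.2))
})
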