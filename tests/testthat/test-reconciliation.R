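congruent_family <- function() {
  gene_family(parse_newick("((a,b),c);"), c(a = "A", b = "B", c = "C"))
}

test_that("congruent trees reconcile at zero cost", {
  r <- lca_reconcile(congruent_family(), parse_newick("((A,B),C);"))
  expect_equal(r$n_duplications, 0)
  expect_equal(r$n_losses, 0)
  expect_equal(r$total_cost, 0)
})

test_that("discordant and duplicated gene trees get the classical counts", {
  fam <- gene_family(parse_newick("((a,c),b);"), c(a = "A", b = "B", c = "C"))
  r <- lca_reconcile(fam, parse_newick("((A,B),C);"))
  expect_equal(r$n_duplications, 1)
  expect_equal(r$n_losses, 3)
  expect_equal(r$total_cost, 4)

  fam2 <- gene_family(parse_newick("((a1,a2),b);"),
                      c(a1 = "A", a2 = "A", b = "B"))
  r2 <- lca_reconcile(fam2, parse_newick("(A,B);"))
  expect_equal(r2$n_duplications, 1)
  expect_equal(r2$n_losses, 0)
  expect_equal(r2$total_cost, 1)

  # costs are configurable and enter linearly
  r3 <- lca_reconcile(fam, parse_newick("((A,B),C);"),
                      costs = recon_costs(dup = 2, loss = 0.5))
  expect_equal(r3$total_cost, 2 * 1 + 0.5 * 3)
})

test_that("losses are not charged for species unsampled in the family", {
  # host has an extra taxon D never seen in the gene tree
  r <- lca_reconcile(congruent_family(), parse_newick("(((A,B),C),D);"))
  expect_equal(r$total_cost, 0)
})

test_that("mul_reconcile finds the homeolog assignment minimizing cost", {
  mul <- build_mul_tree(parse_newick("((P,S),O);"), "H", "P", "S")
  fam <- gene_family(parse_newick("((h1,p),(h2,s));"),
                     c(h1 = "H", h2 = "H", p = "P", s = "S"))
  r <- mul_reconcile(fam, mul)
  expect_equal(r$total_cost, 0)
  expect_equal(r$assignment, c(h1 = "A", h2 = "B"))

  fam_sw <- gene_family(parse_newick("((h1,s),(h2,p));"),
                        c(h1 = "H", h2 = "H", p = "P", s = "S"))
  r_sw <- mul_reconcile(fam_sw, mul)
  expect_equal(r_sw$total_cost, 0)
  expect_equal(r_sw$assignment, c(h1 = "B", h2 = "A"))

  expect_error(mul_reconcile(
    gene_family(parse_newick("(x,p);"), c(x = "X", p = "P")), mul),
    "missing from host")
})

test_that("unambiguous families reduce to plain LCA reconciliation", {
  sys <- toy_system()
  mul0 <- network_to_multree(parse_enewick(write_newick(sys$pruned)))
  fam <- gene_family(parse_newick("((p,d1),(s,d2));"),
                     c(p = "P", d1 = "D1", s = "S", d2 = "D2"))
  a <- mul_reconcile(fam, mul0)
  b <- lca_reconcile(fam, mul0)
  expect_equal(a$total_cost, b$total_cost)
  expect_equal(a$node_map, b$node_map)
  expect_equal(brute_force_mul_score(fam, mul0)$total_cost, b$total_cost)
})

test_that("enumeration search equals the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:60) {
    inst <- random_mul_instance(n_backbone = sample(3:5, 1),
                                n_poly = sample(1:3, 1))
    fast <- mul_reconcile(inst$family, inst$mul)
    slow <- brute_force_mul_score(inst$family, inst$mul)
    expect_equal(fast$total_cost, slow$total_cost)
    expect_equal(fast$assignment, slow$assignment)
  }
})

test_that("cost is invariant under copy relabeling and A/B tag swap", {
  set.seed(41)
  for (i in 1:20) {
    inst <- random_mul_instance()
    base <- mul_reconcile(inst$family, inst$mul)$total_cost

    # relabel gene copies
    fam2 <- inst$family
    new_labs <- paste0("g", seq_along(fam2$tree$tip.label))
    names(fam2$leaf_to_species) <- new_labs
    fam2$tree$tip.label <- new_labs
    expect_equal(mul_reconcile(fam2, inst$mul)$total_cost, base)

    # swap the subgenome tags on the host
    mul2 <- inst$mul
    mul2$copy_tag <- c(A = "B", B = "A")[mul2$copy_tag]
    expect_equal(mul_reconcile(inst$family, mul2)$total_cost, base)
  }
})

test_that("zero cost occurs exactly when the family embeds congruently", {
  sys <- toy_system()
  mul <- network_to_multree(sys$net)
  good <- simulate_gene_families(sys$net, 1, 0, 0, seed = 5)[[1]]
  expect_equal(mul_reconcile(good, mul)$total_cost, 0)
  # perturb: swap two leaves across subgenomes to break congruence
  bad <- good
  i <- which(bad$leaf_to_species == "P")[1]
  j <- which(bad$leaf_to_species == "S")[1]
  bad$leaf_to_species[c(i, j)] <- bad$leaf_to_species[c(j, i)]
  expect_gt(mul_reconcile(bad, mul)$total_cost, 0)
})

test_that("hypothesis scores are additive and monotone in families", {
  mul <- build_mul_tree(parse_newick("((P,S),O);"), "H", "P", "S")
  f0 <- gene_family(parse_newick("((h1,p),(h2,s));"),
                    c(h1 = "H", h2 = "H", p = "P", s = "S"))
  f4 <- gene_family(parse_newick("((p,o),s);"),
                    c(p = "P", o = "O", s = "S"))
  cost4 <- mul_reconcile(f4, mul)$total_cost
  s1 <- score_hypothesis(mul, list(f0, f0, f4))
  expect_equal(s1$total_score, 2 * 0 + cost4)
  s2 <- score_hypothesis(mul, list(f0, f0, f4, f0, f0, f4))
  expect_equal(s2$total_score, 2 * s1$total_score)
  expect_gte(score_hypothesis(mul, list(f0, f4, f4))$total_score,
             s1$total_score)
  expect_equal(nrow(tidy(s1)), 3)
  expect_equal(glance(s1)$n_families, 3)
})
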