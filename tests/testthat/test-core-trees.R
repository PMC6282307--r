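test_that("newick parse/write roundtrip preserves topology and lengths", {
  x <- "((A:1,B:2):0.5,C:3);"
  tr <- parse_newick(x)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 3)
  back <- parse_newick(write_newick(tr))
  expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))

  set.seed(11)
  for (i in 1:100) {
    tr <- ape::rtree(sample(3:20, 1))
    back <- parse_newick(write_newick(tr))
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))
  }
})

test_that("malformed newick is rejected with a position", {
  expect_error(parse_newick("((A,B,C);"), "position")
  expect_error(parse_newick("(A,B))C;"), "position")
  expect_error(parse_newick(""), "empty")
  expect_error(parse_newick("(A,B)"), "';'")
})

test_that("extended newick parsing builds hybridization networks", {
  net <- parse_enewick("((P,(H)#H1),(#H1,S));")
  expect_s3_class(net, "species_network")
  expect_equal(n_hybridizations(net), 1)
  dec <- homeologr:::network_events(net)
  expect_equal(dec$events[[1]]$parent1, "P")
  expect_equal(dec$events[[1]]$parent2, "S")
  expect_equal(dec$events[[1]]$clade, "H")

  # plain newick yields a 0-hybridization network
  net0 <- parse_enewick("((A,B),C);")
  expect_equal(n_hybridizations(net0), 0)
  expect_equal(network_taxa(net0), c("A", "B", "C"))

  expect_error(parse_enewick("((P,(H)#H1),S);"), "exactly twice")
  expect_error(parse_enewick(
    "((((A,(H)#H1),(#H2,B)),((#H1,C),((K)#H2,D))),((#H3,(M)#H3),E));"),
    "at most 2")
})

test_that("build_mul_tree grafts a polyploid clade under both parents", {
  bb <- parse_newick("((P,S),O);")
  m <- build_mul_tree(bb, "H", "P", "S")
  expect_equal(sort(m$tree$tip.label), c("H", "H", "O", "P", "S"))
  expect_equal(write_newick(m$tree), "(((H,P),(H,S)),O);")
  expect_equal(m$copy_tag[m$species == "H"], c("A", "B"))

  m2 <- build_mul_tree(bb, parse_newick("(H1,H2);"), "P", "S")
  expect_equal(sum(m2$species %in% c("H1", "H2")), 4)
  expect_equal(unname(c(table(m2$species)[c("H1", "H2")])), c(2L, 2L))

  expect_error(build_mul_tree(bb, "H", "P", "P"), "must differ")
  expect_error(build_mul_tree(bb, "P", "P", "S"), "overlap")
})

test_that("network_to_multree expands hybridizations and is identity on trees", {
  net0 <- parse_enewick("((A,B),C);")
  m0 <- network_to_multree(net0)
  expect_true(ape::all.equal.phylo(m0$tree, parse_newick("((A,B),C);"),
                                   use.edge.length = FALSE))
  expect_true(all(is.na(m0$copy_tag)))

  net1 <- parse_enewick("((P,(H)#H1),(#H1,S));")
  m1 <- network_to_multree(net1)
  expect_equal(sort(m1$tree$tip.label), c("H", "H", "P", "S"))

  # leaf multiset = backbone taxa + polyploid taxa twice (1-event network)
  sys <- toy_system()
  m <- network_to_multree(sys$net)
  expected <- sort(c(sys$pruned$tip.label, rep(c("H1", "H2"), 2)))
  expect_equal(sort(m$tree$tip.label), expected)

  # two independent hybridizations: both clades duplicated
  net2 <- parse_enewick(
    "(((A,(H)#H1),(#H1,B)),((C,(K)#H2),(#H2,D)));")
  m2 <- network_to_multree(net2)
  expect_equal(sum(m2$tree$tip.label == "H"), 2)
  expect_equal(sum(m2$tree$tip.label == "K"), 2)
})

test_that("lca matches exhaustive ancestor-set intersection", {
  tr <- parse_newick("((A,B),C);")
  expect_equal(lca(tr, "A"), 1L)
  expect_equal(lca(tr, c("A", "B")), 5L)
  expect_equal(lca(tr, c("A", "C")), 4L)
  expect_equal(lca(tr, tr$tip.label), 4L)
  expect_error(lca(tr, character(0)), "empty|unknown")

  set.seed(21)
  for (i in 1:25) {
    tr <- ape::rtree(sample(4:12, 1))
    nn <- length(tr$tip.label) + tr$Nnode
    parent <- homeologr:::parent_vector(tr)
    anc_set <- function(v) {
      out <- v
      while (!is.na(parent[v])) { v <- parent[v]; out <- c(out, v) }
      out
    }
    nodes <- sample(nn, sample(2:4, 1))
    got <- lca(tr, nodes)
    common <- Reduce(intersect, lapply(nodes, anc_set))
    # deepest common ancestor = the one with the longest ancestor chain
    depths <- lengths(lapply(common, anc_set))
    expect_equal(got, common[which.max(depths)])
  }
})

test_that("polytomies are rejected where binary trees are required", {
  poly <- parse_newick("(A,B,C);")
  expect_error(gene_family(poly, stats::setNames(c("A", "B", "C"),
                                                 c("A", "B", "C"))),
               "bifurcating")
  fam <- gene_family(parse_newick("((a,b),c);"),
                     c(a = "A", b = "B", c = "C"))
  expect_error(lca_reconcile(fam, poly), "bifurcating")
})
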