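test_that("pruning likelihood matches exhaustive state summation", {
  set.seed(51)
  for (i in 1:8) {
    nt <- sample(3:6, 1)
    k <- sample(2:3, 1)
    tr <- ape::rtree(nt)
    states <- as.character(seq_len(k) - 1)
    Q <- matrix(stats::runif(k * k, 0.1, 1.5), k, k)
    diag(Q) <- 0; diag(Q) <- -rowSums(Q)
    prior <- stats::runif(k); prior <- prior / sum(prior)
    m <- mk_model(states, Q = Q, root_prior = prior)
    x <- sample(c(states, NA), nt, replace = TRUE)
    names(x) <- tr$tip.label
    if (all(is.na(x))) x[1] <- states[1]
    ll <- prune_likelihood(tr, m, x)
    expect_equal(exp(ll), exhaustive_mk_likelihood(tr, m, x),
                 tolerance = 1e-10)
  }
})

test_that("limiting cases of the pruning likelihood are exact", {
  # rate -> 0, all tips in one state, uniform root prior: likelihood 1/2
  m0 <- mk_model(c("0", "1"), rate = 0)
  tips <- stats::setNames(rep("0", 5), tree5()$tip.label)
  expect_equal(exp(prune_likelihood(tree5(), m0, tips)), 0.5)

  # single-leaf tree: likelihood equals the root prior of the tip state
  one <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "A",
                        Nnode = 1L, edge.length = 0), class = "phylo")
  m <- mk_model(c("x", "y"), rate = 0.4, root_prior = c(0.3, 0.7))
  expect_equal(exp(prune_likelihood(one, m, c(A = "y"))), 0.7)

  # all tips missing: likelihood 1
  miss <- stats::setNames(rep(NA_character_, 5), tree5()$tip.label)
  m1 <- mk_model(c("0", "1"), rate = 0.8)
  expect_equal(prune_likelihood(tree5(), m1, miss), 0, tolerance = 1e-12)
})

test_that("pruning likelihood agrees with an external Mk implementation", {
  tr <- tree5()
  x <- stats::setNames(c("0", "1", "0", "1", "1"), tr$tip.label)
  m <- mk_model(c("0", "1"), rate = 0.6)
  fit <- phytools::fitMk(tr, x, fixedQ = m$Q, pi = c(0.5, 0.5))
  expect_equal(prune_likelihood(tr, m, x), fit$logLik, tolerance = 1e-6)
})

test_that("fit_mk maximizes the likelihood", {
  tr <- tree5()
  x <- stats::setNames(c("0", "1", "0", "1", "1"), tr$tip.label)
  fit <- fit_mk(tr, x, "ER")
  q <- fit$model$Q[1, 2]
  grid <- exp(seq(log(1e-4), log(50), length.out = 20))
  for (g in grid) {
    expect_gte(fit$logLik + 1e-6,
               prune_likelihood(tr, mk_model(c("0", "1"), rate = g), x))
  }
  # monomorphic tips: boundary fit at rate 0 with a warning
  x0 <- stats::setNames(rep("0", 5), tr$tip.label)
  expect_warning(fit0 <- fit_mk(tr, x0, "ER"), "boundary")
  expect_equal(fit0$model$Q[1, 2], 0)
  expect_equal(fit0$logLik, log(0.5))
})

test_that("fit_mk recovers a known generating rate", {
  set.seed(61)
  tr <- ape::rtree(50)
  truth <- mk_model(c("0", "1"), rate = 0.5)
  ok <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    sim <- simulate_trait(tr, truth)
    if (length(unique(sim$data$state)) < 2) next
    fit <- fit_mk(tr, sim$data, "ER")
    q <- fit$model$Q[1, 2]
    if (q > 0.25 && q < 1.0) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.8)
})

test_that("stochastic maps honor endpoints, dwell times and the seed", {
  tr <- tree5()
  m <- mk_model(c("0", "1"), rate = 0.7)
  x <- stats::setNames(c("0", "1", "0", "1", "1"), tr$tip.label)
  maps <- stochastic_map(tr, m, x, n_maps = 25, seed = 101)
  total_len <- sum(tr$edge.length)
  for (h in maps) {
    expect_equal(sum(h$dwell), total_len, tolerance = 1e-9)
    # tip states match observations
    expect_equal(h$node_states[1:5], unname(x))
    # branch endpoint states consistent across edges
    for (e in seq_len(nrow(tr$edge))) {
      seg <- h$maps[[e]]
      expect_equal(names(seg)[1], h$node_states[tr$edge[e, 1]])
      expect_equal(names(seg)[length(seg)], h$node_states[tr$edge[e, 2]])
    }
  }
  again <- stochastic_map(tr, m, x, n_maps = 25, seed = 101)
  expect_identical(lapply(maps, function(h) h$maps),
                   lapply(again, function(h) h$maps))
  other <- stochastic_map(tr, m, x, n_maps = 25, seed = 102)
  expect_false(identical(lapply(maps, function(h) h$maps),
                         lapply(other, function(h) h$maps)))

  # all rates zero and uniform tips: zero changes everywhere
  m0 <- mk_model(c("0", "1"), rate = 0)
  x0 <- stats::setNames(rep("1", 5), tr$tip.label)
  maps0 <- stochastic_map(tr, m0, x0, n_maps = 5, seed = 1)
  expect_true(all(vapply(maps0, function(h) h$n_changes, numeric(1)) == 0))
  expect_true(all(vapply(maps0, function(h)
    all(h$node_states == "1"), logical(1))))
  # conflicting tips under zero rates are impossible
  xc <- stats::setNames(c("0", "1", "0", "1", "1"), tr$tip.label)
  expect_error(stochastic_map(tr, m0, xc, n_maps = 1, seed = 1),
               "impossible")
})

test_that("summarize_maps yields normalized frequencies and change counts", {
  tr <- tree5()
  m <- mk_model(c("0", "1"), rate = 0.7)
  x <- stats::setNames(c("0", "1", "0", "1", "1"), tr$tip.label)
  maps <- stochastic_map(tr, m, x, n_maps = 40, seed = 11)
  sm <- summarize_maps(maps)
  sums <- tapply(sm$node_freq$freq, sm$node_freq$node, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  one <- summarize_maps(maps[1])
  expect_true(all(one$node_freq$freq %in% c(0, 1)))
  expect_equal(sum(one$changes$mean_n), maps[[1]]$n_changes)
})
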