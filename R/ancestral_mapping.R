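# Discrete-trait ancestral state reconstruction by stochastic character
# mapping under an Mk model.  Likelihoods use the pruning algorithm; full
# character histories are drawn from their posterior given tip states by
# backward node sampling followed by endpoint-conditioned branch sampling
# via uniformization (rejection sampling fails on short branches that are
# forced to change state).

#' Construct an Mk model
#'
#' Continuous-time Markov model for a discrete character with `k` states.
#' Either a single `rate` (equal-rates, ER) or a full rate matrix `Q`
#' (rows sum to zero, nonnegative off-diagonals) may be given.
#'
#' @param states Character vector of state labels (>= 2).
#' @param rate Instantaneous rate between any two states (ER model).
#' @param Q Full `k x k` rate matrix (overrides `rate`).
#' @param root_prior Probability vector over states at the root (defaults
#'   to uniform).
#' @return An object of class `mk_model`.
#' @export
mk_model <- function(states, rate = NULL, Q = NULL, root_prior = NULL) {
  states <- as.character(states)
  k <- length(states)
  if (k < 2L) stop("need >= 2 states", call. = FALSE)
  if (is.null(Q)) {
    if (is.null(rate)) stop("give either rate or Q", call. = FALSE)
    stopifnot(rate >= 0)
    Q <- matrix(rate, k, k)
    diag(Q) <- -(k - 1) * rate
  }
  Q <- as.matrix(Q)
  stopifnot(nrow(Q) == k, ncol(Q) == k)
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0", call. = FALSE)
  if (any(abs(rowSums(Q)) > 1e-8)) stop("Q rows must sum to 0", call. = FALSE)
  dimnames(Q) <- list(states, states)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  stopifnot(length(root_prior) == k, abs(sum(root_prior) - 1) < 1e-8,
            all(root_prior >= 0))
  names(root_prior) <- states
  structure(list(states = states, Q = Q, root_prior = root_prior),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat("<mk_model> states:", paste(x$states, collapse = ", "), "\n")
  print(x$Q)
  invisible(x)
}

# normalize character data to a named character vector (NA = unknown);
# accepts a tibble/data.frame (taxon, state) or a named vector; "-" and ""
# are unknown
as_character_data <- function(data, model, tree) {
  if (is.data.frame(data)) {
    stopifnot(all(c("taxon", "state") %in% names(data)))
    x <- stats::setNames(as.character(data$state), data$taxon)
  } else {
    x <- as.character(data)
    names(x) <- names(data)
  }
  x[x %in% c("-", "")] <- NA_character_
  extra <- setdiff(names(x), tree$tip.label)
  if (length(extra))
    stop("trait data for taxa not in the tree: ",
         paste(extra, collapse = ", "), call. = FALSE)
  bad <- setdiff(x[!is.na(x)], model$states)
  if (length(bad))
    stop("state(s) not in the model: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  out <- stats::setNames(rep(NA_character_, n_tips(tree)), tree$tip.label)
  out[names(x)] <- x
  out
}

assert_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be present and >= 0", call. = FALSE)
  invisible(tree)
}

# transition matrices for a set of branch lengths (eigendecomposition,
# Matrix::expm fallback for defective Q); returns a list keyed by edge index
transition_matrices <- function(Q, lengths) {
  k <- nrow(Q)
  eg <- eigen(Q)
  use_eigen <- Matrix::rankMatrix(eg$vectors)[1] == k
  Vi <- if (use_eigen) solve(eg$vectors) else NULL
  lapply(lengths, function(t) {
    P <- if (use_eigen) {
      Re(eg$vectors %*% diag(exp(eg$values * t), k) %*% Vi)
    } else {
      as.matrix(Matrix::expm(Q * t))
    }
    P[P < 0] <- 0
    P
  })
}

# pruning pass: per-node partial likelihood matrices with log scaling
prune_partials <- function(tree, model, x) {
  k <- length(model$states)
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  Pm <- transition_matrices(model$Q, tree$edge.length)
  edge_of <- integer(nn)               # edge index above each node
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  L <- matrix(1, nn, k)
  logscale <- numeric(nn)
  for (i in seq_len(nt)) {
    if (!is.na(x[tree$tip.label[i]]))
      L[i, ] <- as.numeric(model$states == x[tree$tip.label[i]])
  }
  ch <- children_list(tree)
  for (v in postorder_nodes(tree)) {
    if (v <= nt) next
    part <- rep(1, k)
    sc <- 0
    for (cc in ch[[v]]) {
      part <- part * as.numeric(Pm[[edge_of[cc]]] %*% L[cc, ])
      sc <- sc + logscale[cc]
    }
    mx <- max(part)
    if (mx > 0) { L[v, ] <- part / mx; logscale[v] <- sc + log(mx) }
    else { L[v, ] <- part; logscale[v] <- sc }
  }
  list(L = L, logscale = logscale, Pm = Pm, edge_of = edge_of)
}

#' Log-likelihood of tip data under an Mk model (pruning algorithm)
#'
#' Missing tips (unknown states, the "dash" taxa) enter as all-ones partial
#' likelihoods; leaves absent from `data` are treated as missing.
#'
#' @param tree A binary `phylo` with branch lengths.
#' @param model An [mk_model()].
#' @param data Trait data: a tibble/data.frame with columns `taxon`,
#'   `state`, or a named character vector; `NA`/`"-"` mark unknown states.
#' @return The log-likelihood (a scalar).
#' @export
prune_likelihood <- function(tree, model, data) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "mk_model"))
  assert_branch_lengths(tree)
  x <- as_character_data(data, model, tree)
  pp <- prune_partials(tree, model, x)
  r <- root_node(tree)
  lik <- sum(model$root_prior * pp$L[r, ])
  log(lik) + pp$logscale[r]
}

#' Maximum-likelihood fit of an Mk model
#'
#' Fits the transition rate(s) by maximizing the pruning likelihood:
#' bounded one-dimensional optimization for the equal-rates (ER) model,
#' multivariate quasi-Newton over log-rates for all-rates-different (ARD).
#' If the tips show a single state the likelihood is maximized at the
#' rate-zero boundary; this is returned with a warning, not an error.
#'
#' @inheritParams prune_likelihood
#' @param model_class `"ER"` (one rate) or `"ARD"` (one rate per ordered
#'   state pair).
#' @param states State labels; defaults to the sorted observed states.
#' @param root_prior Root state prior (default uniform).
#' @return An object of class `mk_fit`: list with `model`, `logLik`,
#'   `model_class`.
#' @export
fit_mk <- function(tree, data, model_class = c("ER", "ARD"), states = NULL,
                   root_prior = NULL) {
  model_class <- match.arg(model_class)
  stopifnot(inherits(tree, "phylo"))
  assert_branch_lengths(tree)
  probe <- if (is.data.frame(data)) {
    stats::setNames(as.character(data$state), data$taxon)
  } else as.character(data)
  probe[probe %in% c("-", "")] <- NA
  observed <- sort(unique(probe[!is.na(probe)]))
  if (is.null(states)) states <- observed
  if (length(states) < 2L) states <- c(states, ".other")[1:2]
  if (length(observed) < 2L) {
    warning("all observed tips share one state; ML rate is 0 (boundary)",
            call. = FALSE)
    model <- mk_model(states, rate = 0, root_prior = root_prior)
    x <- as_character_data(data, model, tree)
    ll <- prune_likelihood(tree, model, x)
    return(structure(list(model = model, logLik = ll,
                          model_class = model_class),
                     class = "mk_fit"))
  }
  k <- length(states)
  total_len <- sum(tree$edge.length)
  if (model_class == "ER") {
    nll <- function(logq) {
      m <- mk_model(states, rate = exp(logq), root_prior = root_prior)
      -prune_likelihood(tree, m, data)
    }
    upper <- log(1e3 / max(total_len, 1e-8))
    opt <- stats::optimize(nll, interval = c(log(1e-8), max(upper, 0)))
    model <- mk_model(states, rate = exp(opt$minimum),
                      root_prior = root_prior)
    ll <- -opt$objective
  } else {
    np <- k * (k - 1)
    fill_Q <- function(logr) {
      Q <- matrix(0, k, k)
      Q[row(Q) != col(Q)] <- exp(logr)
      diag(Q) <- -rowSums(Q)
      Q
    }
    nll <- function(logr) {
      m <- mk_model(states, Q = fill_Q(logr), root_prior = root_prior)
      -prune_likelihood(tree, m, data)
    }
    er <- fit_mk(tree, data, "ER", states = states, root_prior = root_prior)
    init <- rep(log(max(er$model$Q[1, 2], 1e-6)), np)
    opt <- stats::optim(init, nll, method = "L-BFGS-B",
                        lower = log(1e-8), upper = log(1e4))
    model <- mk_model(states, Q = fill_Q(opt$par), root_prior = root_prior)
    ll <- -opt$value
  }
  structure(list(model = model, logLik = ll, model_class = model_class),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("<mk_fit> ", x$model_class, " model, logLik ",
      format(x$logLik, digits = 6), "\n", sep = "")
  print(x$model$Q)
  invisible(x)
}

#' @export
tidy.mk_fit <- function(x, ...) {
  Q <- x$model$Q
  idx <- which(row(Q) != col(Q), arr.ind = TRUE)
  tibble::tibble(from = x$model$states[idx[, 1]],
                 to = x$model$states[idx[, 2]],
                 rate = Q[idx])
}

#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(model_class = x$model_class,
                 n_states = length(x$model$states),
                 logLik = x$logLik)
}

# endpoint-conditioned path by uniformization; returns the ordered state
# sequence and change times within (0, t); a==b may yield no changes
sample_branch_path <- function(a, b, t, Q, states, Pm_ab) {
  k <- nrow(Q)
  Omega <- max(-diag(Q))
  if (Omega <= 0 || t <= 0) {
    if (a != b)
      stop("impossible history: state change forced on a zero-rate or ",
           "zero-length branch", call. = FALSE)
    return(list(states = a, times = numeric(0)))
  }
  R <- diag(k) + Q / Omega
  if (Pm_ab <= 0)
    stop("impossible history: endpoint pair has probability 0",
         call. = FALSE)
  # number of uniformized jumps N | endpoints
  u <- stats::runif(1) * Pm_ab
  Rpow <- list(diag(k))                 # R^0
  n <- 0
  acc <- stats::dpois(0, Omega * t) * Rpow[[1]][a, b]
  while (acc < u && n < 10000) {
    n <- n + 1
    Rpow[[n + 1]] <- Rpow[[n]] %*% R
    acc <- acc + stats::dpois(n, Omega * t) * Rpow[[n + 1]][a, b]
  }
  if (n == 0) return(list(states = a, times = numeric(0)))
  # state sequence x_0 = a, ..., x_n = b
  xs <- integer(n + 1)
  xs[1] <- a; xs[n + 1] <- b
  if (n > 1) {
    for (i in 2:n) {
      w <- R[xs[i - 1], ] * Rpow[[n - i + 2]][, b]
      xs[i] <- sample.int(k, 1, prob = w)
    }
  }
  times <- sort(stats::runif(n)) * t
  keep <- which(xs[-1] != xs[-(n + 1)])   # real changes only
  list(states = c(a, xs[keep + 1]), times = times[keep])
}

#' Stochastic character mapping
#'
#' Samples full character histories from their posterior given the tip
#' states and the model: node states are drawn backward from the pruning
#' conditionals, then each branch history is drawn conditional on its
#' endpoint states by uniformization.  Reproducible given `seed`.
#'
#' @inheritParams prune_likelihood
#' @param n_maps Number of histories to sample (>= 1).
#' @param seed Optional integer seed.
#' @return A list of `simmap_history` objects; each has per-edge state
#'   segments (`maps`, parent-to-child order, durations named by state),
#'   sampled `node_states`, the total change count and per-state dwell
#'   times.
#' @export
stochastic_map <- function(tree, model, data, n_maps = 10, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "mk_model"),
            n_maps >= 1)
  assert_branch_lengths(tree)
  if (!is.null(seed)) set.seed(seed)
  x <- as_character_data(data, model, tree)
  pp <- prune_partials(tree, model, x)
  k <- length(model$states)
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  r <- root_node(tree)
  pre <- rev(postorder_nodes(tree))
  parent <- parent_vector(tree)
  root_w <- model$root_prior * pp$L[r, ]
  if (sum(root_w) <= 0)
    stop("impossible history: data have likelihood 0 under the model",
         call. = FALSE)
  lapply(seq_len(n_maps), function(rep) {
    st <- integer(nn)
    st[r] <- sample.int(k, 1, prob = root_w)
    for (v in pre) {
      if (v == r) next
      P <- pp$Pm[[pp$edge_of[v]]]
      w <- P[st[parent[v]], ] * pp$L[v, ]
      if (sum(w) <= 0)
        stop("impossible history: no state reachable at node ", v,
             call. = FALSE)
      st[v] <- sample.int(k, 1, prob = w)
    }
    maps <- vector("list", nrow(tree$edge))
    n_changes <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
      t <- tree$edge.length[e]
      path <- sample_branch_path(st[p], st[c], t, model$Q, model$states,
                                 pp$Pm[[e]][st[p], st[c]])
      bounds <- c(0, path$times, t)
      seg <- diff(bounds)
      names(seg) <- model$states[path$states]
      maps[[e]] <- seg
      n_changes <- n_changes + length(path$times)
    }
    dwell <- stats::setNames(numeric(k), model$states)
    for (seg in maps)
      for (i in seq_along(seg))
        dwell[names(seg)[i]] <- dwell[names(seg)[i]] + seg[i]
    structure(list(tree = tree,
                   node_states = stats::setNames(model$states[st], NULL),
                   maps = maps,
                   n_changes = n_changes,
                   dwell = dwell,
                   states = model$states),
              class = "simmap_history")
  })
}

#' @export
print.simmap_history <- function(x, ...) {
  cat("<simmap_history> ", x$n_changes, " change(s); dwell: ",
      paste(sprintf("%s=%.3g", names(x$dwell), x$dwell), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Summarize sampled character histories
#'
#' Empirical per-node state frequencies and mean numbers of changes per
#' ordered state pair across a set of histories on a common tree.
#'
#' @param histories List of `simmap_history` objects from
#'   [stochastic_map()].
#' @return An `ancestral_summary`: list with `node_freq` (tibble: node,
#'   state, freq) and `changes` (tibble: from, to, mean_n).
#' @export
summarize_maps <- function(histories) {
  stopifnot(length(histories) >= 1L)
  topo <- write_newick(histories[[1]]$tree)
  ok <- vapply(histories, function(h)
    identical(write_newick(h$tree), topo), logical(1))
  if (!all(ok)) stop("histories are on different trees", call. = FALSE)
  states <- histories[[1]]$states
  nn <- length(histories[[1]]$node_states)
  freq <- matrix(0, nn, length(states), dimnames = list(NULL, states))
  chg <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
  for (h in histories) {
    for (v in seq_len(nn)) freq[v, h$node_states[v]] <-
        freq[v, h$node_states[v]] + 1
    for (seg in h$maps) {
      s <- names(seg)
      if (length(s) > 1)
        for (i in seq_len(length(s) - 1))
          chg[s[i], s[i + 1]] <- chg[s[i], s[i + 1]] + 1
    }
  }
  freq <- freq / length(histories)
  node_freq <- tibble::tibble(
    node = rep(seq_len(nn), times = length(states)),
    state = rep(states, each = nn),
    freq = as.vector(freq))
  idx <- which(row(chg) != col(chg), arr.ind = TRUE)
  changes <- tibble::tibble(from = states[idx[, 1]], to = states[idx[, 2]],
                            mean_n = chg[idx] / length(histories))
  structure(list(node_freq = node_freq, changes = changes,
                 n_histories = length(histories)),
            class = "ancestral_summary")
}

#' @export
print.ancestral_summary <- function(x, ...) {
  cat("<ancestral_summary> over", x$n_histories, "histories\n")
  print(utils::head(tidyr::pivot_wider(x$node_freq,
                                       names_from = "state",
                                       values_from = "freq"), 8))
  invisible(x)
}

#' @export
tidy.ancestral_summary <- function(x, ...) x$node_freq
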