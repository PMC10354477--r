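# Symmetric two-state Mk machinery, implemented from first principles on
# top of ape's tree structures. For the symmetric rate matrix with rate q,
# the transition probabilities along a branch of length t are
#   p_same(t) = (1 + exp(-2 q t)) / 2,  p_diff(t) = (1 - exp(-2 q t)) / 2.

#' Read a rooted tree from a newick file
#'
#' Requires branch lengths on every edge; internal node labels are
#' permitted and ignored.
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed newick in ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick in ", path)
  .check_tree(tree)
  tree
}

.check_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have a branch length on every edge")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  invisible(tree)
}

#' Prune a tree to a set of tips
#'
#' Drops all other tips and suppresses the resulting degree-two nodes,
#' summing their branch lengths.
#'
#' @param tree An `ape::phylo` tree.
#' @param tips Character vector of at least two tip labels to keep.
#' @return The pruned tree.
#' @export
prune_to <- function(tree, tips) {
  .check_tree(tree)
  absent <- setdiff(tips, tree$tip.label)
  if (length(absent)) stop("tip(s) not in tree: ", paste(absent, collapse = ", "))
  if (length(unique(tips)) < 2L) stop("pruning to fewer than 2 tips")
  ape::keep.tip(tree, tips)
}

#' Symmetric two-state Mk model
#'
#' @param q Transition rate between the two states per unit branch length.
#' @param root_prior Probabilities of states 0 and 1 at the root; the
#'   default is the stationary distribution (1/2, 1/2) of the symmetric
#'   chain.
#' @return A `kincomp_mk` model object.
#' @export
mk_model <- function(q, root_prior = c(0.5, 0.5)) {
  stopifnot(q >= 0, length(root_prior) == 2, all(root_prior >= 0),
            abs(sum(root_prior) - 1) < 1e-12)
  structure(list(q = q, root_prior = root_prior), class = "kincomp_mk")
}

.p_same <- function(q, t) 0.5 * (1 + exp(-2 * q * t))
.p_diff <- function(q, t) 0.5 * (1 - exp(-2 * q * t))

.check_states <- function(tree, states) {
  if (is.null(names(states))) stop("tip states must be a named vector")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) stop("missing tip state(s): ", paste(miss, collapse = ", "))
  s <- as.integer(states[tree$tip.label])
  if (!all(s %in% c(0L, 1L))) stop("tip states must be 0 or 1")
  s
}

# Felsenstein pruning: matrix of conditional (partial) likelihoods
# L[node, state] of the data below each node.
.mk_partials <- function(tree, s, q) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- matrix(0, nnode, 2)
  L[cbind(seq_len(ntip), s + 1L)] <- 1
  L[(ntip + 1):nnode, ] <- 1
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]; t <- po$edge.length[e]
    ps <- .p_same(q, t); pd <- .p_diff(q, t)
    # message to parent: sum over child state of P(transition) * L[child]
    m0 <- ps * L[ch, 1] + pd * L[ch, 2]
    m1 <- pd * L[ch, 1] + ps * L[ch, 2]
    L[par, ] <- L[par, ] * c(m0, m1)
  }
  L
}

#' Log-likelihood of binary tip states under the symmetric Mk model
#'
#' Felsenstein pruning over the two-state symmetric chain, with the root
#' weighted by the model's root prior.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param states Named 0/1 vector of tip states (one per tip).
#' @param model A [mk_model()], or a bare rate `q`.
#' @return The log-likelihood.
#' @export
mk_loglik <- function(tree, states, model) {
  .check_tree(tree)
  if (is.numeric(model)) model <- mk_model(model)
  s <- .check_states(tree, states)
  L <- .mk_partials(tree, s, model$q)
  root <- length(tree$tip.label) + 1L
  log(sum(model$root_prior * L[root, ]))
}

#' Maximum-likelihood rate of the symmetric Mk model
#'
#' One-dimensional bounded optimization of [mk_loglik()] over q. A
#' constant character sits at the q = 0 boundary and is reported as such.
#'
#' @inheritParams mk_loglik
#' @param q_max Upper bound of the search interval; default scales with
#'   the reciprocal mean branch length.
#' @param root_prior Root prior passed through to the fitted model.
#' @return A [mk_model()] with extra fields `loglik` and `boundary`
#'   (`"none"`, `"lower"` or `"upper"`).
#' @export
mk_fit <- function(tree, states, q_max = NULL, root_prior = c(0.5, 0.5)) {
  .check_tree(tree)
  s <- .check_states(tree, states)
  if (length(s) < 2L) stop("need >= 2 tips")
  if (is.null(q_max)) q_max <- 100 / mean(tree$edge.length)
  if (length(unique(s)) == 1L) {
    m <- mk_model(0, root_prior)
    m$loglik <- mk_loglik(tree, states, m)
    m$boundary <- "lower"
    return(m)
  }
  f <- function(q) mk_loglik(tree, states, mk_model(q, root_prior))
  # the profile flattens for large q (saturation plateau), which can trap a
  # plain golden-section search; bracket the optimum on a log grid first
  grid <- exp(seq(log(1e-4), log(q_max), length.out = 30))
  lls <- vapply(grid, f, 1)
  best <- which.max(lls)
  lo <- if (best == 1) 0 else grid[best - 1]
  hi <- if (best == length(grid)) q_max else grid[best + 1]
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  m <- mk_model(opt$maximum, root_prior)
  m$loglik <- opt$objective
  m$boundary <- if (opt$maximum < 1e-6) "lower"
                else if (opt$maximum > 0.99 * q_max) "upper"
                else "none"
  m
}

# Sample change counts on a branch of length t at rate q, conditioned on
# endpoint parity, by uniformization. With dominating rate q the jump
# chain of the symmetric two-state process is the deterministic flip, so
# every virtual event is a real change and N | endpoints is Poisson(q t)
# restricted to even (equal endpoints) or odd (unequal) values.
.sample_changes <- function(n, qt, odd) {
  if (qt == 0) {
    if (any(odd)) stop("zero-rate branch with unequal endpoints")
    return(integer(n))
  }
  nmax <- max(20, ceiling(qt + 12 * sqrt(qt) + 20))
  k <- 0:nmax
  pmf <- stats::dpois(k, qt)
  out <- integer(n)
  for (parity in c(FALSE, TRUE)) {
    sel <- which(odd == parity)
    if (!length(sel)) next
    kk <- k[k %% 2 == as.integer(parity)]
    pp <- pmf[kk + 1L]
    cdf <- cumsum(pp) / sum(pp)
    u <- stats::runif(length(sel))
    out[sel] <- kk[findInterval(u, cdf) + 1L]
  }
  out
}

#' Stochastic character mapping under the symmetric Mk model
#'
#' Samples full character histories conditional on the tip data: internal
#' node states are drawn from their joint conditional distribution
#' (pruning pass followed by preorder sampling), then each branch's path
#' is drawn conditional on its endpoints by uniformization, which
#' terminates for any rate and branch length. All sampling is vectorized
#' across simulations.
#'
#' @inheritParams mk_loglik
#' @param n_sims Number of simulated histories (default 10000).
#' @param seed Integer seed.
#' @return A `kincomp_simmap` list: `n_sims`, `changes` (per-simulation
#'   total change count), `branch_changes` (edge-by-simulation change-count
#'   matrix), `node_probs` (per-node posterior state probabilities),
#'   `edge` / `edge.length` (the preorder edge table the rows of
#'   `branch_changes` refer to), `q`.
#' @export
stochastic_map <- function(tree, states, model, n_sims = 10000, seed) {
  .check_tree(tree)
  if (!ape::is.binary(tree))
    stop("stochastic mapping requires a binary tree; resolve polytomies first ",
         "(e.g. ape::multi2di)")
  if (is.numeric(model)) model <- mk_model(model)
  set.seed(seed)
  s <- .check_states(tree, states)
  q <- model$q
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- .mk_partials(tree, s, q)
  root <- ntip + 1L
  # node state samples, nnode x n_sims (0/1)
  node_state <- matrix(NA_integer_, nnode, n_sims)
  w <- model$root_prior * L[root, ]
  node_state[root, ] <- stats::rbinom(n_sims, 1L, w[2] / sum(w))
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]; ch <- pre$edge[e, 2]; t <- pre$edge.length[e]
    ps <- .p_same(q, t); pd <- .p_diff(q, t)
    sp <- node_state[par, ]
    # P(child = 1 | parent, data below child)
    w1 <- ifelse(sp == 1L, ps, pd) * L[ch, 2]
    w0 <- ifelse(sp == 0L, ps, pd) * L[ch, 1]
    node_state[ch, ] <- stats::rbinom(n_sims, 1L, w1 / (w0 + w1))
  }
  branch_changes <- matrix(0L, nrow(pre$edge), n_sims)
  for (e in seq_len(nrow(pre$edge))) {
    odd <- node_state[pre$edge[e, 1], ] != node_state[pre$edge[e, 2], ]
    branch_changes[e, ] <- .sample_changes(n_sims, q * pre$edge.length[e], odd)
  }
  node_probs <- cbind(`0` = rowMeans(node_state == 0L),
                      `1` = rowMeans(node_state == 1L))
  structure(list(n_sims = n_sims, q = q,
                 changes = colSums(branch_changes),
                 branch_changes = branch_changes,
                 node_state = node_state,
                 node_probs = node_probs,
                 edge = pre$edge, edge.length = pre$edge.length,
                 tip_label = pre$tip.label),
            class = "kincomp_simmap")
}

#' @export
print.kincomp_simmap <- function(x, ...) {
  cat("<stochastic character maps> ", x$n_sims, " simulations, q = ",
      signif(x$q, 4), "\n  mean total state changes: ",
      round(mean(x$changes), 2), "\n", sep = "")
  invisible(x)
}

#' Summarize a stochastic mapping to CSV
#'
#' Writes per-simulation total change counts and per-node posterior state
#' probabilities.
#'
#' @param x A `kincomp_simmap` result.
#' @param changes_path,node_probs_path Output CSV paths (either may be
#'   `NULL` to skip).
#' @export
write_simmap <- function(x, changes_path = NULL, node_probs_path = NULL) {
  if (!is.null(changes_path))
    utils::write.csv(data.frame(sim = seq_len(x$n_sims), changes = x$changes),
                     changes_path, row.names = FALSE, quote = FALSE)
  if (!is.null(node_probs_path))
    utils::write.csv(data.frame(node = seq_len(nrow(x$node_probs)),
                                p0 = x$node_probs[, 1], p1 = x$node_probs[, 2]),
                     node_probs_path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

# Fitch small-parsimony score of a binary character (oracle for the lower
# bound on mapped change counts).
.fitch_score <- function(tree, states) {
  s <- .check_states(tree, states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- s[i]
  po <- ape::reorder.phylo(tree, "postorder")
  score <- 0L
  kids <- split(po$edge[, 2], po$edge[, 1])
  done <- logical(nnode)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]
    if (done[par]) next
    ch <- kids[[as.character(par)]]
    if (any(vapply(sets[ch], is.null, TRUE))) next  # a child subtree pending
    inter <- Reduce(intersect, sets[ch])
    if (length(inter)) {
      sets[[par]] <- inter
    } else {
      sets[[par]] <- Reduce(union, sets[ch])
      score <- score + length(ch) - 1L
    }
    done[par] <- TRUE
  }
  score
}
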