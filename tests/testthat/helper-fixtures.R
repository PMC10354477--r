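# Pedigree fixtures built in code, and independent oracles used by the
# unit and acceptance suites.

# The worked-example mixed trio: focal X, paternal half-sibling H (shared
# sire S, unrelated dams), maternal first cousin C (dams M1/M2 are full
# sisters), H and C mutually unrelated.
mixed_trio_pedigree <- function() {
  pedigree(
    id   = c("GM", "GS", "M1", "M2", "S", "D1", "D2", "X", "H", "C"),
    dam  = c(NA, NA, "GM", "GM", NA, NA, NA, "M1", "D1", "M2"),
    sire = c(NA, NA, "GS", "GS", NA, NA, NA, "S", "S", "D2"),
    sex  = c("F", "M", "F", "F", "M", "F", "M", "F", "F", "F"))
}

# Three maternal first cousins: mothers are full sisters (same maternal
# grandparents), fathers mutually unrelated founders.
cousin_trio_pedigree <- function() {
  pedigree(
    id   = c("GM", "GS", "A", "B", "C", "FA", "FB", "FC", "x1", "x2", "x3"),
    dam  = c(NA, NA, "GM", "GM", "GM", NA, NA, NA, "A", "B", "C"),
    sire = c(NA, NA, "GS", "GS", "GS", NA, NA, NA, "FA", "FB", "FC"),
    sex  = c("F", "M", "F", "F", "F", "M", "M", "M", "F", "F", "F"))
}

# Random pedigree: founders first, later individuals draw parents (possibly
# unknown) from earlier individuals, which keeps it acyclic.
random_pedigree <- function(n, seed, p_known = 0.75) {
  set.seed(seed)
  id <- sprintf("I%02d", seq_len(n))
  dam <- sire <- rep(NA_character_, n)
  nf <- max(4L, ceiling(n / 4))
  for (i in (nf + 1):n) {
    if (stats::runif(1) < p_known) dam[i] <- id[sample.int(i - 1L, 1)]
    if (stats::runif(1) < p_known) sire[i] <- id[sample.int(i - 1L, 1)]
    if (!is.na(dam[i]) && identical(dam[i], sire[i])) sire[i] <- NA
  }
  pedigree(id, dam, sire)
}

# Gene-dropping oracle: founder alleles transmitted through the pedigree;
# kinship f(i, j) estimated as the probability that two randomly drawn
# homologous alleles are identical by descent. Unknown parents contribute
# fresh founder alleles.
gene_drop_kinship <- function(ped, i, j, ndrops, seed) {
  set.seed(seed)
  n <- nrow(ped)
  ord <- attr(ped, "topo_order")
  pd <- match(ped$dam, ped$id)
  ps <- match(ped$sire, ped$id)
  a1 <- matrix(0L, n, ndrops)
  a2 <- matrix(0L, n, ndrops)
  cnt <- 0L
  for (v in ord) {
    if (is.na(pd[v])) {
      cnt <- cnt + 1L; a1[v, ] <- cnt
    } else {
      pick <- stats::runif(ndrops) < 0.5
      a1[v, ] <- ifelse(pick, a1[pd[v], ], a2[pd[v], ])
    }
    if (is.na(ps[v])) {
      cnt <- cnt + 1L; a2[v, ] <- cnt
    } else {
      pick <- stats::runif(ndrops) < 0.5
      a2[v, ] <- ifelse(pick, a1[ps[v], ], a2[ps[v], ])
    }
  }
  ii <- match(i, ped$id); jj <- match(j, ped$id)
  per_drop <- ((a1[ii, ] == a1[jj, ]) + (a1[ii, ] == a2[jj, ]) +
               (a2[ii, ] == a1[jj, ]) + (a2[ii, ] == a2[jj, ])) / 4
  c(est = mean(per_drop), se = stats::sd(per_drop) / sqrt(ndrops))
}

# Brute-force Mk likelihood: enumerate all internal-node state assignments.
mk_loglik_enum <- function(tree, states, q, prior = c(0.5, 0.5)) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  s <- as.integer(states[tree$tip.label])
  total <- 0
  for (code in 0:(2^nn - 1)) {
    ist <- as.integer(intToBits(code))[seq_len(nn)]
    full <- c(s, ist)
    p <- prior[full[ntip + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      a <- full[tree$edge[e, 1]]; b <- full[tree$edge[e, 2]]
      t <- tree$edge.length[e]
      p <- p * if (a == b) 0.5 * (1 + exp(-2 * q * t))
               else 0.5 * (1 - exp(-2 * q * t))
    }
    total <- total + p
  }
  log(total)
}

# Enumeration-based marginal posterior P(node = 1 | tips) for every node.
mk_marginals_enum <- function(tree, states, q, prior = c(0.5, 0.5)) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  s <- as.integer(states[tree$tip.label])
  joint <- numeric(2^nn)
  for (code in 0:(2^nn - 1)) {
    ist <- as.integer(intToBits(code))[seq_len(nn)]
    full <- c(s, ist)
    p <- prior[full[ntip + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      a <- full[tree$edge[e, 1]]; b <- full[tree$edge[e, 2]]
      t <- tree$edge.length[e]
      p <- p * if (a == b) 0.5 * (1 + exp(-2 * q * t))
               else 0.5 * (1 - exp(-2 * q * t))
    }
    joint[code + 1L] <- p
  }
  joint <- joint / sum(joint)
  p1 <- numeric(nn)
  for (code in 0:(2^nn - 1)) {
    ist <- as.integer(intToBits(code))[seq_len(nn)]
    p1 <- p1 + ist * joint[code + 1L]
  }
  c(s, p1)  # tips are fixed at their observed state
}

# Random binary tree with branch lengths, via ape.
random_tree <- function(ntip, seed) {
  set.seed(seed)
  ape::rtree(ntip)
}
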