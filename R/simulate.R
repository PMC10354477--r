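# Forward-time generators with known ground truth. The simulator emulates
# the demographic regimes thought to shape kinship composition: number of
# breeding females, litter size (monotocy vs polytocy), philopatric
# recruitment, immigration of unrelated adults, and paternity skew.
# Immigrants are represented exactly as real pedigrees represent them:
# founders with unknown parents, which is what makes fully unrelated units
# hard to certify in the field.

#' Simulation parameters for a social-unit pedigree
#'
#' @param n_breeding_females Number of breeding females per generation
#'   (>= 1).
#' @param litter_size Either a single number (fixed litter size) or
#'   `list(lambda = x)` for a zero-truncated Poisson with rate `x`
#'   (minimum litter of 1).
#' @param n_generations Number of breeding generations (0 = founders only).
#' @param immigration_rate Per-generation probability that one unrelated
#'   adult female founder joins the unit.
#' @param paternity `"single_sire"` (one male sires every litter of a
#'   generation, i.e. complete paternity skew) or `list(n_sires = k)`
#'   (each offspring draws its sire uniformly from k males).
#' @param sex_ratio Probability that an offspring is female.
#' @param seed Integer seed; mandatory, all randomness is derived from it.
#' @return A validated `kincomp_sim_params` list.
#' @export
sim_params <- function(n_breeding_females = 2, litter_size = 2,
                       n_generations = 2, immigration_rate = 0,
                       paternity = "single_sire", sex_ratio = 0.5,
                       seed) {
  if (missing(seed) || is.null(seed) || length(seed) != 1 || is.na(seed))
    stop("seed is mandatory and must be a single integer")
  stopifnot(n_breeding_females >= 1, n_generations >= 0,
            immigration_rate >= 0, immigration_rate <= 1,
            sex_ratio >= 0, sex_ratio <= 1)
  if (is.numeric(litter_size)) {
    stopifnot(litter_size >= 1)
    litter_size <- list(type = "fixed", k = as.integer(litter_size))
  } else if (is.list(litter_size) && !is.null(litter_size$lambda)) {
    stopifnot(litter_size$lambda > 0)
    litter_size <- list(type = "poisson", lambda = litter_size$lambda)
  } else stop("litter_size must be a number or list(lambda = x)")
  if (identical(paternity, "single_sire")) {
    paternity <- list(type = "single_sire")
  } else if (is.list(paternity) && !is.null(paternity$n_sires)) {
    stopifnot(paternity$n_sires >= 1)
    paternity <- list(type = "random_sires", n_sires = as.integer(paternity$n_sires))
  } else stop("paternity must be 'single_sire' or list(n_sires = k)")
  structure(list(n_breeding_females = as.integer(n_breeding_females),
                 litter_size = litter_size,
                 n_generations = as.integer(n_generations),
                 immigration_rate = immigration_rate,
                 paternity = paternity, sex_ratio = sex_ratio,
                 seed = as.integer(seed)),
            class = "kincomp_sim_params")
}

.draw_litter <- function(ls) {
  if (ls$type == "fixed") ls$k
  else stats::qpois(stats::runif(1, stats::ppois(0, ls$lambda), 1), ls$lambda)
}

# Ground-truth dyad check, independent of classify_dyad() and
# ancestors_to_depth2(): closures are rebuilt directly from the parent
# columns the simulator itself laid down.
.truth_kin_pairs <- function(ped, members) {
  dam <- ped$dam[match(members, ped$id)]
  sire <- ped$sire[match(members, ped$id)]
  gp_of <- function(p) {
    if (is.na(p)) return(character(0))
    k <- match(p, ped$id)
    c(ped$dam[k], ped$sire[k])
  }
  anc <- lapply(seq_along(members), function(k) {
    as.character(stats::na.omit(c(dam[k], sire[k], gp_of(dam[k]), gp_of(sire[k]))))
  })
  names(anc) <- members
  pairs <- utils::combn(members, 2L)
  kin <- logical(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    kin[k] <- i %in% anc[[j]] || j %in% anc[[i]] ||
      length(intersect(anc[[i]], anc[[j]])) > 0
  }
  kin
}

.truth_label <- function(ped, members) {
  if (length(members) < 2L) return(NA_character_)
  kin <- .truth_kin_pairs(ped, members)
  if (all(kin)) "RELATED" else if (!any(kin)) "UNRELATED" else "MIX_RELATED"
}

#' Simulate a social-unit pedigree with known composition
#'
#' Forward-time breeding from founding females over discrete
#' non-overlapping generations. Each generation, breeding females are
#' recruited philopatrically from the previous generation (founders at
#' generation 1); sires are new unrelated males according to the paternity
#' regime; with probability `immigration_rate` one unrelated adult female
#' founder immigrates into the cohort. The adults of the final generation
#' form the same-sex social units. Ground truth is derived from the
#' construction records (founder identities and parent links laid down by
#' the simulator), not from the classifier under test.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `pedigree` (a [pedigree()]), `units`
#'   (per-sex [social_unit()] or NOT_A_UNIT sentinel), `truth` (per-sex
#'   expected label `RELATED`/`UNRELATED`/`MIX_RELATED`, `NA` when that sex
#'   has no unit), and `params`.
#' @export
simulate_unit_pedigree <- function(params) {
  stopifnot(inherits(params, "kincomp_sim_params"))
  set.seed(params$seed)
  p <- params
  id <- character(0); dam <- character(0); sire <- character(0)
  sex <- character(0); bu <- character(0)
  add <- function(i, d, s, x, b) {
    id <<- c(id, i); dam <<- c(dam, d); sire <<- c(sire, s)
    sex <<- c(sex, x); bu <<- c(bu, b)
  }
  founders_f <- sprintf("F0_%03d", seq_len(p$n_breeding_females))
  for (k in seq_along(founders_f))
    add(founders_f[k], NA, NA, "F", sprintf("L%d", k))
  cohort <- founders_f  # adults of the current generation
  if (p$n_generations > 0) {
    for (g in seq_len(p$n_generations)) {
      moms_avail <- cohort[sex[match(cohort, id)] == "F"]
      moms <- utils::head(sort(moms_avail), p$n_breeding_females)
      offspring <- character(0)
      if (length(moms)) {
        if (p$paternity$type == "single_sire") {
          sires_g <- sprintf("S%d", g)
        } else {
          sires_g <- sprintf("S%d_%d", g, seq_len(p$paternity$n_sires))
        }
        for (s in sires_g) add(s, NA, NA, "M", NA)
        cnt <- 0L
        for (m in moms) {
          ls <- .draw_litter(p$litter_size)
          for (o in seq_len(ls)) {
            cnt <- cnt + 1L
            oid <- sprintf("G%d_%03d", g, cnt)
            osex <- if (stats::runif(1) < p$sex_ratio) "F" else "M"
            osire <- if (length(sires_g) == 1L) sires_g
                     else sample(sires_g, 1L)
            add(oid, m, osire, osex, bu[match(m, id)])
            offspring <- c(offspring, oid)
          }
        }
      }
      if (stats::runif(1) < p$immigration_rate) {
        imm <- sprintf("I%d", g)
        add(imm, NA, NA, "F", sprintf("IMM%d", g))
        offspring <- c(offspring, imm)
      }
      cohort <- offspring
    }
  }
  ped <- pedigree(id, dam, sire, sex, bu)
  cohort_sex <- sex[match(cohort, id)]
  units <- list(); truth <- list()
  for (sx in c("F", "M")) {
    mem <- cohort[cohort_sex == sx]
    if (length(mem) >= 2L) {
      units[[sx]] <- social_unit("sim_unit", mem, sx, period = "final")
      truth[[sx]] <- .truth_label(ped, mem)
    } else {
      units[[sx]] <- structure(list(unit_id = "sim_unit", sex = sx,
                                    n_candidates = length(mem)),
                               class = "kincomp_not_a_unit")
      truth[[sx]] <- NA_character_
    }
  }
  list(pedigree = ped, units = units, truth = truth, params = params)
}

#' Noisy marker-style relatedness estimates for a set of individuals
#'
#' Adds unbounded Gaussian noise to true pedigree relatedness, mimicking
#' marker-based estimators: estimates may be negative, and only averages
#' over many dyads are trustworthy. Line labels are taken from the
#' pedigree's `birth_unit` (matriline) column.
#'
#' @param ped A [pedigree()].
#' @param ids Individuals to cover (all unordered pairs).
#' @param sd Noise standard deviation (>= 0; 0 returns true r exactly).
#' @param seed Integer seed.
#' @return A list with `evidence` (data frame `i`, `j`, `r_hat`) and
#'   `lines` (named character vector of line labels, `NA` if unknown).
#' @export
noisy_relatedness <- function(ped, ids, sd, seed) {
  stopifnot(sd >= 0)
  set.seed(seed)
  idx <- .ped_index(ped, ids)
  r <- relatedness_matrix(ped, ids)
  pairs <- utils::combn(as.character(ids), 2L)
  true_r <- r[cbind(pairs[1, ], pairs[2, ])]
  ev <- data.frame(i = pairs[1, ], j = pairs[2, ],
                   r_hat = true_r + stats::rnorm(ncol(pairs), 0, sd),
                   stringsAsFactors = FALSE)
  lines <- ped$birth_unit[idx]
  names(lines) <- ped$id[idx]
  list(evidence = ev, lines = lines)
}

#' Simulate a binary trait on a phylogeny
#'
#' Evolves a two-state character along a rooted tree with branch lengths
#' under the continuous-time symmetric Markov model (equal rate q between
#' states). The probability of an end state differing from the start state
#' across a branch of length t is (1 - exp(-2 q t)) / 2.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param q Symmetric transition rate (>= 0) per unit branch length.
#' @param root_state `0`, `1`, or `"stationary"` (equal-probability draw).
#' @param seed Integer seed.
#' @return Named integer vector of tip states (0/1).
#' @export
simulate_binary_trait <- function(tree, q, root_state = "stationary", seed) {
  stopifnot(inherits(tree, "phylo"), q >= 0)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths on every edge")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  state <- integer(nnode)
  root <- ntip + 1L
  state[root] <- if (identical(root_state, "stationary")) {
    stats::rbinom(1, 1, 0.5)
  } else as.integer(root_state)
  # preorder: ape trees in cladewise order list parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    t <- ord$edge.length[e]
    p_flip <- 0.5 * (1 - exp(-2 * q * t))
    flip <- stats::runif(1) < p_flip
    state[ch] <- if (flip) 1L - state[par] else state[par]
  }
  out <- state[seq_len(ntip)]
  names(out) <- tree$tip.label
  out
}

#' Write a simulation to disk
#'
#' Writes `pedigree.tsv`, `units.csv`, and a `metadata.txt` sidecar
#' recording the parameters and seed; byte-identical for identical seeds.
#'
#' @param sim Output of [simulate_unit_pedigree()].
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- sim$pedigree
  out <- as.data.frame(ped)
  out[is.na(out)] <- "."
  utils::write.table(out, file.path(dir, "pedigree.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  rows <- do.call(rbind, lapply(Filter(is_social_unit, sim$units), function(u)
    data.frame(unit_id = u$unit_id, period = u$period,
               individual_id = u$members, sex = u$sex, age_class = "adult",
               stringsAsFactors = FALSE)))
  if (!is.null(rows))
    utils::write.csv(rows, file.path(dir, "units.csv"), row.names = FALSE,
                     quote = FALSE)
  p <- sim$params
  meta <- c(sprintf("n_breeding_females: %d", p$n_breeding_females),
            sprintf("litter_size: %s", paste(deparse(p$litter_size), collapse = "")),
            sprintf("n_generations: %d", p$n_generations),
            sprintf("immigration_rate: %g", p$immigration_rate),
            sprintf("paternity: %s", paste(deparse(p$paternity), collapse = "")),
            sprintf("sex_ratio: %g", p$sex_ratio),
            sprintf("seed: %d", p$seed))
  writeLines(meta, file.path(dir, "metadata.txt"))
  invisible(dir)
}
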