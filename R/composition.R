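# Group-level kinship composition. A social unit here is the largest
# temporally stable aggregation containing two or more adults of the same
# sex; temporal stability is input metadata (a `period` label), not
# inferred. Composition is evaluated over the unordered same-sex adult
# dyads of one unit-period.

#' Construct a social unit
#'
#' @param unit_id Unit label.
#' @param members Character vector of at least two distinct member ids, all
#'   adults of the same sex.
#' @param sex `"F"` or `"M"`.
#' @param period Optional period label (e.g. a year) identifying the
#'   unit-period the membership snapshot refers to.
#' @return An object of class `kincomp_unit`.
#' @export
social_unit <- function(unit_id, members, sex, period = NA_character_) {
  members <- as.character(members)
  if (length(members) < 2L)
    stop("a social unit needs >= 2 same-sex adult members")
  if (anyDuplicated(members))
    stop("duplicate member id(s): ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'")
  structure(list(unit_id = as.character(unit_id), period = as.character(period),
                 sex = sex, members = members),
            class = "kincomp_unit")
}

#' @export
print.kincomp_unit <- function(x, ...) {
  cat("<social unit> ", x$unit_id,
      if (!is.na(x$period)) paste0(" [", x$period, "]"),
      ": ", length(x$members), " adult ", x$sex, "\n", sep = "")
  invisible(x)
}

#' Filter a membership table down to a same-sex adult social unit
#'
#' Retains adult members of the requested sex. When fewer than two remain
#' the aggregation is not a social unit for that sex (for example a lone
#' adult male attached to a female unit has no same-sex adults to be
#' related or unrelated to) and `NULL` is returned with attribute
#' `"reason" = "NOT_A_UNIT"`.
#'
#' @param members A data frame with columns `id`, `sex` and optionally
#'   `age_class` (`"adult"`/`"immature"`; missing column means all adult,
#'   as most source datasets are pre-filtered to adults).
#' @param sex Sex to retain, `"F"` or `"M"`.
#' @param unit_id,period Labels for the resulting unit.
#' @return A [social_unit()] or `NULL` (NOT_A_UNIT).
#' @export
filter_social_unit <- function(members, sex, unit_id = "unit", period = NA) {
  stopifnot(is.data.frame(members), all(c("id", "sex") %in% names(members)))
  if (!"age_class" %in% names(members)) members$age_class <- "adult"
  dup <- members[duplicated(members$id) | duplicated(members$id, fromLast = TRUE), ]
  if (nrow(dup)) {
    # duplicates allowed only if fully consistent
    chk <- unique(dup[, c("id", "sex", "age_class")])
    if (anyDuplicated(chk$id))
      stop("contradictory duplicate rows for member(s): ",
           paste(unique(chk$id[duplicated(chk$id)]), collapse = ", "))
    members <- members[!duplicated(members$id), ]
  }
  keep <- members$sex == sex & members$age_class == "adult"
  ids <- members$id[keep & !is.na(keep)]
  if (length(ids) < 2L)
    return(structure(list(unit_id = as.character(unit_id), sex = sex,
                          n_candidates = length(ids)),
                     class = "kincomp_not_a_unit"))
  social_unit(unit_id, ids, sex, period)
}

#' Test whether a filtering result is a valid social unit
#'
#' [filter_social_unit()] returns a NOT_A_UNIT sentinel when fewer than two
#' same-sex adults remain; this predicate distinguishes the two outcomes.
#'
#' @param x Result of [filter_social_unit()].
#' @return `TRUE` for a [social_unit()], `FALSE` for the sentinel.
#' @export
is_social_unit <- function(x) inherits(x, "kincomp_unit")

#' @export
print.kincomp_not_a_unit <- function(x, ...) {
  cat("NOT_A_UNIT: ", x$unit_id, " has ", x$n_candidates,
      " adult ", x$sex, " (need >= 2)\n", sep = "")
  invisible(x)
}

.composition_label <- function(n_kin, n_nonkin, n_und) {
  if (n_und > 0L) "INCONCLUSIVE"
  else if (n_nonkin == 0L) "RELATED"
  else if (n_kin == 0L) "UNRELATED"
  else "MIX_RELATED"
}

#' Classify the kinship composition of a social unit
#'
#' Every unordered member dyad is classified with the two-generation kin
#' criterion; the unit is then labelled RELATED (all dyads kin), UNRELATED
#' (all dyads non-kin), MIX_RELATED (both present) or INCONCLUSIVE (at
#' least one dyad undetermined under the strict policy). The continuous
#' alternative, the proportion of kin dyads, is reported alongside and is
#' `NA` when any dyad is undetermined.
#'
#' @param ped A [pedigree()] containing every member.
#' @param unit A [social_unit()].
#' @inheritParams classify_dyad
#' @return A one-row data frame: `unit_id`, `period`, `sex`, `label`,
#'   `proportion_kin`, `n_kin`, `n_nonkin`, `n_undetermined`, `mean_r`.
#' @export
classify_composition <- function(ped, unit, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  stopifnot(inherits(unit, "kincomp_unit"))
  absent <- setdiff(unit$members, ped$id)
  if (length(absent))
    stop("unit member(s) absent from pedigree: ", paste(absent, collapse = ", "))
  st <- classify_all_dyads(ped, unit$members, policy)
  n_kin <- sum(st$status == "KIN")
  n_nonkin <- sum(st$status == "NON_KIN")
  n_und <- sum(st$status == "UNDETERMINED")
  prop <- if (n_und == 0L) n_kin / (n_kin + n_nonkin) else NA_real_
  data.frame(unit_id = unit$unit_id, period = unit$period, sex = unit$sex,
             label = .composition_label(n_kin, n_nonkin, n_und),
             proportion_kin = prop, n_kin = n_kin, n_nonkin = n_nonkin,
             n_undetermined = n_und,
             mean_r = mean_relatedness(ped, unit),
             stringsAsFactors = FALSE)
}

#' Mean pairwise relatedness of a social unit
#'
#' The sum of dyadic relatedness coefficients over all n(n-1)/2 member
#' dyads divided by the number of dyads. A central-tendency summary that
#' deliberately discards the dyad-level information composition retains:
#' two units can share a mean of 0.125 yet have different compositions.
#'
#' @inheritParams classify_composition
#' @return Mean dyadic r.
#' @export
mean_relatedness <- function(ped, unit) {
  stopifnot(inherits(unit, "kincomp_unit"))
  absent <- setdiff(unit$members, ped$id)
  if (length(absent))
    stop("unit member(s) absent from pedigree: ", paste(absent, collapse = ", "))
  r <- relatedness_matrix(ped, unit$members)
  mean(r[upper.tri(r)])
}

#' Classify a unit as mix-related from genetic-cluster evidence
#'
#' For units lacking full pedigrees, marker-based dyadic relatedness
#' estimates can be combined with line labels (suspected matrilines, birth
#' units or breeding lines). If at least one line has positive mean
#' within-line estimated relatedness (a cluster that must contain related
#' dyads) and at least one pair of lines has zero-or-negative mean
#' between-line relatedness (a cluster that must contain unrelated dyads),
#' the unit demonstrably holds both kin and non-kin and is MIX_RELATED.
#' This evidence route can never certify RELATED or UNRELATED, so any
#' other configuration is INCONCLUSIVE.
#'
#' @param evidence A data frame with columns `i`, `j`, `r_hat` (long
#'   dyadic estimates) covering every within-unit dyad.
#' @param unit A [social_unit()].
#' @param lines Named character vector mapping member id to line label.
#' @param epsilon Threshold separating "positive" from "zero/negative"
#'   mean relatedness (default 0, with a 1e-9 numerical tolerance).
#' @return A one-row data frame with `label` (`MIX_RELATED` or
#'   `INCONCLUSIVE`), within- and between-line mean summaries attached as
#'   attribute `"cluster_means"`.
#' @export
classify_from_clusters <- function(evidence, unit, lines, epsilon = 0) {
  stopifnot(inherits(unit, "kincomp_unit"), is.data.frame(evidence),
            all(c("i", "j", "r_hat") %in% names(evidence)))
  mem <- unit$members
  lab <- lines[mem]
  if (anyNA(lab) || length(unique(lab)) < 2L)
    stop("need >= 2 line labels covering all members")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ev <- evidence[!duplicated(key(evidence$i, evidence$j)), ]
  want <- utils::combn(mem, 2L)
  m <- match(key(want[1, ], want[2, ]), key(ev$i, ev$j))
  if (anyNA(m))
    stop("missing relatedness estimate for dyad(s): ",
         paste(want[1, is.na(m)], want[2, is.na(m)], sep = "-", collapse = ", "))
  r <- ev$r_hat[m]
  li <- lab[want[1, ]]; lj <- lab[want[2, ]]
  tol <- 1e-9
  within <- tapply(r[li == lj], li[li == lj], mean)
  between <- tapply(r[li != lj], key(li[li != lj], lj[li != lj]), mean)
  has_pos_within <- length(within) > 0 && any(within > epsilon + tol)
  has_nonpos_between <- length(between) > 0 && any(between <= epsilon + tol)
  label <- if (has_pos_within && has_nonpos_between) "MIX_RELATED" else "INCONCLUSIVE"
  out <- data.frame(unit_id = unit$unit_id, period = unit$period,
                    sex = unit$sex, label = label,
                    proportion_kin = NA_real_,
                    n_kin = NA_integer_, n_nonkin = NA_integer_,
                    n_undetermined = NA_integer_, mean_r = mean(r),
                    stringsAsFactors = FALSE)
  attr(out, "cluster_means") <- list(within = within, between = between)
  out
}

#' Read a unit membership table
#'
#' CSV with columns `unit_id`, `period`, `individual_id`, `sex`,
#' `age_class`.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
load_unit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("unit_id", "period", "individual_id", "sex", "age_class")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("unit table lacks column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' Write composition results as CSV
#'
#' @param results Data frame of rows from [classify_composition()].
#' @param path Output file.
#' @export
write_composition <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
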