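# Two-generation categorical kin criterion: a dyad is kin if it is
# parent-offspring, grandparent-grandoffspring, or the two individuals
# share at least one known parent or known grandparent. Deeper ancestry is
# deliberately ignored; this keeps the criterion usable with the shallow
# pedigrees available for most wild populations while staying conservative
# relative to the r >= 0.125 kin-bias threshold.

.KIN_BASES <- c("PARENT_OFFSPRING", "GRANDPARENT_GRANDOFFSPRING",
                "SHARED_PARENT", "SHARED_GRANDPARENT")

#' Classify a same-sex dyad as kin or non-kin
#'
#' Applies the two-generation criterion: KIN if one individual is the
#' other's parent or grandparent, or if the two share a known parent or a
#' known grandparent. When no criterion is met the outcome depends on the
#' completeness policy: under `"strict"` a dyad is called NON_KIN only when
#' both individuals have complete depth-two ancestry (both parent links and
#' all four grandparent links known), and is UNDETERMINED otherwise; under
#' `"permissive"` any dyad with no shared known ancestor is NON_KIN.
#' Absence of evidence differs from evidence of absence, and the two
#' policies make that distinction explicit.
#'
#' @param ped A [pedigree()].
#' @param i,j Distinct individual ids.
#' @param policy `"strict"` (default) or `"permissive"`.
#' @return A one-row data frame with columns `i`, `j`, `status`
#'   (`KIN`/`NON_KIN`/`UNDETERMINED`) and `basis` (the first satisfied
#'   criterion, or `NO_SHARED_KNOWN_ANCESTOR` / `INSUFFICIENT_PEDIGREE`).
#' @export
classify_dyad <- function(ped, i, j, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  if (identical(i, j)) stop("a dyad requires two distinct individuals: ", i)
  .ped_index(ped, c(i, j))
  ai <- ancestors_to_depth2(ped, i)
  aj <- ancestors_to_depth2(ped, j)
  basis <-
    if (i %in% aj$parents || j %in% ai$parents) "PARENT_OFFSPRING"
    else if (i %in% aj$grandparents || j %in% ai$grandparents) "GRANDPARENT_GRANDOFFSPRING"
    else if (length(intersect(ai$parents, aj$parents))) "SHARED_PARENT"
    else if (length(intersect(c(ai$parents, ai$grandparents),
                              c(aj$parents, aj$grandparents)))) "SHARED_GRANDPARENT"
    else NA_character_
  if (!is.na(basis)) {
    status <- "KIN"
  } else if (policy == "permissive" ||
             (.depth2_complete(ped, i) && .depth2_complete(ped, j))) {
    status <- "NON_KIN"
    basis <- "NO_SHARED_KNOWN_ANCESTOR"
  } else {
    status <- "UNDETERMINED"
    basis <- "INSUFFICIENT_PEDIGREE"
  }
  data.frame(i = i, j = j, status = status, basis = basis,
             stringsAsFactors = FALSE)
}

# complete depth-2 ancestry: both parent links known and all four
# grandparent links known (grandparents need not be distinct individuals)
.depth2_complete <- function(ped, id) {
  k <- match(id, ped$id)
  par <- c(ped$dam[k], ped$sire[k])
  if (anyNA(par)) return(FALSE)
  pk <- match(par, ped$id)
  !anyNA(c(ped$dam[pk], ped$sire[pk]))
}

#' Classify every unordered dyad among a set of individuals
#'
#' @param ped A [pedigree()].
#' @param ids At least two distinct individual ids.
#' @inheritParams classify_dyad
#' @return A data frame with one row per unordered pair, n(n-1)/2 rows,
#'   columns as in [classify_dyad()].
#' @export
classify_all_dyads <- function(ped, ids, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ids must be distinct")
  if (length(ids) < 2L) stop("need at least 2 ids, got ", length(ids))
  pairs <- utils::combn(ids, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k)
    classify_dyad(ped, pairs[1, k], pairs[2, k], policy)))
  rownames(out) <- NULL
  out
}

#' Write dyad classifications to a long CSV
#'
#' @param statuses Output of [classify_all_dyads()].
#' @param path Output file.
#' @export
write_dyad_status <- function(statuses, path) {
  utils::write.csv(statuses[, c("i", "j", "status", "basis")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
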