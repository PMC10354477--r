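#' @keywords internal
"_PACKAGE"

# Unknown parent / field sentinel used in text files: "." or empty string.
# Internally unknowns are NA_character_.

.as_unknown_na <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "."] <- NA_character_
  x
}

#' Construct a pedigree
#'
#' A pedigree is a validated table of individuals with (possibly unknown)
#' dam and sire links, sex, and natal-unit (matriline) labels. Parents that
#' are referenced but have no record of their own are added automatically
#' as founders and reported with a warning, mirroring how field pedigrees
#' treat immigrants and individuals of unknown origin.
#'
#' @param id Character vector of unique individual identifiers.
#' @param dam,sire Character vectors of parent identifiers; `NA`, `"."` or
#'   `""` mean unknown.
#' @param sex Character vector, `"F"`, `"M"` or unknown.
#' @param birth_unit Optional character vector of natal unit / matriline
#'   labels (unknown allowed).
#' @return An object of class `kincomp_pedigree`: a data frame with columns
#'   `id`, `dam`, `sire`, `sex`, `birth_unit`, plus attributes `topo_order`
#'   (topological evaluation order, ancestors first) and `auto_founders`
#'   (ids of records created to back referenced-but-absent parents).
#' @examples
#' ped <- pedigree(id = c("A", "B"), dam = c(NA, "A"), sire = c(NA, NA),
#'                 sex = c("F", "F"))
#' relatedness(ped, "A", "B")
#' @export
pedigree <- function(id, dam = NA, sire = NA, sex = NA, birth_unit = NA) {
  id <- as.character(id)
  n <- length(id)
  dam <- rep_len(.as_unknown_na(dam), n)
  sire <- rep_len(.as_unknown_na(sire), n)
  sex <- rep_len(.as_unknown_na(sex), n)
  birth_unit <- rep_len(.as_unknown_na(birth_unit), n)

  if (anyNA(id) || any(id == "" | id == "."))
    stop("individual ids must be non-missing")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate individual id(s): ", paste(dup, collapse = ", "))
  bad_sex <- !is.na(sex) & !sex %in% c("F", "M")
  if (any(bad_sex))
    stop("invalid sex value(s): ", paste(unique(sex[bad_sex]), collapse = ", "))

  # auto-create founder records for referenced-but-absent parents
  miss_dam <- setdiff(stats::na.omit(dam), id)
  miss_sire <- setdiff(stats::na.omit(sire), id)
  auto <- unique(c(miss_dam, miss_sire))
  if (length(auto)) {
    warning(length(auto), " referenced parent(s) without a record added as founder(s): ",
            paste(auto, collapse = ", "))
    id <- c(id, auto)
    dam <- c(dam, rep(NA_character_, length(auto)))
    sire <- c(sire, rep(NA_character_, length(auto)))
    sex <- c(sex, ifelse(auto %in% miss_dam & !auto %in% miss_sire, "F",
                         ifelse(auto %in% miss_sire & !auto %in% miss_dam, "M",
                                NA_character_)))
    birth_unit <- c(birth_unit, rep(NA_character_, length(auto)))
  }
  self_parent <- id[!is.na(dam) & dam == id | !is.na(sire) & sire == id]
  if (length(self_parent))
    stop("individual(s) recorded as own parent: ",
         paste(self_parent, collapse = ", "))

  ord <- .topo_order(id, dam, sire)

  ped <- data.frame(id = id, dam = dam, sire = sire, sex = sex,
                    birth_unit = birth_unit, stringsAsFactors = FALSE)
  attr(ped, "topo_order") <- ord
  attr(ped, "auto_founders") <- auto
  class(ped) <- c("kincomp_pedigree", "data.frame")
  ped
}

# Kahn topological sort, ancestors first; names a cycle path on failure.
.topo_order <- function(id, dam, sire) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  pd <- ifelse(is.na(dam), NA_integer_, idx[dam])
  ps <- ifelse(is.na(sire), NA_integer_, idx[sire])
  indeg <- integer(n)  # number of unprocessed parents
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(pd[i], ps[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    leftover <- setdiff(idx, out)
    # walk parent links among leftover nodes until a repeat: that is a cycle
    v <- leftover[[1]]
    path <- v
    repeat {
      nxt <- c(pd[v], ps[v])
      nxt <- nxt[!is.na(nxt) & nxt %in% leftover]
      v <- nxt[[1]]
      if (v %in% path) {
        cyc <- c(path[which(path == v):length(path)], v)
        stop("pedigree contains an ancestry cycle: ",
             paste(id[cyc], collapse = " -> "))
      }
      path <- c(path, v)
    }
  }
  out
}

#' Read a pedigree from a tab-separated file
#'
#' The file must have a header with columns `id`, `dam`, `sire`, `sex` and
#' optionally `birth_unit`; `.` or empty fields denote unknown.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A [pedigree()] object.
#' @export
load_pedigree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("id", "dam", "sire", "sex")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("pedigree file lacks column(s): ", paste(missing_cols, collapse = ", "))
  bu <- if ("birth_unit" %in% names(df)) df$birth_unit else NA
  pedigree(df$id, df$dam, df$sire, df$sex, bu)
}

#' @export
print.kincomp_pedigree <- function(x, ...) {
  cat("<pedigree> ", nrow(x), " individuals (",
      sum(is.na(x$dam) & is.na(x$sire)), " founders, ",
      length(attr(x, "auto_founders")), " auto-created)\n", sep = "")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

.ped_index <- function(ped, ids, arg = "id") {
  idx <- match(ids, ped$id)
  if (anyNA(idx))
    stop("unknown ", arg, "(s) not in pedigree: ",
         paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Known parents and grandparents of an individual
#'
#' Returns the depth-two ancestor closure: the known parents and the known
#' parents of known parents. Unknown links contribute nothing, so a founder
#' has empty sets.
#'
#' @param ped A [pedigree()].
#' @param id A single individual id.
#' @return A list with character vectors `parents` and `grandparents`.
#' @export
ancestors_to_depth2 <- function(ped, id) {
  stopifnot(length(id) == 1L)
  i <- .ped_index(ped, id)
  parents <- stats::na.omit(c(ped$dam[i], ped$sire[i]))
  gp <- character(0)
  for (p in parents) {
    k <- match(p, ped$id)
    gp <- c(gp, ped$dam[k], ped$sire[k])
  }
  list(parents = as.character(unique(parents)),
       grandparents = as.character(unique(stats::na.omit(gp))))
}

#' Kinship matrix of a pedigree
#'
#' Computes the full matrix of kinship coefficients f by the standard
#' tabular recursion in topological order: f(i,i) = (1 + f(dam_i, sire_i))/2
#' and, for j processed before i, f(i,j) = (f(dam_i, j) + f(sire_i, j))/2,
#' with unknown parents contributing zero. Founders are taken to be
#' mutually unrelated and non-inbred.
#'
#' @param ped A [pedigree()].
#' @param ids Optional subset of ids for the returned matrix (computation
#'   always runs over the whole pedigree).
#' @return A symmetric numeric matrix of kinship coefficients with id
#'   dimnames.
#' @export
kinship_matrix <- function(ped, ids = NULL) {
  n <- nrow(ped)
  ord <- attr(ped, "topo_order")
  pd <- match(ped$dam, ped$id)
  ps <- match(ped$sire, ped$id)
  f <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  pos <- integer(n)  # processing rank
  pos[ord] <- seq_len(n)
  for (step in seq_len(n)) {
    i <- ord[step]
    d <- pd[i]; s <- ps[i]
    fds <- if (!is.na(d) && !is.na(s)) f[d, s] else 0
    f[i, i] <- 0.5 * (1 + fds)
    earlier <- ord[seq_len(step - 1L)]
    if (length(earlier)) {
      fd <- if (!is.na(d)) f[d, earlier] else 0
      fs <- if (!is.na(s)) f[s, earlier] else 0
      v <- 0.5 * (fd + fs)
      f[i, earlier] <- v
      f[earlier, i] <- v
    }
  }
  if (!is.null(ids)) {
    idx <- .ped_index(ped, ids)
    f <- f[idx, idx, drop = FALSE]
  }
  f
}

#' Kinship coefficient between two individuals
#'
#' @param ped A [pedigree()].
#' @param i,j Individual ids.
#' @return The kinship coefficient f(i, j) in `[0, 1]`.
#' @export
kinship_coefficient <- function(ped, i, j) {
  idx <- .ped_index(ped, c(i, j))
  f <- kinship_matrix(ped)
  f[idx[1], idx[2]]
}

#' Pairwise relatedness
#'
#' Numerator relatedness r = 2 f(i, j). With `normalized = TRUE` the
#' coefficient is divided by sqrt((1 + F_i)(1 + F_j)), where F is the
#' pedigree inbreeding coefficient; the default leaves inbreeding
#' unnormalized because comparative pedigrees typically treat founders as
#' outbred.
#'
#' @param ped A [pedigree()].
#' @param i,j Individual ids.
#' @param normalized Divide by the inbreeding normalizer (default `FALSE`).
#' @return Dyadic relatedness; 0.5 for parent-offspring, 0.125 for first
#'   cousins, 0 for unrelated founders.
#' @export
relatedness <- function(ped, i, j, normalized = FALSE) {
  idx <- .ped_index(ped, c(i, j))
  f <- kinship_matrix(ped)
  r <- 2 * f[idx[1], idx[2]]
  if (normalized) {
    Fi <- 2 * f[idx[1], idx[1]] - 1
    Fj <- 2 * f[idx[2], idx[2]] - 1
    r <- r / sqrt((1 + Fi) * (1 + Fj))
  }
  r
}

#' Relatedness matrix
#'
#' @inheritParams relatedness
#' @param ids Optional id subset.
#' @return Symmetric matrix of 2 f(i, j); the diagonal holds 1 + F_i.
#' @export
relatedness_matrix <- function(ped, ids = NULL, normalized = FALSE) {
  f <- kinship_matrix(ped, ids)
  r <- 2 * f
  if (normalized) {
    s <- sqrt(diag(r))  # sqrt(1 + F_i)
    r <- r / tcrossprod(s)
  }
  r
}

#' Write a square relatedness matrix as CSV
#'
#' Square CSV with a header row and a leading id column; values are written
#' to six decimal places.
#'
#' @param ped A [pedigree()].
#' @param path Output file.
#' @param ids Optional id subset.
#' @export
write_relatedness_matrix <- function(ped, path, ids = NULL) {
  r <- relatedness_matrix(ped, ids)
  out <- data.frame(id = rownames(r),
                    format(round(r, 6), nsmall = 6, trim = TRUE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("id", colnames(r))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
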