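# Pairwise genealogical distances on the 1-10 relatedness scale and the
# derived trait/environment pairwise-difference tables.
#
# Scale semantics: 1 = potential dialects of one language; 2-8 = closer to
# more distant relationships within an accepted family; 9 = strongly divided
# expert opinion about highest-level family membership; 10 = no accepted
# family relationship at all (an isolate scores 10 against every language).

#' Construct a relatedness table
#'
#' Distances are stored sparsely as unordered pairs.  An absent pair is
#' interpreted as distance 10 only when both languages are flagged as
#' belonging to no shared family (via `no_family`); otherwise absent pairs
#' are reported by [validate_relatedness()].
#'
#' @param ids character vector of language ids.
#' @param pairs data frame with columns `id_i`, `id_j`, `d` (integer 1-10).
#'   Both orientations may be present as long as they agree.
#' @param no_family optional character vector of ids treated as sharing no
#'   family with any other language (isolates): all their distances are 10.
#' @return object of class `relatedness_table`.
#' @export
relatedness_table <- function(ids, pairs, no_family = character(0)) {
  stopifnot(!anyDuplicated(ids), all(pairs$id_i %in% ids), all(pairs$id_j %in% ids))
  swap <- pairs$id_i > pairs$id_j
  tmp <- pairs$id_i[swap]
  pairs$id_i[swap] <- pairs$id_j[swap]
  pairs$id_j[swap] <- tmp
  key <- paste(pairs$id_i, pairs$id_j, sep = "\r")
  asymmetries <- character(0)
  if (anyDuplicated(key)) {
    agg <- tapply(pairs$d, key, function(v) length(unique(v)))
    asymmetries <- gsub("\r", "~", names(agg)[agg > 1])
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  structure(
    list(ids = ids,
         pairs = tibble::as_tibble(pairs[c("id_i", "id_j", "d")]),
         no_family = no_family,
         asymmetries = asymmetries),
    class = "relatedness_table"
  )
}

#' @export
print.relatedness_table <- function(x, ...) {
  cat(sprintf("<relatedness_table: %d languages, %d stored pairs>\n",
              length(x$ids), nrow(x$pairs)))
  invisible(x)
}

# distance lookup for all unordered pairs, filling absent pairs with 10 when
# both members are flagged no_family, NA otherwise
relatedness_all_pairs <- function(table) {
  ids <- table$ids
  n <- length(ids)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- tibble::tibble(id_i = ids[idx[, 1]], id_j = ids[idx[, 2]])
  a <- pmin(out$id_i, out$id_j)
  b <- pmax(out$id_i, out$id_j)
  key <- paste(a, b, sep = "\r")
  stored <- stats::setNames(table$pairs$d,
                            paste(table$pairs$id_i, table$pairs$id_j, sep = "\r"))
  out$d <- unname(stored[key])
  # a flagged isolate shares no family with anyone, so the pair scores 10
  fill <- is.na(out$d) &
    (out$id_i %in% table$no_family | out$id_j %in% table$no_family)
  out$d[fill] <- 10L
  out
}

#' Validate a relatedness table
#'
#' Checks the 1-10 range, self-distances, coverage (absent pairs without the
#' no-shared-family flag), and the isolate rule (a flagged isolate must have
#' distance 10 against every other language).
#'
#' @param table a [relatedness_table()].
#' @return character vector of problems; empty if valid.
#' @export
validate_relatedness <- function(table) {
  problems <- character(0)
  if (length(table$asymmetries) > 0) {
    problems <- c(problems, sprintf("asymmetric distances for pairs: %s",
                                    paste(utils::head(table$asymmetries, 5),
                                          collapse = ", ")))
  }
  p <- table$pairs
  self <- p$id_i == p$id_j
  if (any(self)) {
    problems <- c(problems, sprintf("self-distance stored for: %s",
                                    paste(unique(p$id_i[self]), collapse = ", ")))
  }
  bad <- !is.na(p$d) & (p$d < 1 | p$d > 10 | p$d != round(p$d))
  if (any(bad)) {
    problems <- c(problems,
                  sprintf("values outside 1-10 for %d pair(s)", sum(bad)))
  }
  all_pairs <- relatedness_all_pairs(table)
  n_absent <- sum(is.na(all_pairs$d))
  if (n_absent > 0) {
    problems <- c(problems,
                  sprintf("%d pair(s) absent without a no-shared-family flag", n_absent))
  }
  iso <- table$no_family
  if (length(iso) > 0) {
    viol <- all_pairs$d != 10 & !is.na(all_pairs$d) &
      (all_pairs$id_i %in% iso | all_pairs$id_j %in% iso)
    if (any(viol)) {
      problems <- c(problems,
                    sprintf("isolate with non-10 distance in %d pair(s)", sum(viol)))
    }
  }
  problems
}

#' Label a relatedness distance class
#'
#' Endpoint labels follow common usage: 1 = "Dialect", 2 = "Close",
#' 8 = "Distant", 9 = "Divided Opinions"; intermediate values 3-7 are
#' labelled "Level 3" ... "Level 7".  Distance 10 (unrelated) has no class
#' and is rejected.
#'
#' @param d integer distances in 1-9.
#' @return character labels.
#' @export
label_distance_class <- function(d) {
  if (any(!d %in% 1:9)) {
    stop("distance class labels are defined for d in 1-9 only", call. = FALSE)
  }
  labs <- c("Dialect", "Close", "Level 3", "Level 4", "Level 5",
            "Level 6", "Level 7", "Distant", "Divided Opinions")
  labs[d]
}

#' Pairwise absolute differences of a variable between related languages
#'
#' For every unordered language pair with relatedness distance 1-9 (pairs
#' with d = 10, i.e. unrelated, are excluded) returns the absolute difference
#' of the supplied variable.  Pairs where either language has a missing value
#' are dropped and counted in the `n_dropped_missing` attribute.
#'
#' @param values named numeric vector (names = language ids).
#' @param table a [relatedness_table()].
#' @param include_dialects keep pairs with d = 1 (default `TRUE`).
#' @return tibble with `id_i`, `id_j`, `d`, `class_label`, `diff`.
#' @export
pairwise_differences <- function(values, table, include_dialects = TRUE) {
  if (is.null(names(values)) || sum(names(values) %in% table$ids) < 2) {
    stop("values must be named by language id and cover at least 2 languages",
         call. = FALSE)
  }
  all_pairs <- relatedness_all_pairs(table)
  keep <- !is.na(all_pairs$d) & all_pairs$d <= 9
  if (!include_dialects) keep <- keep & all_pairs$d > 1
  p <- all_pairs[keep, , drop = FALSE]
  xi <- values[p$id_i]
  xj <- values[p$id_j]
  miss <- is.na(xi) | is.na(xj)
  out <- tibble::tibble(
    id_i = p$id_i[!miss], id_j = p$id_j[!miss], d = as.integer(p$d[!miss]),
    class_label = label_distance_class(p$d[!miss]),
    diff = unname(abs(xi[!miss] - xj[!miss]))
  )
  attr(out, "n_dropped_missing") <- sum(miss)
  out
}

#' Per-class summaries of pairwise differences
#'
#' One row per occupied distance class with the boxplot-style statistics used
#' to display pairwise differences by relatedness: n, median, quartiles
#' (type-7 by default) and Tukey whisker bounds at 1.5 IQR.
#'
#' @param pairs output of [pairwise_differences()].
#' @param quantile_type quantile algorithm passed to [stats::quantile()].
#' @return tibble ordered by distance value.
#' @export
summarize_by_class <- function(pairs, quantile_type = 7) {
  if (nrow(pairs) == 0) stop("empty pair table", call. = FALSE)
  ds <- sort(unique(pairs$d))
  rows <- lapply(ds, function(dv) {
    x <- pairs$diff[pairs$d == dv]
    s <- boxplot_stats(x, quantile_type = quantile_type)
    tibble::tibble(d = dv, class_label = label_distance_class(dv),
                   n = s$n, median = s$median, q1 = s$q1, q3 = s$q3,
                   whisker_lo = s$whisker_lo, whisker_hi = s$whisker_hi)
  })
  do.call(rbind, rows)
}

#' Read / write relatedness tables as long-format CSV
#'
#' Long format `id_i,id_j,d`; flagged isolates may be listed in a separate
#' one-column CSV or passed directly.
#'
#' @param path CSV file.
#' @param ids optional explicit id universe (default: ids seen in pairs).
#' @param no_family ids flagged as sharing no family with any other language.
#' @return a [relatedness_table()].
#' @export
read_relatedness_csv <- function(path, ids = NULL, no_family = character(0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id_i", "id_j", "d") %in% names(df)))
  if (is.null(ids)) ids <- sort(unique(c(df$id_i, df$id_j, no_family)))
  relatedness_table(ids, df, no_family = no_family)
}

#' @rdname read_relatedness_csv
#' @param table a [relatedness_table()] to write.
#' @export
write_relatedness_csv <- function(table, path) {
  utils::write.csv(table$pairs, path, row.names = FALSE)
  invisible(path)
}
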