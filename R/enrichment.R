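## Hypergeometric gene-set over-representation with BH adjustment.

#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of drawing at least \code{k} members of a set of size
#' \code{K} when sampling \code{n} genes without replacement from a universe
#' of \code{N}: \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}.
#'
#' @param N universe size.
#' @param K set size.
#' @param n query size.
#' @param k observed overlap.
#' @return the upper-tail p-value (1 when \code{k} = 0).
#' @export
hypergeom_overrep <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values (monotone in sorted order, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Gene-set collection
#'
#' @param universe character vector of background gene ids.
#' @param sets named list of gene-id vectors; members outside the universe
#'   are dropped.
#' @return a \code{GeneSetCollection} list.
#' @export
gene_set_collection <- function(universe, sets) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named", call. = FALSE)
  universe <- unique(universe)
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  structure(list(universe = universe, sets = sets),
            class = "GeneSetCollection")
}

#' Over-representation of a query gene list in each set of a collection
#'
#' One upper-tail hypergeometric test per named set, BH-adjusted across the
#' collection. Query genes outside the universe are dropped with a warning.
#'
#' @param query character vector of gene ids.
#' @param collection a \code{\link{gene_set_collection}}.
#' @return \code{EnrichmentResult} data.frame: \code{set_name}, \code{N},
#'   \code{K}, \code{n}, \code{k}, \code{p_value}, \code{fdr}, sorted by
#'   p-value.
#' @export
enrich_sets <- function(query, collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  query <- unique(query)
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0) {
    warning(length(outside), " query genes outside the universe were dropped")
    query <- intersect(query, collection$universe)
  }
  N <- length(collection$universe)
  n <- length(query)
  res <- data.frame(
    set_name = names(collection$sets),
    N = N,
    K = vapply(collection$sets, length, integer(1)),
    n = n,
    k = vapply(collection$sets, function(s) length(intersect(s, query)), integer(1)),
    stringsAsFactors = FALSE)
  res$p_value <- mapply(hypergeom_overrep, res$N, res$K, res$n, res$k)
  res$fdr <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Union the target sets of multiple mature forms of one miRNA
#'
#' Mature-form target lists (e.g. -5p/-3p) of the same hairpin are combined
#' before testing.
#'
#' @param sets named list of target-id vectors.
#' @param groups named list: hairpin name -> character vector of mature-form
#'   names present in \code{sets}.
#' @return named list of unioned target sets, one per hairpin.
#' @export
combine_mirna_targets <- function(sets, groups) {
  lapply(groups, function(members) {
    missing <- setdiff(members, names(sets))
    if (length(missing) > 0)
      stop("unknown mature forms: ", paste(missing, collapse = ", "), call. = FALSE)
    sort(unique(unlist(sets[members], use.names = FALSE)))
  })
}
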