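#' Construct a weighted functional gene network
#'
#' A functional gene network is an undirected graph over genes whose edge
#' weights are log likelihood scores (LLS) expressing confidence that the
#' two genes act in the same biological process. The network carries no
#' self-edges and at most one edge per unordered gene pair; this property
#' is what makes summed-edge-weight scoring of a seed set an implicit
#' leave-one-out cross-validation (see [score_vector()]).
#'
#' Self-edges in the input are dropped with a warning. Duplicate unordered
#' pairs are collapsed to a single edge keeping the maximum weight; a
#' warning is emitted when the duplicates disagree on the weight.
#'
#' @param edges data frame whose first three columns are gene A, gene B and
#'   the LLS weight (finite, non-negative). Extra columns are ignored.
#' @param genes optional character vector of gene identifiers to include in
#'   the network even when they have no incident edge (e.g. the full assayed
#'   gene universe). Identifiers are trimmed; comparison is case-sensitive.
#' @return An object of class `functional_network` with components
#'   `genes` (sorted character vector), `edges` (data frame `a`, `b`, `lls`
#'   with `a < b`) and a sparse symmetric adjacency matrix used internally.
#' @examples
#' net <- functional_network(data.frame(a = c("G1", "G2"),
#'                                      b = c("G2", "G3"),
#'                                      lls = c(1.5, 2)))
#' net
#' @export
functional_network <- function(edges, genes = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 3L) {
    stop("`edges` must be a data frame with >= 3 columns (gene A, gene B, weight)",
         call. = FALSE)
  }
  a <- trimws(as.character(edges[[1L]]))
  b <- trimws(as.character(edges[[2L]]))
  w <- edges[[3L]]
  if (!is.numeric(w)) stop("edge weights must be numeric", call. = FALSE)
  w <- as.double(w)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("empty gene identifier in edge list", call. = FALSE)
  }
  if (any(!is.finite(w))) stop("edge weights must be finite", call. = FALSE)
  if (any(w < 0)) stop("edge weights (LLS) must be >= 0", call. = FALSE)

  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped", call. = FALSE)
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    agg_max <- tapply(w, key, max)
    agg_min <- tapply(w, key, min)
    if (any(agg_max != agg_min)) {
      warning("duplicate edges with conflicting weights collapsed to the maximum",
              call. = FALSE)
    }
    first <- !duplicated(key)
    lo <- lo[first]; hi <- hi[first]
    w <- as.double(agg_max[key[first]])
    key <- key[first]
  }
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]; w <- w[ord]

  all_genes <- sort(unique(c(lo, hi, if (!is.null(genes)) trimws(as.character(genes)))))
  all_genes <- all_genes[nzchar(all_genes)]
  idx <- seq_along(all_genes)
  names(idx) <- all_genes
  n <- length(all_genes)
  adj <- Matrix::sparseMatrix(
    i = c(idx[lo], idx[hi]), j = c(idx[hi], idx[lo]),
    x = c(w, w), dims = c(n, n), dimnames = list(all_genes, all_genes)
  )
  structure(
    list(genes = all_genes,
         edges = data.frame(a = lo, b = hi, lls = w, stringsAsFactors = FALSE),
         adjacency = adj),
    class = "functional_network"
  )
}

#' @export
print.functional_network <- function(x, ...) {
  cat("functional gene network:", length(x$genes), "genes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    cat("  LLS range: [", format(min(x$edges$lls)), ", ",
        format(max(x$edges$lls)), "]\n", sep = "")
  }
  invisible(x)
}

#' Genes of a functional network
#' @param network a [functional_network()] object.
#' @return Character vector of gene identifiers.
#' @export
network_genes <- function(network) {
  stopifnot(inherits(network, "functional_network"))
  network$genes
}

#' Edge weight lookup
#'
#' Weight of the edge between two genes, 0 when no edge exists (including
#' when either gene is absent from the network).
#'
#' @param network a [functional_network()] object.
#' @param a,b gene identifiers (vectorised).
#' @return Numeric vector of LLS weights.
#' @export
edge_weight <- function(network, a, b) {
  stopifnot(inherits(network, "functional_network"))
  a <- trimws(as.character(a)); b <- trimws(as.character(b))
  out <- numeric(length(a))
  ia <- match(a, network$genes); ib <- match(b, network$genes)
  ok <- !is.na(ia) & !is.na(ib) & a != b
  if (any(ok)) out[ok] <- network$adjacency[cbind(ia[ok], ib[ok])]
  out
}

#' Genetic interaction degree
#'
#' Number of distinct interaction partners of each gene in an interaction
#' table, optionally restricted to one interaction class. The degree of a
#' gene absent from every record is 0.
#'
#' @param interactions a [gi_table()] of interaction records.
#' @param gene optional gene identifier(s); when `NULL`, degrees of all
#'   genes appearing in the (filtered) table are returned.
#' @param interaction_type optional class label (matched case-insensitively
#'   after trimming); `NULL` pools all classes.
#' @return Named integer vector of degrees.
#' @export
gi_degree <- function(interactions, gene = NULL, interaction_type = NULL) {
  x <- as.data.frame(interactions)
  if (!is.null(interaction_type)) {
    x <- x[tolower(trimws(x$type)) == tolower(trimws(interaction_type)), , drop = FALSE]
  }
  # distinct partners regardless of class: collapse to unique unordered pairs
  if (nrow(x)) {
    keep <- !duplicated(pair_key(x$a, x$b))
    x <- x[keep, , drop = FALSE]
  }
  deg <- table(c(x$a, x$b))
  out <- stats::setNames(as.integer(deg), names(deg))
  if (is.null(gene)) return(out[order(names(out))])
  gene <- trimws(as.character(gene))
  res <- stats::setNames(integer(length(gene)), gene)
  hit <- gene %in% names(out)
  res[hit] <- out[gene[hit]]
  res
}
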