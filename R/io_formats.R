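#' Genetic interaction record table
#'
#' Canonical container for genetic interaction records: unordered gene
#' pairs annotated with an interaction class label (e.g. "Synthetic
#' Lethality", "Phenotypic Enhancement"), an organism label and an optional
#' publication year. Records are deduplicated per (unordered pair, class);
#' when duplicates disagree on the year the earliest year is kept, so that
#' a year-cutoff circularity filter removes a pair whenever any record of
#' it predates the cutoff. Self-pairs are dropped with a warning.
#'
#' @param a,b gene identifiers of the two interactors.
#' @param type interaction class label (arbitrary; matched
#'   case-insensitively by downstream filters).
#' @param organism organism/taxon label.
#' @param year optional integer publication year (`NA` when unknown).
#' @param quiet suppress the self-pair warning.
#' @return Data frame of class `gi_table` with columns `a`, `b` (with
#'   `a < b`), `type`, `organism`, `year`.
#' @export
gi_table <- function(a, b, type, organism = NA_character_, year = NA_integer_,
                     quiet = FALSE) {
  a <- trimws(as.character(a)); b <- trimws(as.character(b))
  type <- trimws(as.character(type))
  if (length(a) != length(b)) stop("`a` and `b` lengths differ", call. = FALSE)
  n <- length(a)
  df <- data.frame(a = a, b = b, type = rep_len(type, n),
                   organism = rep_len(trimws(as.character(organism)), n),
                   year = rep_len(suppressWarnings(as.integer(year)), n),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$a)) || any(!nzchar(df$b))) {
    stop("empty gene identifier in interaction records", call. = FALSE)
  }
  self <- df$a == df$b
  if (any(self)) {
    if (!quiet) warning(sum(self), " self-interaction row(s) dropped", call. = FALSE)
    df <- df[!self, , drop = FALSE]
  }
  lo <- pmin(df$a, df$b); hi <- pmax(df$a, df$b)
  df$a <- lo; df$b <- hi
  key <- paste(pair_key(df$a, df$b), tolower(df$type), sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, df$year, na.last = TRUE)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(key[ord]), , drop = FALSE]
  }
  df <- df[order(df$a, df$b, df$type), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gi_table", "data.frame")
  df
}

#' Column map for BioGRID TAB 2.0 interaction files
#'
#' Maps the fields required by [read_interactions()] to BioGRID TAB 2.0
#' header names. Supply your own named character vector to read other
#' dialects; required names are `a`, `b`, `type`, `organism`, with `year`
#' optional.
#' @return Named character vector.
#' @export
biogrid_colmap <- function() {
  c(a = "Official Symbol Interactor A",
    b = "Official Symbol Interactor B",
    type = "Experimental System",
    organism = "Organism Interactor A",
    year = "Publication Year")
}

#' Read a functional network edge list
#'
#' Tab-delimited file with at least three columns (gene A, gene B, LLS
#' weight); lines starting with `#` are comments. Self-edges are dropped
#' with a warning; duplicate unordered pairs keep the maximum weight.
#'
#' @param path file path.
#' @param weight_floor optional minimum LLS; rows with a weight strictly
#'   below it are dropped before the network is assembled.
#' @param genes optional extra gene identifiers to carry as isolated nodes.
#' @return A [functional_network()].
#' @export
read_network <- function(path, weight_floor = NULL, genes = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty network file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L)) {
    bad <- lineno[which(ncols < 3L)[1L]]
    stop("malformed network row (needs >= 3 tab-separated columns) at line ",
         bad, " of ", path, call. = FALSE)
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w)) {
    bad <- lineno[which(is.na(w))[1L]]
    stop("non-numeric edge weight at line ", bad, " of ", path, call. = FALSE)
  }
  df <- data.frame(a = a, b = b, lls = w, stringsAsFactors = FALSE)
  if (!is.null(weight_floor)) df <- df[df$lls >= weight_floor, , drop = FALSE]
  if (!nrow(df)) stop("no edges survive the weight floor in ", path, call. = FALSE)
  functional_network(df, genes = genes)
}

#' Write a functional network edge list
#'
#' Inverse of [read_network()]: one tab-separated row per edge, preceded by
#' a `#`-comment header.
#'
#' @param network a [functional_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "functional_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gene_a\tgene_b\tlls", con)
  if (nrow(network$edges)) {
    writeLines(sprintf("%s\t%s\t%s", network$edges$a, network$edges$b,
                       formatC(network$edges$lls, digits = 15, format = "g")),
               con)
  }
  invisible(path)
}

#' Read genetic interaction records
#'
#' Tab-delimited file with a header. The `col_map` (default:
#' [biogrid_colmap()], matching BioGRID TAB 2.0) names the columns holding
#' the two interactors, the experimental-system class label, the organism
#' and optionally the publication year. Records are canonicalised and
#' deduplicated by [gi_table()].
#'
#' @param path file path.
#' @param col_map named character vector with entries `a`, `b`, `type`,
#'   `organism` and optionally `year`.
#' @param interaction_type,organism optional convenience filters, matched
#'   case-insensitively after trimming.
#' @return A [gi_table()].
#' @export
read_interactions <- function(path, col_map = biogrid_colmap(),
                              interaction_type = NULL, organism = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  required <- c("a", "b", "type", "organism")
  missing_map <- setdiff(required, names(col_map))
  if (length(missing_map)) {
    stop("col_map lacks entries: ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(unname(col_map[required]), names(df))
  if (length(missing_cols)) {
    stop("interaction file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  year <- if ("year" %in% names(col_map) && col_map[["year"]] %in% names(df)) {
    df[[col_map[["year"]]]]
  } else {
    NA_integer_
  }
  out <- gi_table(a = df[[col_map[["a"]]]], b = df[[col_map[["b"]]]],
                  type = df[[col_map[["type"]]]],
                  organism = df[[col_map[["organism"]]]], year = year)
  out <- filter_gi(out, interaction_type = interaction_type, organism = organism)
  out
}

#' Write genetic interaction records
#'
#' Emits a BioGRID TAB 2.0-style header (per `col_map`) readable back by
#' [read_interactions()].
#' @param interactions a [gi_table()].
#' @param path output file path.
#' @param col_map as in [read_interactions()].
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path, col_map = biogrid_colmap()) {
  x <- as.data.frame(interactions)
  out <- data.frame(x$a, x$b, x$type, x$organism,
                    ifelse(is.na(x$year), "", as.character(x$year)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- unname(col_map[c("a", "b", "type", "organism", "year")])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Filter interaction records
#'
#' Restrict a [gi_table()] by interaction class, organism (both matched
#' case-insensitively after trimming) and/or publication-year cutoff
#' (records with `year < year_cutoff` are removed; unknown years are
#' kept).
#'
#' @param x a [gi_table()].
#' @param interaction_type,organism,year_cutoff filters; `NULL` disables.
#' @return The filtered [gi_table()].
#' @export
filter_gi <- function(x, interaction_type = NULL, organism = NULL,
                      year_cutoff = NULL) {
  df <- as.data.frame(x)
  if (!is.null(interaction_type)) {
    df <- df[tolower(trimws(df$type)) == tolower(trimws(interaction_type)), ,
             drop = FALSE]
  }
  if (!is.null(organism)) {
    df <- df[tolower(trimws(df$organism)) == tolower(trimws(organism)), ,
             drop = FALSE]
  }
  if (!is.null(year_cutoff)) {
    df <- df[is.na(df$year) | df$year >= year_cutoff, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("gi_table", "data.frame")
  df
}

#' Seed-set construction policy
#'
#' Filters applied when assembling seed sets from interaction records:
#' minimum partner count (seed sets backed by a single interacting pair
#' are uninformative and removed), exclusion of seed-partner pairs that
#' are themselves functional-network edges (circularity guard), an
#' optional publication-year cutoff (records older than the cutoff are
#' excluded, mirroring the yeast protocol where the network was built from
#' pre-2006 evidence), and optional interaction-class / organism
#' restriction.
#'
#' @param min_partners minimum surviving partners per seed (>= 2).
#' @param exclude_pairs_in_network drop seed-partner pairs that are edges
#'   of the functional network.
#' @param year_cutoff optional integer year; records with `year < cutoff`
#'   are excluded (records with unknown year are kept).
#' @param interaction_type optional class label restriction.
#' @param organism optional organism restriction.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_partners = 2L, exclude_pairs_in_network = TRUE,
                          year_cutoff = NULL, interaction_type = NULL,
                          organism = NULL) {
  min_partners <- as.integer(min_partners)
  if (is.na(min_partners) || min_partners < 2L) {
    stop("min_partners must be >= 2", call. = FALSE)
  }
  structure(list(min_partners = min_partners,
                 exclude_pairs_in_network = isTRUE(exclude_pairs_in_network),
                 year_cutoff = if (!is.null(year_cutoff)) as.integer(year_cutoff),
                 interaction_type = interaction_type,
                 organism = organism),
            class = "filter_policy")
}

#' A seed set: a gene and its known interaction partners
#'
#' @param seed the query gene.
#' @param partners character vector of known partners (the seed itself is
#'   removed; duplicates collapse).
#' @param interaction_type class label of the interactions backing the set.
#' @param n_partners_total partner count before network intersection and
#'   edge exclusion (bookkeeping; defaults to `length(partners)`).
#' @param n_dropped_not_in_network,n_dropped_network_edge bookkeeping
#'   counts of partners removed by the two filters.
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(seed, partners, interaction_type = "all",
                     n_partners_total = NULL,
                     n_dropped_not_in_network = 0L,
                     n_dropped_network_edge = 0L) {
  seed <- assert_string(seed, "seed")
  partners <- sort(unique(setdiff(trimws(as.character(partners)), seed)))
  if (length(partners) < 2L) {
    stop("a seed set needs at least two partners (seed ", seed, ")", call. = FALSE)
  }
  structure(list(seed = seed, partners = partners,
                 interaction_type = interaction_type,
                 n_partners_total = n_partners_total %||% length(partners),
                 n_dropped_not_in_network = as.integer(n_dropped_not_in_network),
                 n_dropped_network_edge = as.integer(n_dropped_network_edge)),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("seed set:", x$seed, "[", x$interaction_type, "]",
      length(x$partners), "partners\n")
  invisible(x)
}

#' Assemble seed sets from interaction records
#'
#' Every gene appearing in any record is a potential seed; its partners are
#' the distinct genes recorded opposite it. Filters are applied in a fixed
#' order: (i) interaction-class / organism restriction, (ii) year cutoff,
#' (iii) intersection of partners with the network's gene set (the AUC is
#' computed only over network genes, so out-of-network partners are
#' unusable), (iv) exclusion of seed-partner pairs that are network edges,
#' and finally the minimum-partner rule.
#'
#' @param interactions a [gi_table()].
#' @param network a [functional_network()].
#' @param policy a [filter_policy()].
#' @return List of [seed_set()] objects, ordered by seed identifier.
#' @export
build_seed_sets <- function(interactions, network, policy = filter_policy()) {
  stopifnot(inherits(network, "functional_network"),
            inherits(policy, "filter_policy"))
  x <- filter_gi(interactions, interaction_type = policy$interaction_type,
                 organism = policy$organism, year_cutoff = policy$year_cutoff)
  type_label <- policy$interaction_type %||% "all"
  if (!nrow(x)) return(list())

  long <- data.frame(seed = c(x$a, x$b), partner = c(x$b, x$a),
                     stringsAsFactors = FALSE)
  long <- long[!duplicated(paste(long$seed, long$partner, sep = "\r")), ,
               drop = FALSE]
  total <- table(long$seed)

  in_net <- long$partner %in% network$genes
  long_net <- long[in_net, , drop = FALSE]

  if (policy$exclude_pairs_in_network && nrow(network$edges)) {
    edge_keys <- pair_key(network$edges$a, network$edges$b)
    is_edge <- pair_key(long_net$seed, long_net$partner) %in% edge_keys
  } else {
    is_edge <- rep(FALSE, nrow(long_net))
  }
  dropped_edge <- table(long_net$seed[is_edge])
  kept <- long_net[!is_edge, , drop = FALSE]

  if (!nrow(kept)) return(list())
  split_partners <- split(kept$partner, kept$seed)
  seeds <- names(split_partners)
  keep_seed <- lengths(split_partners) >= policy$min_partners
  seeds <- sort(seeds[keep_seed])
  lapply(seeds, function(s) {
    tot <- as.integer(total[s])
    part <- split_partners[[s]]
    n_edge <- if (s %in% names(dropped_edge)) as.integer(dropped_edge[s]) else 0L
    seed_set(seed = s, partners = part, interaction_type = type_label,
             n_partners_total = tot,
             n_dropped_not_in_network = tot - n_edge - length(part),
             n_dropped_network_edge = n_edge)
  })
}

#' Read a protein-complex membership table
#'
#' Two tab-separated columns: complex id and member gene. A header line
#' whose second field is `gene` (any case) is skipped, as are `#` comments.
#' Duplicate memberships collapse. Complexes with fewer than two distinct
#' members are retained but are ineligible for enrichment testing.
#'
#' @param path file path.
#' @return Data frame of class `complex_table` with columns `complex_id`,
#'   `gene`.
#' @export
read_complexes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty complex file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    bad <- lineno[which(lengths(parts) < 2L)[1L]]
    stop("malformed complex row (needs 2 tab-separated columns) at line ",
         bad, " of ", path, call. = FALSE)
  }
  id <- trimws(vapply(parts, `[[`, "", 1L))
  gene <- trimws(vapply(parts, `[[`, "", 2L))
  if (length(id) && tolower(gene[1L]) == "gene") {
    id <- id[-1L]; gene <- gene[-1L]
  }
  complex_table(id, gene)
}

#' Protein-complex membership container
#' @param complex_id complex identifiers (one row per membership).
#' @param gene member gene identifiers.
#' @return Data frame of class `complex_table`.
#' @export
complex_table <- function(complex_id, gene) {
  df <- data.frame(complex_id = trimws(as.character(complex_id)),
                   gene = trimws(as.character(gene)),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$complex_id)) || any(!nzchar(df$gene))) {
    stop("empty identifier in complex table", call. = FALSE)
  }
  df <- df[!duplicated(paste(df$complex_id, df$gene, sep = "\r")), , drop = FALSE]
  df <- df[order(df$complex_id, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("complex_table", "data.frame")
  df
}

#' Complex member lists
#' @param complexes a [complex_table()].
#' @return Named list mapping complex id to its member genes.
#' @export
complex_members <- function(complexes) {
  split(complexes$gene, complexes$complex_id)
}

#' Write a complex membership table
#' @param complexes a [complex_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(complexes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("complex_id\tgene", con)
  if (nrow(complexes)) {
    writeLines(sprintf("%s\t%s", complexes$complex_id, complexes$gene), con)
  }
  invisible(path)
}

#' Read a two-column gene identifier mapping
#'
#' Columns: source id, target id (tab-separated; optional header whose
#' first field is `from`). Sources mapping to more than one distinct target
#' are collisions and are dropped entirely with a warning, so the surviving
#' mapping is a function.
#'
#' @param path file path.
#' @return Data frame with columns `from`, `to`.
#' @export
read_mapping <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty mapping file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    bad <- lineno[which(lengths(parts) < 2L)[1L]]
    stop("malformed mapping row at line ", bad, " of ", path, call. = FALSE)
  }
  from <- trimws(vapply(parts, `[[`, "", 1L))
  to <- trimws(vapply(parts, `[[`, "", 2L))
  if (length(from) && tolower(from[1L]) == "from") {
    from <- from[-1L]; to <- to[-1L]
  }
  df <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  n_targets <- tapply(df$to, df$from, function(v) length(unique(v)))
  collide <- names(n_targets)[n_targets > 1L]
  if (length(collide)) {
    warning(length(collide), " source id(s) with colliding targets dropped",
            call. = FALSE)
    df <- df[!(df$from %in% collide), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Translate gene identifiers through a mapping
#'
#' Identifiers without a mapping entry are left unchanged (harmonization is
#' assumed partial); translation of a network rebuilds it so duplicate
#' translated edges collapse.
#'
#' @param x a character vector, [functional_network()], [gi_table()] or
#'   [complex_table()].
#' @param mapping data frame from [read_mapping()].
#' @return Object of the same class with translated identifiers.
#' @export
translate_genes <- function(x, mapping) {
  UseMethod("translate_genes")
}

#' @export
translate_genes.character <- function(x, mapping) {
  i <- match(x, mapping$from)
  out <- x
  out[!is.na(i)] <- mapping$to[i[!is.na(i)]]
  out
}

#' @export
translate_genes.functional_network <- function(x, mapping) {
  e <- x$edges
  e$a <- translate_genes(e$a, mapping)
  e$b <- translate_genes(e$b, mapping)
  e <- e[e$a != e$b, , drop = FALSE]
  suppressWarnings(
    functional_network(e, genes = unique(translate_genes(x$genes, mapping)))
  )
}

#' @export
translate_genes.gi_table <- function(x, mapping) {
  df <- as.data.frame(x)
  suppressWarnings(
    gi_table(translate_genes(df$a, mapping), translate_genes(df$b, mapping),
             df$type, df$organism, df$year, quiet = TRUE)
  )
}

#' @export
translate_genes.complex_table <- function(x, mapping) {
  complex_table(x$complex_id, translate_genes(x$gene, mapping))
}
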