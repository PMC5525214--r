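# Search orchestration: the phylogeny-aware range-search analysis
# (GNAT/AESA + contextualization) and the coarse Bray-Curtis analysis,
# plus empirical p-values and the phyla-key false-negative evaluation.

#' Package defaults
#'
#' The operating defaults of the search engine: range-search radius,
#' context size k, p-value histogram bins, maximum number of coarse
#' representatives, the radii surfaced by the command line, and the
#' per-method query-count limits.
#'
#' @return A named list.
#' @export
ms_defaults <- function() {
  list(
    radius = 0.3,
    k = 20L,
    pvalue_bins = 10000L,
    max_representatives = 1000L,
    cli_radii = c(0.1, 0.2, 0.3, 0.4),
    max_queries_gnat = 10L,
    max_queries_aesa = 100L
  )
}

#' EMD-UniFrac metric closure over a fixed tree
#'
#' Returns a plain `function(p, q) -> number` suitable for the index
#' builders and searches; profiles prepared with [prepare_relative()]
#' carry cached leaf indices and skip per-call validation.
#'
#' @param tree An `ms_tree`.
#' @return A metric function.
#' @export
emd_metric <- function(tree) {
  force(tree)
  function(p, q) {
    a <- attr(p, "ms_prep") %||% profile_leaf_mass(tree, p)
    b <- attr(q, "ms_prep") %||% profile_leaf_mass(tree, q)
    .emd_sparse(tree, a$idx, a$val, b$idx, b$val)$value
  }
}

#' Normalize profiles and cache their tree leaf indices
#'
#' @param tree An `ms_tree`.
#' @param profiles List of count or relative `ms_profile`s.
#' @return Named list of relative profiles with cached index attribute.
#' @export
prepare_relative <- function(tree, profiles) {
  out <- lapply(profiles, function(p) {
    r <- if (abs(p$depth - 1) <= NORM_TOL) p else to_relative(p)
    attr(r, "ms_prep") <- profile_leaf_mass(tree, r)
    r
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "sample_id"))
}

#' Select the contextualization set from per-query search records
#'
#' Database samples must have been compared against every query (the
#' intersection of the records' evaluated sets) so the composed matrix
#' has no missing cells; among those, a sample is retained iff it ranks
#' within the `k` smallest recorded distances of at least one query,
#' ranking restricted to the intersection.
#'
#' @param records List of `ms_search_record`s (one per query).
#' @param k Context size per query (default 20).
#' @return Sorted character vector of database ids. Signals a classed
#'   error (`ms_empty_context`) when the intersection is empty.
#' @export
select_context <- function(records, k = 20L) {
  stopifnot(length(records) >= 1L, k >= 1L)
  inter <- Reduce(intersect, lapply(records, function(r) names(r$evaluated)))
  if (!length(inter)) {
    rlang::abort("no database sample was compared to all queries",
                 class = "ms_empty_context")
  }
  keep <- lapply(records, function(r) {
    d <- r$evaluated[inter]
    inter[order(d, inter)][seq_len(min(k, length(inter)))]
  })
  sort(unique(unlist(keep)))
}

#' Compose the full context distance matrix
#'
#' Builds the symmetric `(|M'| + |N|)`-square matrix contextualization
#' needs, block by block: context-context cells from the precomputed
#' database store, context-query cells from the recorded search
#' evaluations, and query-query cells by calling the metric directly.
#'
#' @param context_ids Database ids M'.
#' @param queries Named list of query profiles N (prepared).
#' @param precalc Symmetric database distance matrix covering M'.
#' @param records Per-query `ms_search_record`s covering M' x N.
#' @param metric Metric function for the query-query block.
#' @return Symmetric matrix with zero diagonal, rows/cols M' then N.
#' @export
assemble_matrix <- function(context_ids, queries, precalc, records, metric) {
  qids <- names(queries)
  if (is.null(precalc)) stop("no precomputed database distances", call. = FALSE)
  validate_dist_matrix(precalc)
  miss <- setdiff(context_ids, rownames(precalc))
  if (length(miss)) {
    stop("precalc store missing sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  all_ids <- c(context_ids, qids)
  full <- matrix(NA_real_, length(all_ids), length(all_ids),
                 dimnames = list(all_ids, all_ids))
  full[context_ids, context_ids] <- precalc[context_ids, context_ids]
  recs <- stats::setNames(records,
                          vapply(records, `[[`, character(1), "query_id"))
  for (qi in qids) {
    ev <- recs[[qi]]$evaluated
    miss <- setdiff(context_ids, names(ev))
    if (length(miss)) {
      stop("record for query ", qi, " missing pair (", qi, ", ",
           miss[1], ")", call. = FALSE)
    }
    full[context_ids, qi] <- ev[context_ids]
    full[qi, context_ids] <- ev[context_ids]
  }
  for (i in seq_along(qids)) {
    full[qids[i], qids[i]] <- 0
    if (i < length(qids)) {
      for (j in seq((i + 1L), length(qids))) {
        d <- metric(queries[[qids[i]]], queries[[qids[j]]])
        full[qids[i], qids[j]] <- full[qids[j], qids[i]] <- d
      }
    }
  }
  validate_dist_matrix(full)
  full
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-0.5 * D^2` and eigendecomposes it (via
#' `stats::cmdscale`). Axes are ordered by eigenvalue; negative
#' eigenvalues (non-Euclidean input) are dropped with a warning.
#'
#' @param m Square symmetric distance matrix with zero diagonal.
#' @param dims Number of requested axes.
#' @return An `ms_pcoa`: tibble of coordinates (`sample_id`, `Axis1`,
#'   ...) with eigenvalues in `attr(, "eigenvalues")`.
#' @export
ms_pcoa <- function(m, dims = 2L) {
  validate_dist_matrix(m)
  n <- nrow(m)
  k <- min(dims, n - 1L)
  fit <- suppressWarnings(stats::cmdscale(m, k = max(k, 1L), eig = TRUE))
  neg <- sum(fit$eig < -1e-12)
  if (neg > 0) {
    warning("dropped ", neg, " negative eigenvalue(s); ",
            "distances are not Euclidean-embeddable", call. = FALSE)
  }
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  if (ncol(pts) == 0L) pts <- matrix(0, n, 1L)  # all points coincide
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  coords <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                             tibble::as_tibble(pts))
  structure(coords, eigenvalues = fit$eig[fit$eig > 1e-12],
            class = c("ms_pcoa", class(coords)))
}

#' @export
tidy.ms_pcoa <- function(x, ...) {
  tibble::as_tibble(unclass(x)[!names(unclass(x)) %in% "eigenvalues"])
}

#' @export
glance.ms_pcoa <- function(x, ...) {
  ev <- attr(x, "eigenvalues")
  tibble::tibble(
    n_samples = nrow(x),
    n_axes = sum(startsWith(names(x), "Axis")),
    prop_axis1 = if (length(ev)) ev[1] / sum(ev) else NA_real_,
    prop_axis2 = if (length(ev) > 1) ev[2] / sum(ev) else NA_real_
  )
}

#' Average-linkage (UPGMA) clustering of a distance matrix
#'
#' Merge heights follow the ultrametric convention (half the cophenetic
#' distance, so two samples at distance d merge at height d/2). Input
#' rows are ordered by sample id before clustering, which fixes the
#' merge order under ties.
#'
#' @param m Square symmetric distance matrix with zero diagonal.
#' @param linkage Only `"average"` is supported.
#' @return An `ms_dendro`: the `hclust` object, ultrametric merge
#'   `heights`, and the `newick` serialization with branch lengths.
#' @export
hierarchical_cluster <- function(m, linkage = "average") {
  linkage <- match.arg(linkage, "average")
  validate_dist_matrix(m)
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  newick <- if (nrow(m) >= 3L) {
    ape::write.tree(ape::as.phylo(hc))
  } else {
    sprintf("(%s:%.10g,%s:%.10g);", rownames(m)[1], m[1, 2] / 2,
            rownames(m)[2], m[1, 2] / 2)
  }
  structure(list(hclust = hc, heights = hc$height / 2, newick = newick),
            class = "ms_dendro")
}

#' @export
print.ms_dendro <- function(x, ...) {
  cat("<ms_dendro> ", length(x$hclust$labels), " samples, first merge at ",
      format(x$heights[1]), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ms_dendro <- function(x, ...) {
  tibble::tibble(
    merge = seq_along(x$heights),
    height = x$heights
  )
}

upper_pair_distances <- function(m) {
  m[upper.tri(m)]
}

#' Precompute the binned distance histogram for empirical p-values
#'
#' Bins all database pair distances into `bins` equal-width bins over
#' `[0, max distance]` and stores the cumulative count of pairs strictly
#' below each bin's lower edge, which makes the p-value lookup a single
#' indexing operation.
#'
#' @param pair_distances Numeric vector of all database pair distances
#'   (length `choose(|M|, 2)`), or a symmetric matrix (upper triangle is
#'   taken).
#' @param bins Number of histogram bins (default 10000).
#' @return An `ms_pvalue_table` with `bin_edges` (length `bins + 1`),
#'   `below_edge` cumulative counts and `total_pairs`.
#' @export
build_pvalue_table <- function(pair_distances, bins = 10000L) {
  if (is.matrix(pair_distances)) {
    pair_distances <- upper_pair_distances(pair_distances)
  }
  stopifnot(length(pair_distances) >= 1L, bins >= 1L)
  dmax <- max(pair_distances)
  if (dmax <= 0) dmax <- 1  # degenerate all-zero distances
  edges <- seq(0, dmax, length.out = bins + 1L)
  # bin i spans [edges[i], edges[i+1]); the final edge closes the last bin
  idx <- findInterval(pair_distances, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = bins)
  structure(
    list(bin_edges = edges,
         below_edge = c(0, cumsum(counts)),
         total_pairs = length(pair_distances)),
    class = "ms_pvalue_table"
  )
}

#' @export
print.ms_pvalue_table <- function(x, ...) {
  cat("<ms_pvalue_table> ", x$total_pairs, " pairs in ",
      length(x$bin_edges) - 1L, " bins over [0, ",
      format(max(x$bin_edges)), "]\n", sep = "")
  invisible(x)
}

#' Empirical p-value of a match distance
#'
#' The fraction of all database pair distances strictly smaller than the
#' observed query-match distance, read from the precomputed histogram at
#' the lower edge of the bin containing `d` (a conservative convention:
#' the table value never exceeds the exact fraction by more than one bin
#' width).
#'
#' @param table An `ms_pvalue_table`.
#' @param d Distance value (vectorized).
#' @return p-values in `[0, 1]`, non-decreasing in `d`.
#' @export
empirical_pvalue <- function(table, d) {
  stopifnot(inherits(table, "ms_pvalue_table"))
  edges <- table$bin_edges
  vapply(d, function(di) {
    if (di <= 0) return(0)
    if (di > edges[length(edges)]) return(1)
    j <- findInterval(di, edges, rightmost.closed = TRUE)
    table$below_edge[j] / table$total_pairs
  }, numeric(1))
}

#' Select coarse-search representative samples
#'
#' Restricts the database to an ecosystem filter, cuts an
#' average-linkage clustering of the precomputed distances into at most
#' `max_n` clusters, and returns each cluster's medoid (the member
#' minimizing its summed within-cluster distance, ties broken by id).
#' If the filtered pool is within `max_n` all samples are returned.
#'
#' @param db An `ms_database` with a precalc matrix.
#' @param ecosystem_filter An ecosystem label, or `"All"`.
#' @param max_n Maximum number of representatives (default 1000).
#' @param seed Seed for the (rarely needed) uniform down-sample.
#' @return Sorted character vector of representative ids.
#' @export
select_representatives <- function(db, ecosystem_filter = "All",
                                   max_n = 1000L, seed = 1L) {
  stopifnot(inherits(db, "ms_database"))
  ids <- if (identical(ecosystem_filter, "All")) {
    db$metadata$sample_id
  } else {
    db$metadata$sample_id[db$metadata$ecosystem == ecosystem_filter]
  }
  ids <- sort(ids)
  if (!length(ids)) {
    stop("no samples match ecosystem filter '", ecosystem_filter, "'",
         call. = FALSE)
  }
  if (length(ids) <= max_n) return(ids)
  if (is.null(db$precalc)) {
    stop("representative selection needs the precalc matrix", call. = FALSE)
  }
  sub <- db$precalc[ids, ids]
  hc <- stats::hclust(stats::as.dist(sub), method = "average")
  cl <- stats::cutree(hc, k = max_n)
  pool <- vapply(split(ids, cl), function(members) {
    if (length(members) == 1L) return(members)
    s <- colSums(sub[members, members, drop = FALSE])
    members[order(s, members)][1L]
  }, character(1))
  pool <- sort(unname(pool))
  if (length(pool) > max_n) {
    pool <- sort(withr::with_seed(seed, sample(pool, max_n)))
  }
  pool
}

ranking_from_hits <- function(record, k, pvt, metadata) {
  n <- min(k, length(record$hits))
  if (n == 0L) {
    return(tibble::tibble(query_id = character(), rank = integer(),
                          match_id = character(), distance = numeric(),
                          p_value = numeric(), ecosystem = character(),
                          annotation = character()))
  }
  ids <- record$hits[seq_len(n)]
  d <- record$hit_distances[seq_len(n)]
  tibble::tibble(
    query_id = record$query_id,
    rank = seq_len(n),
    match_id = ids,
    distance = d,
    p_value = if (is.null(pvt)) NA_real_ else empirical_pvalue(pvt, d),
    ecosystem = metadata$ecosystem[match(ids, metadata$sample_id)],
    annotation = metadata$annotation[match(ids, metadata$sample_id)]
  )
}

check_query_limit <- function(n, method, enforce) {
  lim <- switch(method,
                gnat = ms_defaults()$max_queries_gnat,
                aesa = ms_defaults()$max_queries_aesa)
  if (n < 1L) {
    rlang::abort("at least one query sample is required",
                 class = "ms_validation_error")
  }
  if (enforce && n > lim) {
    rlang::abort(paste0(n, " query samples exceed the ", lim,
                        "-sample limit for ", method, " search"),
                 class = "ms_validation_error")
  }
  invisible(lim)
}

#' Phylogenetic search with contextualization (Analysis Type I)
#'
#' Range-searches each query against the database with the chosen exact
#' metric index (EMD-UniFrac metric), selects the context set from the
#' recorded evaluations, composes the full context distance matrix, and
#' contextualizes via PCoA and UPGMA clustering. Matches are ranked by
#' distance with empirical p-values from the precomputed database
#' distances.
#'
#' @param db `ms_database` with a precalc matrix (for context cells and
#'   p-values).
#' @param queries List of query count profiles.
#' @param tree `ms_tree`; defaults to the tree attached to `db`.
#' @param method `"gnat"` or `"aesa"`.
#' @param radius Range-search radius (default 0.3).
#' @param k Context size / maximum ranked matches per query (default 20).
#' @param copy_numbers Optional named copy-number vector; queries are
#'   corrected before normalization.
#' @param rarefy Rarefy all queries to their common minimum depth before
#'   correction/normalization.
#' @param seed Seed for rarefaction and index construction.
#' @param index Optional prebuilt `ms_gnat`/`ms_aesa` over `db`.
#' @param taxonomy Optional taxonomy tibble; when given, each ranked
#'   match carries a composition-comparison table (list column).
#' @param ranks Taxonomic ranks for the composition comparison.
#' @param enforce_limits Enforce the per-method query-count limits
#'   (10 for GNAT, 100 for AESA).
#' @param bins Histogram bins for the p-value table.
#' @param dims PCoA axes.
#' @return An `ms_type1` list: `ranking` (tibble), `context_ids`,
#'   `full_matrix`, `pcoa`, `dendrogram`, `records`, `index`.
#' @export
run_type1 <- function(db, queries, tree = NULL,
                      method = c("gnat", "aesa"),
                      radius = 0.3, k = 20L,
                      copy_numbers = NULL, rarefy = FALSE, seed = 1L,
                      index = NULL, taxonomy = NULL,
                      ranks = c("phylum", "family", "genus"),
                      enforce_limits = TRUE, bins = 10000L, dims = 2L) {
  method <- match.arg(method)
  stopifnot(inherits(db, "ms_database"), radius >= 0)
  tree <- tree %||% attr(db, "tree")
  if (is.null(tree)) {
    rlang::abort("no phylogeny supplied", class = "ms_validation_error")
  }
  check_query_limit(length(queries), method, enforce_limits)
  queries <- preprocess_queries(queries, copy_numbers, rarefy, seed)
  metric <- emd_metric(tree)
  qprep <- prepare_relative(tree, queries)
  dbprep <- prepare_relative(tree, db$profiles)
  if (is.null(index)) {
    index <- if (method == "gnat") {
      build_gnat(dbprep, metric, seed = seed)
    } else {
      build_aesa(dbprep, metric)
    }
  }
  records <- lapply(qprep, function(q) {
    if (method == "gnat") {
      gnat_range_search(index, q, radius, metric)
    } else {
      aesa_range_search(index, q, radius, metric)
    }
  })
  context_ids <- select_context(records, k = k)
  full <- assemble_matrix(context_ids, qprep, db$precalc, records, metric)
  pvt <- if (!is.null(db$precalc)) {
    build_pvalue_table(db$precalc, bins = bins)
  }
  ranking <- dplyr::bind_rows(
    lapply(records, ranking_from_hits, k = k, pvt = pvt,
           metadata = db$metadata))
  if (!is.null(taxonomy) && nrow(ranking)) {
    ranking$composition <- purrr::map2(
      ranking$query_id, ranking$match_id,
      function(qi, mi) {
        composition_comparison(qprep[[qi]], dbprep[[mi]], taxonomy, ranks)
      })
  }
  # non-Euclidean input is the norm for UniFrac matrices; negative
  # eigenvalues are recorded on the pcoa object rather than warned about
  coords <- suppressWarnings(ms_pcoa(full, dims = dims))
  labels <- c(
    stats::setNames(db$metadata$ecosystem, db$metadata$sample_id)[context_ids],
    stats::setNames(rep("query", length(qprep)), names(qprep)))
  attr(coords, "groups") <- unname(labels[coords$sample_id])
  structure(
    list(ranking = ranking, context_ids = context_ids, full_matrix = full,
         pcoa = coords, dendrogram = hierarchical_cluster(full),
         records = records, index = index, method = method,
         radius = radius, k = k),
    class = "ms_type1"
  )
}

preprocess_queries <- function(queries, copy_numbers, rarefy, seed) {
  ids <- vapply(queries, `[[`, character(1), "sample_id")
  names(queries) <- ids
  if (rarefy && length(queries) > 1L) {
    target <- min(vapply(queries, `[[`, numeric(1), "depth"))
    anchor <- queries[[which.min(vapply(queries, `[[`, numeric(1), "depth"))]]
    queries <- lapply(queries, function(p) {
      rarefy_pair(p, anchor, seed = seed)$p
    })
  }
  if (!is.null(copy_numbers)) {
    queries <- lapply(queries, function(p) {
      suppressWarnings(copy_number_correct(p, copy_numbers))
    })
  }
  stats::setNames(queries, ids)
}

#' @export
print.ms_type1 <- function(x, ...) {
  cat("<ms_type1> ", x$method, " search, radius ", x$radius, ": ",
      length(unique(x$ranking$query_id)), " queried, ",
      length(x$context_ids), " context samples\n", sep = "")
  invisible(x)
}

#' Coarse Bray-Curtis search against representatives (Analysis Type II)
#'
#' Compares the queries only against clustering-derived representative
#' samples using Bray-Curtis dissimilarity (which is not a metric, so
#' exact metric indexes do not apply), ranks the top `k` per query, and
#' contextualizes queries and representatives together via PCoA and
#' UPGMA. P-values come from the representative pair distances.
#'
#' @inheritParams run_type1
#' @param ecosystem_filter Ecosystem label or `"All"`.
#' @param max_n Maximum number of representatives.
#' @param rarefy Apply pairwise adaptive rarefaction to each compared
#'   pair before computing Bray-Curtis.
#' @return An `ms_type2` list: `ranking`, `representatives`,
#'   `full_matrix`, `pcoa`, `dendrogram`.
#' @export
run_type2 <- function(db, queries, ecosystem_filter = "All", k = 20L,
                      max_n = 1000L, rarefy = FALSE, seed = 1L,
                      bins = 10000L, dims = 2L) {
  stopifnot(inherits(db, "ms_database"))
  ids <- vapply(queries, `[[`, character(1), "sample_id")
  names(queries) <- ids
  reps <- select_representatives(db, ecosystem_filter, max_n = max_n,
                                 seed = seed)
  bc <- function(p, q) {
    if (rarefy) {
      pr <- rarefy_pair(p, q, seed = seed)
      bray_curtis(pr$p, pr$q)
    } else {
      bray_curtis(p, q)
    }
  }
  all_ids <- c(reps, ids)
  full <- matrix(0, length(all_ids), length(all_ids),
                 dimnames = list(all_ids, all_ids))
  profs <- c(db$profiles[reps], queries)
  for (i in seq_along(all_ids)) {
    if (i < length(all_ids)) {
      for (j in seq((i + 1L), length(all_ids))) {
        d <- bc(profs[[all_ids[i]]], profs[[all_ids[j]]])
        full[all_ids[i], all_ids[j]] <- full[all_ids[j], all_ids[i]] <- d
      }
    }
  }
  pvt <- if (length(reps) >= 2L) {
    build_pvalue_table(full[reps, reps], bins = bins)
  }
  ranking <- dplyr::bind_rows(lapply(ids, function(qi) {
    dq <- stats::setNames(full[qi, reps], reps)
    rec <- new_search_record(qi, dq, radius = Inf)
    ranking_from_hits(rec, k = k, pvt = pvt, metadata = db$metadata)
  }))
  coords <- suppressWarnings(ms_pcoa(full, dims = dims))
  labels <- c(
    stats::setNames(db$metadata$ecosystem, db$metadata$sample_id)[reps],
    stats::setNames(rep("query", length(ids)), ids))
  attr(coords, "groups") <- unname(labels[coords$sample_id])
  structure(
    list(ranking = ranking, representatives = reps, full_matrix = full,
         pcoa = coords, dendrogram = hierarchical_cluster(full),
         ecosystem_filter = ecosystem_filter, k = k),
    class = "ms_type2"
  )
}

#' @export
print.ms_type2 <- function(x, ...) {
  cat("<ms_type2> Bray-Curtis search vs ", length(x$representatives),
      " representatives (filter '", x$ecosystem_filter, "')\n", sep = "")
  invisible(x)
}

#' Compositional comparison between a query and a match
#'
#' Aggregates both samples' relative abundances at each requested
#' taxonomic rank; within a rank, taxa are ordered by descending query
#' fraction (the match's fractions are reported in the same order), so
#' the barcharts line up for visual inspection. Fractions sum to 1 per
#' sample per rank; taxa absent from a sample report 0.
#'
#' @param query,match `ms_profile`s.
#' @param tax Taxonomy tibble with the seven ranked lineage columns.
#' @param ranks Up to three of phylum, class, order, family, genus.
#' @return A tibble: `rank`, `taxon`, `query_fraction`, `match_fraction`.
#' @export
composition_comparison <- function(query, match, tax,
                                   ranks = c("phylum", "family", "genus")) {
  ok <- c("phylum", "class", "order", "family", "genus")
  ranks <- match.arg(ranks, ok, several.ok = TRUE)
  if (length(ranks) > 3L) {
    stop("at most three ranks", call. = FALSE)
  }
  frac_at <- function(p, rank) {
    lab <- tax[[rank]][match(p$otu, tax$otu)]
    lab[is.na(lab) | !nzchar(lab)] <- "unclassified"
    tot <- tapply(p$count, lab, sum) / sum(p$count)
    stats::setNames(as.numeric(tot), names(tot))
  }
  dplyr::bind_rows(lapply(ranks, function(rk) {
    qf <- frac_at(query, rk)
    mf <- frac_at(match, rk)
    taxa <- union(names(qf), names(mf))
    qv <- ifelse(taxa %in% names(qf), qf[taxa], 0)
    mv <- ifelse(taxa %in% names(mf), mf[taxa], 0)
    ord <- order(-qv, taxa)
    tibble::tibble(rank = rk, taxon = taxa[ord],
                   query_fraction = unname(qv[ord]),
                   match_fraction = unname(mv[ord]))
  }))
}

#' False-negative percentage under half-up two-decimal rounding
#'
#' @param total Number of sample pairs below the distance threshold.
#' @param differing How many of those pairs have differing keys.
#' @return `100 * differing / total` rounded half-up to two decimals;
#'   `NA` when `total` is zero (undefined, not 0).
#' @export
fn_percentage <- function(total, differing) {
  ifelse(total == 0, NA_real_,
         floor(100 * differing / total * 100 + 0.5) / 100)
}

#' False negatives of top-five-phyla key indexing
#'
#' For each distance threshold, counts the database sample pairs whose
#' distance is below the threshold and, among them, those whose
#' top-five-phyla keys differ — the pairs a phyla-key index would fail
#' to retrieve even though they are similar. An exact range search has
#' none of these by construction.
#'
#' @param precalc Symmetric distance matrix over the database.
#' @param keys Named list (or named character vector of serialized keys)
#'   of per-sample phyla keys, covering the matrix ids.
#' @param thresholds Distance thresholds.
#' @return A tibble: `threshold`, `total_pairs`, `differing_pairs`,
#'   `percentage` (half-up, two decimals; `NA` when no pair qualifies).
#' @export
phyla_index_fn_table <- function(precalc, keys,
                                 thresholds = c(0.05, 0.1, 0.2, 0.3)) {
  validate_dist_matrix(precalc)
  ids <- rownames(precalc)
  key_str <- if (is.list(keys)) {
    vapply(keys, paste, character(1), collapse = "|")
  } else {
    stats::setNames(as.character(keys), names(keys))
  }
  if (is.null(names(key_str)) || !all(ids %in% names(key_str))) {
    stop("keys must be named and cover all matrix ids", call. = FALSE)
  }
  key_str <- key_str[ids]
  ut <- upper.tri(precalc)
  d <- precalc[ut]
  differ <- outer(key_str, key_str, "!=")[ut]
  dplyr::bind_rows(lapply(thresholds, function(t) {
    below <- d < t
    total <- sum(below)
    diffn <- sum(below & differ)
    tibble::tibble(threshold = t, total_pairs = total,
                   differing_pairs = diffn,
                   percentage = fn_percentage(total, diffn))
  }))
}
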