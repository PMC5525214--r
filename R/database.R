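#' Construct a sample database
#'
#' Bundles abundance profiles with sample metadata (ecosystem label,
#' free-text annotation) and, optionally, a precomputed symmetric
#' all-versus-all distance matrix over the database samples.
#'
#' @param profiles Named list of [abundance_profile()] objects.
#' @param metadata A data frame with columns `sample_id`, `ecosystem`
#'   and optionally `annotation`; defaults to unlabelled metadata.
#' @param precalc Optional symmetric numeric matrix with zero diagonal,
#'   dimnames = sample ids.
#' @return An `ms_database`.
#' @export
sample_database <- function(profiles, metadata = NULL, precalc = NULL) {
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(profiles) <- ids
  if (is.null(metadata)) {
    metadata <- tibble::tibble(sample_id = ids, ecosystem = "unknown",
                               annotation = "")
  }
  metadata <- tibble::as_tibble(metadata)
  if (!all(c("sample_id", "ecosystem") %in% names(metadata))) {
    stop("metadata needs sample_id and ecosystem columns", call. = FALSE)
  }
  if (!"annotation" %in% names(metadata)) metadata$annotation <- ""
  if (!setequal(metadata$sample_id, ids)) {
    stop("metadata sample ids do not match profiles", call. = FALSE)
  }
  if (!is.null(precalc)) validate_dist_matrix(precalc, ids)
  structure(
    list(profiles = profiles, metadata = metadata, precalc = precalc,
         size = length(profiles)),
    class = "ms_database"
  )
}

validate_dist_matrix <- function(m, ids = NULL, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("distance matrix must have matching dimnames", call. = FALSE)
  }
  if (!is.null(ids) && !setequal(rownames(m), ids)) {
    stop("distance matrix ids do not match database", call. = FALSE)
  }
  if (any(abs(diag(m)) > tol)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  if (any(abs(m - t(m)) > tol)) {
    bad <- which(abs(m - t(m)) > tol, arr.ind = TRUE)[1, ]
    stop("distance matrix is asymmetric at (", rownames(m)[bad[1]], ", ",
         colnames(m)[bad[2]], ")", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.ms_database <- function(x, ...) {
  cat("<ms_database> ", x$size, " samples, ",
      length(unique(x$metadata$ecosystem)), " ecosystems, precalc ",
      if (is.null(x$precalc)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Read / write sample metadata
#'
#' Three-column tab-separated table: sample id, ecosystem label,
#' free-text annotation.
#'
#' @param path File path.
#' @return A tibble with columns `sample_id`, `ecosystem`, `annotation`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("sample_id", "ecosystem") %in% names(df))) {
    stop("format error: metadata needs sample_id and ecosystem columns",
         call. = FALSE)
  }
  if (!"annotation" %in% names(df)) df$annotation <- ""
  tibble::as_tibble(df[c("sample_id", "ecosystem", "annotation")])
}

#' @rdname read_metadata
#' @param metadata Metadata tibble.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a dense distance matrix store
#'
#' Plain-text dense layout: a header row of sample ids, then one row per
#' sample (id + distances) with values printed at full double precision,
#' so the store round-trips bit-exactly.
#'
#' @param path File path.
#' @return A symmetric numeric matrix with sample-id dimnames.
#' @export
read_dist_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  m <- t(vapply(rows, function(r) as.numeric(r[-1]),
                numeric(length(ids))))
  dimnames(m) <- list(vapply(rows, `[[`, character(1), 1L), ids)
  validate_dist_matrix(m)
  m
}

#' @rdname read_dist_matrix
#' @param m Symmetric numeric matrix with dimnames.
#' @export
write_dist_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Load a sample database from a fixture directory
#'
#' Expects the files the synthetic generator writes: `otu_table.tsv`,
#' `metadata.tsv` and optionally `precalc.tsv`, `tree.nwk`,
#' `taxonomy.tsv`, `copy_numbers.tsv`.
#'
#' @param dir Directory path.
#' @param precalc Load the precomputed distance store if present.
#' @return An `ms_database`; tree/taxonomy/copy numbers are attached as
#'   attributes when their files exist.
#' @export
read_database <- function(dir, precalc = TRUE) {
  otu_path <- file.path(dir, "otu_table.tsv")
  if (!file.exists(otu_path)) {
    stop("no otu_table.tsv under ", dir, call. = FALSE)
  }
  profiles <- read_profiles(otu_path, "tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  metadata <- if (file.exists(meta_path)) read_metadata(meta_path) else NULL
  pm <- NULL
  if (precalc && file.exists(file.path(dir, "precalc.tsv"))) {
    pm <- read_dist_matrix(file.path(dir, "precalc.tsv"))
  }
  db <- sample_database(profiles, metadata, pm)
  if (file.exists(file.path(dir, "tree.nwk"))) {
    attr(db, "tree") <- parse_newick(
      paste(readLines(file.path(dir, "tree.nwk"), warn = FALSE),
            collapse = ""))
  }
  if (file.exists(file.path(dir, "taxonomy.tsv"))) {
    attr(db, "taxonomy") <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  }
  if (file.exists(file.path(dir, "copy_numbers.tsv"))) {
    attr(db, "copy_numbers") <- read_copy_numbers(
      file.path(dir, "copy_numbers.tsv"))
  }
  db
}
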