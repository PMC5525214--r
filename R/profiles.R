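#' Construct an abundance profile
#'
#' A sparse OTU-to-abundance mapping for one sample. Zero entries are
#' dropped on construction; `depth` is the sum of stored values.
#'
#' @param sample_id Sample identifier.
#' @param counts Named numeric vector (names = OTU labels, values >= 0).
#' @return An `ms_profile` object with fields `sample_id`, `otu`,
#'   `count` and `depth`.
#' @export
abundance_profile <- function(sample_id, counts) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  counts <- unlist(counts)
  if (length(counts) && is.null(names(counts))) {
    stop("counts must be named by OTU label", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("negative abundance in sample ", sample_id, call. = FALSE)
  }
  if (anyDuplicated(names(counts))) {
    stop("duplicate OTU labels in sample ", sample_id, call. = FALSE)
  }
  keep <- counts > 0
  counts <- counts[keep]
  structure(
    list(
      sample_id = sample_id,
      otu = names(counts),
      count = unname(as.numeric(counts)),
      depth = sum(counts)
    ),
    class = "ms_profile"
  )
}

#' @export
print.ms_profile <- function(x, ...) {
  cat("<ms_profile> ", x$sample_id, ": ", length(x$otu),
      " OTUs, depth ", format(x$depth), "\n", sep = "")
  invisible(x)
}

#' Tidy an abundance profile into a tibble
#'
#' @param x An `ms_profile` object.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `otu`, `count`.
#' @export
tidy.ms_profile <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id, otu = x$otu, count = x$count)
}

named_counts <- function(p) stats::setNames(p$count, p$otu)

#' Read OTU abundance profiles from a table file
#'
#' Supports the classic tab-separated OTU table (header row starting with
#' `#OTU ID`, one row per OTU, one column per sample, optional trailing
#' `taxonomy` column) and the BIOM-JSON v1.0 dialect (sparse or dense),
#' read through the biomformat package. Both dialects of the same matrix
#' yield identical profiles.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"biom-json"`.
#' @return A named list of [abundance_profile()] objects, one per sample
#'   column, in column order.
#' @export
read_profiles <- function(path, dialect = c("tsv", "biom-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("profile file not found: ", path, call. = FALSE)
  }
  mat <- switch(dialect,
    "tsv" = read_otu_tsv(path),
    "biom-json" = read_otu_biom_json(path)
  )
  profiles_from_matrix(mat)
}

profiles_from_matrix <- function(mat) {
  if (any(mat < 0)) stop("format error: negative counts", call. = FALSE)
  out <- lapply(colnames(mat), function(s) {
    abundance_profile(s, stats::setNames(mat[, s], rownames(mat)))
  })
  stats::setNames(out, colnames(mat))
}

read_otu_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#OTU ID\t", lines)
  if (!length(hdr)) {
    hdr <- which(startsWith(lines, "#OTU ID"))
  }
  if (!length(hdr)) {
    stop("format error: no '#OTU ID' header row in ", path, call. = FALSE)
  }
  hdr <- hdr[1]
  fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- fields[-1]
  tax_col <- length(samples) > 0 && tolower(samples[length(samples)]) == "taxonomy"
  if (tax_col) samples <- samples[-length(samples)]
  if (!length(samples)) stop("format error: no sample columns", call. = FALSE)
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  otus <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(otus)) {
    stop("format error: duplicate OTU rows: ",
         paste(unique(otus[duplicated(otus)]), collapse = ", "), call. = FALSE)
  }
  vals <- vapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r[seq_along(samples) + 1L]))
    if (anyNA(v)) stop("format error: non-numeric count in row '", r[1L], "'",
                       call. = FALSE)
    v
  }, numeric(length(samples)))
  mat <- if (length(samples) == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(mat) <- list(otus, samples)
  if (any(mat < 0)) stop("format error: negative counts", call. = FALSE)
  mat
}

read_otu_biom_json <- function(path) {
  b <- tryCatch(
    biomformat::read_biom(path),
    error = function(e) stop("format error: malformed BIOM-JSON: ",
                             conditionMessage(e), call. = FALSE)
  )
  mat <- as(biomformat::biom_data(b), "matrix")
  storage.mode(mat) <- "double"
  mat
}

#' Write profiles as a classic TSV OTU table
#'
#' @param profiles A list of `ms_profile` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(profiles, path) {
  otus <- sort(unique(unlist(lapply(profiles, `[[`, "otu"))))
  samples <- vapply(profiles, `[[`, character(1), "sample_id")
  mat <- matrix(0, length(otus), length(samples),
                dimnames = list(otus, samples))
  for (p in profiles) mat[p$otu, p$sample_id] <- p$count
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Constructed from biom file", con)
  writeLines(paste(c("#OTU ID", samples), collapse = "\t"), con)
  writeLines(paste(otus, apply(mat, 1L, function(r) {
    paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t")
  }), sep = "\t"), con)
  invisible(path)
}

#' Write profiles as BIOM-JSON v1.0 (sparse)
#'
#' @inheritParams write_otu_table
#' @export
write_biom_json <- function(profiles, path) {
  otus <- sort(unique(unlist(lapply(profiles, `[[`, "otu"))))
  samples <- vapply(profiles, `[[`, character(1), "sample_id")
  mat <- matrix(0, length(otus), length(samples),
                dimnames = list(otus, samples))
  for (p in profiles) mat[p$otu, p$sample_id] <- p$count
  biomformat::write_biom(biomformat::make_biom(mat), path)
  invisible(path)
}

#' Convert a profile to relative abundances
#'
#' @param p An `ms_profile`.
#' @return A profile with the same support whose values sum to 1.
#' @export
to_relative <- function(p) {
  stopifnot(inherits(p, "ms_profile"))
  if (length(p$otu) == 0L || p$depth <= 0) {
    stop("cannot normalize empty profile ", p$sample_id, call. = FALSE)
  }
  abundance_profile(p$sample_id, stats::setNames(p$count / p$depth, p$otu))
}

#' Correct abundances for 16S rRNA gene copy number
#'
#' Divides each OTU's abundance by its 16S operon copy number. OTUs
#' missing from the table default to copy number 1 and are reported in
#' the `missing` attribute and a warning.
#'
#' @param p An `ms_profile`.
#' @param table Named numeric vector, OTU label to copy number (>= 1).
#' @return The corrected profile (fractional counts), with attribute
#'   `missing` listing OTUs that used the default.
#' @export
copy_number_correct <- function(p, table) {
  stopifnot(inherits(p, "ms_profile"))
  table <- unlist(table)
  if (length(table) && any(table <= 0)) {
    stop("copy number table contains values <= 0", call. = FALSE)
  }
  cn <- table[p$otu]
  missing <- p$otu[is.na(cn)]
  cn[is.na(cn)] <- 1
  if (length(missing)) {
    warning("no copy number for ", length(missing), " OTU(s): ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "", call. = FALSE)
  }
  out <- abundance_profile(p$sample_id,
                           stats::setNames(p$count / as.numeric(cn), p$otu))
  attr(out, "missing") <- missing
  out
}

# Deterministic per-pair RNG stream: combine the job seed with a small
# rolling hash of the two sample ids so pair results are order-independent.
pair_seed <- function(seed, id_a, id_b) {
  key <- paste(sort(c(id_a, id_b)), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 1073741789
  as.integer((as.numeric(seed) %% 1048573) * 1021 + h) %% 2147483629L
}

#' Pairwise adaptive rarefaction
#'
#' Subsamples the deeper of two integer-count profiles, uniformly without
#' replacement, down to the shallower profile's depth, so both members of
#' a compared pair carry the same number of reads. The shallower profile
#' is returned unchanged. Results are a pure function of `seed` and the
#' two sample ids (order-independent).
#'
#' @param p,q `ms_profile` objects with integer counts.
#' @param seed Integer job seed.
#' @return A list with elements `p` and `q` at equal depth.
#' @export
rarefy_pair <- function(p, q, seed = 1L) {
  stopifnot(inherits(p, "ms_profile"), inherits(q, "ms_profile"))
  for (x in list(p, q)) {
    if (x$depth <= 0) stop("cannot rarefy empty profile ", x$sample_id,
                           call. = FALSE)
    if (any(x$count != round(x$count))) {
      stop("non-integer counts in ", x$sample_id,
           "; rarefy before copy-number correction", call. = FALSE)
    }
  }
  target <- min(p$depth, q$depth)
  sub <- function(x) {
    if (x$depth <= target) return(x)
    reads <- rep.int(seq_along(x$otu), x$count)
    keep <- sample(reads, target, replace = FALSE)
    counts <- tabulate(keep, nbins = length(x$otu))
    abundance_profile(x$sample_id, stats::setNames(counts, x$otu))
  }
  withr::with_seed(pair_seed(seed, p$sample_id, q$sample_id),
                   list(p = sub(p), q = sub(q)))
}

#' Read a taxonomy table (OTU + seven ranked lineage columns)
#'
#' @param path Tab-separated file with columns otu, kingdom, phylum,
#'   class, order, family, genus, species (header optional).
#' @return A tibble with those eight columns.
#' @export
read_taxonomy <- function(path) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != 8L) {
    stop("format error: taxonomy table must have 8 columns", call. = FALSE)
  }
  if (identical(tolower(df[1, 1]), "otu")) df <- df[-1, , drop = FALSE]
  names(df) <- c("otu", ranks)
  tibble::as_tibble(df)
}

#' @rdname read_taxonomy
#' @param tax Taxonomy tibble as returned by [read_taxonomy()].
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a two-column 16S copy-number table
#'
#' @param path Tab-separated file: OTU label, copy number.
#' @return Named numeric vector of copy numbers.
#' @export
read_copy_numbers <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2L) {
    stop("format error: copy-number table must have 2 columns", call. = FALSE)
  }
  cn <- as.numeric(df[[2]])
  if (anyNA(cn)) stop("format error: non-numeric copy number", call. = FALSE)
  stats::setNames(cn, as.character(df[[1]]))
}

#' @rdname read_copy_numbers
#' @param cn Named numeric vector of copy numbers.
#' @export
write_copy_numbers <- function(cn, path) {
  utils::write.table(data.frame(names(cn), unname(cn)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

otu_phylum <- function(otus, tax) {
  ph <- tax$phylum[match(otus, tax$otu)]
  ph[is.na(ph) | !nzchar(ph)] <- "unclassified"
  ph
}

#' Top-five-phyla key of a sample
#'
#' Aggregates a profile's abundance by phylum and returns the up-to-five
#' most abundant phyla in descending order — the index scheme whose false
#' negatives the fn-table evaluation measures. Ties break
#' lexicographically; OTUs without a lineage aggregate under
#' `"unclassified"`, which sorts last among ties.
#'
#' @param p An `ms_profile`.
#' @param tax Taxonomy tibble (see [read_taxonomy()]).
#' @return Character vector of length <= 5.
#' @export
phyla_key <- function(p, tax) {
  stopifnot(inherits(p, "ms_profile"))
  ph <- otu_phylum(p$otu, tax)
  tot <- tapply(p$count, ph, sum)
  nm <- names(tot)
  ord <- order(-unname(tot), nm == "unclassified", nm)
  utils::head(nm[ord], 5L)
}
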