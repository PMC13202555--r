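#' @importFrom stats as.formula coef confint cor lm lm.fit median pnorm
#'   qnorm quantile rlnorm rnorm runif sd setNames shapiro.test set.seed
#'   t.test wilcox.test complete.cases cmdscale p.adjust cor.test
#'   resid update var
#' @importFrom utils read.delim write.table combn head
NULL

GENE_CLASSES <- c("MRG", "ARG", "VFG", "MGE")
MGE_SUBCLASSES <- c("plasmid_gene", "IS", "transposon", "integron", "ICE")
MOBILITY_CONTEXTS <- c("chromosome-like", "plasmid", "phage", "unknown")

HIT_COLUMNS <- c("sample_id", "contig_id", "gene_class", "subclass",
                 "gene_name", "pident", "evalue", "bitscore")
CONTIG_COLUMNS <- c("sample_id", "contig_id", "length_bp", "mobility_context")

#' Parse an annotation hit table
#'
#' Reads alignment hits in either the 12-column blast tabular dialect
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore) or the package's native tab-separated dialect with a
#' mandatory header (`sample_id, contig_id, gene_class, subclass, gene_name,
#' pident, evalue, bitscore`). No filtering is applied; every row becomes
#' one hit and row order is preserved.
#'
#' In the blast dialect the query id is taken as the contig id and the
#' subject id as the gene name; `sample_id`, `gene_class` and `subclass`
#' are not part of that format and must be supplied.
#'
#' @param path Path to the hit table.
#' @param gene_class Gene class assigned to every row when `dialect =
#'   "blast"`: one of `"MRG"`, `"ARG"`, `"VFG"`, `"MGE"`. Ignored for the
#'   native dialect, which carries its own `gene_class` column.
#' @param dialect `"blast"` or `"native"`.
#' @param sample_id Sample id assigned to every row (blast dialect only).
#' @param subclass Subclass label assigned to every row (blast dialect
#'   only); defaults to `NA`.
#' @return A data.frame of hits with columns `sample_id, contig_id,
#'   gene_class, subclass, gene_name, pident, evalue, bitscore`.
#' @export
parse_hit_table <- function(path, gene_class = NULL,
                            dialect = c("blast", "native"),
                            sample_id = NULL, subclass = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("hit table not found: ", path)
  if (dialect == "blast") {
    if (is.null(gene_class)) stop("gene_class is required for the blast dialect")
    gene_class <- match.arg(gene_class, GENE_CLASSES)
    if (is.null(sample_id)) stop("sample_id is required for the blast dialect")
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) return(empty_hits())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(fields)
    if (any(ncols != 12L)) {
      stop("malformed blast tabular row (expected 12 columns) at line ",
           which(ncols != 12L)[1L])
    }
    m <- do.call(rbind, fields)
    num <- function(col, name) {
      v <- suppressWarnings(as.numeric(m[, col]))
      if (anyNA(v)) {
        stop("non-numeric ", name, " at line ", which(is.na(v))[1L])
      }
      v
    }
    hits <- data.frame(
      sample_id = sample_id,
      contig_id = m[, 1L],
      gene_class = gene_class,
      subclass = subclass,
      gene_name = m[, 2L],
      pident = num(3L, "percent identity"),
      evalue = num(11L, "E-value"),
      bitscore = num(12L, "bit score"),
      stringsAsFactors = FALSE
    )
  } else {
    hits <- read.delim(path, stringsAsFactors = FALSE,
                       colClasses = "character")
    missing_cols <- setdiff(HIT_COLUMNS, names(hits))
    if (length(missing_cols) > 0L) {
      stop("native hit table is missing columns: ",
           paste(missing_cols, collapse = ", "))
    }
    hits <- hits[HIT_COLUMNS]
    for (col in c("pident", "evalue", "bitscore")) {
      v <- suppressWarnings(as.numeric(hits[[col]]))
      if (anyNA(v) && nrow(hits) > 0L) {
        stop("non-numeric ", col, " at line ",
             which(is.na(v))[1L] + 1L)  # +1 for the header line
      }
      hits[[col]] <- v
    }
    if (nrow(hits) == 0L) return(empty_hits())
  }
  validate_hits(hits)
  hits
}

empty_hits <- function() {
  data.frame(sample_id = character(), contig_id = character(),
             gene_class = character(), subclass = character(),
             gene_name = character(), pident = numeric(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits), all(HIT_COLUMNS %in% names(hits)))
  if (nrow(hits) == 0L) return(invisible(hits))
  bad_class <- !hits$gene_class %in% GENE_CLASSES
  if (any(bad_class)) {
    stop("unknown gene_class: ",
         paste(unique(hits$gene_class[bad_class]), collapse = ", "))
  }
  mge_sub <- hits$gene_class == "MGE" & !is.na(hits$subclass)
  if (any(!hits$subclass[mge_sub] %in% MGE_SUBCLASSES)) {
    stop("MGE subclass must be one of: ",
         paste(MGE_SUBCLASSES, collapse = ", "))
  }
  non_mge <- hits$gene_class != "MGE" & !is.na(hits$subclass)
  if (any(hits$subclass[non_mge] %in% MGE_SUBCLASSES)) {
    stop("MGE subclasses are only valid for gene_class = MGE")
  }
  if (any(hits$pident < 0 | hits$pident > 100, na.rm = TRUE)) {
    stop("percent identity outside [0, 100]")
  }
  if (any(hits$evalue < 0, na.rm = TRUE)) stop("negative E-value")
  invisible(hits)
}

#' Filter hits on E-value and percent identity
#'
#' Retains exactly the hits with `evalue <= max_evalue` and
#' `pident >= min_identity`; both comparisons are inclusive. Idempotent.
#'
#' @param hits Hit data.frame from [parse_hit_table()].
#' @param max_evalue Maximum E-value (default `1e-5`).
#' @param min_identity Minimum percent identity in \[0, 100\] (default 80).
#' @return The retained subset, row order preserved.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_identity = 80) {
  stopifnot(is.finite(max_evalue), is.finite(min_identity),
            min_identity >= 0, min_identity <= 100)
  keep <- hits$evalue <= max_evalue & hits$pident >= min_identity
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the single best hit per locus
#'
#' For each (sample, contig, gene class, gene name) group the hit with the
#' highest bit score is kept; ties are broken by the lowest E-value, then
#' by subclass, then by original row order, so the result is deterministic.
#' Running the function on its own output is the identity.
#'
#' @param hits Filtered hit data.frame.
#' @param dedup Set `FALSE` to return the input unchanged (per-locus
#'   deduplication disabled).
#' @return Deduplicated hits ordered by sample, contig, class, gene name.
#' @export
resolve_best_hit <- function(hits, dedup = TRUE) {
  if (!dedup || nrow(hits) == 0L) {
    rownames(hits) <- NULL
    return(hits)
  }
  sub <- ifelse(is.na(hits$subclass), "", hits$subclass)
  ord <- order(hits$sample_id, hits$contig_id, hits$gene_class,
               hits$gene_name, -hits$bitscore, hits$evalue, sub,
               seq_len(nrow(hits)))
  sorted <- hits[ord, , drop = FALSE]
  key <- paste(sorted$sample_id, sorted$contig_id, sorted$gene_class,
               sorted$gene_name, sep = "\r")
  out <- sorted[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a per-sample annotation set
#'
#' Joins a sample's contig table, its (filtered, deduplicated) hits and an
#' optional metadata row into the container every index computation reads.
#' Every hit must resolve to a contig of the same sample; orphan hits are
#' an error.
#'
#' @param contigs Contig data.frame with columns `sample_id, contig_id,
#'   length_bp, mobility_context` for one sample.
#' @param hits Hit data.frame for the same sample (may be empty).
#' @param metadata Named list or one-row data.frame of sample covariates,
#'   or `NULL`.
#' @return An object of class `sample_set` with elements `sample_id`,
#'   `contigs`, `hits`, `metadata`.
#' @export
build_sample_set <- function(contigs, hits = empty_hits(), metadata = NULL) {
  stopifnot(is.data.frame(contigs), all(CONTIG_COLUMNS %in% names(contigs)))
  sample_id <- unique(contigs$sample_id)
  if (length(sample_id) != 1L) {
    stop("contig table must contain exactly one sample, found: ",
         paste(sample_id, collapse = ", "))
  }
  if (any(!nzchar(contigs$contig_id))) stop("empty contig_id")
  if (anyDuplicated(contigs$contig_id)) {
    stop("duplicated contig_id within sample ", sample_id)
  }
  if (any(contigs$length_bp < 1)) stop("contig length_bp must be >= 1")
  if (any(!contigs$mobility_context %in% MOBILITY_CONTEXTS)) {
    stop("mobility_context must be one of: ",
         paste(MOBILITY_CONTEXTS, collapse = ", "))
  }
  if (nrow(hits) > 0L) {
    if (any(hits$sample_id != sample_id)) {
      stop("hits contain sample ids other than ", sample_id)
    }
    orphan <- setdiff(unique(hits$contig_id), contigs$contig_id)
    if (length(orphan) > 0L) {
      stop("hits reference contigs absent from the contig table: ",
           paste(head(orphan, 10L), collapse = ", "))
    }
  }
  if (is.data.frame(metadata)) metadata <- as.list(metadata)
  rownames(contigs) <- NULL
  rownames(hits) <- NULL
  structure(list(sample_id = sample_id, contigs = contigs, hits = hits,
                 metadata = metadata),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("sample_set:", x$sample_id, "-", nrow(x$contigs), "contigs,",
      nrow(x$hits), "hits\n")
  counts <- table(factor(x$hits$gene_class, levels = GENE_CLASSES))
  cat("  hits by class:",
      paste(names(counts), counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read a native contig table
#'
#' Tab-separated with header `sample_id, contig_id, length_bp,
#' mobility_context`; may span several samples. A missing
#' `mobility_context` column defaults to `"unknown"`.
#'
#' @param path Path to the TSV file.
#' @return Contig data.frame.
#' @export
read_contig_table <- function(path) {
  if (!file.exists(path)) stop("contig table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"mobility_context" %in% names(df)) df$mobility_context <- "unknown"
  missing_cols <- setdiff(CONTIG_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("contig table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$length_bp <- as.integer(df$length_bp)
  df[CONTIG_COLUMNS]
}

#' Read a sample metadata table
#'
#' Tab-separated, one row per sample, first column `sample_id`; remaining
#' columns are covariates (metal concentrations, physicochemical
#' properties) plus an optional `group` label.
#'
#' @param path Path to the TSV file.
#' @return Metadata data.frame with unique `sample_id`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  df
}

#' Build sample sets for a whole dataset
#'
#' Splits multi-sample contig and hit tables by sample, applies the
#' E-value/identity filter and per-locus deduplication, and attaches
#' metadata rows.
#'
#' @param contigs Multi-sample contig data.frame.
#' @param hits Multi-sample hit data.frame (unfiltered).
#' @param metadata Metadata data.frame or `NULL`.
#' @param max_evalue,min_identity Filter thresholds, see [filter_hits()].
#' @param dedup Per-locus deduplication flag, see [resolve_best_hit()].
#' @return Named list of `sample_set` objects, ordered by sample id.
#' @export
build_dataset <- function(contigs, hits, metadata = NULL,
                          max_evalue = 1e-5, min_identity = 80,
                          dedup = TRUE) {
  validate_hits(hits)
  hits <- resolve_best_hit(filter_hits(hits, max_evalue, min_identity),
                           dedup = dedup)
  ids <- sort(unique(contigs$sample_id))
  sets <- lapply(ids, function(id) {
    meta <- NULL
    if (!is.null(metadata)) {
      row <- metadata[metadata$sample_id == id, , drop = FALSE]
      if (nrow(row) == 1L) meta <- as.list(row)
    }
    build_sample_set(contigs[contigs$sample_id == id, , drop = FALSE],
                     hits[hits$sample_id == id, , drop = FALSE],
                     metadata = meta)
  })
  names(sets) <- ids
  sets
}

#' Write hits or contigs in the native TSV dialect
#'
#' @param df Hit or contig data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_native_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
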