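#' Contig-level co-localization indices
#'
#' The three statistics at the heart of the package, computed per sample
#' from a [build_sample_set()] object:
#'
#' * carrying rate (CR): the fraction of contigs carrying at least one
#'   gene of a class — a proxy for the proportion of organisms carrying
#'   that gene type;
#' * co-occurrence rate (CoR): the fraction of contigs carrying genes of
#'   two or more classes simultaneously;
#' * mobility potential (MP): the fraction of a class's genes that sit on
#'   a contig together with a mobile genetic element — a co-localization
#'   proxy for horizontal-transfer likelihood, not a transfer frequency.
#'
#' All three are dimensionless ratios: in a sample with 100,000 contigs a
#' change of one carrier moves CR by exactly 1e-5. Rates are returned as
#' doubles carrying the exact integer numerator and denominator as
#' attributes `count` and `total`, so differences of rates can be formed
#' without round-off via [rate_delta()].
#'
#' @name colocation-indices
NULL

rate_value <- function(count, total) {
  structure(count / total, count = as.double(count),
            total = as.double(total), class = "mobindex_rate")
}

#' @export
print.mobindex_rate <- function(x, ...) {
  cat(format(unclass(x)), " (", attr(x, "count"), "/", attr(x, "total"),
      ")\n", sep = "")
  invisible(x)
}

#' Exact difference of two rates
#'
#' Computes `b - a` from the integer numerators and denominators carried
#' by rates returned from [carrying_rate()] and friends, so the result is
#' a single correctly rounded double rather than a difference of two
#' rounded quotients. Both rates must share a denominator.
#'
#' @param a,b Rates from [carrying_rate()], [cooccurrence_rate()] or
#'   [mobility_potential()].
#' @return The exact rational difference, converted to double once.
#' @export
rate_delta <- function(a, b) {
  ta <- attr(a, "total"); tb <- attr(b, "total")
  if (is.null(ta) || is.null(tb)) stop("inputs must be mobindex rates")
  if (ta != tb) stop("rates have different denominators")
  (attr(b, "count") - attr(a, "count")) / ta
}

# per-contig set of gene classes present (deduplicated hits assumed)
contig_class_map <- function(set, classes = c("MRG", "ARG", "VFG")) {
  h <- set$hits[set$hits$gene_class %in% classes, , drop = FALSE]
  split(h$gene_class, factor(h$contig_id, levels = set$contigs$contig_id))
}

#' Carrying rate of a gene class
#'
#' Fraction of the sample's contigs carrying at least one gene of
#' `gene_class` (MRG, ARG or VFG).
#'
#' @param set A `sample_set`.
#' @param gene_class `"MRG"`, `"ARG"` or `"VFG"`.
#' @return A rate in \[0, 1\] with exact `count`/`total` attributes.
#' @export
carrying_rate <- function(set, gene_class = c("MRG", "ARG", "VFG")) {
  gene_class <- match.arg(gene_class)
  n <- nrow(set$contigs)
  if (n == 0L) stop("carrying rate undefined: sample has zero contigs")
  carriers <- unique(set$hits$contig_id[set$hits$gene_class == gene_class])
  rate_value(length(carriers), n)
}

#' Co-occurrence rate of gene classes
#'
#' Fraction of contigs carrying at least one gene of every class in
#' `classes`, or — with `classes = "any_pair"` — at least two distinct
#' classes among MRG/ARG/VFG. For any subset S, CoR(S) is bounded above by
#' the smallest carrying rate of its member classes.
#'
#' @param set A `sample_set`.
#' @param classes Character vector of two or three of `"MRG"`, `"ARG"`,
#'   `"VFG"`, or the sentinel `"any_pair"`.
#' @return A rate in \[0, 1\] with exact `count`/`total` attributes.
#' @export
cooccurrence_rate <- function(set, classes = c("MRG", "ARG", "VFG")) {
  n <- nrow(set$contigs)
  if (n == 0L) stop("co-occurrence rate undefined: sample has zero contigs")
  by_contig <- contig_class_map(set)
  if (identical(classes, "any_pair")) {
    count <- sum(vapply(by_contig, function(cl) length(unique(cl)) >= 2L,
                        logical(1)))
  } else {
    classes <- unique(match.arg(classes, c("MRG", "ARG", "VFG"),
                                several.ok = TRUE))
    if (length(classes) < 2L) {
      stop("co-occurrence needs at least two gene classes")
    }
    count <- sum(vapply(by_contig,
                        function(cl) all(classes %in% cl), logical(1)))
  }
  rate_value(count, n)
}

# contigs associated with an MGE category; plasmid/phage use the contig's
# mobility-context label (assembly-level plasmid/phage calls), the element
# categories use MGE hits on the contig. "plasmid" additionally accepts a
# plasmid_gene hit as evidence of plasmid context.
mge_contigs <- function(set, category) {
  mge <- set$hits[set$hits$gene_class == "MGE", , drop = FALSE]
  ctx <- set$contigs
  switch(category,
    overall = unique(c(
      mge$contig_id,
      ctx$contig_id[ctx$mobility_context %in% c("plasmid", "phage")]
    )),
    plasmid = unique(c(
      ctx$contig_id[ctx$mobility_context == "plasmid"],
      mge$contig_id[!is.na(mge$subclass) & mge$subclass == "plasmid_gene"]
    )),
    phage = ctx$contig_id[ctx$mobility_context == "phage"],
    unique(mge$contig_id[!is.na(mge$subclass) & mge$subclass == category])
  )
}

MP_CATEGORIES <- c("overall", "plasmid", "phage", "IS", "transposon",
                   "integron", "ICE")

#' Mobility potential of a gene class
#'
#' Fraction of the (deduplicated) genes of a class co-located on the same
#' contig as at least one mobile genetic element. Each gene is counted
#' once regardless of how many MGE partners share its contig. With zero
#' genes of the class the ratio is 0/0 and is reported as `NA` (missing),
#' never as 0 — a sample with no ARGs has no measurable ARG mobility.
#'
#' Categories `"IS"`, `"transposon"`, `"integron"` and `"ICE"` use MGE
#' hits on the contig; `"plasmid"` uses the contig's plasmid
#' mobility-context label or a plasmid-gene hit, and `"phage"` the phage
#' context label; `"overall"` is the union of all of these.
#'
#' @param set A `sample_set`.
#' @param gene_class `"MRG"`, `"ARG"` or `"VFG"`.
#' @param category One of `"overall"`, `"plasmid"`, `"phage"`, `"IS"`,
#'   `"transposon"`, `"integron"`, `"ICE"`.
#' @return A rate in \[0, 1\], or `NA` when the class has no genes.
#' @export
mobility_potential <- function(set, gene_class = c("MRG", "ARG", "VFG"),
                               category = "overall") {
  gene_class <- match.arg(gene_class)
  category <- match.arg(category, MP_CATEGORIES)
  genes <- set$hits[set$hits$gene_class == gene_class, , drop = FALSE]
  if (nrow(genes) == 0L) return(NA_real_)
  mobile <- genes$contig_id %in% mge_contigs(set, category)
  rate_value(sum(mobile), nrow(genes))
}

#' Per-sample index table
#'
#' One row per sample with every CR, CoR and MP column in a fixed order,
#' plus the integer denominators. Rows are sorted by sample id, so the
#' result is invariant to input order. Missing MP values (classes with
#' zero genes) are `NA`.
#'
#' @param dataset Named list of `sample_set` objects, as produced by
#'   [build_dataset()].
#' @return A data.frame with columns `sample_id`, `cr_*`, `cor_*`, `mp_*`
#'   and denominators `n_contigs`, `n_genes_*`.
#' @export
index_table <- function(dataset) {
  if (length(dataset) == 0L) stop("index table needs at least one sample")
  rows <- lapply(dataset, function(set) {
    row <- tryCatch(index_row(set), error = function(e) {
      stop("sample ", set$sample_id, ": ", conditionMessage(e), call. = FALSE)
    })
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

index_row <- function(set) {
  num <- function(r) as.numeric(r)
  cls <- c("MRG", "ARG", "VFG")
  row <- data.frame(sample_id = set$sample_id, stringsAsFactors = FALSE)
  row$cr_mrg <- num(carrying_rate(set, "MRG"))
  row$cr_arg <- num(carrying_rate(set, "ARG"))
  row$cr_vfg <- num(carrying_rate(set, "VFG"))
  row$cor_arg_mrg <- num(cooccurrence_rate(set, c("ARG", "MRG")))
  row$cor_arg_vfg <- num(cooccurrence_rate(set, c("ARG", "VFG")))
  row$cor_mrg_vfg <- num(cooccurrence_rate(set, c("MRG", "VFG")))
  row$cor_all3 <- num(cooccurrence_rate(set, cls))
  row$cor_any_pair <- num(cooccurrence_rate(set, "any_pair"))
  for (cl in cls) {
    row[[paste0("mp_", tolower(cl))]] <-
      num(mobility_potential(set, cl, "overall"))
  }
  for (cl in cls) {
    for (cat in setdiff(MP_CATEGORIES, "overall")) {
      row[[paste0("mp_", tolower(cl), "_", tolower(cat))]] <-
        num(mobility_potential(set, cl, cat))
    }
  }
  row$n_contigs <- nrow(set$contigs)
  for (cl in cls) {
    row[[paste0("n_genes_", tolower(cl))]] <-
      sum(set$hits$gene_class == cl)
  }
  row
}

#' Write an index table to TSV (missing values as empty fields)
#'
#' @param tbl Table from [index_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indices <- function(tbl, path) {
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Per-gene abundance matrix from hits
#'
#' Counts deduplicated hits per (sample, gene) for one gene class and
#' returns a samples-by-genes matrix, optionally converted to relative
#' abundance, as input to the diversity layer.
#'
#' @param hits Multi-sample hit data.frame (filtered, deduplicated).
#' @param gene_class One of `"MRG"`, `"ARG"`, `"VFG"`.
#' @param relative Normalize each row to sum to 1.
#' @return Numeric matrix, samples in rows, genes in columns.
#' @export
abundance_from_hits <- function(hits, gene_class = c("MRG", "ARG", "VFG"),
                                relative = FALSE) {
  gene_class <- match.arg(gene_class)
  h <- hits[hits$gene_class == gene_class, , drop = FALSE]
  if (nrow(h) == 0L) stop("no hits for gene class ", gene_class)
  tab <- table(h$sample_id, h$gene_name)
  m <- matrix(as.numeric(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  if (relative) m <- m / rowSums(m)
  m
}
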