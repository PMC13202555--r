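# Fixture builders and independent brute-force oracles used across the
# suite. Oracles are written as plain per-row / per-contig scans so they
# never share code with the implementation they check.

make_contigs <- function(sample_id, n, contexts = "chromosome-like") {
  data.frame(
    sample_id = sample_id,
    contig_id = sprintf("%s_c%04d", sample_id, seq_len(n)),
    length_bp = rep(1000L, n),
    mobility_context = rep_len(contexts, n),
    stringsAsFactors = FALSE
  )
}

make_hit <- function(sample_id, contig_id, gene_class, gene_name,
                     subclass = NA_character_, pident = 95,
                     evalue = 1e-10, bitscore = 100) {
  data.frame(sample_id = sample_id, contig_id = contig_id,
             gene_class = gene_class, subclass = subclass,
             gene_name = gene_name, pident = pident, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

empty_hits_df <- function() {
  make_hit("S", "c", "ARG", "g")[0, ]
}

# random annotated sample: genes and MGEs thrown on contigs uniformly
random_sample_set <- function(n_contigs = 50, n_hits = 60,
                              sample_id = "SX", plasmid_frac = 0.1) {
  ctx <- sample(c("plasmid", "phage", "chromosome-like", "unknown"),
                n_contigs, replace = TRUE,
                prob = c(plasmid_frac, 0.05, 0.8 - plasmid_frac, 0.15))
  contigs <- make_contigs(sample_id, n_contigs, contexts = "chromosome-like")
  contigs$mobility_context <- ctx
  classes <- sample(c("MRG", "ARG", "VFG", "MGE"), n_hits, replace = TRUE)
  sub <- ifelse(classes == "MGE",
                sample(c("plasmid_gene", "IS", "transposon", "integron",
                         "ICE"), n_hits, replace = TRUE),
                NA_character_)
  hits <- data.frame(
    sample_id = sample_id,
    contig_id = sample(contigs$contig_id, n_hits, replace = TRUE),
    gene_class = classes, subclass = sub,
    gene_name = paste0("g", sample.int(20, n_hits, replace = TRUE)),
    pident = runif(n_hits, 80, 100),
    evalue = 10^runif(n_hits, -20, -6),
    bitscore = runif(n_hits, 50, 300),
    stringsAsFactors = FALSE
  )
  hits <- resolve_best_hit(hits)
  build_sample_set(contigs, hits)
}

# --- brute-force index oracles --------------------------------------

oracle_cr <- function(set, gene_class) {
  carriers <- 0L
  for (cid in set$contigs$contig_id) {
    rows <- set$hits[set$hits$contig_id == cid, ]
    if (any(rows$gene_class == gene_class)) carriers <- carriers + 1L
  }
  carriers / nrow(set$contigs)
}

oracle_cor <- function(set, classes) {
  count <- 0L
  for (cid in set$contigs$contig_id) {
    present <- unique(set$hits$gene_class[set$hits$contig_id == cid])
    present <- intersect(present, c("MRG", "ARG", "VFG"))
    hit <- if (identical(classes, "any_pair")) {
      length(present) >= 2L
    } else {
      all(classes %in% present)
    }
    if (hit) count <- count + 1L
  }
  count / nrow(set$contigs)
}

oracle_mp <- function(set, gene_class, category = "overall") {
  genes <- set$hits[set$hits$gene_class == gene_class, ]
  if (nrow(genes) == 0L) return(NA_real_)
  mobile <- 0L
  for (r in seq_len(nrow(genes))) {
    cid <- genes$contig_id[r]
    ctx <- set$contigs$mobility_context[set$contigs$contig_id == cid]
    mge <- set$hits[set$hits$contig_id == cid &
                      set$hits$gene_class == "MGE", ]
    ok <- switch(category,
      overall = nrow(mge) > 0 || ctx %in% c("plasmid", "phage"),
      plasmid = ctx == "plasmid" ||
        any(mge$subclass == "plasmid_gene", na.rm = TRUE),
      phage = ctx == "phage",
      any(mge$subclass == category, na.rm = TRUE))
    if (ok) mobile <- mobile + 1L
  }
  mobile / nrow(genes)
}

# pseudo-F recomputed from first principles for a grouping
oracle_permanova_f <- function(dmat, groups) {
  dmat <- as.matrix(dmat)
  n <- length(groups)
  sst <- sum(dmat[lower.tri(dmat)]^2) / n
  ssw <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    sub <- dmat[i, i, drop = FALSE]
    ssw <- ssw + sum(sub[lower.tri(sub)]^2) / length(i)
  }
  a <- length(unique(groups))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

write_blast_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

blast_row <- function(qseqid, sseqid, pident, evalue, bitscore) {
  c(qseqid, sseqid, pident, "100", "5", "1", "1", "100", "1", "100",
    evalue, bitscore)
}

combinat_perms <- function(n) {
  # iterative permutation enumeration (n! rows)
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    nr <- nrow(out)
    grown <- matrix(0L, nr * k, k)
    r <- 0L
    for (pos in 1:k) {
      block <- cbind(out[, seq_len(pos - 1), drop = FALSE], k,
                     out[, seq.int(pos, k - 1)[seq_len(k - pos)],
                         drop = FALSE])
      grown[r + seq_len(nr), ] <- as.matrix(block)
      r <- r + nr
    }
    out <- grown
  }
  out
}
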