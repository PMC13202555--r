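#' Synthetic study configuration
#'
#' Describes a synthetic mining-soil metagenome annotation study: 12
#' samples (8 metal-contaminated "MS", 4 control) by default, each with a
#' contig table and per-class gene/MGE placements whose probabilities
#' depend linearly on the sample's metal covariates. Defaults emulate the
#' field design: Fe in g/kg, trace metals (Cr, V, Mn, Zn, Cu, Ni) in
#' mg/kg, plus pH, EC (uS/cm), WS, SOM, N (g/kg), AP and AK (mg/kg),
#' with the MS group elevated in metals. Carriage effects default to the
#' 1e-6 to 1e-4 per-unit magnitudes typical of contig-level rates.
#'
#' The carriage model is linear with clamping to \[0, 1\]:
#' p_class(x) = clamp(b0 + sum(b_m x_m)); clamping keeps the per-sample
#' expectations closed-form, and configurations that clamp more than
#' `max_clamp_frac` of samples are rejected at generation time.
#' `couple_prob` optionally adds a shared "cassette" Bernoulli that makes
#' a contig carry all three classes at once, creating genuine
#' co-selection signal (default 0: classes independent).
#'
#' @param n_samples Total samples (default 12).
#' @param n_ms Samples in the metal-contaminated group (default 8).
#' @param contigs_per_sample Contigs per sample (default 5000).
#' @param metal_model Named list of covariate specs, each
#'   `list(ms = c(mean, sd), control = c(mean, sd))`; concentrations are
#'   truncated at zero.
#' @param baseline Named per-class baseline carriage probabilities.
#' @param effects Named list per class: named vector of per-unit linear
#'   effects of covariates on carriage probability.
#' @param mge_prob Named per-category MGE placement probabilities.
#' @param mge_boost Multiplier on MGE placement probability for contigs
#'   carrying at least one MRG/ARG/VFG (default 3; 1 = independence).
#' @param context_prob Probabilities of plasmid / phage mobility-context
#'   labels.
#' @param couple_prob Shared-cassette probability (default 0).
#' @param noise_sd Sample-level index noise for regression study designs.
#' @param contaminate Fraction of extra below-threshold hit rows to
#'   inject, to exercise the E-value/identity filter (default 0).
#' @param max_clamp_frac Maximum tolerated fraction of clamped
#'   probabilities (default 0.01).
#' @param seed Integer seed (mandatory).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_samples = 12, n_ms = 8,
                         contigs_per_sample = 5000,
                         metal_model = default_metal_model(),
                         baseline = c(MRG = 0.02, ARG = 0.012, VFG = 0.016),
                         effects = default_carriage_effects(),
                         mge_prob = c(plasmid_gene = 0.004, IS = 0.006,
                                      transposon = 0.005, integron = 0.002,
                                      ICE = 0.002),
                         mge_boost = 3,
                         context_prob = c(plasmid = 0.02, phage = 0.01),
                         couple_prob = 0,
                         noise_sd = 0.005,
                         contaminate = 0,
                         max_clamp_frac = 0.01,
                         seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic generation")
  stopifnot(n_samples >= 2, n_ms >= 1, n_ms < n_samples,
            contigs_per_sample >= 0, mge_boost >= 0,
            couple_prob >= 0, couple_prob < 1,
            contaminate >= 0, contaminate < 1)
  for (cov in metal_model) {
    if (any(c(cov$ms[2], cov$control[2]) < 0)) stop("negative covariate sd")
  }
  structure(list(n_samples = n_samples, n_ms = n_ms,
                 contigs_per_sample = contigs_per_sample,
                 metal_model = metal_model, baseline = baseline,
                 effects = effects, mge_prob = mge_prob,
                 mge_boost = mge_boost, context_prob = context_prob,
                 couple_prob = couple_prob, noise_sd = noise_sd,
                 contaminate = contaminate,
                 max_clamp_frac = max_clamp_frac, seed = seed),
            class = "synth_config")
}

#' Default covariate model for the synthetic study
#'
#' Group means and standard deviations for the metal and physicochemical
#' covariates, MS group elevated in metals; values sit in the ranges
#' reported for mining-impacted desert soils (Fe tens of g/kg, V around
#' 100 mg/kg, N below 0.1 g/kg).
#'
#' @return Named list of `list(ms = c(mean, sd), control = c(mean, sd))`.
#' @export
default_metal_model <- function() {
  list(
    Fe = list(ms = c(100, 40), control = c(30, 8)),     # g/kg
    Cr = list(ms = c(90, 30), control = c(45, 12)),     # mg/kg
    V  = list(ms = c(120, 35), control = c(50, 15)),    # mg/kg
    Mn = list(ms = c(800, 200), control = c(550, 120)), # mg/kg
    Zn = list(ms = c(150, 50), control = c(70, 20)),    # mg/kg
    Cu = list(ms = c(60, 20), control = c(25, 8)),      # mg/kg
    Ni = list(ms = c(45, 15), control = c(25, 8)),      # mg/kg
    pH = list(ms = c(7.9, 0.4), control = c(7.6, 0.3)),
    EC = list(ms = c(1500, 800), control = c(300, 120)),  # uS/cm
    WS = list(ms = c(2.5, 1.0), control = c(1.0, 0.4)),   # g/kg
    SOM = list(ms = c(12, 4), control = c(15, 4)),        # g/kg
    N = list(ms = c(0.067, 0.02), control = c(0.037, 0.005)), # g/kg
    AP = list(ms = c(8, 3), control = c(10, 3)),          # mg/kg
    AK = list(ms = c(150, 50), control = c(120, 30))      # mg/kg
  )
}

#' Default per-unit carriage effects
#'
#' Linear effects of covariates on per-contig carriage probability, in
#' probability per covariate unit, at the 1e-6 to 1e-4 magnitudes of
#' contig-level rates: Cu and Fe promote carriage, Ni and Zn inhibit it,
#' V promotes ARG carriage.
#'
#' @return Named list (per class) of named effect vectors.
#' @export
default_carriage_effects <- function() {
  list(
    MRG = c(Cu = 5e-5, Fe = 2e-5, Ni = -4e-5),
    ARG = c(V = 5e-5, Ni = -6e-5, Zn = -1e-5),
    VFG = c(Cu = 3e-5, Zn = -1e-5)
  )
}

# synthetic gene catalogs with subclasses
GENE_CATALOG <- list(
  MRG = data.frame(
    gene_name = c("acn", "arsM", "ctpV", "czcA", "merA", "chrA", "nikA",
                  "zntA"),
    subclass = c("Fe", "As", "Cu", "multi-metal", "Hg", "Cr", "Ni", "Zn"),
    stringsAsFactors = FALSE),
  ARG = data.frame(
    gene_name = c("rpoB2", "Bado_rpoB_RIF", "vanR", "aac6", "tetM",
                  "mexB"),
    subclass = c("multidrug", "rifamycin", "glycopeptide",
                 "aminoglycoside", "tetracycline", "multidrug"),
    stringsAsFactors = FALSE),
  VFG = data.frame(
    gene_name = c("tufA", "clpC", "flgB", "sodB", "pilA", "hlyA"),
    subclass = c("adherence", "stress survival", "motility",
                 "stress survival", "adherence", "exotoxin"),
    stringsAsFactors = FALSE)
)

truncnorm_draw <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(x < 0)) x[x < 0] <- rnorm(sum(x < 0), mean, sd)
  x
}

#' Generate synthetic sample metadata
#'
#' Draws group-structured covariates from truncated normal distributions
#' (no negative concentrations), seeded from the config.
#'
#' @param config A [synth_config()].
#' @return List with `metadata` (data.frame, `sample_id`, `group`,
#'   covariates) and `truth` fragment recording the generative moments.
#' @export
generate_metadata <- function(config) {
  set.seed(config$seed)
  n <- config$n_samples
  group <- c(rep("MS", config$n_ms), rep("control", n - config$n_ms))
  meta <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = group, stringsAsFactors = FALSE
  )
  for (cov in names(config$metal_model)) {
    spec <- config$metal_model[[cov]]
    v <- numeric(n)
    v[group == "MS"] <- truncnorm_draw(sum(group == "MS"),
                                       spec$ms[1], spec$ms[2])
    v[group == "control"] <- truncnorm_draw(sum(group == "control"),
                                            spec$control[1], spec$control[2])
    meta[[cov]] <- v
  }
  list(metadata = meta,
       truth = list(metal_model = config$metal_model))
}

carriage_probs <- function(config, metadata) {
  out <- list()
  clamped <- 0L; total <- 0L
  for (cl in names(config$baseline)) {
    eff <- config$effects[[cl]]
    p <- rep(config$baseline[[cl]], nrow(metadata))
    for (cov in names(eff)) {
      p <- p + eff[[cov]] * metadata[[cov]]
    }
    total <- total + length(p)
    clamped <- clamped + sum(p < 0 | p > 1)
    out[[cl]] <- pmin(pmax(p, 0), 1)
  }
  attr(out, "clamp_frac") <- clamped / total
  out
}

#' Generate synthetic contig and hit tables
#'
#' For each contig, independently: per-class carriage Bernoulli draws
#' with the linear-in-covariates probability (plus the optional shared
#' cassette), gene names drawn from a fixed synthetic catalog, and MGE
#' hits placed with a probability multiplied by `mge_boost` on
#' gene-carrying contigs (inducing nonzero mobility potential). Identity
#' and E-value fields are drawn so every row passes the default filter
#' (identity in \[80, 100\], E-value log-uniform in \[1e-30, 1e-6\]);
#' with `contaminate > 0` extra below-threshold rows are appended.
#'
#' @param config A [synth_config()].
#' @param metadata Metadata from [generate_metadata()].
#' @return List with `contigs`, `hits` (native-dialect data.frames) and a
#'   `clamp_report`.
#' @export
generate_contigs_and_hits <- function(config, metadata) {
  probs <- carriage_probs(config, metadata)
  if (attr(probs, "clamp_frac") > config$max_clamp_frac) {
    stop("carriage model clamps ",
         format(100 * attr(probs, "clamp_frac"), digits = 3),
         "% of probabilities; loosen effects or raise max_clamp_frac")
  }
  set.seed((config$seed * 2654435761) %% .Machine$integer.max)
  contig_list <- list(); hit_list <- list()
  classes <- names(config$baseline)
  for (i in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[i]
    nc <- config$contigs_per_sample
    if (nc == 0L) next
    cid <- sprintf("%s_c%06d", sid, seq_len(nc))
    len <- pmax(500L, as.integer(round(rlnorm(nc, log(2000), 0.8))))
    ctx <- sample(c("plasmid", "phage", "chromosome-like"), nc,
                  replace = TRUE,
                  prob = c(config$context_prob[["plasmid"]],
                           config$context_prob[["phage"]],
                           1 - sum(config$context_prob)))
    contig_list[[sid]] <- data.frame(
      sample_id = sid, contig_id = cid, length_bp = len,
      mobility_context = ctx, stringsAsFactors = FALSE)

    cassette <- if (config$couple_prob > 0) {
      runif(nc) < config$couple_prob
    } else rep(FALSE, nc)
    carries <- matrix(FALSE, nc, length(classes),
                      dimnames = list(NULL, classes))
    for (cl in classes) {
      carries[, cl] <- (runif(nc) < probs[[cl]][i]) | cassette
    }
    any_gene <- rowSums(carries) > 0

    rows <- list()
    for (cl in classes) {
      idx <- which(carries[, cl])
      if (length(idx) == 0L) next
      cat_df <- GENE_CATALOG[[cl]]
      pick <- sample.int(nrow(cat_df), length(idx), replace = TRUE)
      rows[[cl]] <- data.frame(
        sample_id = sid, contig_id = cid[idx], gene_class = cl,
        subclass = cat_df$subclass[pick],
        gene_name = cat_df$gene_name[pick],
        pident = runif(length(idx), 80, 100),
        evalue = 10^runif(length(idx), -30, -6),
        bitscore = runif(length(idx), 60, 300),
        stringsAsFactors = FALSE)
    }
    mge_rows <- list()
    for (cat in names(config$mge_prob)) {
      p_cat <- pmin(config$mge_prob[[cat]] *
                      ifelse(any_gene, config$mge_boost, 1), 1)
      idx <- which(runif(nc) < p_cat)
      if (length(idx) == 0L) next
      mge_rows[[cat]] <- data.frame(
        sample_id = sid, contig_id = cid[idx], gene_class = "MGE",
        subclass = cat, gene_name = paste0(cat, "_element"),
        pident = runif(length(idx), 80, 100),
        evalue = 10^runif(length(idx), -30, -6),
        bitscore = runif(length(idx), 60, 300),
        stringsAsFactors = FALSE)
    }
    hit_list[[sid]] <- do.call(rbind, c(rows, mge_rows))
  }
  contigs <- do.call(rbind, contig_list)
  hits <- do.call(rbind, hit_list)
  if (is.null(hits)) hits <- empty_hits()
  if (is.null(contigs)) {
    contigs <- data.frame(sample_id = character(), contig_id = character(),
                          length_bp = integer(),
                          mobility_context = character(),
                          stringsAsFactors = FALSE)
  }
  if (config$contaminate > 0 && nrow(hits) > 0) {
    n_bad <- ceiling(config$contaminate * nrow(hits))
    bad <- hits[sample.int(nrow(hits), n_bad, replace = TRUE), ,
                drop = FALSE]
    low_id <- runif(n_bad) < 0.5
    bad$pident[low_id] <- runif(sum(low_id), 20, 79.9)
    bad$evalue[!low_id] <- 10^runif(sum(!low_id), -4, -1)
    hits <- rbind(hits, bad)
  }
  rownames(contigs) <- NULL; rownames(hits) <- NULL
  list(contigs = contigs, hits = hits,
       clamp_report = list(clamp_frac = attr(probs, "clamp_frac")))
}

#' Closed-form expected indices under the generative model
#'
#' Per-sample analytic expectations from independent-Bernoulli algebra,
#' used as oracles for the empirical indices. With carriage probability
#' p_c per class, shared-cassette probability q and MGE placement
#' probabilities m_k boosted by factor B on gene-carrying contigs:
#' E\[CR_c\] = 1 - (1 - p_c)(1 - q); pairwise E\[CoR\] =
#' q + (1 - q) p_a p_b; and E\[MP\] is the probability that a
#' gene-carrying contig is MGE-associated,
#' 1 - (1 - ctx_plasmid)(1 - ctx_phage) prod_k (1 - min(1, B m_k)).
#'
#' @param config A [synth_config()].
#' @param metadata Metadata from [generate_metadata()].
#' @return data.frame, one row per sample, columns `cr_*`, `cor_*`,
#'   `mp_any` plus `sample_id`.
#' @export
truth_indices <- function(config, metadata) {
  probs <- carriage_probs(config, metadata)
  q <- config$couple_prob
  eff <- function(p) 1 - (1 - p) * (1 - q)
  p_mrg <- probs$MRG; p_arg <- probs$ARG; p_vfg <- probs$VFG
  pair <- function(a, b) q + (1 - q) * a * b
  triple <- q + (1 - q) * p_mrg * p_arg * p_vfg
  m <- pmin(config$mge_prob * config$mge_boost, 1)
  p_mob <- 1 - (1 - config$context_prob[["plasmid"]]) *
    (1 - config$context_prob[["phage"]]) * prod(1 - m)
  data.frame(
    sample_id = metadata$sample_id,
    cr_mrg = eff(p_mrg), cr_arg = eff(p_arg), cr_vfg = eff(p_vfg),
    cor_arg_mrg = pair(p_arg, p_mrg),
    cor_arg_vfg = pair(p_arg, p_vfg),
    cor_mrg_vfg = pair(p_mrg, p_vfg),
    cor_all3 = triple,
    mp_any = p_mob,
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic dataset
#'
#' Metadata, contig table, hit table, analytic ground truth and the
#' clamping report, all from one seed. Regenerating with the same config
#' reproduces identical tables.
#'
#' @param config A [synth_config()].
#' @return List with `metadata`, `contigs`, `hits`, `truth`,
#'   `clamp_report`, `config`.
#' @export
generate_dataset <- function(config) {
  md <- generate_metadata(config)
  ch <- generate_contigs_and_hits(config, md$metadata)
  truth <- truth_indices(config, md$metadata)
  list(metadata = md$metadata, contigs = ch$contigs, hits = ch$hits,
       truth = truth, clamp_report = ch$clamp_report, config = config)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `meta.tsv`, `contigs.tsv`, `hits.tsv` in the native dialects and
#' `truth.json`.
#'
#' @param dataset From [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_native_tsv(dataset$metadata, file.path(dir, "meta.tsv"))
  write_native_tsv(dataset$contigs, file.path(dir, "contigs.tsv"))
  write_native_tsv(dataset$hits, file.path(dir, "hits.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
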