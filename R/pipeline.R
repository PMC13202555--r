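# Stage seeds are derived from the run seed and the stage name, so every
# stochastic stage has its own reproducible stream and adding a stage
# never perturbs the others. The mapping is part of the package contract.
fanout_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

config_checksum <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

default_run_config <- function() {
  list(
    seed = 17,
    out_dir = "mobindex_run",
    synth = list(enabled = TRUE),
    ingest = list(max_evalue = 1e-5, min_identity = 80, dedup = TRUE),
    diversity = list(gene_class = "ARG", metric = "horn",
                     permutations = 999),
    regress = list(
      models = list(
        list(response = "cr_mrg", predictors = c("Cu", "Ni", "Zn", "pH"),
             family = "auto"),
        list(response = "cr_arg", predictors = c("V", "Ni", "Zn", "pH"),
             family = "auto")
      ),
      chains = 4, draws = 2000, warmup = 1000
    )
  )
}

validate_run_config <- function(config) {
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$out_dir)) stop("config must set out_dir")
  synth_on <- isTRUE(config$synth$enabled)
  if (!synth_on) {
    for (f in c("contigs", "hits", "meta")) {
      path <- config$ingest[[f]]
      if (is.null(path)) stop("config ingest stage must name a ", f, " file")
      if (!file.exists(path)) stop("input file not found: ", path)
    }
  }
  for (m in config$regress$models) {
    if (is.null(m$response) || is.null(m$predictors)) {
      stop("each regression model needs a response and predictors")
    }
  }
  invisible(config)
}

#' Run the full pipeline
#'
#' Orchestrates synthetic generation (or ingestion of real annotation
#' tables), index computation, the diversity layer and the regression
#' cascade as one seeded, reproducible run. Individual regression models
#' fail independently: a singular fit is collected as an error in the
#' manifest without aborting the other models. All outputs are written
#' atomically (temp file + rename).
#'
#' @param config Path to a YAML run configuration, or an equivalent
#'   nested list. See `default_run_config` in the package sources for
#'   the schema; the defaults run a complete synthetic demonstration.
#' @return A `run_manifest` (list) with config checksum, input checksums,
#'   seed, package version, per-stage status and timings, output paths
#'   and collected per-model errors.
#' @export
run_all <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  # modifyList merges by name, so an unnamed user model list would be
  # silently dropped in favor of the defaults; keep it explicitly
  user_models <- config$regress$models
  config <- utils::modifyList(default_run_config(), config)
  if (!is.null(user_models)) config$regress$models <- user_models
  validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = config,
    config_checksum = config_checksum(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("mobindex")),
    input_checksums = list(),
    stages = list(), outputs = list(), errors = list()
  )
  t_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    status <- "ok"
    result <- tryCatch(fn(), error = function(e) {
      status <<- "error"
      manifest$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    manifest$stages[[name]] <<- list(
      status = status,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    result
  }

  # --- data stage: synthesize or ingest -------------------------------
  data_in <- t_stage("data", function() {
    if (isTRUE(config$synth$enabled)) {
      args <- config$synth
      args$enabled <- NULL
      args$seed <- fanout_seed(config$seed, "synth")
      cfg <- do.call(synth_config, args)
      ds <- generate_dataset(cfg)
      list(contigs = ds$contigs, hits = ds$hits, metadata = ds$metadata,
           truth = ds$truth)
    } else {
      for (f in c("contigs", "hits", "meta")) {
        manifest$input_checksums[[f]] <<-
          unname(tools::md5sum(config$ingest[[f]]))
      }
      list(contigs = read_contig_table(config$ingest$contigs),
           hits = do.call(rbind, lapply(
             strsplit(config$ingest$hits, ",")[[1]],
             parse_hit_table, dialect = "native")),
           metadata = read_metadata(config$ingest$meta),
           truth = NULL)
    }
  })
  if (is.null(data_in)) return(finish_manifest(manifest, out_dir))

  dataset <- t_stage("indices", function() {
    sets <- build_dataset(data_in$contigs, data_in$hits, data_in$metadata,
                          max_evalue = config$ingest$max_evalue,
                          min_identity = config$ingest$min_identity,
                          dedup = isTRUE(config$ingest$dedup))
    tbl <- index_table(sets)
    path <- file.path(out_dir, "indices.tsv")
    atomic_write(function(p) write_indices(tbl, p), path)
    manifest$outputs$indices <<- path
    jpath <- file.path(out_dir, "indices.json")
    atomic_write(function(p) jsonlite::write_json(
      tbl, p, dataframe = "rows", digits = NA, na = "null"), jpath)
    manifest$outputs$indices_json <<- jpath
    list(sets = sets, tbl = tbl,
         hits = resolve_best_hit(filter_hits(
           data_in$hits, config$ingest$max_evalue,
           config$ingest$min_identity), isTRUE(config$ingest$dedup)))
  })
  if (is.null(dataset)) return(finish_manifest(manifest, out_dir))

  t_stage("diversity", function() {
    cl <- config$diversity$gene_class
    mat <- abundance_from_hits(dataset$hits, cl)
    alpha <- alpha_diversity(mat)
    apath <- file.path(out_dir, "alpha.tsv")
    atomic_write(function(p) write.table(
      alpha, p, sep = "\t", quote = FALSE, row.names = FALSE), apath)
    manifest$outputs$alpha <<- apath

    d <- dissimilarity_matrix(mat, config$diversity$metric)
    dpath <- file.path(out_dir,
                       paste0("dissim_", config$diversity$metric, ".tsv"))
    atomic_write(function(p) write.table(
      as.matrix(d), p, sep = "\t", quote = FALSE), dpath)
    manifest$outputs$dissimilarity <<- dpath

    ord <- pcoa_ordination(d)
    ppath <- file.path(out_dir,
                       paste0("pcoa_", config$diversity$metric, ".tsv"))
    atomic_write(function(p) write.table(
      ord$coordinates, p, sep = "\t", quote = FALSE), ppath)
    manifest$outputs$pcoa <<- ppath

    groups <- data_in$metadata$group[
      match(rownames(as.matrix(d)), data_in$metadata$sample_id)]
    pm <- permanova(d, groups,
                    n_permutations = config$diversity$permutations,
                    seed = fanout_seed(config$seed, "permanova"))
    jpath <- file.path(out_dir, "permanova.json")
    atomic_write(function(p) jsonlite::write_json(
      unclass(pm), p, auto_unbox = TRUE, digits = NA), jpath)
    manifest$outputs$permanova <<- jpath
    manifest$results$permanova <<- pm
    NULL
  })

  t_stage("regress", function() {
    merged <- merge(dataset$tbl, data_in$metadata, by = "sample_id")
    results <- list()
    for (m in config$regress$models) {
      key <- paste0(m$response, "~", paste(m$predictors, collapse = "+"))
      fit <- tryCatch({
        fitter <- switch(m$family %||% "auto",
                         auto = auto_cascade, mlr = fit_mlr,
                         m_estimation = fit_m_estimation,
                         bayes = fit_bayes,
                         stop("unknown family: ", m$family))
        extra <- if (identical(m$family %||% "auto", "mlr") ||
                     identical(m$family, "m_estimation")) {
          list()
        } else {
          list(chains = config$regress$chains,
               draws = config$regress$draws,
               warmup = config$regress$warmup,
               seed = fanout_seed(config$seed, paste0("regress:", key)))
        }
        do.call(fitter, c(list(m$response, m$predictors, merged), extra))
      }, error = function(e) {
        manifest$errors[[paste0("regress:", key)]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(fit)) {
        fit$model <- NULL  # drop lm/rlm objects from the manifest
        fit$draws <- NULL
        fit$draws_by_chain <- NULL
        results[[key]] <- unclass(fit)
      }
    }
    rpath <- file.path(out_dir, "regression_results.json")
    atomic_write(function(p) jsonlite::write_json(
      results, p, auto_unbox = TRUE, digits = NA, force = TRUE,
      na = "null"), rpath)
    manifest$outputs$regression <<- rpath
    manifest$results$regression <<- results
    NULL
  })

  finish_manifest(manifest, out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finish_manifest <- function(manifest, out_dir) {
  manifest$ok <- length(manifest$errors) == 0L &&
    all(vapply(manifest$stages, function(s) s$status == "ok", logical(1)))
  mpath <- file.path(out_dir, "manifest.json")
  atomic_write(function(p) jsonlite::write_json(
    manifest[setdiff(names(manifest), "results")], p, auto_unbox = TRUE,
    digits = NA, force = TRUE, na = "null"), mpath)
  manifest$outputs$manifest <- mpath
  class(manifest) <- "run_manifest"
  manifest
}

#' Render a run manifest as a markdown report
#'
#' Deterministic, plain-markdown summary of a pipeline run: stage status,
#' index table, PERMANOVA result, selected regression families and their
#' convergence diagnostics. Missing mobility-potential values are shown
#' as missing, never as zero. An incomplete manifest yields a partial
#' report with warnings rather than an error.
#'
#' @param manifest A `run_manifest` from [run_all()].
#' @return Character vector of markdown lines, invisibly; also returned
#'   visibly as one string via `paste`.
#' @export
report <- function(manifest) {
  lines <- c("# mobindex run report", "",
             paste0("- seed: ", manifest$seed),
             paste0("- package version: ", manifest$package_version),
             paste0("- config checksum: ", manifest$config_checksum), "")
  lines <- c(lines, "## Stages", "")
  for (nm in names(manifest$stages)) {
    st <- manifest$stages[[nm]]
    lines <- c(lines, paste0("- ", nm, ": ", st$status,
                             " (", st$seconds, " s)"))
  }
  if (length(manifest$errors) > 0L) {
    lines <- c(lines, "", "## Errors", "")
    for (nm in names(manifest$errors)) {
      lines <- c(lines, paste0("- ", nm, ": ", manifest$errors[[nm]]))
    }
  }
  idx_path <- manifest$outputs$indices
  if (!is.null(idx_path) && file.exists(idx_path)) {
    tbl <- read.delim(idx_path, stringsAsFactors = FALSE)
    lines <- c(lines, "", "## Indices", "",
               paste0("- samples: ", nrow(tbl)))
    show <- intersect(c("sample_id", "cr_mrg", "cr_arg", "cr_vfg",
                        "cor_all3", "mp_mrg", "mp_arg", "mp_vfg"),
                      names(tbl))
    hdr <- paste0("| ", paste(show, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", length(show)), collapse = "|"), "|")
    fmt <- function(v) {
      if (is.numeric(v)) ifelse(is.na(v), "missing", signif(v, 4)) else v
    }
    body <- apply(tbl[show], 1, function(r) {
      vals <- mapply(function(v, nm) {
        x <- suppressWarnings(as.numeric(v))
        if (nm != "sample_id" && is.na(x)) "missing"
        else if (nm == "sample_id") v
        else format(signif(x, 4))
      }, r, show)
      paste0("| ", paste(vals, collapse = " | "), " |")
    })
    lines <- c(lines, hdr, sep, body)
  } else {
    lines <- c(lines, "", "_warning: indices output missing_")
  }
  pm <- manifest$results$permanova
  if (!is.null(pm)) {
    lines <- c(lines, "", "## PERMANOVA", "",
               paste0("- pseudo-F = ", signif(pm$pseudo_F, 4),
                      ", R2 = ", signif(pm$R2, 4),
                      ", p = ", signif(pm$p_value, 4),
                      " (", if (pm$exhaustive) "exhaustive" else
                        paste0(pm$n_permutations, " permutations"), ")"))
  }
  reg <- manifest$results$regression
  if (!is.null(reg) && length(reg) > 0L) {
    lines <- c(lines, "", "## Regression models", "")
    for (nm in names(reg)) {
      r <- reg[[nm]]
      extra <- if (identical(r$family_used, "bayes")) {
        paste0("; max R-hat = ",
               format(round(max(r$diagnostics$rhat, na.rm = TRUE), 2),
                      nsmall = 2),
               ", min bulk ESS = ",
               round(min(r$diagnostics$bulk_ess, na.rm = TRUE)))
      } else ""
      lines <- c(lines, paste0("- `", nm, "`: family = ",
                               r$family_used, extra))
    }
  }
  invisible(lines)
  paste(lines, collapse = "\n")
}
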