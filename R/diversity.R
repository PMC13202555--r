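#' Shannon diversity of one abundance row
#'
#' Natural-log Shannon index H = -sum(p log p) on the row's proportions;
#' zero-abundance features contribute nothing.
#'
#' @param x Non-negative numeric vector with positive sum.
#' @return H in nats.
#' @export
shannon_index <- function(x) {
  check_abundance_row(x)
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' Richness of one abundance row
#'
#' @param x Non-negative numeric vector with positive sum.
#' @return Integer count of strictly positive features.
#' @export
richness <- function(x) {
  check_abundance_row(x)
  sum(x > 0)
}

#' Pielou's evenness of one abundance row
#'
#' J = H / log(richness); undefined (`NA`) when only one feature is
#' present, since evenness of a single category has no meaning. Invariant
#' to the logarithm base used for H.
#'
#' @param x Non-negative numeric vector with positive sum.
#' @return J in \[0, 1\], or `NA` for richness 1.
#' @export
pielou_evenness <- function(x) {
  s <- richness(x)
  if (s == 1L) return(NA_real_)
  shannon_index(x) / log(s)
}

check_abundance_row <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  if (sum(x) <= 0) stop("all-zero abundance row")
  invisible(x)
}

#' Alpha-diversity table for an abundance matrix
#'
#' @param mat Samples-by-features non-negative matrix with rownames.
#' @return data.frame with `sample_id`, `shannon`, `richness`, `pielou`.
#' @export
alpha_diversity <- function(mat) {
  mat <- as.matrix(mat)
  data.frame(
    sample_id = rownames(mat),
    shannon = apply(mat, 1, shannon_index),
    richness = apply(mat, 1, richness),
    pielou = apply(mat, 1, pielou_evenness),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Two-group comparison (Student's t or Wilcoxon rank-sum)
#'
#' Two-sided tests. The Wilcoxon test uses exact enumeration when the
#' combined sample size is at most 12 and no ties are present, and the
#' normal approximation with tie correction otherwise.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (exactly two levels).
#' @param method `"t"` or `"wilcoxon"`.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
group_compare <- function(values, groups, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  split_vals <- split(values, groups)
  n <- lengths(split_vals)
  if (method == "t") {
    if (any(n < 2L)) stop("t-test needs >= 2 observations per group")
    if (all(vapply(split_vals, function(v) var(v) == 0, logical(1)))) {
      stop("zero variance in both groups: t statistic undefined")
    }
    ht <- t.test(split_vals[[1]], split_vals[[2]])
  } else {
    if (any(n < 1L)) stop("wilcoxon needs >= 1 observation per group")
    ties <- anyDuplicated(values) > 0L
    exact <- sum(n) <= 12L && !ties
    ht <- suppressWarnings(
      wilcox.test(split_vals[[1]], split_vals[[2]], exact = exact,
                  correct = !exact)
    )
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method)
}

#' Dissimilarity matrix (Bray-Curtis or Morisita-Horn)
#'
#' `"bray"` is the Bray-Curtis dissimilarity sum(|x-y|)/sum(x+y);
#' `"horn"` is 1 minus the Morisita-Horn similarity, the abundance-based
#' overlap measure that is invariant to total counts (so rescaling a row
#' leaves it unchanged, unlike Bray-Curtis).
#'
#' @param mat Samples-by-features non-negative matrix, no all-zero rows.
#' @param metric `"bray"` or `"horn"`.
#' @return A `dist` object with values in \[0, 1\].
#' @export
dissimilarity_matrix <- function(mat, metric = c("bray", "horn")) {
  metric <- match.arg(metric)
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be non-negative")
  if (any(rowSums(mat) == 0)) stop("all-zero abundance row")
  vegan::vegdist(mat, method = if (metric == "bray") "bray" else "horn")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a dissimilarity matrix: Gower double
#' centering and eigendecomposition, axes ordered by eigenvalue.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities such
#' as Bray-Curtis) are reported, not corrected. Axis signs are fixed by
#' making the largest-magnitude coordinate on each axis positive, so
#' results are reproducible across platforms.
#'
#' @param d A `dist` object or square symmetric matrix.
#' @return List with `coordinates` (samples x axes), `eigenvalues`, and
#'   `explained` (eigenvalue / sum of positive eigenvalues, for positive
#'   axes).
#' @export
pcoa_ordination <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop("dissimilarity matrix must be symmetric")
  }
  n <- nrow(m)
  fit <- cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE)
  coords <- fit$points
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  eig <- fit$eig
  pos <- sum(eig[eig > 0])
  list(coordinates = coords, eigenvalues = eig,
       explained = ifelse(eig > 0, eig / pos, NA_real_)[seq_len(ncol(coords))])
}

n_distinct_relabelings <- function(counts) {
  exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)))
}

permanova_f <- function(d2, groups) {
  n <- length(groups)
  a <- nlevels(groups)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  ss_among <- ss_total - ss_within
  f <- (ss_among / (a - 1)) / (ss_within / (n - a))
  c(f = f, r2 = ss_among / ss_total, ss_total = ss_total)
}

#' Permutational multivariate analysis of variance
#'
#' Anderson's pseudo-F from within- and between-group sums of squared
#' dissimilarities, with a raw-label permutation test. The p-value
#' includes the observed statistic: p = (1 + #\{F_perm >= F_obs\}) /
#' (1 + n_permutations), so p is never 0 and has resolution
#' 1/(n_permutations + 1). When the number of distinct relabelings is at
#' most `exhaustive_limit` the test enumerates all of them instead of
#' sampling, making the p-value seed-independent.
#'
#' @param d A `dist` or square symmetric dissimilarity matrix.
#' @param grouping Group labels, one per sample (>= 2 groups).
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive_limit Enumerate exhaustively when the number of
#'   distinct relabelings does not exceed this (default 10000).
#' @return List of class `mobindex_permanova`: `pseudo_F`, `R2`,
#'   `p_value`, `n_permutations`, `seed`, `exhaustive`, `degenerate`.
#' @export
permanova <- function(d, grouping, n_permutations = 999, seed = 1,
                      exhaustive_limit = 10000) {
  m <- as.matrix(d)
  groups <- droplevels(as.factor(as.character(grouping)))
  if (nlevels(groups) < 2L) stop("PERMANOVA needs at least two groups")
  if (any(table(groups) == 0L)) stop("empty group")
  if (length(groups) != nrow(m)) stop("grouping length must match matrix")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  d2 <- m^2
  obs <- permanova_f(d2, groups)
  if (obs[["ss_total"]] < 1e-300) {
    res <- list(pseudo_F = NaN, R2 = NaN, p_value = 1,
                n_permutations = 0L, seed = seed, exhaustive = TRUE,
                degenerate = TRUE)
    class(res) <- "mobindex_permanova"
    return(res)
  }
  n <- length(groups)
  counts <- table(groups)
  n_arr <- n_distinct_relabelings(counts)
  eps <- 1e-12 * max(1, abs(obs[["f"]]))
  if (is.finite(n_arr) && n_arr <= exhaustive_limit && nlevels(groups) == 2L) {
    k <- counts[[1]]
    combos <- combn(n, k)
    fs <- apply(combos, 2, function(idx) {
      g <- factor(ifelse(seq_len(n) %in% idx, levels(groups)[1],
                         levels(groups)[2]), levels = levels(groups))
      permanova_f(d2, g)[["f"]]
    })
    p <- mean(fs >= obs[["f"]] - eps)
    res <- list(pseudo_F = unname(obs[["f"]]), R2 = unname(obs[["r2"]]),
                p_value = p, n_permutations = ncol(combos), seed = seed,
                exhaustive = TRUE, degenerate = FALSE)
  } else {
    rng <- make_rng(seed)
    ge <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- sample_perm(rng, n)
      f <- permanova_f(d2, groups[perm])[["f"]]
      if (f >= obs[["f"]] - eps) ge <- ge + 1L
    }
    p <- (1 + ge) / (1 + n_permutations)
    res <- list(pseudo_F = unname(obs[["f"]]), R2 = unname(obs[["r2"]]),
                p_value = p, n_permutations = n_permutations, seed = seed,
                exhaustive = FALSE, degenerate = FALSE)
  }
  class(res) <- "mobindex_permanova"
  res
}

# local RNG stream: keeps permutation draws independent of the caller's
# global RNG state
make_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  env
}

sample_perm <- function(rng, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  assign(".Random.seed", rng$state, globalenv())
  out <- sample.int(n)
  rng$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  out
}

#' @export
print.mobindex_permanova <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", format(x$pseudo_F, digits = 4),
      " R2 =", format(x$R2, digits = 4),
      " p =", format(x$p_value, digits = 4),
      if (x$exhaustive) "(exhaustive)" else
        sprintf("(%d permutations, seed %d)", x$n_permutations, x$seed),
      "\n")
  invisible(x)
}

#' Shared and unique feature partition between two groups
#'
#' Splits the union of two feature sets into shared, unique-to-a and
#' unique-to-b compartments and reports counts and percentages of the
#' total, percentages rounded to one decimal — the numbers behind a
#' two-set Venn diagram.
#'
#' @param features_a,features_b Character vectors of feature ids observed
#'   in each group.
#' @return data.frame with `compartment`, `count`, `percent`.
#' @export
venn_partition <- function(features_a, features_b) {
  a <- unique(features_a); b <- unique(features_b)
  shared <- length(intersect(a, b))
  only_a <- length(setdiff(a, b))
  only_b <- length(setdiff(b, a))
  total <- shared + only_a + only_b
  if (total == 0L) stop("no features in either group")
  counts <- c(shared = shared, unique_a = only_a, unique_b = only_b)
  data.frame(compartment = names(counts), count = as.integer(counts),
             percent = round(100 * counts / total, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
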