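#' Default embryonic stage grid
#'
#' Ten developmental stages spanning early cleavage to hatching: 4-cell,
#' E-cell division, the 4th-7th AB cell divisions, ventral enclosure
#' (~290 min), comma stage, first movement, and L1. Minutes are measured
#' from the first cell division; the first six stages fall before the
#' 200-minute early-embryogenesis cutoff and ventral enclosure onward lies
#' at or after 290 minutes.
#'
#' @return data.frame with `label` and `minutes`.
#' @export
default_stages <- function() {
  data.frame(
    label = c("4cell", "Ediv", "AB4", "AB5", "AB6", "AB7",
              "VE", "comma", "movement", "L1"),
    minutes = c(5, 35, 65, 95, 125, 155, 290, 360, 430, 550),
    stringsAsFactors = FALSE)
}

#' Standardize expression profiles for pattern clustering
#'
#' "Relative expression" is implemented as per-gene z-scoring of log2
#' values (population-sd denominator): profiles become comparable across
#' absolute levels so clustering groups by shape. Zeros are replaced by
#' half the smallest positive value in the matrix (logged via message);
#' constant rows get a zero vector and a flag rather than dividing by a
#' zero sd.
#'
#' @param expr `chap_expression` or a numeric matrix of positive values.
#' @return `chap_profiles`: list with `z` (genes x stages matrix of
#'   standardized log2 values) and `constant` (logical per gene).
#' @export
normalize_profiles <- function(expr) {
  values <- if (inherits(expr, "chap_expression")) expr$values
            else as.matrix(expr)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (any(values == 0)) {
    half_min <- min(values[values > 0]) / 2
    message(sum(values == 0), " zero cell(s) replaced by ", half_min)
    values[values == 0] <- half_min
  }
  lg <- log2(values)
  mu <- rowMeans(lg)
  # population (1/n) sd: a 3-point profile (2,4,8) maps to +-1.2247, 0
  sdv <- sqrt(rowMeans((lg - mu)^2))
  constant <- sdv < 1e-12
  z <- (lg - mu) / ifelse(constant, 1, sdv)
  z[constant, ] <- 0
  structure(list(z = z, constant = constant), class = "chap_profiles")
}

#' Agglomerative hierarchical clustering of expression profiles
#'
#' Correlation distance (1 - Pearson) with average linkage is the default,
#' the standard choice for expression pattern discovery; Euclidean distance
#' and complete linkage are available. The merge tree comes from
#' [stats::hclust()] and flat labels from cutting into `k` clusters or at a
#' height threshold.
#'
#' @param profiles `chap_profiles` or a numeric matrix (rows are genes).
#' @param metric `"correlation"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @param k number of flat clusters (optional if `h` given).
#' @param h height threshold alternative to `k`.
#' @return `chap_clust`: list with `labels` (named integer vector),
#'   `tree` (hclust object) and `params`.
#' @export
hierarchical_cluster <- function(profiles,
                                 metric = c("correlation", "euclidean"),
                                 linkage = c("average", "complete"),
                                 k = NULL, h = NULL) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  m <- if (inherits(profiles, "chap_profiles")) profiles$z
       else as.matrix(profiles)
  if (nrow(m) < 2) stop("need at least 2 profiles to cluster")
  if (!is.null(k) && k > nrow(m)) stop("k exceeds the number of profiles")
  d <- if (metric == "correlation") stats::as.dist(1 - stats::cor(t(m)))
       else stats::dist(m)
  tree <- stats::hclust(d, method = linkage)
  labels <- if (!is.null(k) || !is.null(h)) stats::cutree(tree, k = k, h = h)
            else stats::setNames(rep(1L, nrow(m)), rownames(m))
  structure(list(labels = labels, tree = tree,
                 params = list(metric = metric, linkage = linkage,
                               k = k, h = h)),
            class = "chap_clust")
}

#' MI (myogenesis-induced) classifier configuration
#'
#' The MI template: essentially flat expression before 200 minutes of
#' embryogenesis, then a strong increase from the ventral-enclosure stage
#' (~290 min) onward. A profile is MI when its early coefficient of
#' variation stays below `max_early_cv` and the maximum post-induction
#' level is at least `min_fold` times the early mean (linear scale).
#'
#' @param early_cutoff_minutes stages strictly before this are "early"
#'   (default 200).
#' @param induction_stage_minutes induction is assessed at stages at or
#'   after this time (default 290, ventral enclosure).
#' @param min_fold minimum linear fold increase (default 2).
#' @param max_early_cv maximum early coefficient of variation (default 0.5).
#' @return `chap_mi_config` list.
#' @export
mi_config <- function(early_cutoff_minutes = 200,
                      induction_stage_minutes = 290,
                      min_fold = 2.0, max_early_cv = 0.5) {
  if (early_cutoff_minutes >= induction_stage_minutes)
    stop("early cutoff must precede the induction stage")
  if (min_fold <= 1) stop("min_fold must exceed 1")
  structure(list(early_cutoff_minutes = early_cutoff_minutes,
                 induction_stage_minutes = induction_stage_minutes,
                 min_fold = min_fold, max_early_cv = max_early_cv),
            class = "chap_mi_config")
}

#' Classify a raw profile against the MI template
#'
#' @param profile_raw numeric vector of raw (unstandardized, positive)
#'   expression values.
#' @param stage_minutes stage times matching the profile.
#' @param config `chap_mi_config`.
#' @return list with `mi` (logical), `fold` (max late / mean early) and
#'   `early_cv`.
#' @export
classify_mi <- function(profile_raw, stage_minutes, config = mi_config()) {
  stopifnot(length(profile_raw) == length(stage_minutes))
  early <- stage_minutes < config$early_cutoff_minutes
  late <- stage_minutes >= config$induction_stage_minutes
  if (!any(early)) stop("no stages before the early cutoff")
  if (!any(late)) stop("no stages at or after the induction stage")
  e <- profile_raw[early]
  mu <- mean(e)
  early_cv <- if (mu > 0) stats::sd(e) / mu else Inf
  fold <- if (mu > 0) max(profile_raw[late]) / mu else Inf
  list(mi = is.finite(fold) && early_cv <= config$max_early_cv &&
         fold >= config$min_fold,
       fold = fold, early_cv = early_cv)
}

#' MI classification and cluster co-membership for gene subsets
#'
#' Applies [classify_mi()] to every gene of an expression matrix, then
#' counts MI-classified genes inside each named subset. Cluster identity is
#' reported as corroboration: the fraction of each subset's MI genes that
#' fall in the single most MI-enriched flat cluster.
#'
#' @param expr `chap_expression`.
#' @param gene_subsets named list of character vectors.
#' @param config `chap_mi_config`.
#' @param k number of flat clusters for co-membership (default 6).
#' @return list with `mi` (per-gene logical), `subset_counts` (data.frame)
#'   and `clusters` (`chap_clust`).
#' @export
mi_cluster_report <- function(expr, gene_subsets = list(),
                              config = mi_config(), k = 6) {
  stopifnot(inherits(expr, "chap_expression"))
  mi <- vapply(seq_len(nrow(expr$values)), function(i)
    classify_mi(expr$values[i, ], expr$stage_minutes, config)$mi, logical(1))
  names(mi) <- expr$gene_ids
  k_use <- min(k, nrow(expr$values))
  clusters <- hierarchical_cluster(normalize_profiles(expr), k = k_use)
  keys <- gene_key(expr$gene_ids)
  counts <- lapply(names(gene_subsets), function(nm) {
    sk <- gene_key(gene_subsets[[nm]])
    present <- keys %in% sk
    if (!any(present))
      warning("subset '", nm, "' shares no genes with the matrix")
    data.frame(subset = nm, n_in_matrix = sum(present),
               n_mi = sum(mi[present]), stringsAsFactors = FALSE)
  })
  list(mi = mi,
       subset_counts = do.call(rbind, c(list(
         data.frame(subset = "all", n_in_matrix = length(mi),
                    n_mi = sum(mi), stringsAsFactors = FALSE)), counts)),
       clusters = clusters)
}

#' Adjusted Rand index between two labelings
#'
#' Used to score cluster recovery against planted ground truth.
#'
#' @param a,b label vectors of equal length.
#' @return numeric in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
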