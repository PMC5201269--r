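#' Simulation configuration
#'
#' One seeded configuration drives every generator. Defaults restate the
#' structure of the published analysis: a 97-gene universe with 62
#' occupancy-positive and 53 muscle-associated genes (enriched 46,
#' required 24), an occupancy-muscle odds ratio of 2.5 (the odds ratio of
#' the published 39/23/14/21 table), MI time courses with fold 8 and log2
#' noise sd 0.2, 1000-bp promoters at C. elegans-like 36% GC, and qPCR at
#' true fold 10 with 0.1-cycle noise over 5 replicates.
#'
#' @param seed integer seed; fully determines all generator output.
#' @param n_genes catalog/universe size.
#' @param n_occ,n_muscle,n_enriched,n_required evidence-set size targets.
#' @param odds_ratio occupancy-muscle association odds ratio (theta > 0).
#' @param detect_p per-experiment detection probability given union
#'   membership.
#' @param n_timecourse_genes,mi_fraction,mi_fold,log2_noise_sd time-course
#'   parameters.
#' @param stage_minutes,stage_labels 10-stage grid (default
#'   [default_stages()]).
#' @param promoter_length,gc_content,n_promoters,planted_sites promoter
#'   parameters; `planted_sites` is a data.frame with columns `gene`,
#'   `tss_rel`, `word`.
#' @param true_folds named numeric of per-gene true fold changes.
#' @param ct_noise_sd,n_replicates,reference_gene qPCR parameters.
#' @return `chap_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 97L, n_occ = 62L, n_muscle = 53L,
                       n_enriched = 46L, n_required = 24L,
                       odds_ratio = 2.5, detect_p = 0.6,
                       n_timecourse_genes = 500L, mi_fraction = 0.2,
                       mi_fold = 8, log2_noise_sd = 0.2,
                       stage_minutes = default_stages()$minutes,
                       stage_labels = default_stages()$label,
                       promoter_length = 1000L, gc_content = 0.36,
                       n_promoters = 10L,
                       planted_sites = default_planted_sites(),
                       true_folds = c("daf-21" = 10),
                       ct_noise_sd = 0.1, n_replicates = 5L,
                       reference_gene = "T07A9.15") {
  stopifnot(odds_ratio > 0, mi_fraction >= 0, mi_fraction <= 1,
            gc_content >= 0, gc_content <= 1, mi_fold > 0,
            n_occ <= n_genes, n_muscle <= n_genes,
            n_enriched <= n_muscle, n_required <= n_muscle,
            n_enriched + n_required >= n_muscle,
            seed == floor(seed), abs(seed) < 2^31)
  structure(as.list(environment()), class = "chap_sim_config")
}

#' Default planted E-box sites
#'
#' Three consensus sites at the TSS-relative positions used in the
#' published promoter mutagenesis (-432 for the Hsp90 promoter; -921 and
#' -266 for the sHsp promoter); the sequences themselves are synthetic.
#'
#' @return data.frame with `gene`, `tss_rel`, `word`.
#' @export
default_planted_sites <- function() {
  data.frame(gene = c("daf-21", "hsp-12.2", "hsp-12.2"),
             tss_rel = c(-432L, -921L, -266L),
             word = c("CAGGTG", "CACCTG", "CAGCTG"),
             stringsAsFactors = FALSE)
}

# Fisher noncentral hypergeometric draw of the overlap count
rnoncentral_hyper <- function(n, K, N, theta) {
  k_min <- max(0L, n + K - N)
  k_max <- min(n, K)
  ks <- k_min:k_max
  lw <- lchoose(K, ks) + lchoose(N - K, n - ks) + ks * log(theta)
  w <- exp(lw - max(lw))
  sample(ks, 1L, prob = w)
}

#' Simulate a catalog with occupancy and muscle evidence sets
#'
#' Set sizes are conditioned on the configured margins; the overlap
#' between the occupancy and muscle-associated sets is drawn from the
#' Fisher noncentral hypergeometric distribution with the configured odds
#' ratio, so theta = 1 reproduces the null of the overlap test exactly.
#' The muscle set is split into enriched/required subsets at the target
#' sizes and each category union is spread over three per-experiment sets
#' (detection probability `detect_p`, conditioned on at least one).
#'
#' @param config `chap_sim_config`.
#' @return list with `catalog`, `evidence_sets` and `truth` (realized 2x2
#'   table, member sets, theta).
#' @export
simulate_catalog <- function(config = sim_config()) {
  set.seed(config$seed)
  N <- config$n_genes
  genes <- sprintf("chap-%03d", seq_len(N))
  families <- sample(c("Hsp60/10", "Hsp70", "Hsp40/NEF",
                       "Hsp90/cochaperone", "sHsp", "other"),
                     N, replace = TRUE)
  occ <- sample(genes, config$n_occ)
  k <- rnoncentral_hyper(config$n_occ, config$n_muscle, N,
                         config$odds_ratio)
  muscle <- c(sample(occ, k),
              sample(setdiff(genes, occ), config$n_muscle - k))
  o <- config$n_enriched + config$n_required - config$n_muscle
  shuffled <- sample(muscle)
  both <- shuffled[seq_len(o)]
  enr_only <- shuffled[o + seq_len(config$n_enriched - o)]
  req_only <- shuffled[config$n_enriched + seq_len(config$n_required - o)]
  enriched <- c(both, enr_only)
  required <- c(both, req_only)
  spread <- function(members, prefix, category) {
    memb <- matrix(stats::runif(length(members) * 3) < config$detect_p,
                   ncol = 3)
    none <- rowSums(memb) == 0
    memb[cbind(which(none), sample.int(3, sum(none), replace = TRUE))] <- TRUE
    lapply(1:3, function(j)
      chap_evidence(paste0(prefix, j), category, members[memb[, j]],
                    source_note = "simulated"))
  }
  list(catalog = chap_catalog(genes, families),
       evidence_sets = c(spread(occ, "occ_", "occupancy"),
                         spread(enriched, "enr_", "enrichment"),
                         spread(required, "req_", "required")),
       truth = list(occupancy = occ, muscle = muscle,
                    enriched = enriched, required = required,
                    table = list(k = k, n = config$n_occ,
                                 K = config$n_muscle, N = N),
                    theta = config$odds_ratio))
}

#' Simulate a 10-stage developmental time course with a planted MI subset
#'
#' Non-MI genes are flat in log2 with Gaussian noise; MI genes step up by
#' log2(`mi_fold`) from the induction stage (ventral enclosure, 290 min)
#' onward. Values are returned on the linear scale.
#'
#' @param config `chap_sim_config`.
#' @return list with `expression` (`chap_expression`) and `truth` (MI gene
#'   ids).
#' @export
simulate_timecourse <- function(config = sim_config()) {
  set.seed(config$seed + 1L)
  mins <- config$stage_minutes
  if (!any(mins < 200) || !any(mins >= 290))
    stop("stage grid must include stages before 200 and at/after 290 min")
  n <- config$n_timecourse_genes
  genes <- sprintf("gene-%04d", seq_len(n))
  n_mi <- round(config$mi_fraction * n)
  mi_genes <- sample(genes, n_mi)
  baseline <- stats::runif(n, 5, 10)
  lg <- matrix(baseline, n, length(mins)) +
    matrix(stats::rnorm(n * length(mins), 0, config$log2_noise_sd),
           n, length(mins))
  step <- outer(genes %in% mi_genes, mins >= 290) * log2(config$mi_fold)
  lg <- lg + step
  list(expression = chap_expression(2^lg, genes, config$stage_labels, mins),
       truth = list(mi_genes = mi_genes))
}

#' Simulate promoter sequences with planted E-box sites
#'
#' Background bases are i.i.d. at the configured GC content; planted words
#' overwrite the background at their TSS-relative positions. The truth is
#' oracle-complete: it lists every consensus (CANNTG) occurrence, planted
#' or background-arising, found with a plain regular expression.
#'
#' @param config `chap_sim_config`.
#' @return list with `sequences` (named character vector) and `truth`
#'   (planted sites and a per-gene data.frame of all consensus positions).
#' @export
simulate_promoters <- function(config = sim_config()) {
  set.seed(config$seed + 2L)
  L <- config$promoter_length
  gc <- config$gc_content
  planted <- config$planted_sites
  genes <- unique(c(planted$gene,
                    sprintf("bg-%03d", seq_len(config$n_promoters))))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(genes, function(g) {
    s <- sample(names(probs), L, replace = TRUE, prob = probs)
    for (i in which(planted$gene == g)) {
      w <- strsplit(planted$word[i], "")[[1]]
      pos0 <- L + planted$tss_rel[i]
      if (pos0 < 0 || pos0 + length(w) > L)
        stop("planted site outside the promoter: ", planted$gene[i])
      s[pos0 + seq_along(w)] <- w
    }
    paste(s, collapse = "")
  }, character(1))
  oracle <- lapply(seqs, function(s) {
    m <- gregexpr("(?=CA..TG)", s, perl = TRUE)[[1]]
    pos <- if (m[1] == -1) integer() else as.integer(m) - 1L
    data.frame(tss_rel = pos - L, stringsAsFactors = FALSE)
  })
  list(sequences = seqs,
       truth = list(planted = planted, consensus_sites = oracle))
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Reference Ct ~ Normal(mu_ref, sd); target Ct adds a baseline offset and
#' subtracts log2(true fold) in the treated condition, so the 2^-ddCt
#' estimate recovers the configured fold.
#'
#' @param config `chap_sim_config`.
#' @param mu_ref mean reference Ct (default 15).
#' @param dct_base baseline target-minus-reference offset (default 5).
#' @return list with `ct` (`chap_ct`) and `truth` (true folds).
#' @export
simulate_qpcr <- function(config = sim_config(), mu_ref = 15,
                          dct_base = 5) {
  stopifnot(config$n_replicates >= 2)
  set.seed(config$seed + 3L)
  rows <- list()
  conds <- c("treated", "control")
  for (cond in conds) {
    rows[[cond]] <- data.frame(
      gene_id = config$reference_gene, condition = cond,
      replicate = seq_len(config$n_replicates),
      ct = stats::rnorm(config$n_replicates, mu_ref, config$ct_noise_sd),
      stringsAsFactors = FALSE)
  }
  for (g in names(config$true_folds)) {
    for (cond in conds) {
      shift <- if (cond == "treated") log2(config$true_folds[[g]]) else 0
      rows[[paste(g, cond)]] <- data.frame(
        gene_id = g, condition = cond,
        replicate = seq_len(config$n_replicates),
        ct = stats::rnorm(config$n_replicates,
                          mu_ref + dct_base - shift, config$ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  list(ct = chap_ct(do.call(rbind, unname(rows))),
       truth = list(true_folds = config$true_folds))
}
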