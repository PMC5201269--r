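#' Run the full analysis pipeline from a configuration
#'
#' Stages run in dependency order: `rank` (evidence integration and group
#' assignment), `overlap` (exact set statistics), `cluster` (time-course
#' normalization and MI classification), `scan` (promoter motif scan) and
#' `qpcr` (relative quantification). Stages communicate only via files; a
#' stage whose inputs are missing is skipped with a recorded reason, and
#' the JSON report collects every stage's outputs together with the config
#' hash and package version.
#'
#' Configuration keys (all optional): `stages` (character vector of stage
#' names to enable), `catalog`, `evidence` (list of
#' `{path, category}`), `use_packaged_evidence` (logical), `expression`
#' (path), `stage_minutes`, `subsets` (named list of gene-list files),
#' `promoters` (FASTA path), `consensus`, `pwm_threshold`, `ct_table`
#' (path), `qpcr` (list with `gene`, `reference_gene`, `treated`,
#' `control`).
#'
#' @param config named list (see [read_config()]) or path to a JSON
#'   config.
#' @param out_dir output directory for stage files and the report.
#' @return `chap_report` (named list), invisibly written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("chaperonet_run_")) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% character()
  report <- list(
    tool = "chaperonet",
    version = as.character(utils::packageVersion("chaperonet")),
    config_hash = attr(config, "config_hash") %||% NA_character_,
    config = config[setdiff(names(config), "stages")],
    stages_enabled = as.list(stages),
    stages = list(), warnings = list(), outputs = list())
  if (!length(stages)) {
    warning("no stages enabled; empty report")
    write_report(report, file.path(out_dir, "report.json"))
    return(invisible(structure(report, class = "chap_report")))
  }
  note <- function(msg) report$warnings[[length(report$warnings) + 1]] <<- msg
  rank_table <- NULL
  sets <- NULL

  if ("rank" %in% stages || "overlap" %in% stages) {
    ev <- NULL
    if (isTRUE(config$use_packaged_evidence)) {
      pk <- packaged_evidence()
      catalog <- pk$catalog
      ev <- pk$evidence_sets
    } else if (!is.null(config$catalog) && !is.null(config$evidence)) {
      catalog <- read_catalog(config$catalog)
      ev <- unlist(lapply(config$evidence, function(e)
        read_evidence_table(e$path, e$category)), recursive = FALSE)
    }
    if (is.null(ev)) {
      note("rank skipped: no catalog/evidence configured")
    } else {
      rank_table <- rank_evidence(catalog, ev)
      sets <- set_summary(rank_table)
      path <- file.path(out_dir, "rank_table.tsv")
      write_ranktable(rank_table, path)
      report$outputs$rank_table <- path
      report$stages$rank <- list(
        n_genes = nrow(rank_table),
        sizes = as.list(sets$sizes),
        group_sizes = as.list(stats::setNames(
          tabulate(rank_table$group, 4), paste0("group", 1:4))))
    }
  }

  if ("overlap" %in% stages) {
    if (is.null(sets)) {
      note("overlap skipped: rank stage did not run")
    } else {
      universe <- rank_table$gene_id
      pair <- function(a, b) {
        fo <- fisher_overlap(sets[[a]], sets[[b]], universe)
        list(k = fo$table$k, n = fo$table$n, K = fo$table$K,
             N = fo$table$N, p_value = fo$test$p_value)
      }
      report$stages$overlap <- list(
        required_vs_enriched = pair("required_set", "enriched_set"),
        occupancy_vs_muscle = pair("occupancy_set", "muscle_set"),
        no_occupancy_vs_muscle = local({
          no_occ <- setdiff(universe, sets$occupancy_set)
          fo <- fisher_overlap(no_occ, sets$muscle_set, universe)
          list(k = fo$table$k, n = fo$table$n, K = fo$table$K,
               N = fo$table$N, p_value = fo$test$p_value)
        }),
        venn_enriched_required = apply(
          venn_counts(list(enriched = sets$enriched_set,
                           required = sets$required_set),
                      universe), 1, function(r) unname(r[["count"]])))
    }
  }

  if ("cluster" %in% stages) {
    if (is.null(config$expression)) {
      note("cluster skipped: no expression matrix configured")
    } else {
      expr <- read_expression_matrix(config$expression,
                                     config$stage_minutes)
      subsets <- lapply(config$subsets %||% list(), function(p)
        readLines(p, warn = FALSE))
      rep_cl <- mi_cluster_report(expr, subsets)
      path <- file.path(out_dir, "mi_classification.tsv")
      utils::write.table(
        data.frame(gene_id = names(rep_cl$mi), mi = rep_cl$mi,
                   cluster = rep_cl$clusters$labels),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
      report$outputs$mi_classification <- path
      report$stages$cluster <- list(
        n_genes = length(rep_cl$mi), n_mi = sum(rep_cl$mi),
        subset_counts = lapply(
          seq_len(nrow(rep_cl$subset_counts)), function(i)
            as.list(rep_cl$subset_counts[i, ])))
    }
  }

  if ("scan" %in% stages) {
    if (is.null(config$promoters)) {
      note("scan skipped: no promoter FASTA configured")
    } else {
      seqs <- read_fasta(config$promoters)
      consensus <- config$consensus %||% "CANNTG"
      hits <- lapply(seqs, scan_consensus, consensus = consensus)
      path <- file.path(out_dir, "motif_hits.tsv")
      all_hits <- do.call(rbind, lapply(names(hits), function(g)
        if (nrow(hits[[g]])) cbind(gene_id = g, hits[[g]])))
      utils::write.table(all_hits %||%
                           data.frame(gene_id = character()), path,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$outputs$motif_hits <- path
      report$stages$scan <- list(
        consensus = consensus, n_promoters = length(seqs),
        n_with_motif = sum(vapply(hits, nrow, integer(1)) > 0),
        n_hits = sum(vapply(hits, nrow, integer(1))))
    }
  }

  if ("qpcr" %in% stages) {
    if (is.null(config$ct_table) || is.null(config$qpcr)) {
      note("qpcr skipped: no Ct table / qpcr settings configured")
    } else {
      ct <- read_ct_table(config$ct_table)
      q <- config$qpcr
      res <- qpcr_quantify(ct, q$gene, q$reference_gene,
                           q$treated, q$control)
      report$stages$qpcr <- list(
        gene = q$gene, reference_gene = q$reference_gene,
        fold = res$fold, ddct = res$ddct, sem = res$sem,
        replicate_folds = res$replicate_folds)
    }
  }

  write_report(report, file.path(out_dir, "report.json"))
  report$outputs$report <- file.path(out_dir, "report.json")
  invisible(structure(report, class = "chap_report"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `rank`, `overlap`, `cluster`, `scan`, `qpcr`, `simulate`,
#' `run`. All take `--config <json>` and `--out-dir <dir>`; `simulate`
#' additionally takes a target (`catalog|timecourse|promoters|qpcr`) and
#' `--seed`. `run` executes the stages listed in the config. Install-time
#' wrapper: `inst/cli/chaperonet.R`.
#'
#' @param args character vector (default `commandArgs(trailingOnly =
#'   TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
chap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: chaperonet <rank|overlap|cluster|scan|qpcr|run> --config FILE",
    "[--out-dir DIR]",
    "       chaperonet simulate <catalog|timecourse|promoters|qpcr>",
    "[--seed N] [--out-dir DIR]", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  out_dir <- opt("--out-dir", tempfile("chaperonet_"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (cmd == "simulate") {
    target <- args[2]
    cfg <- sim_config(seed = as.integer(opt("--seed", "1")))
    res <- switch(target,
      catalog = {
        sim <- simulate_catalog(cfg)
        write_ranktable(rank_evidence(sim$catalog, sim$evidence_sets),
                        file.path(out_dir, "rank_table.tsv"))
        sim$truth
      },
      timecourse = {
        sim <- simulate_timecourse(cfg)
        df <- data.frame(gene_id = sim$expression$gene_ids,
                         sim$expression$values, check.names = FALSE)
        names(df)[-1] <- paste0(sim$expression$stage_labels, ":",
                                sim$expression$stage_minutes)
        utils::write.table(df, file.path(out_dir, "timecourse.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        sim$truth
      },
      promoters = {
        sim <- simulate_promoters(cfg)
        write_fasta(sim$sequences, file.path(out_dir, "promoters.fa"))
        list(planted = sim$truth$planted)
      },
      qpcr = {
        sim <- simulate_qpcr(cfg)
        utils::write.csv(sim$ct, file.path(out_dir, "ct_table.csv"),
                         row.names = FALSE)
        sim$truth
      },
      stop("unknown simulate target: ", target))
    write_report(res, file.path(out_dir, "truth.json"))
    message("wrote ", out_dir)
    return(invisible(0L))
  }
  if (!cmd %in% c("rank", "overlap", "cluster", "scan", "qpcr", "run")) {
    message(usage); return(invisible(1L))
  }
  cfg_path <- opt("--config")
  if (is.null(cfg_path)) { message(usage); return(invisible(1L)) }
  cfg <- read_config(cfg_path)
  if (cmd != "run") {
    cfg$stages <- switch(cmd, overlap = c("rank", "overlap"), cmd)
  }
  run_pipeline(cfg, out_dir)
  message("wrote ", file.path(out_dir, "report.json"))
  invisible(0L)
}
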