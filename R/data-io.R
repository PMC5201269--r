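#' Normalize a gene identifier
#'
#' Strips italic markers (`*daf-21*`), surrounding whitespace and a trailing
#' parenthesized family tag (`daf-21(Hsp90)` -> `daf-21`). Matching elsewhere
#' in the package is case-insensitive; the stripped family tag, if any, is
#' returned as an attribute by [split_gene_id()].
#'
#' @param x character vector of raw gene identifiers.
#' @return character vector of cleaned identifiers.
#' @export
normalize_gene_id <- function(x) {
  x <- gsub("\\*", "", trimws(x))
  sub("\\s*\\([^)]*\\)\\s*$", "", x)
}

#' Split gene identifiers into id and family tag
#'
#' @param x character vector like `"daf-21(Hsp90)"`.
#' @return data.frame with columns `gene_id` and `tag` (NA when absent).
#' @export
split_gene_id <- function(x) {
  x <- gsub("\\*", "", trimws(x))
  tag <- ifelse(grepl("\\(([^)]*)\\)\\s*$", x),
                sub(".*\\(([^)]*)\\)\\s*$", "\\1", x), NA_character_)
  data.frame(gene_id = normalize_gene_id(x), tag = tag,
             stringsAsFactors = FALSE)
}

gene_key <- function(x) tolower(normalize_gene_id(x))

#' Chaperone catalog constructor
#'
#' The catalog anchors every set operation: it is the universe (size `N`)
#' for all overlap statistics. The packaged catalog has N = 97 genes across
#' the major chaperone families.
#'
#' @param gene_id character vector of unique, non-empty gene ids.
#' @param family character vector of family labels.
#' @return `chap_catalog` data.frame with attribute `N`.
#' @export
chap_catalog <- function(gene_id, family = rep("other", length(gene_id))) {
  gene_id <- normalize_gene_id(gene_id)
  if (any(!nzchar(gene_id))) stop("empty gene_id in catalog")
  if (anyDuplicated(gene_key(gene_id)))
    stop("duplicate gene_id in catalog: ",
         gene_id[duplicated(gene_key(gene_id))][1])
  stopifnot(length(family) == length(gene_id))
  out <- data.frame(gene_id = gene_id, family = family,
                    stringsAsFactors = FALSE)
  attr(out, "N") <- nrow(out)
  class(out) <- c("chap_catalog", "data.frame")
  out
}

#' Read a chaperone catalog from a delimited file
#'
#' Expects a header with columns `gene_id` and optionally `family`.
#'
#' @param path file path (TSV or CSV, sniffed from the header line).
#' @return `chap_catalog`.
#' @export
read_catalog <- function(path) {
  df <- read_delim_sniff(path)
  if (!"gene_id" %in% names(df)) stop("catalog needs a gene_id column")
  chap_catalog(df$gene_id,
               if ("family" %in% names(df)) df$family
               else rep("other", nrow(df)))
}

#' Evidence set constructor
#'
#' @param name experiment/list name.
#' @param category one of `"occupancy"`, `"enrichment"`, `"required"`.
#' @param genes character vector of member gene ids (deduplicated).
#' @param source_note free-text provenance note.
#' @return `chap_evidence` object.
#' @export
chap_evidence <- function(name, category, genes, source_note = "") {
  category <- match.arg(category, c("occupancy", "enrichment", "required"))
  genes <- unique(normalize_gene_id(genes))
  genes <- genes[nzchar(genes)]
  structure(list(name = name, category = category, genes = genes,
                 source_note = source_note), class = "chap_evidence")
}

#' @export
print.chap_evidence <- function(x, ...) {
  cat(sprintf("<evidence %s [%s]: %d genes>\n", x$name, x$category,
              length(x$genes)))
  invisible(x)
}

read_delim_sniff <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    return(data.frame())
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#", blank.lines.skip = TRUE)
}

#' Read evidence sets from a delimited table
#'
#' Two layouts are auto-detected by header sniffing (the curated sources the
#' analysis mirrors come in both shapes):
#' \describe{
#'   \item{wide-binary}{first column `gene_id`, one 0/1 column per
#'     experiment; any non-binary cell is a validation error.}
#'   \item{long gene-list}{two columns `set` and `gene_id`, one gene per
#'     row per named set.}
#' }
#' Duplicate genes within one set are collapsed to a single membership.
#'
#' @param path delimited text file (TSV or CSV).
#' @param category evidence category for all sets in the file.
#' @return list of `chap_evidence`, one per experiment.
#' @export
read_evidence_table <- function(path, category) {
  df <- read_delim_sniff(path)
  if (nrow(df) == 0L) {
    warning("empty evidence table: ", path)
    nm <- setdiff(names(df), c("gene_id", "set"))
    if (!length(nm)) nm <- "empty"
    return(lapply(nm, function(n) chap_evidence(n, category, character())))
  }
  if (ncol(df) < 2) stop("malformed evidence header in ", path,
                         ": need gene_id plus at least one set column")
  long <- identical(sort(names(df)), sort(c("set", "gene_id")))
  if (long) {
    sets <- split(df$gene_id, df$set)
    return(unname(lapply(names(sets), function(n)
      chap_evidence(n, category, sets[[n]], source_note = path))))
  }
  if (!"gene_id" %in% names(df))
    stop("malformed evidence header in ", path, " at line 1: no gene_id")
  expcols <- setdiff(names(df), "gene_id")
  for (cc in expcols) {
    v <- df[[cc]]
    if (!all(v %in% c(0, 1)))
      stop("non-binary cell in column '", cc, "' of ", path,
           " (row ", which(!v %in% c(0, 1))[1], ")")
  }
  unname(lapply(expcols, function(cc)
    chap_evidence(cc, category, df$gene_id[df[[cc]] == 1],
                  source_note = path)))
}

#' Expression matrix constructor
#'
#' @param values numeric matrix, genes x stages.
#' @param gene_ids row identifiers (unique).
#' @param stage_labels column labels.
#' @param stage_minutes numeric vector of stage times, strictly increasing.
#' @return `chap_expression` object.
#' @export
chap_expression <- function(values, gene_ids, stage_labels, stage_minutes) {
  values <- as.matrix(values)
  if (nrow(values) != length(gene_ids)) stop("row count != number of genes")
  if (ncol(values) != length(stage_labels) ||
      ncol(values) != length(stage_minutes))
    stop("column count must equal stage labels and stage minutes")
  if (ncol(values) < 2) stop("need at least 2 stages")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_id in expression matrix")
  if (any(diff(stage_minutes) <= 0))
    stop("stage_minutes must be strictly increasing")
  dimnames(values) <- list(gene_ids, stage_labels)
  structure(list(values = values, gene_ids = gene_ids,
                 stage_labels = stage_labels, stage_minutes = stage_minutes),
            class = "chap_expression")
}

#' @export
print.chap_expression <- function(x, ...) {
  cat(sprintf("<expression matrix: %d genes x %d stages (%g-%g min)>\n",
              nrow(x$values), ncol(x$values), min(x$stage_minutes),
              max(x$stage_minutes)))
  invisible(x)
}

#' Read a genes-by-stages expression matrix
#'
#' First column is `gene_id`; remaining header cells carry the stage label
#' and time as `label:minutes` (e.g. `VE:290`), or `stage_minutes` is
#' supplied explicitly. Rows containing any non-numeric cell are dropped and
#' the count is reported via a message.
#'
#' @param path delimited file.
#' @param stage_minutes optional numeric vector overriding header metadata.
#' @return `chap_expression`.
#' @export
read_expression_matrix <- function(path, stage_minutes = NULL) {
  df <- read_delim_sniff(path)
  if (ncol(df) < 3) stop("expression matrix needs gene_id plus >= 2 stages")
  stage_cols <- names(df)[-1]
  if (is.null(stage_minutes)) {
    if (!all(grepl(":[0-9.]+$", stage_cols)))
      stop("stage header must encode minutes as label:minutes, ",
           "or pass stage_minutes=")
    stage_minutes <- as.numeric(sub(".*:", "", stage_cols))
    stage_labels <- sub(":[0-9.]+$", "", stage_cols)
  } else {
    stage_labels <- stage_cols
  }
  vals <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df))
  bad <- apply(vals, 1, function(r) any(!is.finite(r)))
  if (any(bad))
    message(sum(bad), " row(s) with non-numeric cells dropped")
  chap_expression(vals[!bad, , drop = FALSE], df$gene_id[!bad],
                  stage_labels, stage_minutes)
}

#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased; characters outside {A,C,G,T,N} are an error
#' naming the offending record.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-DNA characters in record(s): ",
         paste(utils::head(names(seqs)[bad], 5), collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Retains `gene` features (or all features when none are typed `gene`).
#' Coordinates stay 1-based inclusive as in the file; downstream promoter
#' extraction converts to 0-based half-open internally.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene_id`, `seqid`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gff3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- if ("type" %in% names(S4Vectors::mcols(gr)) &&
              any(gr$type == "gene")) gr[gr$type == "gene"] else gr
  id <- if ("Name" %in% names(S4Vectors::mcols(keep)) &&
            !all(is.na(keep$Name))) keep$Name else keep$ID
  data.frame(gene_id = sub("^gene:", "", as.character(id)),
             seqid = as.character(GenomicRanges::seqnames(keep)),
             start = GenomicRanges::start(keep),
             end = GenomicRanges::end(keep),
             strand = as.character(GenomicRanges::strand(keep)),
             stringsAsFactors = FALSE)
}

#' Read a qPCR Ct table from CSV
#'
#' Columns: `gene_id`, `condition`, `replicate`, `ct`. Enforces uniqueness of
#' (gene_id, condition, replicate) and finite Ct in [0, 45].
#'
#' @param path CSV/TSV file.
#' @return `chap_ct` data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read_delim_sniff(path)
  chap_ct(df)
}

#' Ct table constructor/validator
#'
#' @param df data.frame with columns gene_id, condition, replicate, ct.
#' @return validated `chap_ct`.
#' @export
chap_ct <- function(df) {
  need <- c("gene_id", "condition", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  df$gene_id <- normalize_gene_id(df$gene_id)
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct)) || any(df$ct < 0 | df$ct > 45))
    stop("Ct values must be finite and in [0, 45]")
  key <- paste(gene_key(df$gene_id), df$condition, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (gene_id, condition, replicate) in Ct table")
  class(df) <- c("chap_ct", "data.frame")
  df
}

#' Write / read a pipeline report as JSON
#'
#' Reports are plain nested lists of scalars and vectors; writing then
#' reading returns identical content. The report carries the package
#' version and a config hash so any run is traceable.
#'
#' @param report named list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

#' Read a structured pipeline configuration (JSON)
#'
#' @param path JSON file of nested key/value settings.
#' @return named list with attribute `config_hash` (md5 of the file).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  cfg
}
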