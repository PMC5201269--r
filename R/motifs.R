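IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param x character scalar.
#' @return reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}

iupac_regex <- function(consensus) {
  letters_ok <- names(IUPAC_DNA)
  cs <- strsplit(toupper(consensus), "")[[1]]
  if (any(!cs %in% letters_ok))
    stop("invalid IUPAC letter in consensus: ",
         paste(setdiff(cs, letters_ok), collapse = ""))
  paste(vapply(cs, function(ch) {
    opts <- IUPAC_DNA[[ch]]
    if (length(opts) == 1) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

match_starts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m) - 1L   # 0-based
}

#' Scan a promoter for a degenerate consensus motif
#'
#' Finds every occurrence of an IUPAC consensus (default the E-box CANNTG
#' bound by bHLH factors such as HLH-1/MyoD) on both strands, reporting
#' overlapping matches. When the consensus is its own reverse complement as
#' a pattern class — CANNTG is — plus- and minus-strand hit positions
#' coincide and each is reported once with strand `"±"`.
#'
#' Positions are TSS-relative negative integers: -1 is the base immediately
#' 5' of the TSS (the last base of the promoter) and a hit's position is
#' that of its leftmost base, so a site reported at -432 starts 432 bp
#' upstream.
#'
#' @param seq promoter sequence (character scalar; the 3' end abuts the
#'   TSS).
#' @param consensus IUPAC consensus string.
#' @return data.frame with `position` (0-based leftmost base), `tss_rel`,
#'   `strand`, `match`.
#' @export
scan_consensus <- function(seq, consensus = "CANNTG") {
  seq <- toupper(seq)
  L <- nchar(seq)
  w <- nchar(consensus)
  fwd <- match_starts(seq, iupac_regex(consensus))
  rc <- revcomp(consensus)
  palindromic <- identical(rc, toupper(consensus))
  hit_row <- function(pos, strand) data.frame(
    position = pos, tss_rel = pos - L, strand = strand,
    match = substring(seq, pos + 1, pos + w), stringsAsFactors = FALSE)
  if (palindromic) {
    out <- if (length(fwd)) hit_row(fwd, "±") else NULL
  } else {
    rev_hits <- match_starts(seq, iupac_regex(rc))
    out <- rbind(if (length(fwd)) hit_row(fwd, "+"),
                 if (length(rev_hits)) hit_row(rev_hits, "-"))
  }
  if (is.null(out))
    out <- data.frame(position = integer(), tss_rel = integer(),
                      strand = character(), match = character(),
                      stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Build a position weight matrix from an IUPAC consensus
#'
#' Each column distributes probability uniformly over the letters the IUPAC
#' code allows, with pseudocount `alpha` on the disallowed letters; scores
#' are log2 odds against the background. With a uniform background an `N`
#' column scores 0 for every base.
#'
#' @param consensus IUPAC string.
#' @param alpha pseudocount probability per disallowed letter (default
#'   0.01).
#' @param background named numeric over A,C,G,T summing to 1 (default
#'   uniform).
#' @return `chap_motif`: list with `width`, `prob` (4 x w), `logodds`
#'   (4 x w, log2), `background`, `alpha`, `consensus`.
#' @export
consensus_to_pwm <- function(consensus, alpha = 0.01,
                             background = c(A = .25, C = .25,
                                            G = .25, T = .25)) {
  stopifnot(alpha > 0, abs(sum(background) - 1) < 1e-9,
            all(background > 0))
  background <- background[c("A", "C", "G", "T")]
  cs <- strsplit(toupper(consensus), "")[[1]]
  prob <- vapply(cs, function(ch) {
    opts <- IUPAC_DNA[[ch]]
    if (is.null(opts)) stop("invalid IUPAC letter: ", ch)
    n_dis <- 4 - length(opts)
    p <- stats::setNames(rep(alpha, 4), c("A", "C", "G", "T"))
    p[opts] <- (1 - alpha * n_dis) / length(opts)
    p
  }, numeric(4))
  prob <- matrix(prob, nrow = 4,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  structure(list(width = length(cs), prob = prob,
                 logodds = log2(prob / background),
                 background = background, alpha = alpha,
                 consensus = toupper(consensus)),
            class = "chap_motif")
}

#' Exact PWM score null distribution by dynamic programming
#'
#' Discretizes column scores to a fixed grid and convolves columns over the
#' i.i.d. background, yielding the exact distribution of the score of a
#' random background word and hence exact match p-values
#' p(s) = P(score >= s). Equivalent to enumerating all 4^w words but linear
#' in width.
#'
#' @param model `chap_motif`.
#' @param bin discretization bin width in score units (default 1e-3).
#' @return `chap_motif_null`: list with `bin`, `support` (integer bins),
#'   `pmf`, `sf` (upper-tail probability aligned with `support`).
#' @export
pwm_null_distribution <- function(model, bin = 1e-3) {
  stopifnot(inherits(model, "chap_motif"), all(is.finite(model$logodds)))
  col_bins <- round(model$logodds / bin)
  bg <- model$background
  # dist: named-by-offset numeric vector over [lo, hi] integer bins
  lo <- 0L; hi <- 0L
  pmf <- 1
  for (j in seq_len(model$width)) {
    cb <- col_bins[, j]
    new_lo <- lo + min(cb); new_hi <- hi + max(cb)
    acc <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      idx <- (lo + cb[b] - new_lo + 1):(hi + cb[b] - new_lo + 1)
      acc[idx] <- acc[idx] + pmf * bg[b]
    }
    pmf <- acc; lo <- new_lo; hi <- new_hi
  }
  stopifnot(abs(sum(pmf) - 1) < 1e-9)
  structure(list(bin = bin, support = lo:hi, pmf = pmf,
                 sf = rev(cumsum(rev(pmf)))),
            class = "chap_motif_null")
}

#' Exact p-value of a PWM score under the background null
#'
#' @param null `chap_motif_null`.
#' @param score numeric score(s) on the PWM's log-odds scale.
#' @return P(score of a random background word >= score), within one
#'   discretization bin.
#' @export
pwm_pvalue <- function(null, score) {
  b <- round(score / null$bin)
  vapply(b, function(bb) {
    if (bb <= null$support[1]) 1
    else if (bb > null$support[length(null$support)]) 0
    else null$sf[bb - null$support[1] + 1]
  }, numeric(1))
}

score_windows <- function(seq, model) {
  L <- nchar(seq)
  w <- model$width
  if (L < w) return(numeric(0))
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))   # N -> NA
  n_win <- L - w + 1
  sc <- numeric(n_win)
  for (j in seq_len(w)) {
    v <- model$logodds[cbind(idx[j:(j + n_win - 1)], j)]
    sc <- sc + v
  }
  sc  # NA where a window contains a non-ACGT base
}

#' Scan a promoter with a PWM at an exact p-value threshold
#'
#' FIMO-style scan: every window on both strands whose exact score p-value
#' is at or below `p_threshold` is a hit. Windows containing N are skipped.
#' Hits at the same start position with equal score on both strands (the
#' palindromic case) are merged to strand `"±"`.
#'
#' @param seq promoter sequence.
#' @param model `chap_motif`.
#' @param p_threshold maximum p-value (default 0.001, the conventional
#'   FIMO cut).
#' @param null precomputed `chap_motif_null` (recomputed if missing).
#' @return data.frame with `position`, `tss_rel`, `strand`, `score`,
#'   `p_value`; attribute `has_motif`.
#' @export
scan_pwm <- function(seq, model, p_threshold = 0.001, null = NULL) {
  seq <- toupper(seq)
  L <- nchar(seq)
  empty <- data.frame(position = integer(), tss_rel = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (L < model$width) {
    warning("sequence shorter than motif width")
    attr(empty, "has_motif") <- FALSE
    return(empty)
  }
  if (is.null(null)) null <- pwm_null_distribution(model)
  fwd <- score_windows(seq, model)
  # minus-strand score at + position i = score of revcomp(window); obtained
  # by scanning the revcomp sequence and mirroring positions
  rcs <- score_windows(revcomp(seq), model)
  rev_scores <- rev(rcs)
  rows <- list()
  add <- function(pos, strand, score) {
    p <- pwm_pvalue(null, score)
    keep <- !is.na(score) & p <= p_threshold
    if (!any(keep)) return(NULL)
    data.frame(position = pos[keep], tss_rel = pos[keep] - L,
               strand = strand, score = score[keep], p_value = p[keep],
               stringsAsFactors = FALSE)
  }
  pos <- seq_len(L - model$width + 1) - 1L
  both <- !is.na(fwd) & !is.na(rev_scores) &
    abs(fwd - rev_scores) < null$bin / 2
  out <- rbind(add(pos[both], "±", fwd[both]),
               add(pos[!both], "+", fwd[!both]),
               add(pos[!both], "-", rev_scores[!both]))
  if (is.null(out)) out <- empty
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "has_motif") <- nrow(out) > 0
  out
}

#' Extract a promoter upstream of a gene's TSS
#'
#' For a plus-strand gene the promoter is the `length` bases ending
#' immediately 5' of the TSS on the plus strand; for a minus-strand gene it
#' is the reverse complement of the bases immediately 3' of the TSS, so the
#' returned sequence always reads 5'->3' toward the TSS. GFF-style 1-based
#' inclusive gene coordinates are accepted; truncation at a contig end is
#' flagged rather than fatal.
#'
#' @param genome named character vector of contig sequences.
#' @param gene_model list or one-row data.frame with `gene_id`, `seqid`,
#'   `start`, `end`, `strand` (1-based inclusive).
#' @param length promoter length (default 1000, the conventional upstream
#'   window).
#' @return `chap_promoter`: list with `gene_id`, `sequence`, `strand`,
#'   `truncated`.
#' @export
extract_promoter <- function(genome, gene_model, length = 1000L) {
  gm <- as.list(gene_model)
  if (!gm$seqid %in% names(genome))
    stop("contig not in genome: ", gm$seqid)
  contig <- toupper(genome[[gm$seqid]])
  clen <- nchar(contig)
  if (identical(gm$strand, "-")) {
    tss <- gm$end
    from <- tss + 1L
    to <- min(clen, tss + length)
    seq <- revcomp(substr(contig, from, to))
    truncated <- (tss + length) > clen
  } else {
    tss <- gm$start
    from <- max(1L, tss - length)
    to <- tss - 1L
    seq <- if (to >= from) substr(contig, from, to) else ""
    truncated <- (tss - length) < 1L
  }
  structure(list(gene_id = gm$gene_id, sequence = seq,
                 strand = if (identical(gm$strand, "-")) "-" else "+",
                 truncated = truncated),
            class = "chap_promoter")
}

#' Effect of a promoter substitution on motif hits
#'
#' Replaces the window starting at a TSS-relative position with
#' `replacement` (same length) and re-scans, mirroring promoter mutagenesis
#' in which E-box sites are overwritten with a neutral word such as ACGCGT.
#' Only windows within motif-width - 1 bases of the edit can change.
#'
#' @param seq promoter sequence.
#' @param tss_rel_position TSS-relative position of the leftmost replaced
#'   base (negative integer, -1 = base just upstream of the TSS).
#' @param replacement replacement string of the same length as the excised
#'   window.
#' @param consensus IUPAC consensus used for scanning (default CANNTG);
#'   ignored when `model` is given.
#' @param model optional `chap_motif` for PWM-mode scanning.
#' @param p_threshold p-value cut for PWM mode.
#' @return list with `sequence_after`, `hits_before`, `hits_after`,
#'   `lost` and `gained` (TSS-relative positions).
#' @export
mutation_effect <- function(seq, tss_rel_position, replacement,
                            consensus = "CANNTG", model = NULL,
                            p_threshold = 0.001) {
  seq <- toupper(seq)
  L <- nchar(seq)
  pos0 <- L + tss_rel_position             # 0-based leftmost base
  wlen <- nchar(replacement)
  if (pos0 < 0 || pos0 + wlen > L)
    stop("replacement window out of sequence bounds")
  after <- paste0(substr(seq, 1, pos0),
                  toupper(replacement),
                  substr(seq, pos0 + wlen + 1, L))
  scan1 <- function(s) {
    if (is.null(model)) scan_consensus(s, consensus)
    else scan_pwm(s, model, p_threshold)
  }
  hb <- scan1(seq)
  ha <- scan1(after)
  key <- function(h) paste(h$tss_rel, h$strand)
  list(sequence_after = after, hits_before = hb, hits_after = ha,
       lost = hb$tss_rel[!key(hb) %in% key(ha)],
       gained = ha$tss_rel[!key(ha) %in% key(hb)])
}
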