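# Exact-locus validation of contigs: local alignment of each contig against
# the genome window where its seed says it must occur, classification of
# trusted/untrusted x aligned/unaligned into a confusion table, and the
# genome-coverage profile of the aligned trusted contigs.

#' Smith-Waterman local alignment score
#'
#' Best local alignment score under linear gap costs: +1 per match, -1 per
#' mismatch, -2 per inserted/deleted base. The recurrence is evaluated
#' row-wise; within a row the chain of left-gap moves is closed in one
#' cumulative-maximum pass, which is exact for linear gap penalties.
#'
#' @param a,b DNA strings or integer code vectors.
#' @param match,mismatch,indel Scoring (defaults +1/-1/-2).
#' @return The best local score (0 if no positive-scoring alignment exists).
#' @export
#' @examples
#' smith_waterman("ACGT", "ACGT")  # 4
#' smith_waterman("ACGT", "TTTT")  # 1
smith_waterman <- function(a, b, match = 1, mismatch = -1, indel = -2) {
  if (is.character(a)) a <- dna_codes(a)
  if (is.character(b)) b <- dna_codes(b)
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("smith_waterman requires nonempty sequences")
  gap <- abs(indel)
  jj <- gap * seq_len(m)
  prev <- numeric(m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    sub <- prev[seq_len(m)] + ifelse(b == a[i], match, mismatch)
    up <- prev[2L:(m + 1L)] - gap
    base <- pmax(sub, up, 0)
    cur <- pmax(base, cummax(base + jj) - jj)
    bi <- max(cur)
    if (bi > best) best <- bi
    prev <- c(0, cur)
  }
  best
}

#' Indel budget of the validation window
#'
#' Number of indels `g` the validation alignment tolerates for a contig of
#' length `|S|`: `g = ceiling(3 |S| / 200)`, i.e. 3 indels every 200 bp on
#' average under the +1/-1/-2 scoring and the 0.95 score-ratio threshold.
#'
#' @param contig_len Contig length (positive).
#' @return Integer indel budget.
#' @export
#' @examples
#' indel_budget(200)  # 3
indel_budget <- function(contig_len) {
  stopifnot(contig_len > 0)
  as.integer(ceiling(3 * contig_len / 200))
}

#' Validate one contig at its seed's exact locus
#'
#' Aligns the contig against the genome window of length `|S| + g` anchored
#' at the seed's true position (Smith-Waterman, +1/-1/-2) and declares it
#' aligned when `score / |S| >= min_ratio`. Reverse-strand seeds have their
#' contig reverse-complemented first; their window ends at the insert's 3'
#' end. Windows are clamped at the genome boundaries (or wrapped when
#' `circular = TRUE`); a locus outside the genome counts as unaligned.
#'
#' @param contig Contig DNA string.
#' @param genome Genome (string or `mf_genome`).
#' @param insert_start 0-based insert start of the seed's pair.
#' @param insert_len Insert length of the pair.
#' @param strand Strand of the seed read (`"+"` or `"-"`).
#' @param min_ratio Acceptance threshold on score/|S| (default 0.95).
#' @param circular Wrap windows around the origin.
#' @return List with `aligned`, `score`, `ratio`, `g`.
#' @export
validate_contig <- function(contig, genome, insert_start, insert_len = NULL,
                            strand = "+", min_ratio = 0.95, circular = FALSE) {
  g <- genome_seq(genome)
  G <- nchar(g)
  S <- contig
  nS <- nchar(S)
  stopifnot(nS > 0)
  gg <- indel_budget(nS)
  w <- nS + gg

  if (strand == "-") {
    if (is.null(insert_len)) stop("insert_len required for reverse-strand seeds")
    S <- revcomp(S)
    win_end <- insert_start + insert_len - 1          # window ends at insert 3' end
    win_start <- win_end - w + 1
  } else {
    win_start <- insert_start
    win_end <- win_start + w - 1
  }

  if (circular) {
    win_start <- ((win_start %% G) + G) %% G
    win <- substring(paste0(g, g), win_start + 1, win_start + w)
  } else {
    lo <- max(win_start, 0); hi <- min(win_end, G - 1)
    if (lo > hi || win_start >= G || win_end < 0)
      return(list(aligned = FALSE, score = 0, ratio = 0, g = gg))
    win <- substring(g, lo + 1, hi + 1)
  }

  score <- smith_waterman(S, win)
  ratio <- score / nS
  list(aligned = ratio >= min_ratio, score = score, ratio = ratio, g = gg)
}

#' Confusion counts and genome coverage of a validated run
#'
#' Crosses the trust label (trusted = MATE_FOUND) with the alignment
#' outcome: TP = trusted & aligned, FP = trusted & unaligned, FN =
#' untrusted & aligned, TN = untrusted & unaligned. Coverage is the
#' fraction of genome bases covered by the union of aligned trusted contig
#' loci.
#'
#' @param verdicts Data frame with columns `label`, `aligned`, and the
#'   forward-strand locus of each contig: `locus_start` (0-based) and
#'   `locus_len`.
#' @param genome_len Genome length.
#' @param circular Treat loci as circular intervals.
#' @return List with `counts` (named TP/FP/FN/TN), `rates` (same, as
#'   fractions of all contigs), `covered_fraction`, `uncovered_fraction`.
#' @export
confusion_and_coverage <- function(verdicts, genome_len, circular = FALSE) {
  trusted <- verdicts$label == "MATE_FOUND"
  aligned <- verdicts$aligned
  counts <- c(TP = sum(trusted & aligned), FP = sum(trusted & !aligned),
              FN = sum(!trusted & aligned), TN = sum(!trusted & !aligned))
  n <- nrow(verdicts)
  rates <- if (n > 0) counts / n else counts * NA_real_
  keep <- which(trusted & aligned)
  covered <- genome_coverage(verdicts$locus_start[keep], verdicts$locus_len[keep],
                             genome_len, circular)
  list(counts = counts, rates = rates,
       covered_fraction = covered, uncovered_fraction = 1 - covered)
}

#' Fraction of a genome covered by a set of intervals
#'
#' @param starts 0-based interval starts.
#' @param lens Interval lengths.
#' @param genome_len Genome length.
#' @param circular Wrap intervals around the origin.
#' @return Covered fraction in `[0, 1]`.
#' @export
genome_coverage <- function(starts, lens, genome_len, circular = FALSE) {
  if (length(starts) == 0L) return(0)
  stopifnot(length(starts) == length(lens))
  s <- starts; e <- starts + lens - 1
  if (circular) {
    s <- ((s %% genome_len) + genome_len) %% genome_len
    e <- s + lens - 1
    wrap <- e >= genome_len
    s2 <- c(s[!wrap], s[wrap], rep(0, sum(wrap)))
    e2 <- c(e[!wrap], rep(genome_len - 1, sum(wrap)), e[wrap] - genome_len)
    s <- s2; e <- pmin(e2, genome_len - 1)
  } else {
    s <- pmax(s, 0); e <- pmin(e, genome_len - 1)
    keep <- s <= e
    s <- s[keep]; e <- e[keep]
    if (length(s) == 0L) return(0)
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = s + 1, end = e + 1))
  sum(IRanges::width(ir)) / genome_len
}

#' Validate every contig of a run against the simulation truth
#'
#' Joins a [mate_fill()] run with the simulator's truth table, validates
#' each contig at its seed's exact locus, and summarizes the confusion
#' table and genome coverage.
#'
#' @param run A `mate_fill_run` object.
#' @param truth The `truth` data.frame of an [make_pairs()] library (row i
#'   corresponds to seed pair i).
#' @param genome The simulated genome.
#' @param min_ratio Alignment acceptance threshold (default 0.95).
#' @param circular Treat the genome as circular.
#' @return List with `verdicts` (per-contig data.frame including TP/FP/FN/TN
#'   class), `counts`, `rates`, `covered_fraction`, `uncovered_fraction`.
#' @export
validate_run <- function(run, truth, genome, min_ratio = 0.95, circular = FALSE) {
  contigs <- run$contigs
  n <- nrow(contigs)
  aligned <- logical(n); score <- numeric(n); ratio <- numeric(n)
  locus_start <- integer(n); locus_len <- integer(n)
  for (i in seq_len(n)) {
    tr <- truth[contigs$pair[i], ]
    v <- validate_contig(contigs$sequence[i], genome, tr$insert_start,
                         tr$insert_len, tr$strand, min_ratio, circular)
    aligned[i] <- v$aligned; score[i] <- v$score; ratio[i] <- v$ratio
    nS <- contigs$length[i]
    locus_start[i] <- if (tr$strand == "+") tr$insert_start
                      else tr$insert_start + tr$insert_len - nS
    locus_len[i] <- nS
  }
  trusted <- contigs$label == "MATE_FOUND"
  klass <- ifelse(trusted, ifelse(aligned, "TP", "FP"),
                  ifelse(aligned, "FN", "TN"))
  verdicts <- data.frame(
    contig_id = contigs$seed_id, pair = contigs$pair, label = contigs$label,
    aligned = aligned, score = score, ratio = ratio, klass = klass,
    locus_start = locus_start, locus_len = locus_len,
    stringsAsFactors = FALSE)
  cc <- confusion_and_coverage(verdicts, nchar(genome_seq(genome)), circular)
  c(list(verdicts = verdicts), cc)
}
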