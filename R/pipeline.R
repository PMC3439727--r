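# End-to-end driver: load paired libraries, build the fingerprint index,
# iterate seed pairs through the extension loop, and collect labelled
# contigs plus run statistics.

# read a library from a character vector or a FASTA/FASTQ file path
read_reads <- function(x, what = "reads") {
  if (is.character(x) && length(x) == 1L && !grepl("^[ACGTNacgtn]+$", x) && file.exists(x)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x, ignore.case = TRUE)) "fastq" else "fasta"
    set <- Biostrings::readDNAStringSet(x, format = fmt)
    stats::setNames(as.character(set), names(set))
  } else {
    stopifnot(is.character(x))
    x
  }
}

#' Fill the gap between paired reads by seed-and-extend local assembly
#'
#' For each seed pair, read 1 is used as the seed and extended through
#' fingerprint-indexed suffix-prefix overlaps and representation-rate
#' policed consensus until read 2 (the mate) is found in the contig, or one
#' of the negative stop criteria fires. The fingerprint index is built over
#' the extension library; when a separate seed library is supplied (e.g.
#' long-insert pairs seeded over a short-insert extension library), the
#' index covers the union of both libraries and seeds iterate over the seed
#' library only.
#'
#' @param reads1,reads2 Extension library: character vectors of sequences or
#'   FASTA/FASTQ file paths; record i of `reads1` is paired with record i of
#'   `reads2`.
#' @param seeds1,seeds2 Optional separate seed library (defaults to the
#'   extension library).
#' @param orientation Pair geometry: `"fr"` (forward-reverse, default),
#'   `"rf"`, or `"ff"`; decides how the seed and its mate are oriented on
#'   the contig strand.
#' @param insert_mean,insert_sd Seed library insert size; used for the
#'   default `Lmax = insert_mean + 3 * insert_sd`.
#' @param L,Delta,m,T1,T2,M,delta Extension parameters, see
#'   [extension_params()]. Defaults L=50, Delta=40, m=2, T1=0.6, T2=0.9,
#'   M=10.
#' @param b,w Fingerprint parameters, see [fingerprint_params()]. Defaults
#'   b=20, q=2^30-1.
#' @param read_len Average read length for the delta rule; inferred from the
#'   extension library when `NULL`.
#' @param Lmax Maximum contig length (overrides the insert-based default).
#' @param seed_limit Process only the first `seed_limit` seed pairs.
#' @param seeds_use_both_mates Also try read 2 of every seed pair as a seed
#'   (doubles the seed count).
#' @return An object of class `mate_fill_run`: list with `contigs` (one row
#'   per processed seed: `pair`, `seed_id`, `label`, `length`, `steps`,
#'   `mate_pos`, `sequence`), `stats`, `params`.
#' @export
mate_fill <- function(reads1, reads2, seeds1 = NULL, seeds2 = NULL,
                      orientation = c("fr", "rf", "ff"),
                      insert_mean = NULL, insert_sd = NULL,
                      L = 50L, Delta = 40L, b = 20L, w = 30L, m = 2L,
                      T1 = 0.6, T2 = 0.9, M = 10L, delta = NULL,
                      read_len = NULL, Lmax = NULL, seed_limit = NULL,
                      seeds_use_both_mates = FALSE) {
  orientation <- match.arg(orientation)
  r1 <- read_reads(reads1); r2 <- read_reads(reads2)
  if (length(r1) != length(r2))
    stop("paired files must have equal record counts (", length(r1), " vs ", length(r2), ")")
  dual <- !is.null(seeds1)
  if (dual) {
    s1 <- read_reads(seeds1); s2 <- read_reads(seeds2)
    if (length(s1) != length(s2)) stop("seed pair files must have equal record counts")
  } else {
    s1 <- r1; s2 <- r2
  }

  ext_reads <- c(r1, r2)
  if (dual && !(identical(unname(s1), unname(r1)) && identical(unname(s2), unname(r2))))
    ext_reads <- c(ext_reads, s1, s2)   # union of both libraries
  if (is.null(read_len)) read_len <- as.integer(round(mean(nchar(ext_reads))))
  if (is.null(Lmax)) {
    if (is.null(insert_mean))
      stop("supply either Lmax or insert_mean (and insert_sd) to bound contig length")
    Lmax <- insert_mean + 3 * (if (is.null(insert_sd)) 0 else insert_sd)
  }

  fp <- fingerprint_params(b = b, w = w)
  ep <- extension_params(L = L, Delta = Delta, m = m, T1 = T1, T2 = T2, M = M,
                         read_len = read_len, delta = delta, Lmax = Lmax)
  index <- build_read_index(ext_reads, fp, L)

  n_seed_pairs <- length(s1)
  use <- seq_len(if (is.null(seed_limit)) n_seed_pairs else min(seed_limit, n_seed_pairs))
  seed_ids <- names(s1)
  if (is.null(seed_ids)) seed_ids <- sprintf("pair%d", seq_len(n_seed_pairs))

  orient_pair <- function(seed, mate) {
    switch(orientation,
           fr = list(seed = seed, mate = revcomp(mate)),
           ff = list(seed = seed, mate = mate),
           rf = list(seed = revcomp(seed), mate = mate))
  }

  rows <- list()
  skipped <- 0L
  run_one <- function(pair_i, seed_raw, mate_raw, id) {
    op <- tryCatch({
      o <- orient_pair(seed_raw, mate_raw)
      list(seed = dna_codes(o$seed), mate = dna_codes(o$mate))
    }, error = function(e) NULL)
    if (is.null(op)) return(NULL)                 # non-ACGT seed or mate
    ctg <- extend_seed(op$seed, op$mate, index, ep, seed_id = id)
    data.frame(pair = pair_i, seed_id = id, label = ctg$label,
               length = ctg$length, steps = ctg$steps,
               mate_pos = ifelse(is.na(ctg$mate_pos), NA_integer_, ctg$mate_pos),
               sequence = ctg$seq, stringsAsFactors = FALSE)
  }
  for (i in use) {
    row <- run_one(i, s1[[i]], s2[[i]], seed_ids[i])
    if (is.null(row)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- row
    if (seeds_use_both_mates) {
      row2 <- run_one(i, s2[[i]], s1[[i]], paste0(seed_ids[i], "/mate2"))
      if (is.null(row2)) skipped <- skipped + 1L
      else rows[[length(rows) + 1L]] <- row2
    }
  }
  contigs <- if (length(rows) > 0) do.call(rbind, rows)
             else data.frame(pair = integer(0), seed_id = character(0),
                             label = character(0), length = integer(0),
                             steps = integer(0), mate_pos = integer(0),
                             sequence = character(0), stringsAsFactors = FALSE)

  labels <- c("MATE_FOUND", "NO_MORE_EXTENSION", "REPEAT_FOUND", "LENGTH_EXCEED")
  label_counts <- stats::setNames(vapply(labels, function(l) sum(contigs$label == l), 0L), labels)
  stats <- list(
    seeds_processed = nrow(contigs), seeds_skipped = skipped,
    label_counts = label_counts,
    reads_indexed = index$n_indexed,
    reads_filtered_short = index$n_short,
    reads_filtered_nonacgt = index$n_nonacgt,
    trusted_bases = sum(contigs$length[contigs$label == "MATE_FOUND"])
  )
  structure(list(contigs = contigs, stats = stats,
                 params = list(fingerprint = fp, extension = ep,
                               orientation = orientation, dual_library = dual,
                               seed_limit = seed_limit)),
            class = "mate_fill_run")
}

#' @export
print.mate_fill_run <- function(x, ...) {
  s <- x$stats
  cat("mate_fill run:", s$seeds_processed, "seeds processed,",
      s$seeds_skipped, "skipped\n")
  lc <- s$label_counts
  for (l in names(lc))
    cat(sprintf("  %-18s %6d (%.1f%%)\n", l, lc[[l]],
                if (s$seeds_processed > 0) 100 * lc[[l]] / s$seeds_processed else 0))
  cat("  trusted bases:", s$trusted_bases, "\n")
  invisible(x)
}

#' @export
summary.mate_fill_run <- function(object, ...) {
  out <- list(
    label_counts = object$stats$label_counts,
    label_rates = object$stats$label_counts / max(object$stats$seeds_processed, 1L),
    length_summary = lapply(split(object$contigs$length, object$contigs$label), summary),
    stats = object$stats)
  class(out) <- "summary.mate_fill_run"
  out
}

#' @export
print.summary.mate_fill_run <- function(x, ...) {
  print(data.frame(count = x$label_counts, rate = round(x$label_rates, 4)))
  invisible(x)
}

#' Write the contigs of a run as FASTA
#'
#' Headers carry the seed id, stop label, contig length, number of
#' extension steps, and the 0-based mate position when found:
#' `>seed=<id> label=<LABEL> len=<n> steps=<k> mate_pos=<p|NA>`.
#'
#' @param run A `mate_fill_run`.
#' @param file Output FASTA path.
#' @export
write_contigs <- function(run, file) {
  ctg <- run$contigs
  x <- Biostrings::DNAStringSet(ctg$sequence)
  names(x) <- sprintf("seed=%s label=%s len=%d steps=%d mate_pos=%s",
                      ctg$seed_id, ctg$label, ctg$length, ctg$steps,
                      ifelse(is.na(ctg$mate_pos), "NA", as.character(ctg$mate_pos)))
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Write run statistics as TSV
#'
#' One key-value row per statistic, plus per-label contig counts.
#'
#' @param run A `mate_fill_run`.
#' @param file Output TSV path.
#' @export
write_stats <- function(run, file) {
  s <- run$stats
  kv <- data.frame(
    key = c("seeds_processed", "seeds_skipped", "reads_indexed",
            "reads_filtered_short", "reads_filtered_nonacgt", "trusted_bases",
            paste0("n_", names(s$label_counts))),
    value = c(s$seeds_processed, s$seeds_skipped, s$reads_indexed,
              s$reads_filtered_short, s$reads_filtered_nonacgt, s$trusted_bases,
              unname(s$label_counts)))
  utils::write.table(kv, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
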