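# Synthetic genomes and paired-read libraries with truth coordinates. The
# generator stands in for an external read simulator: uniform insert
# placement, Gaussian insert length, forward-reverse read orientation,
# i.i.d. per-base substitution errors, and a truth table that records where
# every pair came from so contigs can be validated at their exact locus.

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_rng_seed <- function(rng_seed, expr) {
  if (is.null(rng_seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(rng_seed)
  expr
}

#' Simulate a random genome, optionally with planted repeats
#'
#' Draws an i.i.d. genome with the requested GC content. `repeat_spec`
#' plants exact repeat families: each element is a list with `len` (unit
#' length), `copies`, and optionally `starts` (0-based); when `starts` is
#' omitted the copies are spaced evenly. Copy 1's sequence is the genome's
#' own window at the first start; the remaining copies overwrite their
#' windows with that unit, so all copies are character-identical.
#'
#' @param length Genome length in bases.
#' @param gc GC fraction (default 0.5).
#' @param rng_seed Optional seed; the caller's RNG state is restored.
#' @param repeat_spec Optional list of repeat families (see above).
#' @return An object of class `mf_genome`: list with `seq` (character) and
#'   `repeats` (data.frame with `family`, `copy`, `start`, `end`, 0-based
#'   inclusive).
#' @export
make_genome <- function(length, gc = 0.5, rng_seed = NULL, repeat_spec = NULL) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  with_rng_seed(rng_seed, {
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    codes <- sample.int(4L, length, replace = TRUE, prob = probs) - 1L
    reps <- data.frame(family = integer(0), copy = integer(0),
                       start = integer(0), end = integer(0))
    if (!is.null(repeat_spec)) {
      for (fi in seq_along(repeat_spec)) {
        spec <- repeat_spec[[fi]]
        len <- spec$len
        copies <- spec$copies
        stopifnot(len >= 1, copies >= 1, copies * len <= length)
        starts <- spec$starts
        if (is.null(starts)) {
          gap <- (length - copies * len) %/% (copies + 1L)
          starts <- cumsum(c(gap, rep(len + gap, copies - 1L)))
        }
        stopifnot(length(starts) == copies, all(starts >= 0),
                  all(starts + len <= length))
        if (copies > 1L && any(diff(sort(starts)) < len))
          stop("repeat copies overlap")
        unit <- codes[(starts[1L] + 1L):(starts[1L] + len)]
        for (ci in seq_along(starts)) {
          codes[(starts[ci] + 1L):(starts[ci] + len)] <- unit
          reps <- rbind(reps, data.frame(family = fi, copy = ci,
                                         start = starts[ci],
                                         end = starts[ci] + len - 1L))
        }
      }
    }
    structure(list(seq = dna_string(codes), repeats = reps), class = "mf_genome")
  })
}

#' @export
print.mf_genome <- function(x, ...) {
  cat("mf_genome:", nchar(x$seq), "bp,", nrow(x$repeats), "planted repeat copies\n")
  invisible(x)
}

genome_seq <- function(genome) {
  if (inherits(genome, "mf_genome")) genome$seq else as.character(genome)
}

# substitute errors at rate `rate` into equal-length reads; returns the
# mutated reads and per-read 0-based error positions
mutate_reads <- function(reads, rate) {
  n <- length(reads)
  if (rate <= 0 || n == 0L) return(list(reads = reads, pos = rep(list(integer(0)), n)))
  rl <- nchar(reads[1L])
  m <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  hit <- matrix(stats::runif(n * rl) < rate, nrow = n)
  idx <- which(hit)
  if (length(idx) > 0L) {
    # replace by one of the three other bases, uniformly
    shift <- sample.int(3L, length(idx), replace = TRUE)
    cur <- match(m[idx], .BASES) - 1L
    m[idx] <- .BASES[((cur + shift) %% 4L) + 1L]
  }
  pos <- lapply(seq_len(n), function(i) which(hit[i, ]) - 1L)
  list(reads = apply(m, 1L, paste, collapse = ""), pos = pos)
}

#' Simulate a paired-end read library with truth coordinates
#'
#' Inserts are placed uniformly on the genome with Gaussian length
#' (truncated to `[2 * read_len, genome length]`); read 1 is the insert's
#' 5' end on the sampled strand and read 2 the reverse complement of its 3'
#' end (forward-reverse orientation). Substitution errors are i.i.d. per
#' base. The pair count defaults to
#' `ceiling(coverage * genome_len / (2 * read_len))`. With
#' `circular = TRUE` the chromosome is treated as circular: inserts may
#' wrap the origin, removing the coverage dip a linear simulation shows at
#' the sequence ends.
#'
#' @param genome An `mf_genome` or DNA string.
#' @param coverage Target nucleotide coverage (ignored when `n_pairs` given).
#' @param read_len Read length (default 100).
#' @param insert_mean,insert_sd Insert size distribution (default 600, 200).
#' @param err_rate Per-base substitution probability in `[0, 1)`.
#' @param rng_seed Optional seed; caller RNG state restored.
#' @param circular Treat the genome as circular (default FALSE).
#' @param n_pairs Explicit pair count overriding `coverage`.
#' @return An object of class `mf_pairs`: `reads1`, `reads2` (character
#'   vectors), `truth` (data.frame: `pair_id`, `insert_start` 0-based,
#'   `insert_len`, `strand` of read 1, `err_pos1`, `err_pos2` comma-joined
#'   0-based read positions), plus the library metadata.
#' @export
make_pairs <- function(genome, coverage = 50, read_len = 100L,
                       insert_mean = 600, insert_sd = 200, err_rate = 0,
                       rng_seed = NULL, circular = FALSE, n_pairs = NULL) {
  g <- genome_seq(genome)
  G <- nchar(g)
  stopifnot(insert_mean >= read_len, err_rate >= 0, err_rate < 1)
  if (2L * read_len > G) stop("genome shorter than one insert")
  if (is.null(n_pairs)) n_pairs <- ceiling(coverage * G / (2 * read_len))
  n_pairs <- as.integer(n_pairs)

  with_rng_seed(rng_seed, {
    ins <- round(stats::rnorm(n_pairs, insert_mean, insert_sd))
    ins <- pmin(pmax(ins, 2L * read_len), G)
    strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
    if (circular) {
      start <- sample.int(G, n_pairs, replace = TRUE) - 1L
      g2 <- paste0(g, g)
      win <- substring(g2, start + 1L, start + ins)
    } else {
      start <- floor(stats::runif(n_pairs) * (G - ins + 1))
      win <- substring(g, start + 1L, start + ins)
    }
    five <- substring(win, 1L, read_len)
    three_rc <- vapply(substring(win, ins - read_len + 1L, ins), revcomp, "",
                       USE.NAMES = FALSE)
    r1 <- ifelse(strand == "+", five, three_rc)
    r2 <- ifelse(strand == "+", three_rc, five)
    e1 <- mutate_reads(r1, err_rate)
    e2 <- mutate_reads(r2, err_rate)
    truth <- data.frame(
      pair_id = seq_len(n_pairs),
      insert_start = as.integer(start),
      insert_len = as.integer(ins),
      strand = strand,
      err_pos1 = vapply(e1$pos, paste, "", collapse = ","),
      err_pos2 = vapply(e2$pos, paste, "", collapse = ","),
      stringsAsFactors = FALSE
    )
    nm <- sprintf("pair%d", seq_len(n_pairs))
    structure(
      list(reads1 = stats::setNames(e1$reads, paste0(nm, "/1")),
           reads2 = stats::setNames(e2$reads, paste0(nm, "/2")),
           truth = truth, read_len = as.integer(read_len),
           insert_mean = insert_mean, insert_sd = insert_sd,
           err_rate = err_rate, orientation = "fr",
           genome_len = G, circular = circular),
      class = "mf_pairs")
  })
}

#' @export
print.mf_pairs <- function(x, ...) {
  cat("mf_pairs:", length(x$reads1), "pairs, read_len", x$read_len,
      ", insert", x$insert_mean, "+/-", x$insert_sd,
      ", err_rate", x$err_rate, if (x$circular) "(circular)" else "", "\n")
  invisible(x)
}

#' Write a simulated genome as FASTA
#' @param genome An `mf_genome` or DNA string.
#' @param file Output path.
#' @param name Sequence name.
#' @export
write_genome_fasta <- function(genome, file, name = "genome") {
  x <- Biostrings::DNAStringSet(genome_seq(genome))
  names(x) <- name
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Write a simulated pair library as two FASTQ files plus a truth TSV
#'
#' Reads are written with constant quality "I"; the truth table documents
#' each pair's insert locus, strand, and planted error positions.
#'
#' @param pairs An `mf_pairs` object.
#' @param file1,file2 FASTQ paths for reads 1 and 2.
#' @param truth_file Optional TSV path for the truth table.
#' @export
write_fastq_pairs <- function(pairs, file1, file2, truth_file = NULL) {
  wr <- function(reads, file) {
    x <- Biostrings::DNAStringSet(reads)
    q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(x, file, format = "fastq", qualities = q)
  }
  wr(pairs$reads1, file1)
  wr(pairs$reads2, file2)
  if (!is.null(truth_file))
    utils::write.table(pairs$truth, truth_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(file1, file2))
}
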