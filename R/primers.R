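# IUPAC ambiguity codes -> base sets; no gaps, no U
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(from = "ACGTRYSWKMBDHVN", to = "TGCAYRSWMKVHDBN")

check_iupac <- function(seq, what = "primer") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad))
    stop(sprintf("invalid IUPAC character '%s' at position %d in %s '%s'",
                 chars[bad[1]], bad[1], what, seq), call. = FALSE)
  invisible(TRUE)
}

#' Define a primer pair
#'
#' A named forward/reverse primer pair, both written 5'->3' as on an order
#' sheet, with optional expected-product length bounds. IUPAC ambiguity codes
#' are permitted (degenerate primers). The forward and reverse primers sit on
#' opposite strands with their 3' ends facing each other, as in benchtop PCR.
#'
#' @param name Pair label used in output headers and summaries.
#' @param forward,reverse Primer sequences, 5'->3', IUPAC alphabet.
#' @param min_length Minimum product length (default 0).
#' @param max_length Maximum product length (default 10000, i.e. 10 kbp).
#' @return A `primer_pair` object.
#' @examples
#' primer_pair("dloop", "GGTCAACAAATCATAAAGAT", "TAAACTTCAGGGTGACCAAA")
#' @export
primer_pair <- function(name, forward, reverse, min_length = 0L,
                        max_length = 10000L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  stopifnot(is.character(name), nzchar(name), nzchar(forward), nzchar(reverse))
  check_iupac(forward, "forward primer")
  check_iupac(reverse, "reverse primer")
  min_length <- as.numeric(min_length); max_length <- as.numeric(max_length)
  stopifnot(min_length >= 0, max_length >= 1, min_length <= max_length)
  structure(list(name = name, forward = forward, reverse = reverse,
                 min_length = min_length, max_length = max_length),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("primer_pair '%s': fwd %s, rev %s, product length [%g, %g]\n",
              x$name, x$forward, x$reverse, x$min_length, x$max_length))
  invisible(x)
}

#' Trim a primer to its searched 3' portion
#'
#' Benchtop primers are typically lengthened beyond what is needed for
#' specificity to tune melting temperature; for k-mer seeding a shorter 3'
#' portion retains specificity while offering fewer opportunities for
#' mismatch. Primers longer than `trim_len` keep only their last (3'-most)
#' `trim_len` bases; shorter primers are returned unchanged.
#'
#' @param primer IUPAC primer, 5'->3'.
#' @param trim_len Searched length (default 15).
#' @return Trimmed primer.
#' @examples
#' trim_primer("GGTCAACAAATCATAAAGAT")  # "ACAAATCATAAAGAT"
#' @export
trim_primer <- function(primer, trim_len = 15L) {
  stopifnot(trim_len >= 1L)
  n <- nchar(primer)
  if (n > trim_len) substr(primer, n - trim_len + 1L, n) else primer
}

#' Resolve IUPAC degeneracies into all plain-base sequences
#'
#' Cartesian product of the per-position base sets; the result size is the
#' product of per-position degeneracies. A hard cap of 65536 variants guards
#' against pathologically degenerate inputs.
#'
#' @param seq IUPAC sequence.
#' @return Character vector of ACGT sequences.
#' @examples
#' expand_iupac("ARY")  # AAC AAT AGC AGT
#' @export
expand_iupac <- function(seq) {
  seq <- toupper(seq)
  check_iupac(seq, "sequence")
  sets <- IUPAC_SETS[strsplit(seq, "", fixed = TRUE)[[1]]]
  n_var <- prod(lengths(sets))
  if (n_var > 65536)
    stop("degenerate expansion of '", seq, "' would produce ", n_var,
         " sequences (cap 65536)", call. = FALSE)
  if (n_var == 1) return(seq)
  grid <- do.call(expand.grid,
                  c(rev(sets), list(stringsAsFactors = FALSE)))
  sort(do.call(paste0, rev(grid)))
}

#' Hamming-distance mismatch neighborhood
#'
#' All ACGT sequences within Hamming distance `m` of any input sequence
#' (inputs included, result deduplicated). Mirrors lowering the stringency
#' of primer binding: with `m = 2` (the default elsewhere in the package) a
#' primer site diverged at up to two positions is still recognised.
#' Mismatches are allowed at any position, including the 3'-terminal base.
#'
#' @param seqs Character vector of equal-length ACGT sequences.
#' @param m Maximum Hamming distance (>= 0).
#' @return Character vector (sorted, unique). For a single input of length L
#'   the size is `sum over i of choose(L, i) * 3^i`, i = 0..m.
#' @export
mismatch_neighborhood <- function(seqs, m = 2L) {
  stopifnot(m >= 0L, length(seqs) >= 1L)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length")
  if (m == 0L) return(sort(unique(seqs)))
  bases <- c("A", "C", "G", "T")
  out <- unique(seqs)
  current <- out
  for (round in seq_len(min(m, L))) {
    nxt <- character(0)
    for (s in current) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      for (p in seq_len(L)) {
        alt <- bases[bases != chars[p]]
        v <- rep(s, 3L)
        substr(v, p, p) <- alt
        nxt <- c(nxt, v)
      }
    }
    nxt <- unique(nxt)
    out <- unique(c(out, nxt))
    current <- nxt
  }
  sort(out)
}

#' Orient the reverse primer onto the forward strand
#'
#' Returns the IUPAC-aware reverse complement of the reverse primer so that
#' it reads on the same strand as the forward primer (complement pairs:
#' A-T, C-G, R-Y, K-M, B-V, D-H; S, W, N self-complementary). Involution.
#'
#' @param reverse_primer IUPAC sequence, 5'->3'.
#' @return Reverse-complemented IUPAC sequence.
#' @export
orient_reverse <- function(reverse_primer) {
  seq <- toupper(reverse_primer)
  check_iupac(seq, "reverse primer")
  comp <- chartr(IUPAC_COMPLEMENT["from"], IUPAC_COMPLEMENT["to"], seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Build start/end k-mer seed sets for a primer pair
#'
#' The pipeline is: trim each primer to its searched 3' portion, resolve
#' IUPAC degeneracies, add the Hamming mismatch neighborhood, then intersect
#' with the counted k-mer table. The reverse primer is first oriented onto
#' the forward strand; trimming the oriented text keeps its *first*
#' `trim_len` bases, which correspond to the reverse primer's 3' end, and
#' end k-mers must *end* with one of these oriented variants (products
#' therefore terminate at the trimmed reverse site). Start k-mers *begin*
#' with a forward variant. Both orientations of every canonical table key
#' are tested, so seeding is independent of read strand.
#'
#' An empty start or end set means the primers were not found in the reads;
#' this is reported as a `found = FALSE` outcome rather than an error so
#' that multi-pair runs continue.
#'
#' @param pair A [primer_pair()].
#' @param table A `kmer_table` from [count_kmers()]; `table$k` must be at
#'   least the searched primer length.
#' @param trim_len Searched primer length (default 15).
#' @param mismatches Maximum Hamming distance for variants (default 2).
#' @return A `seed_sets` object: list with `pair_name`, `start_kmers`,
#'   `end_kmers` (oriented k-mer strings), `k`, `trim_len`, `found`.
#' @export
build_seed_sets <- function(pair, table, trim_len = 15L, mismatches = 2L) {
  stopifnot(inherits(pair, "primer_pair"), inherits(table, "kmer_table"))
  fwd <- trim_primer(pair$forward, trim_len)
  rev_oriented <- orient_reverse(pair$reverse)
  if (nchar(rev_oriented) > trim_len)
    rev_oriented <- substr(rev_oriented, 1L, trim_len)  # 3' end of reverse primer
  if (max(nchar(fwd), nchar(rev_oriented)) > table$k)
    stop(sprintf(paste0("k (%d) must be as long as, or longer than, the ",
                        "longest searched primer (%d) for pair '%s'"),
         table$k, max(nchar(fwd), nchar(rev_oriented)), pair$name),
         call. = FALSE)
  fwd_variants <- mismatch_neighborhood(expand_iupac(fwd), mismatches)
  rev_variants <- mismatch_neighborhood(expand_iupac(rev_oriented), mismatches)
  hits <- .kt_scan_seeds(table$ptr, fwd_variants, rev_variants)
  structure(list(pair_name = pair$name,
                 start_kmers = as.character(hits$start_kmers),
                 end_kmers = as.character(hits$end_kmers),
                 k = table$k, trim_len = as.integer(trim_len),
                 found = length(hits$start_kmers) > 0 && length(hits$end_kmers) > 0),
            class = "seed_sets")
}

#' @export
print.seed_sets <- function(x, ...) {
  cat(sprintf("seed_sets '%s': %d start k-mers, %d end k-mers (k=%d)%s\n",
              x$pair_name, length(x$start_kmers), length(x$end_kmers), x$k,
              if (x$found) "" else " -- primers not found"))
  invisible(x)
}

#' Read a primer panel file (YAML or TSV)
#'
#' YAML: a list of maps with keys `name`, `forward`, `reverse` and optional
#' `min_length`, `max_length` (either a top-level list or under a `pairs`
#' key). TSV: a header line with those column names. Per-pair length bounds
#' override run-level defaults.
#'
#' @param path Panel file path.
#' @param min_length,max_length Defaults for pairs that omit bounds.
#' @return List of [primer_pair()] objects.
#' @export
read_panel <- function(path, min_length = 0L, max_length = 10000L) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$pairs)) y <- y$pairs
    y
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  lapply(rows, function(r) {
    primer_pair(
      name = as.character(r$name),
      forward = as.character(r$forward),
      reverse = as.character(r$reverse),
      min_length = if (!is.null(r$min_length) && !is.na(r$min_length))
        r$min_length else min_length,
      max_length = if (!is.null(r$max_length) && !is.na(r$max_length))
        r$max_length else max_length)
  })
}
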