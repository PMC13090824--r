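#' 2-bit encoding of a DNA k-mer
#'
#' Packs a k-mer over `{A,C,G,T}` into an integer code, big-endian, with
#' `A=00, C=01, G=10, T=11`: the leftmost base occupies the highest bit pair,
#' so integer order on codes equals lexicographic order on sequences. Odd k
#' guarantees no k-mer equals its own reverse complement, so the canonical
#' (minimum) form is always strict.
#'
#' Numeric codes are exact in an R double only up to 2^53, so this R-level
#' API accepts k up to 25 (odd); the counting engine itself works with full
#' 64-bit codes internally and supports k up to 31.
#'
#' @param seq Character scalar of length k over `{A,C,G,T}`.
#' @return Numeric code in `[0, 4^k)`, or `NA` if `seq` contains a character
#'   outside `{A,C,G,T}` (callers skip such k-mers).
#' @examples
#' encode_kmer("ACGTA")  # 108
#' @export
encode_kmer <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .encode_kmer(seq)
}

#' Decode a 2-bit k-mer code back to its sequence
#'
#' Inverse of [encode_kmer()]: `decode_kmer(encode_kmer(s), nchar(s)) == s`.
#'
#' @param code Numeric code in `[0, 4^k)`.
#' @param k Odd k-mer length, 3..25.
#' @return Character scalar of length `k`.
#' @export
decode_kmer <- function(code, k) {
  vapply(as.numeric(code), .decode_kmer, character(1), k = as.integer(k))
}

#' Reverse-complement a k-mer code
#'
#' Operates directly on the 2-bit code; involution, i.e.
#' `revcomp_code(revcomp_code(x, k), k) == x`.
#'
#' @inheritParams decode_kmer
#' @return Numeric code of the reverse complement.
#' @export
revcomp_code <- function(code, k) {
  vapply(as.numeric(code), .revcomp_code, numeric(1), k = as.integer(k))
}

#' Canonical form of a k-mer code
#'
#' The smaller of a code and its reverse-complement code; under the
#' lexicographic 2-bit packing this is the lexicographically smaller of the
#' two strands, the standard strand-independent representative. Idempotent.
#'
#' @inheritParams decode_kmer
#' @return Numeric canonical code.
#' @export
canonical_code <- function(code, k) {
  pmin(as.numeric(code), revcomp_code(code, k))
}

#' Count canonical k-mers over a set of reads
#'
#' Every window of length `k` consisting solely of `A/C/G/T` contributes one
#' observation to its canonical k-mer's count; windows containing any other
#' character (including `N` and IUPAC codes) contribute nothing, and reads
#' shorter than `k` contribute nothing. Counting is strand-independent.
#'
#' @param reads A `read_stream` object, or a character vector of (uppercase)
#'   read sequences.
#' @param k Odd k-mer length in `[3, 31]` (default 21).
#' @return A `kmer_table` object (hash table keyed by canonical 2-bit code).
#' @examples
#' tab <- count_kmers("ACGTACG", k = 5)
#' kmer_counts(tab)
#' @export
count_kmers <- function(reads, k = 21L) {
  tab <- kmer_table(k)
  kt_add_reads(tab, reads)
  tab
}

#' Create an empty k-mer count table
#'
#' @param k Odd k-mer length in `[3, 31]`.
#' @return An empty `kmer_table`.
#' @export
kmer_table <- function(k = 21L) {
  k <- as.integer(k)
  ptr <- .kt_new(k)
  structure(list(ptr = ptr, k = k), class = "kmer_table")
}

#' Add reads to an existing k-mer table (in place)
#'
#' Used by [count_kmers_incremental()] to accumulate counts chunk by chunk.
#'
#' @param table A `kmer_table`.
#' @param reads A `read_stream` or character vector of read sequences.
#' @return `table`, invisibly (modified in place).
#' @export
kt_add_reads <- function(table, reads) {
  stopifnot(inherits(table, "kmer_table"))
  .kt_insert(table$ptr, read_sequences(reads))
  invisible(table)
}

#' Look up canonical counts of k-mer strings
#'
#' @param table A `kmer_table`.
#' @param kmers Character vector of k-mer strings (either orientation).
#' @return Integer vector: count of the canonical form of each k-mer (0 if
#'   absent, `NA` for strings of wrong length or with ambiguous characters).
#' @export
kmer_count <- function(table, kmers) {
  stopifnot(inherits(table, "kmer_table"))
  .kt_lookup(table$ptr, as.character(kmers))
}

#' All entries of a k-mer table
#'
#' @param table A `kmer_table`.
#' @return A data.frame with columns `kmer` (decoded canonical k-mer) and
#'   `count`, sorted by `kmer`.
#' @export
kmer_counts <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  e <- .kt_entries(table$ptr)
  df <- data.frame(kmer = as.character(e$kmer), count = as.integer(e$count),
                   stringsAsFactors = FALSE)
  df <- df[order(df$kmer), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Number of distinct canonical k-mers in a table
#' @param table A `kmer_table`.
#' @return Numeric scalar.
#' @export
kmer_n_distinct <- function(table) .kt_size(table$ptr)

#' Total number of counted k-mer windows
#' @param table A `kmer_table`.
#' @return Numeric scalar (sum of all counts).
#' @export
kmer_n_total <- function(table) .kt_total(table$ptr)

#' K-mer spectrum (multiplicity histogram)
#'
#' Histogram of count values over the distinct canonical k-mers of a table.
#' Counts exceeding `max_multiplicity` are pooled into the top bin, the usual
#' treatment for spectrum plots and genome-size work.
#'
#' @param table A `kmer_table`.
#' @param max_multiplicity Top histogram bin; counts `>= max_multiplicity`
#'   pool there. Default 10000.
#' @return A `kmer_spectrum`: data.frame with columns `multiplicity` and
#'   `n_kmers`, plus attributes `k` and `n_reads` (if known).
#' @export
kmer_spectrum <- function(table, max_multiplicity = 10000L) {
  stopifnot(inherits(table, "kmer_table"))
  h <- .kt_spectrum(table$ptr, as.integer(max_multiplicity))
  df <- data.frame(multiplicity = as.integer(h$multiplicity),
                   n_kmers = as.numeric(h$n_kmers))
  structure(df, k = table$k, class = c("kmer_spectrum", "data.frame"))
}

#' Incremental k-mer counting over read chunks
#'
#' Splits the reads, in input order, into `n_chunks` near-equal chunks and
#' counts cumulatively: spectrum `i` reflects the union of chunks `1..i`, and
#' the final spectrum equals the spectrum of counting all reads at once. This
#' supports assessing how k-mer-based summaries stabilise with sequencing
#' depth without recounting from scratch at every depth.
#'
#' @inheritParams count_kmers
#' @param n_chunks Number of cumulative increments (>= 1). If there are fewer
#'   reads than chunks, trailing empty chunks repeat the previous spectrum.
#' @param max_multiplicity Passed to [kmer_spectrum()].
#' @return List of `kmer_spectrum` objects, one per increment, each carrying
#'   an `n_reads` attribute with the cumulative read count.
#' @export
count_kmers_incremental <- function(reads, k = 21L, n_chunks = 10L,
                                    max_multiplicity = 10000L) {
  n_chunks <- as.integer(n_chunks)
  stopifnot(n_chunks >= 1L)
  seqs <- read_sequences(reads)
  n <- length(seqs)
  # near-equal split by read count, in order; remainder goes to early chunks
  sizes <- rep(n %/% n_chunks, n_chunks) + (seq_len(n_chunks) <= n %% n_chunks)
  bounds <- c(0L, cumsum(sizes))
  tab <- kmer_table(k)
  out <- vector("list", n_chunks)
  for (i in seq_len(n_chunks)) {
    idx <- seq_len(bounds[i + 1L] - bounds[i]) + bounds[i]
    if (length(idx)) .kt_insert(tab$ptr, seqs[idx])
    sp <- kmer_spectrum(tab, max_multiplicity)
    attr(sp, "n_reads") <- as.integer(bounds[i + 1L])
    out[[i]] <- sp
  }
  out
}

#' Write incremental spectra as TSV files
#'
#' One two-column TSV (multiplicity, n_kmers) per increment, named with the
#' cumulative read count: `<prefix>_spectrum_<n_reads>.tsv`.
#'
#' @param spectra List of `kmer_spectrum` objects from
#'   [count_kmers_incremental()].
#' @param prefix Output path prefix.
#' @return Character vector of paths written, invisibly.
#' @export
write_spectra <- function(spectra, prefix) {
  paths <- character(length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    n <- attr(sp, "n_reads")
    if (is.null(n)) n <- i
    paths[i] <- sprintf("%s_spectrum_%d.tsv", prefix, n)
    utils::write.table(as.data.frame(sp), paths[i], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k=%d, %s distinct canonical k-mers, %s windows counted\n",
              x$k, format(kmer_n_distinct(x), big.mark = ","),
              format(kmer_n_total(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k=%d, %d multiplicity bins, %s distinct k-mers\n",
              attr(x, "k"), nrow(x), format(sum(x$n_kmers), big.mark = ",")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
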