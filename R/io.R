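#' Open sequencing reads from FASTA/FASTQ files
#'
#' Reads sequence records from one or more FASTA or FASTQ files (plain or
#' gzip-compressed; format and compression auto-detected from content, not
#' from the file name). Files are consumed in the order given and an optional
#' cap on the total number of records is applied jointly across files with
#' first-N semantics, before any k-mer counting. Sequences are uppercased;
#' characters outside the IUPAC nucleotide alphabet are an error. Qualities
#' in FASTQ are ignored.
#'
#' @param paths Character vector of file paths, consumed in order.
#' @param max_reads Optional positive integer cap on total records.
#' @return A `read_stream` object; use [read_sequences()] to extract the
#'   named character vector of sequences.
#' @export
open_reads <- function(paths, max_reads = NULL) {
  stopifnot(is.character(paths), length(paths) >= 1L)
  if (!is.null(max_reads)) {
    max_reads <- as.integer(max_reads)
    stopifnot(length(max_reads) == 1L, !is.na(max_reads), max_reads >= 1L)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file not found: ", paste(missing, collapse = ", "))

  seqs <- character(0)
  for (p in paths) {
    remaining <- if (is.null(max_reads)) -1L else max_reads - length(seqs)
    if (!is.null(max_reads) && remaining <= 0L) break
    fmt <- detect_format(p)
    rec <- tryCatch(
      Biostrings::readBStringSet(p, format = fmt, nrec = remaining),
      error = function(e) stop("malformed ", fmt, " in '", p, "': ",
                               conditionMessage(e), call. = FALSE))
    s <- toupper(as.character(rec))
    bad <- grep("[^ACGTRYSWKMBDHVN]", s)
    if (length(bad))
      stop("invalid sequence character in '", p, "', record ", bad[1],
           " ('", names(rec)[bad[1]], "')", call. = FALSE)
    names(s) <- sub("\\s.*$", "", names(rec))
    seqs <- c(seqs, s)
  }
  structure(list(sequences = seqs, sources = paths,
                 max_reads = max_reads),
            class = "read_stream")
}

# Peek at the first non-whitespace byte ('>' = FASTA, '@' = FASTQ);
# gzfile() transparently handles both plain and gzip files.
detect_format <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("empty input file: ", path, call. = FALSE)
    line <- trimws(line)
    if (nzchar(line)) break
  }
  first <- substr(line, 1L, 1L)
  if (first == ">") return("fasta")
  if (first == "@") return("fastq")
  stop("cannot detect FASTA/FASTQ format of '", path,
       "' (first record starts with '", first, "')", call. = FALSE)
}

#' Extract read sequences from a stream (or pass a character vector through)
#'
#' @param reads A `read_stream` or a character vector of sequences.
#' @return Uppercased named character vector of sequences.
#' @export
read_sequences <- function(reads) {
  if (inherits(reads, "read_stream")) return(reads$sequences)
  if (is.character(reads)) return(toupper(reads))
  stop("reads must be a read_stream or a character vector")
}

#' @export
print.read_stream <- function(x, ...) {
  cat(sprintf("read_stream: %d records from %d file(s)%s\n",
              length(x$sequences), length(x$sources),
              if (is.null(x$max_reads)) "" else sprintf(" (max_reads=%d)", x$max_reads)))
  invisible(x)
}

#' @export
length.read_stream <- function(x) length(x$sequences)

#' Write assembly products as FASTA
#'
#' One record per product, header
#' `<run_name>__<pair_name>__<index> len=<L> min_cov=<c>` with the index
#' numbered per primer pair, sequence wrapped at 80 columns. An empty product
#' set writes an empty file.
#'
#' @param products A data.frame of assembly products (see [assemble_pair()]),
#'   with columns `pair_name`, `sequence`, `length`, `min_coverage`.
#' @param out_path Output FASTA path.
#' @param run_name Run label used as the header prefix.
#' @return Number of records written, invisibly.
#' @export
write_products <- function(products, out_path, run_name = "ispcr") {
  if (is.null(products) || nrow(products) == 0L) {
    file.create(out_path)
    return(invisible(0L))
  }
  idx <- stats::ave(seq_len(nrow(products)), products$pair_name,
                    FUN = seq_along)
  headers <- sprintf("%s__%s__%d len=%d min_cov=%d",
                     run_name, products$pair_name, idx,
                     products$length, products$min_coverage)
  set <- Biostrings::DNAStringSet(products$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, out_path, width = 80L)
  invisible(nrow(products))
}
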