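#' Traversal configuration
#'
#' Tunables for the bounded de Bruijn graph traversal. `min_count` is the
#' coverage floor for graph edges: a k-mer must have canonical count at
#' least `min_count` to be walked, which suppresses singleton k-mers arising
#' from sequencing errors (set 1 for error-free simulations). `max_paths`
#' caps the number of simultaneously live paths per start k-mer; hitting the
#' cap truncates that traversal with a warning, making failure from graph
#' complexity observable and deterministic.
#'
#' @param min_count Edge coverage floor (default 2).
#' @param max_paths Live-path cap per start k-mer (default 10000).
#' @param min_length,max_length Product length window (defaults 0 and
#'   10000); per-pair bounds on a [primer_pair()] take precedence.
#' @return A `traversal_config` list.
#' @export
traversal_config <- function(min_count = 2L, max_paths = 10000L,
                             min_length = 0L, max_length = 10000L) {
  stopifnot(min_count >= 1L, max_paths >= 1L,
            min_length >= 0, min_length <= max_length)
  structure(list(min_count = as.integer(min_count),
                 max_paths = as.integer(max_paths),
                 min_length = as.numeric(min_length),
                 max_length = as.numeric(max_length)),
            class = "traversal_config")
}

#' Successors of an oriented k-mer in the counted graph
#'
#' Drops the first base and appends each of A, C, G, T (in that fixed
#' order); a successor is present iff its canonical count in the table is at
#' least `min_count`. An empty result is a dead end.
#'
#' @param kmer Oriented k-mer string of length `table$k`.
#' @param table A `kmer_table`.
#' @param min_count Edge coverage floor.
#' @return data.frame with columns `base` and `kmer`.
#' @export
successors <- function(kmer, table, min_count = 2L) {
  stopifnot(inherits(table, "kmer_table"), nchar(kmer) == table$k)
  bases <- c("A", "C", "G", "T")
  cand <- paste0(substr(kmer, 2L, table$k), bases)
  keep <- kmer_count(table, cand) >= min_count
  keep[is.na(keep)] <- FALSE
  data.frame(base = bases[keep], kmer = cand[keep], stringsAsFactors = FALSE)
}

#' Assemble products for one primer pair
#'
#' Enumerates every path from each start k-mer through k-mers whose
#' canonical count meets the coverage floor, emitting the path sequence
#' whenever the current k-mer is an end k-mer and the sequence length lies
#' within the product-length window. Traversal continues past an end hit so
#' nested, longer products up to `max_length` remain discoverable; a k-mer
#' may not be revisited within one path (no cycles within a product).
#' Products are deduplicated by exact sequence across all start k-mers and
#' sorted by descending minimum coverage, then length, then sequence.
#'
#' @param seeds A `seed_sets` object from [build_seed_sets()].
#' @param table The `kmer_table` the seeds were derived from.
#' @param cfg A [traversal_config()]; `min_length`/`max_length` here define
#'   the product window.
#' @return A data.frame of class `spcr_products` with columns `pair_name`,
#'   `sequence`, `length`, `min_coverage`, `mean_coverage`, and attribute
#'   `truncated` (TRUE if the live-path cap was hit).
#' @export
assemble_pair <- function(seeds, table, cfg = traversal_config()) {
  stopifnot(inherits(seeds, "seed_sets"), inherits(table, "kmer_table"))
  if (!seeds$found)
    stop("seed sets for pair '", seeds$pair_name,
         "' are empty (primers not found)", call. = FALSE)
  res <- .kt_assemble(table$ptr, seeds$start_kmers, seeds$end_kmers,
                      cfg$min_count, cfg$min_length, cfg$max_length,
                      cfg$max_paths)
  if (isTRUE(res$truncated))
    warning("live-path cap (", cfg$max_paths, ") reached for pair '",
            seeds$pair_name, "'; traversal truncated (complex graph)",
            call. = FALSE)
  seqs <- as.character(res$sequences)
  cov <- lapply(seqs, function(s) product_window_counts(s, table))
  df <- data.frame(
    pair_name = rep(seeds$pair_name, length(seqs)),
    sequence = seqs,
    length = nchar(seqs),
    min_coverage = vapply(cov, function(x) as.integer(min(x)), integer(1)),
    mean_coverage = vapply(cov, mean, numeric(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$pair_name, -df$min_coverage, df$length, df$sequence), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, truncated = isTRUE(res$truncated),
            class = c("spcr_products", "data.frame"))
}

# canonical counts of every k-window of a product sequence
product_window_counts <- function(seq, table) {
  k <- table$k
  n <- nchar(seq) - k + 1L
  windows <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  kmer_count(table, windows)
}

empty_products <- function() {
  structure(data.frame(pair_name = character(0), sequence = character(0),
                       length = integer(0), min_coverage = integer(0),
                       mean_coverage = numeric(0), stringsAsFactors = FALSE),
            truncated = FALSE, class = c("spcr_products", "data.frame"))
}

#' Run in silico PCR
#'
#' The full pipeline: count k-mers once over the reads, then for each primer
#' pair independently build seed sets and assemble products. A pair whose
#' forward or reverse primer yields no seed k-mers produces a
#' `primers_not_found` outcome without affecting other pairs; this mirrors a
#' failed benchtop reaction in a multi-target run.
#'
#' @param reads A `read_stream` (see [open_reads()]) or character vector of
#'   read sequences.
#' @param pairs A [primer_pair()] or list of them.
#' @param k Odd k-mer length in `[3, 31]`, at least `trim_len` (default 21).
#' @param trim_len Searched primer length (default 15).
#' @param mismatches Hamming mismatch allowance for primer variants
#'   (default 2).
#' @param cfg A [traversal_config()]; its `min_length`/`max_length` act as
#'   run-level defaults, overridden by per-pair bounds.
#' @return An `spcr_result`: list with `products` (combined `spcr_products`
#'   data.frame), `outcomes` (per-pair summary data.frame with columns
#'   `pair_name`, `outcome`, `n_products`, `best_min_coverage`, `lengths`,
#'   `n_start_kmers`, `n_end_kmers`), `table` (the `kmer_table`), `k`,
#'   `n_reads`.
#' @examples
#' res <- run_spcr("AACGTTGCAAGGTCC",
#'                 primer_pair("toy", "AACGT", "GGACC"),
#'                 k = 7, trim_len = 5, mismatches = 0,
#'                 cfg = traversal_config(min_count = 1))
#' res$products$sequence  # "AACGTTGCAAGGTCC"
#' @export
run_spcr <- function(reads, pairs, k = 21L, trim_len = 15L, mismatches = 2L,
                     cfg = traversal_config()) {
  if (inherits(pairs, "primer_pair")) pairs <- list(pairs)
  stopifnot(length(pairs) >= 1L,
            all(vapply(pairs, inherits, logical(1), "primer_pair")))
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd (even k admits palindromic k-mers)")
  if (k < trim_len)
    stop("k (", k, ") must be as long as, or longer than, the longest ",
         "searched primer (trim_len = ", trim_len, ")")

  table <- count_kmers(reads, k)  # one counting pass shared by all pairs
  prod_list <- list()
  outcomes <- vector("list", length(pairs))

  for (i in seq_along(pairs)) {
    pair <- pairs[[i]]
    seeds <- build_seed_sets(pair, table, trim_len, mismatches)
    pair_cfg <- traversal_config(min_count = cfg$min_count,
                                 max_paths = cfg$max_paths,
                                 min_length = pair$min_length,
                                 max_length = pair$max_length)
    if (!seeds$found) {
      outcomes[[i]] <- data.frame(
        pair_name = pair$name, outcome = "primers_not_found",
        n_products = 0L, best_min_coverage = NA_integer_, lengths = "",
        n_start_kmers = length(seeds$start_kmers),
        n_end_kmers = length(seeds$end_kmers), stringsAsFactors = FALSE)
      next
    }
    prods <- assemble_pair(seeds, table, pair_cfg)
    prod_list[[length(prod_list) + 1L]] <- prods
    outcomes[[i]] <- data.frame(
      pair_name = pair$name,
      outcome = if (attr(prods, "truncated")) "truncated"
                else if (nrow(prods)) "products_found" else "no_products",
      n_products = nrow(prods),
      best_min_coverage = if (nrow(prods)) max(prods$min_coverage) else NA_integer_,
      lengths = paste(prods$length, collapse = ","),
      n_start_kmers = length(seeds$start_kmers),
      n_end_kmers = length(seeds$end_kmers), stringsAsFactors = FALSE)
  }

  products <- if (length(prod_list)) {
    combined <- do.call(rbind, lapply(prod_list, as.data.frame))
    combined <- combined[order(combined$pair_name, -combined$min_coverage,
                               combined$length, combined$sequence), ,
                         drop = FALSE]
    rownames(combined) <- NULL
    structure(combined,
              truncated = any(vapply(prod_list, attr, logical(1), "truncated")),
              class = c("spcr_products", "data.frame"))
  } else empty_products()

  structure(list(products = products,
                 outcomes = do.call(rbind, outcomes),
                 table = table, k = k,
                 n_reads = length(read_sequences(reads))),
            class = "spcr_result")
}

#' @export
print.spcr_result <- function(x, ...) {
  cat(sprintf("in silico PCR: %d reads, k=%d, %s distinct canonical k-mers\n",
              x$n_reads, x$k,
              format(kmer_n_distinct(x$table), big.mark = ",")))
  for (i in seq_len(nrow(x$outcomes))) {
    o <- x$outcomes[i, ]
    cat(sprintf("  %-20s %-18s products=%d%s\n", o$pair_name, o$outcome,
                o$n_products,
                if (nzchar(o$lengths)) paste0(" lengths=", o$lengths) else ""))
  }
  invisible(x)
}

#' Write the per-pair outcome summary as TSV
#'
#' Columns: `pair_name`, `outcome` (`products_found`, `no_products`,
#' `primers_not_found`, or `truncated`), `n_products`, `best_min_coverage`,
#' `lengths`, `n_start_kmers`, `n_end_kmers`.
#'
#' @param result An `spcr_result` from [run_spcr()].
#' @param out_path Output TSV path.
#' @return `out_path`, invisibly.
#' @export
write_summary <- function(result, out_path) {
  stopifnot(inherits(result, "spcr_result"))
  utils::write.table(result$outcomes, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_path)
}
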