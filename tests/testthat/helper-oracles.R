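# Independent oracles, deliberately implemented on strings (Biostrings for
# reverse complement) so they share nothing with the package's 2-bit-coded
# C++ path.

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# naive canonical k-mer counting: enumerate windows as text, reverse
# complement as text, take the lexicographically smaller string
oracle_count_kmers <- function(reads, k) {
  wins <- unlist(lapply(reads, function(r) {
    n <- nchar(r) - k + 1L
    if (n < 1L) return(character(0))
    w <- substring(r, seq_len(n), seq_len(n) + k - 1L)
    w[!grepl("[^ACGT]", w)]
  }), use.names = FALSE)
  if (!length(wins)) {
    return(data.frame(kmer = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  canon <- pmin(wins, rc(wins))
  tab <- table(canon)
  df <- data.frame(kmer = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(df$kmer), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# exhaustive simple-path enumeration between seed sets on a string-keyed
# de Bruijn graph; same emission semantics as the assembler contract
# (continue past end hits, no oriented-k-mer revisit within a path)
oracle_assemble <- function(counts_df, start_kmers, end_kmers, k,
                            min_count = 1L, min_len = 0, max_len = 10000) {
  # index counts under both orientations so lookups avoid per-call revcomp
  lookup <- new.env(parent = emptyenv())
  rcs <- if (nrow(counts_df)) rc(counts_df$kmer) else character(0)
  for (i in seq_len(nrow(counts_df))) {
    assign(counts_df$kmer[i], counts_df$count[i], envir = lookup)
    assign(rcs[i], counts_df$count[i], envir = lookup)
  }
  count_of <- function(kmer) {
    v <- mget(kmer, envir = lookup, ifnotfound = 0L)[[1]]
    v
  }
  end_set <- unique(end_kmers)
  products <- new.env(parent = emptyenv())
  # classic DFS with backtracking: `visited` marks the k-mers on the current
  # path only, so membership tests are O(1) without copying per branch
  visited <- new.env(parent = emptyenv())
  recurse <- function(seq, kmer) {
    if (kmer %in% end_set && nchar(seq) >= min_len && nchar(seq) <= max_len)
      assign(seq, TRUE, envir = products)
    if (nchar(seq) < max_len) {
      for (b in c("A", "C", "G", "T")) {
        nxt <- paste0(substr(kmer, 2L, k), b)
        if (count_of(nxt) >= min_count && !exists(nxt, envir = visited)) {
          assign(nxt, TRUE, envir = visited)
          recurse(paste0(seq, b), nxt)
          rm(list = nxt, envir = visited)
        }
      }
    }
    invisible()
  }
  for (s in unique(start_kmers)) {
    if (count_of(s) >= min_count) {
      assign(s, TRUE, envir = visited)
      recurse(s, s)
      rm(list = s, envir = visited)
    }
  }
  sort(ls(products))
}

# brute-force Hamming ball around one sequence (used for L <= 6)
oracle_hamming_ball <- function(seq, m) {
  L <- nchar(seq)
  bases <- c("A", "C", "G", "T")
  all_strings <- do.call(paste0, expand.grid(rep(list(bases), L),
                                             stringsAsFactors = FALSE))
  ref <- strsplit(seq, "")[[1]]
  dist <- vapply(strsplit(all_strings, ""), function(x) sum(x != ref),
                 integer(1))
  sort(all_strings[dist <= m])
}

random_reads <- function(n, max_len, min_len = 10L) {
  lens <- min_len + sample.int(max_len - min_len + 1L, n, replace = TRUE) - 1L
  vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

random_iupac <- function(L) {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  paste(sample(codes, L, replace = TRUE, prob = c(rep(4, 4), rep(1, 11))),
        collapse = "")
}

iupac_degeneracy <- c(A = 1, C = 1, G = 1, T = 1, R = 2, Y = 2, S = 2, W = 2,
                      K = 2, M = 2, B = 3, D = 3, H = 3, V = 3, N = 4)

# a genome with planted primer sites around a random insert, for small
# end-to-end fixtures
plant_genome <- function(fwd_site, rev_site, insert_len, flank_len,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  paste0(rnd(flank_len), fwd_site, rnd(insert_len), rc(rev_site),
         rnd(flank_len))
}
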