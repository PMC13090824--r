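# Synthetic genomes with embedded primer-flanked amplicons, plus a simple
# uniform read simulator. All randomness flows from one explicit seed via a
# local RNG state, so fixtures are reproducible and the global RNG untouched.

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

revcomp_text <- function(seq) {
  vapply(seq, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = ""),
    character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Specify an amplicon to embed in a synthetic genome
#'
#' The embedded locus is `forward_site + insert + reverse complement of
#' reverse_site`: the forward primer binding site, the variable insert, and
#' the reverse primer binding site as it appears on the forward strand.
#' `copy_number > 1` embeds that many identical copies at disjoint,
#' non-tandem loci, emulating high-copy targets such as mitochondrial and
#' ribosomal genes.
#'
#' @param pair_name Label matching the primer pair that targets this locus.
#' @param forward_site ACGT realisation of the forward primer binding site.
#' @param reverse_site ACGT realisation of the reverse primer (5'->3', i.e.
#'   as ordered; it is reverse-complemented on embedding).
#' @param insert Either an ACGT string or a single integer length (the
#'   insert is then drawn randomly when the genome is built).
#' @param copy_number Number of embedded copies (>= 1).
#' @return An `amplicon_spec` list.
#' @export
amplicon_spec <- function(pair_name, forward_site, reverse_site,
                          insert = 570L, copy_number = 1L) {
  stopifnot(copy_number >= 1L)
  structure(list(pair_name = pair_name, forward_site = toupper(forward_site),
                 reverse_site = toupper(reverse_site), insert = insert,
                 copy_number = as.integer(copy_number)),
            class = "amplicon_spec")
}

#' Build a synthetic genome with embedded amplicons
#'
#' The background is sampled uniformly from ACGT; each amplicon copy is
#' placed at a random locus on a random strand, with no two placements
#' overlapping. Optional substitutions mutate single bases of an amplicon
#' before placement (used to validate that targeted mutations are recovered
#' base-for-base). The truth table records each placement and the expected
#' product sequence, always reported on the forward-primer strand.
#'
#' @param genome_length Total genome length in bp.
#' @param amplicons List of [amplicon_spec()] objects (may be empty).
#' @param substitutions Optional data.frame with columns `amplicon` (index
#'   into `amplicons`), `offset` (1-based position within the embedded
#'   amplicon) and `base` (new base); applied to every copy of that
#'   amplicon.
#' @param seed Integer seed; the same seed yields a byte-identical genome.
#' @return List with `genome` (single string) and `truth` (data.frame:
#'   `pair_name`, `copy`, `start`, `end`, `strand`, `expected_sequence`).
#' @export
build_genome <- function(genome_length, amplicons = list(),
                         substitutions = NULL, seed = 1L) {
  with_local_seed(seed, {
    # resolve amplicon sequences (inserts may be drawn here)
    seqs <- lapply(seq_along(amplicons), function(i) {
      a <- amplicons[[i]]
      insert <- if (is.character(a$insert)) toupper(a$insert)
                else random_dna(as.integer(a$insert))
      amp <- paste0(a$forward_site, insert, revcomp_text(a$reverse_site))
      if (!is.null(substitutions)) {
        sub_i <- substitutions[substitutions$amplicon == i, , drop = FALSE]
        for (j in seq_len(nrow(sub_i))) {
          off <- sub_i$offset[j]
          stopifnot(off >= 1L, off <= nchar(amp))
          substr(amp, off, off) <- toupper(sub_i$base[j])
        }
      }
      amp
    })
    total_amp <- sum(vapply(seqs, nchar, integer(1)) *
                       vapply(amplicons, `[[`, integer(1), "copy_number"))
    if (total_amp >= genome_length)
      stop("amplicons (", total_amp, " bp) do not fit in a ", genome_length,
           " bp genome", call. = FALSE)

    genome <- random_dna(genome_length)
    occupied <- integer(0)  # positions already used by a placement
    truth <- list()
    for (i in seq_along(amplicons)) {
      a <- amplicons[[i]]
      amp <- seqs[[i]]
      L <- nchar(amp)
      for (copy in seq_len(a$copy_number)) {
        placed <- FALSE
        for (attempt in seq_len(1000L)) {
          start <- sample.int(genome_length - L + 1L, 1L)
          span <- start:(start + L - 1L)
          if (!any(span %in% occupied)) { placed <- TRUE; break }
        }
        if (!placed) stop("could not place amplicon '", a$pair_name,
                          "' copy ", copy, " without overlap", call. = FALSE)
        strand <- sample(c("+", "-"), 1L)
        embedded <- if (strand == "+") amp else revcomp_text(amp)
        substr(genome, start, start + L - 1L) <- embedded
        occupied <- c(occupied, span)
        truth[[length(truth) + 1L]] <- data.frame(
          pair_name = a$pair_name, copy = copy, start = start,
          end = start + L - 1L, strand = strand,
          expected_sequence = amp, stringsAsFactors = FALSE)
      }
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(pair_name = character(0), copy = integer(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 expected_sequence = character(0), stringsAsFactors = FALSE)
    list(genome = genome, truth = truth_df)
  })
}

#' Simulate shotgun reads from a genome
#'
#' Reads are drawn uniformly over start positions and strands;  each base is
#' substituted with a uniformly chosen different base with probability
#' `error_rate` (substitution-only error model, no indels). The number of
#' reads is `round(depth * genome_length / read_length)`. Deterministic
#' under `seed`.
#'
#' @param genome Genome string.
#' @param read_length Read length in bp (default 150).
#' @param depth Mean fold-coverage (default 50).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param out Optional path; if given, reads are also written as FASTQ
#'   (dummy qualities, gzipped if the path ends in `.gz`).
#' @return Named character vector of reads (invisibly if `out` is given).
#' @export
simulate_reads <- function(genome, read_length = 150L, depth = 50,
                           error_rate = 0, seed = 1L, out = NULL) {
  G <- nchar(genome)
  stopifnot(read_length <= G, error_rate >= 0, error_rate < 1)
  n_reads <- round(depth * G / read_length)
  reads <- with_local_seed(seed, {
    starts <- sample.int(G - read_length + 1L, n_reads, replace = TRUE)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    r <- substring(genome, starts, starts + read_length - 1L)
    minus <- strands == "-"
    r[minus] <- revcomp_text(r[minus])
    if (error_rate > 0) {
      bases <- c("A", "C", "G", "T")
      mat <- matrix(unlist(strsplit(r, "", fixed = TRUE), use.names = FALSE),
                    nrow = read_length)
      hit <- which(stats::runif(length(mat)) < error_rate)
      if (length(hit)) {
        # uniform over the three non-matching bases
        shift <- sample.int(3L, length(hit), replace = TRUE)
        old <- match(mat[hit], bases)
        mat[hit] <- bases[((old - 1L + shift) %% 4L) + 1L]
      }
      r <- apply(mat, 2L, paste, collapse = "")
    }
    names(r) <- sprintf("read_%d", seq_len(n_reads))
    r
  })
  if (!is.null(out)) {
    write_fastq(reads, out)
    return(invisible(reads))
  }
  reads
}

#' Write reads as FASTQ
#'
#' Four-line records with constant dummy qualities ("I"); gzip-compressed if
#' the path ends in `.gz`.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  lines <- rbind(paste0("@", ids), reads,
                 rep("+", length(reads)),
                 vapply(nchar(reads), function(n) strrep("I", n), character(1)))
  writeLines(as.vector(lines), con)
  invisible(path)
}

#' Write a truth table as TSV
#'
#' @param truth Truth data.frame from [build_genome()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
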