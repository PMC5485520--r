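# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin wrapper over [Biostrings::reverseComplement()] that accepts and
#' returns plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements, names preserved.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# coerce a genome to a named character vector of chromosome sequences
as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!is.character(genome)) stop("genome must be a character vector or DNAStringSet")
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  toupper(genome)
}

# uniform random DNA with a given GC content
random_dna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, len, replace = TRUE, prob = p[DNA_BASES]), collapse = "")
}

# RNA-style U -> DNA T, uppercased
normalize_u <- function(x) chartr("uU", "tT", x) |> toupper()

# Hamming distance between equal-length strings (vectorized over b)
hamming <- function(a, b) {
  av <- utf8ToInt(a)
  vapply(b, function(s) sum(utf8ToInt(s) != av), 0L, USE.NAMES = FALSE)
}

# sample from a vector even when it has length 1 (avoids sample(n, ...) rules)
resample <- function(x, size = 1L, ...) x[sample.int(length(x), size, ...)]

# integer check helper
is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == round(x)

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name))
}

# read FASTQ/FASTA into a plain character vector of sequences
read_seqs <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  as.character(Biostrings::readDNAStringSet(path, format = format))
}

# write sequences + uniform qualities as Sanger FASTQ
write_fastq <- function(seqs, path, quality_char = "I") {
  ds <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(ds) <- paste0("read", seq_along(seqs))
  qual <- Biostrings::BStringSet(strrep(quality_char, Biostrings::width(ds)))
  Biostrings::writeXStringSet(ds, filepath = path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

# write a named character vector as FASTA
write_fasta <- function(seqs, path) {
  ds <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ds, filepath = path, format = "fasta")
  invisible(path)
}
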