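# Low-level sequence helpers shared by the aligner, the CRISPR detector and
# the synthetic community generator.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x A single DNA string over A/C/G/T/N.
#' @return The reverse complement string (N maps to N).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# i.i.d. per-site substitution: each site mutates with probability `rate`,
# uniformly to one of the three alternative bases.
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit) > 0) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
  }
  paste(ch, collapse = "")
}

# All k-mers of a string as a character vector (1-based start positions).
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character())
  substring(x, 1:(n - k + 1), k:n)
}

# Per-position match vector of two equal-length substrings; positions where
# either base is N never count as a match.
match_vector <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  ra == rb & ra != charToRaw("N")[1]
}

# Derive a reproducible child seed from a root seed and a string label, so
# that each sub-generator of the simulator owns an independent stream and
# adding a feature never perturbs existing draws. Plain polynomial hash,
# kept below 2^31.
child_seed <- function(root, label) {
  h <- as.double(root) %% 2147483629
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
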