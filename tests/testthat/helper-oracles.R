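# Shared fixtures and independent oracles for the suite. Oracles are
# deliberately written from the definitions (brute force / enumeration),
# not by calling the implementation under test.

# Memoized default bundle and demo run, shared across test files.
tv_cache <- new.env(parent = emptyenv())

test_bundle <- function() {
  if (is.null(tv_cache$bundle)) {
    tv_cache$bundle <- suppressMessages(simulate_bundle(sim_config(seed = 42)))
  }
  tv_cache$bundle
}

test_demo <- function() {
  if (is.null(tv_cache$demo)) {
    tv_cache$demo <- suppressMessages(demo_run(seed = 7, permutations = 199))
  }
  tv_cache$demo
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at_rate <- function(x, rate) {
  ch <- strsplit(x, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# Full dynamic-programming ANI oracle via Biostrings overlap alignment:
# identities over aligned (substitution) columns.
dp_ani <- function(a, b) {
  one <- function(bb) {
    al <- Biostrings::pairwiseAlignment(a, bb, type = "overlap",
                                        substitutionMatrix =
                                          Biostrings::nucleotideSubstitutionMatrix(
                                            match = 1, mismatch = -1),
                                        gapOpening = 4, gapExtension = 2)
    c(Biostrings::nmatch(al), Biostrings::nmismatch(al))
  }
  fw <- one(b)
  rv <- one(as.character(Biostrings::reverseComplement(Biostrings::DNAString(b))))
  st <- if (rv[1] > fw[1]) rv else fw
  if (sum(st) == 0) return(0)
  st[1] / sum(st)
}

# Naive O(n*m) spacer scan: exact full-length substring on either strand,
# no N anywhere in the matched window.
naive_spacer_hits <- function(spacer, seqs, ids) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(spacer)))
  hits <- list()
  for (k in seq_along(seqs)) {
    s <- seqs[k]
    n <- nchar(s); m <- nchar(spacer)
    if (n < m) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") spacer else rc
      for (i in 1:(n - m + 1)) {
        win <- substr(s, i, i + m - 1)
        if (win == pat && !grepl("N", win, fixed = TRUE)) {
          hits[[length(hits) + 1]] <- data.frame(
            virus_id = ids[k], position = i - 1L, strand = strand)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(virus_id = character(), position = integer(),
                      strand = character()))
  }
  do.call(rbind, hits)
}

# Independent ANOSIM R from the definition.
oracle_anosim_R <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  vals <- c(); within <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    vals <- c(vals, dm[i, j])
    within <- c(within, groups[i] == groups[j])
  }
  rk <- rank(vals)
  (mean(rk[!within]) - mean(rk[within])) / (length(vals) / 2)
}

# Independent one-factor PERMANOVA pseudo-F and R2 from the definition.
oracle_permanova <- function(d, groups) {
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  g <- unique(groups)
  ss_tot <- sum(dm[upper.tri(dm)]) / n
  ss_w <- 0
  for (gg in g) {
    idx <- which(groups == gg)
    sub <- dm[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_b <- ss_tot - ss_w
  list(F = (ss_b / (length(g) - 1)) / (ss_w / (n - length(g))),
       R2 = ss_b / ss_tot)
}

# Exhaustive permutation matrix over distinct two-group assignments:
# each row is a sample-index permutation realising one assignment.
exhaustive_two_group_perms <- function(groups) {
  groups <- as.factor(groups)
  n <- length(groups)
  n1 <- sum(groups == levels(groups)[1])
  g1_idx <- which(groups == levels(groups)[1])
  g2_idx <- which(groups == levels(groups)[2])
  subsets <- utils::combn(n, n1)
  t(apply(subsets, 2, function(S) {
    ix <- integer(n)
    ix[S] <- g1_idx
    ix[setdiff(1:n, S)] <- g2_idx
    ix
  }))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- NULL
  for (i in 1:n) {
    block <- cbind(i, matrix((1:n)[-i][sub], nrow(sub)))
    out <- rbind(out, block)
  }
  unname(out)
}

# Exact two-sided rank-sum p by direct enumeration (independent of the
# implementation's code path).
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[1:n1])
  mu <- n1 * (n + 1) / 2
  subsets <- utils::combn(n, n1)
  w_all <- apply(subsets, 2, function(S) sum(rk[S]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
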