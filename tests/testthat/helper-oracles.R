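# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the package's k-mer index: plain double loops over
# substrings, so agreement is a real cross-check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

rand_aa_str <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_nt_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force frame/protein scoring: scan every window against every peptide
oracle_score <- function(seq, group) {
  peps <- names(group$peptides)
  n <- nchar(seq)
  k <- if (length(peps)) nchar(peps[1L]) else 6L
  covered <- rep(FALSE, n)
  matched <- character(0)
  if (n >= k) {
    for (p in peps) {
      for (s in seq_len(n - k + 1L)) {
        if (substr(seq, s, s + k - 1L) == p) {
          matched <- union(matched, p)
          covered[s:(s + k - 1L)] <- TRUE
        }
      }
    }
  }
  list(n_peptides = length(matched),
       frequency_score = unname(sum(group$peptides[matched])),
       covered_aa = sum(covered))
}

# brute-force shared-peptide counts: naive double loop over peptide pairs
oracle_shared <- function(groups) {
  n <- length(groups)
  S <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cnt <- 0L
    for (p in names(groups[[i]]$peptides))
      for (q in names(groups[[j]]$peptides))
        if (p == q) cnt <- cnt + 1L
    S[i, j] <- cnt
  }
  dimnames(S) <- list(vapply(groups, `[[`, "", "id"),
                      vapply(groups, `[[`, "", "id"))
  S
}

# a random group drawn partly from substrings of `seq` (guaranteed matches)
# and partly from unrelated random peptides
rand_group <- function(seq, id = "G_01", family = "G", n_hit = 3L,
                       n_miss = 5L, k = 6L) {
  n <- nchar(seq)
  hits <- character(0)
  if (n_hit > 0L && n >= k) {
    starts <- sample(n - k + 1L, min(n_hit, n - k + 1L), replace = TRUE)
    hits <- substring(seq, starts, starts + k - 1L)
  }
  miss <- vapply(seq_len(n_miss), function(i) rand_aa_str(k), character(1L))
  peps <- unique(c(hits, miss))
  peps <- peps[!grepl("[^ACDEFGHIKLMNPQRSTVWY]", peps)]
  freq <- stats::runif(length(peps), min = 0.05, max = 1)
  peptide_group(id, family, structure(freq, names = peps))
}

# build one peptide list per planted family of a synthetic pool
build_pool_groups <- function(pool, config = ppr_config()) {
  fams <- unique(pool$truth$family)
  unlist(lapply(fams, function(f) {
    ids <- pool$truth$protein_id[pool$truth$family == f]
    build_subfamilies(pool$proteins[ids], config, family = f)$groups
  }), recursive = FALSE)
}

# map each recovered group to the planted subfamily of its members;
# errors if any group mixes subfamilies
map_groups_to_planted <- function(groups, truth) {
  out <- vapply(groups, function(g) {
    sf <- unique(truth$subfamily[match(g$members, truth$protein_id)])
    stopifnot("a recovered group mixes planted subfamilies" = length(sf) == 1L)
    sf
  }, character(1L))
  names(out) <- vapply(groups, `[[`, "", "id")
  out
}
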