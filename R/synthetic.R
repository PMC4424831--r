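.rand_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                              collapse = "")

.rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

.hexamers <- function(s, k = 6L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Parameters of the synthetic protein-family generator
#'
#' Describes a pool of protein families split into subfamilies, each
#' subfamily defined by a set of conserved hexapeptide motifs planted at
#' subfamily-consistent positions. Motifs are realized as two conserved
#' sequence blocks (mirroring the two conserved regions of real peptide
#' profiles): block one starts at residue `region_starts[1]` and carries
#' half of the motifs as overlapping hexamer windows, block two starts at
#' `region_starts[2]` and carries the rest, so with the defaults all motifs
#' lie before residue 250. The remainder of each protein is random sequence,
#' scrubbed so that no background window reproduces any planted motif —
#' zero sharing between subfamilies is exact, not probabilistic.
#'
#' @param n_families Number of families.
#' @param subfamilies_per_family Subfamilies per family.
#' @param proteins_per_subfamily Proteins per subfamily.
#' @param motifs_per_subfamily Planted hexapeptide motifs per subfamily.
#' @param protein_len Length range (uniform integer draw), residues.
#' @param mutation_rate Per-residue substitution probability applied i.i.d.
#'   to every protein after planting, in `[0, 1]`.
#' @param shared_within_family Number of motifs each subfamily shares with
#'   the previous subfamily of the same family (at least; realized by
#'   overlapping conserved blocks). Default 0 (exact disjointness).
#' @param shared_cross_family Number of motifs the first subfamily of each
#'   family shares with the previous family. Default 0.
#' @param region_starts Start residues of the two conserved blocks.
#' @param intergenic_len Default intergenic spacing used by
#'   [generate_genome()], bases.
#' @param seed Integer seed; generation is byte-reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_families = 3L, subfamilies_per_family = 4L,
                           proteins_per_subfamily = 20L,
                           motifs_per_subfamily = 70L,
                           protein_len = c(200L, 350L),
                           mutation_rate = 0,
                           shared_within_family = 0L,
                           shared_cross_family = 0L,
                           region_starts = c(81L, 141L),
                           intergenic_len = 10000L,
                           seed = 1L) {
  spec <- list(n_families = as.integer(n_families),
               subfamilies_per_family = as.integer(subfamilies_per_family),
               proteins_per_subfamily = as.integer(proteins_per_subfamily),
               motifs_per_subfamily = as.integer(motifs_per_subfamily),
               protein_len = as.integer(protein_len),
               mutation_rate = as.numeric(mutation_rate),
               shared_within_family = as.integer(shared_within_family),
               shared_cross_family = as.integer(shared_cross_family),
               region_starts = as.integer(region_starts),
               intergenic_len = as.integer(intergenic_len),
               seed = as.integer(seed))
  counts <- spec[c("n_families", "subfamilies_per_family",
                   "proteins_per_subfamily", "motifs_per_subfamily",
                   "intergenic_len")]
  if (any(vapply(counts, function(x) x < 1L, logical(1L))))
    stop("all counts must be positive")
  if (spec$mutation_rate < 0 || spec$mutation_rate > 1)
    stop("mutation_rate must lie in [0, 1]")
  if (length(spec$protein_len) != 2L ||
      spec$protein_len[1L] > spec$protein_len[2L])
    stop("protein_len must be c(min, max)")
  m1 <- spec$motifs_per_subfamily %/% 2L
  m2 <- spec$motifs_per_subfamily - m1
  r1_end <- spec$region_starts[1L] + m1 + 4L
  r2_end <- spec$region_starts[2L] + m2 + 4L
  if (spec$region_starts[2L] - r1_end < 6L)
    stop("conserved blocks must be separated by at least 6 residues")
  if (r2_end > spec$protein_len[1L])
    stop("second conserved block (ending at residue ", r2_end,
         ") does not fit in the shortest protein")
  if (spec$shared_within_family > m1 || spec$shared_cross_family > m1)
    stop("shared motif counts cannot exceed the first block's motif count")
  spec$block_sizes <- c(m1, m2)
  structure(spec, class = "synthetic_spec")
}

# rewrite background windows that accidentally reproduce a planted motif:
# mutate one residue outside the conserved blocks until no stray match
# remains (collisions are ~1e-4 probable, so this almost never fires)
.scrub_background <- function(chars, motif_env, allowed_starts, region_pos,
                              k = 6L) {
  n <- length(chars)
  if (n < k) return(chars)
  for (round in seq_len(100L)) {
    s <- paste(chars, collapse = "")
    wins <- .hexamers(s, k)
    match <- vapply(wins, function(w)
      exists(w, envir = motif_env, inherits = FALSE), logical(1L),
      USE.NAMES = FALSE)
    bad <- setdiff(which(match), allowed_starts)
    if (!length(bad)) return(chars)
    for (o in bad) {
      span <- o:(o + k - 1L)
      free <- setdiff(span, region_pos)
      p <- free[1L]
      chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
    }
  }
  stop("failed to scrub background motif collisions")
}

#' Generate a synthetic protein pool with planted subfamilies
#'
#' Draws, for every subfamily, two random conserved blocks whose overlapping
#' hexamer windows are the subfamily's motifs (rejection-sampled so that
#' motif sets are exactly disjoint across subfamilies except for any
#' requested sharing), then builds each member protein as random sequence
#' with the blocks planted at the spec's fixed positions, applies i.i.d.
#' per-residue mutations, and scrubs stray background matches to any
#' planted motif. Fully deterministic under the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_pool`: `proteins` (named character),
#'   `truth` (`data.frame` protein_id/family/subfamily), `motifs` (named
#'   list subfamily -> motif vector), `motif_positions` (named list
#'   subfamily -> named integer vector of planted start positions) and
#'   `spec`.
#' @export
generate_family_pool <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m1 <- spec$block_sizes[1L]; m2 <- spec$block_sizes[2L]
  r1s <- spec$region_starts[1L]; r2s <- spec$region_starts[2L]
  motif_env <- new.env(hash = TRUE, parent = emptyenv())
  motifs <- list(); blocks <- list(); fam_of <- character(0)
  for (f in seq_len(spec$n_families)) {
    fam <- sprintf("F%d", f)
    for (s in seq_len(spec$subfamilies_per_family)) {
      sf <- sprintf("%s_%02d", fam, s)
      prefix <- ""
      if (s > 1L && spec$shared_within_family > 0L) {
        prev <- blocks[[sprintf("%s_%02d", fam, s - 1L)]]$r1
        prefix <- substring(prev, nchar(prev) - spec$shared_within_family - 4L,
                            nchar(prev))
      } else if (s == 1L && f > 1L && spec$shared_cross_family > 0L) {
        prev <- blocks[[sprintf("F%d_%02d", f - 1L, 1L)]]$r1
        prefix <- substring(prev, nchar(prev) - spec$shared_cross_family - 4L,
                            nchar(prev))
      }
      allowed <- .hexamers(prefix)
      repeat {
        r1 <- paste0(prefix, .rand_aa(m1 + 5L - nchar(prefix)))
        r2 <- .rand_aa(m2 + 5L)
        hex <- c(.hexamers(r1), .hexamers(r2))
        fresh <- setdiff(hex, allowed)
        clash <- anyDuplicated(hex) ||
          any(vapply(fresh, function(h)
            exists(h, envir = motif_env, inherits = FALSE), logical(1L)))
        if (!clash) break
      }
      for (h in hex) motif_env[[h]] <- TRUE
      motifs[[sf]] <- hex
      blocks[[sf]] <- list(r1 = r1, r2 = r2)
      fam_of[sf] <- fam
    }
  }
  region_pos <- c(r1s:(r1s + m1 + 4L), r2s:(r2s + m2 + 4L))
  allowed_starts <- c(r1s:(r1s + m1 - 1L), r2s:(r2s + m2 - 1L))
  proteins <- character(0)
  truth <- list()
  for (sf in names(motifs)) {
    b <- blocks[[sf]]
    for (j in seq_len(spec$proteins_per_subfamily)) {
      len <- sample(spec$protein_len[1L]:spec$protein_len[2L], 1L)
      chars <- sample(AA_ALPHABET, len, replace = TRUE)
      chars[r1s:(r1s + m1 + 4L)] <- strsplit(b$r1, "")[[1L]]
      chars[r2s:(r2s + m2 + 4L)] <- strsplit(b$r2, "")[[1L]]
      if (spec$mutation_rate > 0) {
        hit <- which(stats::runif(len) < spec$mutation_rate)
        for (p in hit) chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
      }
      chars <- .scrub_background(chars, motif_env, allowed_starts, region_pos)
      id <- sprintf("%s_p%02d", sf, j)
      proteins[id] <- paste(chars, collapse = "")
      truth[[id]] <- data.frame(protein_id = id, family = fam_of[sf],
                                subfamily = sf, stringsAsFactors = FALSE)
    }
  }
  positions <- lapply(motifs, function(hex) {
    structure(c(seq.int(r1s, length.out = m1),
                seq.int(r2s, length.out = m2)),
              names = hex)
  })
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(proteins = proteins,
                 truth = truth,
                 motifs = motifs,
                 motif_positions = positions,
                 spec = spec),
            class = "synthetic_pool")
}

#' @export
print.synthetic_pool <- function(x, ...) {
  cat(sprintf("<synthetic_pool> %d proteins, %d subfamilies, %d families\n",
              length(x$proteins), length(x$motifs),
              length(unique(x$truth$family))))
  invisible(x)
}

# uniform synonymous reverse translation (no codon-bias model: downstream
# matching operates on translated peptides, so bias is irrelevant here)
.reverse_translate <- function(aa_seq) {
  codons <- split(names(Biostrings::GENETIC_CODE),
                  unname(Biostrings::GENETIC_CODE))
  res <- strsplit(aa_seq, "")[[1L]]
  if (any(!res %in% names(codons)) || any(res == "*"))
    stop("cannot reverse-translate residues outside the standard code")
  paste(vapply(res, function(a) {
    cs <- codons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1L)), collapse = "")
}

#' Generate a synthetic genome with planted genes
#'
#' Reverse-translates each protein with uniformly drawn synonymous codons,
#' frames the coding sequence with in-frame stop codons on both sides,
#' places it on a random strand and separates the genes with random
#' intergenic sequence. Coordinates of every planted gene are recorded.
#'
#' @param proteins Named character vector of amino-acid sequences to plant,
#'   in genome order.
#' @param truth Optional `data.frame` with columns `protein_id`, `family`,
#'   `subfamily` (e.g. from [generate_family_pool()]); joined onto the gene
#'   table when given.
#' @param intergenic_len Intergenic spacing in bases: scalar or vector of
#'   length `length(proteins) + 1` (leading/trailing spacer included). The
#'   default 10000 keeps distinct same-family genes from merging under the
#'   5800-base rule even after 2000-base fragmentation.
#' @param genome_id Genome id.
#' @param seed Optional integer seed.
#' @return List: `genome` (named character scalar) and `genes`
#'   (`data.frame` with `protein_id`, `start`, `end` (1-based inclusive
#'   coding-sequence coordinates on the forward strand), `strand`, plus
#'   family/subfamily when `truth` is given).
#' @export
generate_genome <- function(proteins, truth = NULL, intergenic_len = 10000L,
                            genome_id = "synth_genome", seed = NULL) {
  stopifnot(is.character(proteins), length(proteins) >= 1L,
            !is.null(names(proteins)))
  if (!is.null(seed)) set.seed(seed)
  n <- length(proteins)
  spacers <- rep_len(as.integer(intergenic_len), n + 1L)
  pieces <- character(0)
  pos <- 0L
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    ig <- .rand_nt(spacers[i])
    pieces <- c(pieces, ig)
    pos <- pos + spacers[i]
    cds <- .reverse_translate(proteins[[i]])
    unit <- paste0("TAA", cds, "TAA")
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-")
      unit <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(unit)))
    pieces <- c(pieces, unit)
    genes[[i]] <- data.frame(protein_id = names(proteins)[i],
                             start = pos + 4L,
                             end = pos + nchar(unit) - 3L,
                             strand = strand,
                             stringsAsFactors = FALSE)
    pos <- pos + nchar(unit)
  }
  pieces <- c(pieces, .rand_nt(spacers[n + 1L]))
  genes <- do.call(rbind, genes)
  if (!is.null(truth))
    genes <- merge(genes, truth[, c("protein_id", "family", "subfamily")],
                   by = "protein_id", sort = FALSE)
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genome <- structure(paste(pieces, collapse = ""), names = genome_id)
  list(genome = genome, genes = genes)
}

#' Write a planted-truth table as TSV
#'
#' @param truth `data.frame` (`truth` from [generate_family_pool()] or
#'   `genes` from [generate_genome()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
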