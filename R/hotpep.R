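#' Genome-annotation parameters
#'
#' Thresholds and geometry for mining a genome with subfamily peptide lists.
#' Defaults are the canonical profile: a hit is significant when it contains
#' at least 3 list peptides, its frequency score exceeds 1.0 (strictly) and
#' the matched peptides cover at least 10 residues; fragments are 2000 bases
#' with 100 bases overlap; same-family hits closer than 5800 bases are
#' merged into one gene call (fungal mode); bacterial mode scores open
#' reading frames longer than 50 residues as independent hits.
#'
#' @param min_peptides Minimum distinct matched peptides.
#' @param min_score Frequency-score threshold; the comparison is strict
#'   (`score > min_score`).
#' @param min_covered_aa Minimum residues covered by matched peptides.
#' @param merge_distance Same-family hits whose fragment start positions
#'   differ by less than this many bases are counted as one gene.
#' @param window,overlap Fragmentation geometry (fungal mode), in bases.
#' @param min_orf_len Exclusive minimum ORF length in residues (bacterial
#'   mode).
#' @param mode `"fungal"` (fragment, merge) or `"bacterial"` (ORFs,
#'   independent hits).
#' @return A list of class `hotpep_config`.
#' @export
hotpep_config <- function(min_peptides = 3L, min_score = 1.0,
                          min_covered_aa = 10L, merge_distance = 5800L,
                          window = 2000L, overlap = 100L, min_orf_len = 50L,
                          mode = c("fungal", "bacterial")) {
  mode <- match.arg(mode)
  cfg <- list(min_peptides = as.integer(min_peptides),
              min_score = as.numeric(min_score),
              min_covered_aa = as.integer(min_covered_aa),
              merge_distance = as.integer(merge_distance),
              window = as.integer(window),
              overlap = as.integer(overlap),
              min_orf_len = as.integer(min_orf_len),
              mode = mode)
  num <- cfg[c("min_peptides", "min_score", "min_covered_aa",
               "merge_distance", "window", "min_orf_len")]
  if (any(vapply(num, function(x) x <= 0, logical(1L))))
    stop("all thresholds must be positive")
  if (cfg$overlap < 0L || cfg$overlap >= cfg$window)
    stop("overlap must be non-negative and smaller than window")
  structure(cfg, class = "hotpep_config")
}

#' Score a translated reading frame against a peptide group
#'
#' Identical contract to [score_protein()], applied to a translated frame:
#' all list peptides present in the frame are found, their within-group
#' frequencies summed, and the residues covered by the union of their
#' occurrences counted. Peptides contain only canonical residues, so matches
#' never cross a stop (`*`) or ambiguity (`X`). Three maximally overlapping
#' hexapeptides (consecutive starts) cover 8 residues; three non-overlapping
#' ones cover 18.
#'
#' @param aa_seq Character scalar translated sequence (may contain `*`/`X`).
#' @param group A [peptide_group()].
#' @return List with `n_peptides`, `frequency_score`, `covered_aa`.
#' @export
score_frame <- function(aa_seq, group) {
  stopifnot(inherits(group, "peptide_group"),
            is.character(aa_seq), length(aa_seq) == 1L)
  k <- .group_k(list(group))
  .score_index(enumerate_peptides(aa_seq, k), group, k)
}

#' Test the three significance conditions of a hit
#'
#' A hit is significant iff it includes at least `min_peptides` conserved
#' peptides, its frequency score is strictly higher than `min_score` and the
#' matched peptides cover at least `min_covered_aa` residues. All three
#' conditions must hold. Vectorized over the rows of `hit`.
#'
#' @param hit List or `data.frame` with fields `n_peptides`,
#'   `frequency_score` and `covered_aa`.
#' @param config A [hotpep_config()].
#' @return Logical vector.
#' @export
is_significant <- function(hit, config = hotpep_config()) {
  hit$n_peptides >= config$min_peptides &
    hit$frequency_score > config$min_score &
    hit$covered_aa >= config$min_covered_aa
}

.empty_hits <- function() {
  data.frame(genome_id = character(0), start = integer(0), end = integer(0),
             frame = integer(0), group_id = character(0),
             family = character(0), n_peptides = integer(0),
             frequency_score = numeric(0), covered_aa = integer(0),
             stringsAsFactors = FALSE)
}

.empty_calls <- function() {
  data.frame(genome_id = character(0), family = character(0),
             group_id = character(0), start = integer(0), end = integer(0),
             frequency_score = numeric(0), n_fragments = integer(0),
             stringsAsFactors = FALSE)
}

#' Assign a genome fragment to its best-matching subfamily
#'
#' Translates the fragment in all six reading frames, scores every frame
#' against every peptide group, discards hits failing [is_significant()] and
#' returns the single best remaining hit (highest frequency score; ties by
#' matched-peptide count, then group id). A fragment therefore contributes
#' at most one hit.
#'
#' @param seq Character scalar nucleotide sequence of the fragment.
#' @param groups List of [peptide_group()] objects.
#' @param config A [hotpep_config()].
#' @return One-row `data.frame` (`frame`, `group_id`, `family`,
#'   `n_peptides`, `frequency_score`, `covered_aa`) or `NULL` when no hit is
#'   significant.
#' @export
assign_fragment <- function(seq, groups, config = hotpep_config()) {
  stopifnot(length(groups) >= 1L)
  fr <- six_frame_translate(seq)
  .assign_frames(fr$aa_seq, fr$frame, groups, config)
}

# best significant (frame x group) hit over a set of translated frames
.assign_frames <- function(aa_vec, frame_ids, groups, config) {
  k <- .group_k(groups)
  best <- NULL
  for (i in seq_along(aa_vec)) {
    aa <- aa_vec[i]
    if (nchar(aa) < k) next
    idx <- enumerate_peptides(aa, k)
    if (!length(idx)) next
    for (g in groups) {
      sc <- .score_index(idx, g, k)
      if (sc$n_peptides >= config$min_peptides &&
          sc$frequency_score > config$min_score &&
          sc$covered_aa >= config$min_covered_aa) {
        cand <- c(sc, list(group_id = g$id, family = g$family,
                           frame = frame_ids[i]))
        if (is.null(best) || .better_hit(cand, best)) best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  data.frame(frame = best$frame, group_id = best$group_id,
             family = best$family, n_peptides = best$n_peptides,
             frequency_score = best$frequency_score,
             covered_aa = best$covered_aa, stringsAsFactors = FALSE)
}

# slice one fragment's six frame translations out of precomputed genome-level
# translations; codon-aligned, so the result equals translating the fragment
.fragment_frames <- function(aa_fwd, aa_rev, s, e, L) {
  flen <- e - s + 1L
  aa_vec <- character(6L)
  for (o in 0:2) {
    ncod <- (flen - o) %/% 3L
    if (ncod < 1L) next
    go <- (s - 1L + o) %% 3L
    astart <- (s - 1L + o) %/% 3L + 1L
    aa_vec[o + 1L] <- substr(aa_fwd[go + 1L], astart, astart + ncod - 1L)
    gro <- (L - e + o) %% 3L
    rstart <- (L - e + o) %/% 3L + 1L
    aa_vec[o + 4L] <- substr(aa_rev[gro + 1L], rstart, rstart + ncod - 1L)
  }
  aa_vec
}

#' Merge fragment hits into gene calls
#'
#' Single-linkage chaining per genome and family: consecutive same-family
#' hits whose fragment start positions differ by less than `merge_distance`
#' bases are counted as one gene. Hits from different families never merge;
#' strand and frame are ignored. Each call reports the span of its
#' contributing fragments and takes its subfamily and score from the
#' highest-scoring contributing hit.
#'
#' @param hits `data.frame` of fragment hits with columns `genome_id`,
#'   `start`, `end`, `group_id`, `family`, `n_peptides`, `frequency_score`
#'   (as produced inside [annotate_genome()]).
#' @param config A [hotpep_config()].
#' @return Gene-call `data.frame` with columns `genome_id`, `family`,
#'   `group_id`, `start`, `end`, `frequency_score`, `n_fragments`.
#' @export
merge_hits <- function(hits, config = hotpep_config()) {
  if (is.null(hits) || nrow(hits) == 0L) return(.empty_calls())
  need <- c("genome_id", "start", "end", "group_id", "family",
            "n_peptides", "frequency_score")
  if (!all(need %in% names(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (gid in unique(hits$genome_id)) {
    for (fam in sort(unique(hits$family[hits$genome_id == gid]))) {
      h <- hits[hits$genome_id == gid & hits$family == fam, , drop = FALSE]
      h <- h[order(h$start, h$group_id), , drop = FALSE]
      chain <- cumsum(c(1L, as.integer(diff(h$start) >= config$merge_distance)))
      for (cl in unique(chain)) {
        hh <- h[chain == cl, , drop = FALSE]
        top <- hh[order(-hh$frequency_score, -hh$n_peptides, hh$group_id),
                  , drop = FALSE][1L, ]
        out[[length(out) + 1L]] <- data.frame(
          genome_id = gid, family = fam, group_id = top$group_id,
          start = min(hh$start), end = max(hh$end),
          frequency_score = top$frequency_score, n_fragments = nrow(hh),
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$genome_id, calls$start, calls$family), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Annotate a genome with subfamily peptide lists
#'
#' Fungal mode splits the genome into overlapping fragments, translates each
#' in six frames, assigns every fragment to its best significant subfamily
#' hit ([assign_fragment()]) and merges nearby same-family hits into gene
#' calls ([merge_hits()]). Bacterial mode translates the whole genome,
#' extracts open reading frames longer than `min_orf_len` residues and
#' scores each ORF independently; no merging is performed and coordinates
#' are the ORF's own.
#'
#' @param genome Character scalar (optionally named) nucleotide sequence.
#' @param groups List of [peptide_group()] objects.
#' @param config A [hotpep_config()]; its `mode` selects the procedure.
#' @return Gene-call `data.frame` (see [merge_hits()]); zero rows when
#'   nothing is significant.
#' @export
annotate_genome <- function(genome, groups, config = hotpep_config()) {
  stopifnot(is.character(genome), length(genome) == 1L, length(groups) >= 1L)
  gid <- names(genome) %||% "genome"
  seq <- toupper(unname(genome))
  if (nchar(seq) < 3L) stop("genome shorter than one codon")
  if (config$mode == "fungal") {
    frags <- fragment_genome(seq, config$window, config$overlap,
                             genome_id = gid)
    gen_fr <- six_frame_translate(seq)
    aa_fwd <- gen_fr$aa_seq[1:3]
    aa_rev <- gen_fr$aa_seq[4:6]
    L <- nchar(seq)
    frame_ids <- gen_fr$frame
    hits <- vector("list", nrow(frags))
    for (i in seq_len(nrow(frags))) {
      aa_vec <- .fragment_frames(aa_fwd, aa_rev, frags$start[i],
                                 frags$end[i], L)
      best <- .assign_frames(aa_vec, frame_ids, groups, config)
      if (!is.null(best))
        hits[[i]] <- cbind(data.frame(genome_id = gid,
                                      start = frags$start[i],
                                      end = frags$end[i],
                                      stringsAsFactors = FALSE),
                           best)
    }
    hits <- hits[!vapply(hits, is.null, logical(1L))]
    if (!length(hits)) return(.empty_calls())
    merge_hits(do.call(rbind, hits), config)
  } else {
    fr <- six_frame_translate(seq)
    orfs <- extract_orfs(fr, config$min_orf_len)
    k <- .group_k(groups)
    out <- list()
    for (i in seq_len(nrow(orfs))) {
      idx <- enumerate_peptides(orfs$aa_seq[i], k)
      best <- NULL
      for (g in groups) {
        sc <- .score_index(idx, g, k)
        if (sc$n_peptides >= config$min_peptides &&
            sc$frequency_score > config$min_score &&
            sc$covered_aa >= config$min_covered_aa) {
          cand <- c(sc, list(group_id = g$id, family = g$family))
          if (is.null(best) || .better_hit(cand, best)) best <- cand
        }
      }
      if (!is.null(best))
        out[[length(out) + 1L]] <- data.frame(
          genome_id = gid, family = best$family, group_id = best$group_id,
          start = orfs$start[i], end = orfs$end[i],
          frequency_score = best$frequency_score, n_fragments = 1L,
          stringsAsFactors = FALSE)
    }
    if (!length(out)) return(.empty_calls())
    calls <- do.call(rbind, out)
    calls <- calls[order(calls$genome_id, calls$start, calls$family), ,
                   drop = FALSE]
    rownames(calls) <- NULL
    calls
  }
}
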