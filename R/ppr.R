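#' PPR grouping parameters
#'
#' Parameters for dividing a protein pool into subfamilies of shared
#' conserved peptides. Defaults are the canonical profile: hexapeptides, 10
#' peptides required per member protein, 70 peptides retained per group, and
#' a 51-residue minimum protein length.
#'
#' @param peptide_len Conserved peptide length in residues.
#' @param peptides_per_protein Minimum number of group-list peptides a
#'   protein must contain to be a group member.
#' @param peptides_per_group Maximum number of peptides retained per group,
#'   ranked by within-group presence frequency.
#' @param min_protein_len Proteins shorter than this are excluded from
#'   training (and reported).
#' @param min_group_size Minimum number of member proteins for a group to be
#'   emitted.
#' @param max_iterations Cap on membership/list refinement rounds per group.
#' @return A list of class `ppr_config`.
#' @export
ppr_config <- function(peptide_len = 6L, peptides_per_protein = 10L,
                       peptides_per_group = 70L, min_protein_len = 51L,
                       min_group_size = 2L, max_iterations = 100L) {
  cfg <- list(peptide_len = as.integer(peptide_len),
              peptides_per_protein = as.integer(peptides_per_protein),
              peptides_per_group = as.integer(peptides_per_group),
              min_protein_len = as.integer(min_protein_len),
              min_group_size = as.integer(min_group_size),
              max_iterations = as.integer(max_iterations))
  if (any(vapply(cfg, function(x) x < 1L, logical(1L))))
    stop("all PPR parameters must be positive")
  if (cfg$peptides_per_protein > cfg$peptides_per_group)
    stop("peptides_per_protein cannot exceed peptides_per_group")
  structure(cfg, class = "ppr_config")
}

#' Construct a peptide group (subfamily)
#'
#' A subfamily is a peptide list with within-group presence frequencies plus
#' the ids of its member proteins. Frequencies are the fraction of members
#' containing each peptide and must lie in (0, 1].
#'
#' @param id Group id, e.g. `"AA9_03"`.
#' @param family Family label, e.g. `"AA9"`.
#' @param peptides Named numeric vector: names are peptides (equal length,
#'   canonical residues only), values are presence frequencies in (0, 1].
#' @param members Character vector of member protein ids.
#' @return An object of class `peptide_group`.
#' @export
peptide_group <- function(id, family, peptides, members = character(0)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(family), length(family) == 1L,
            is.numeric(peptides))
  peps <- names(peptides)
  if (length(peptides)) {
    if (is.null(peps) || any(!nzchar(peps)))
      stop("peptides must be a named numeric vector")
    if (length(unique(nchar(peps))) != 1L)
      stop("all peptides in a group must have the same length")
    if (any(grepl(.AA_INVALID, peps)))
      stop("peptides must use only the 20 canonical residues")
    if (anyDuplicated(peps))
      stop("duplicate peptides in group ", id)
    if (any(peptides <= 0 | peptides > 1))
      stop("peptide frequencies must lie in (0, 1]")
  }
  structure(list(id = id, family = family,
                 peptides = peptides, members = as.character(members)),
            class = "peptide_group")
}

#' @export
print.peptide_group <- function(x, ...) {
  cat(sprintf("<peptide_group> %s (family %s): %d peptides, %d members\n",
              x$id, x$family, length(x$peptides), length(x$members)))
  invisible(x)
}

#' Enumerate the peptides of a sequence
#'
#' Slides a window of `k` residues along the sequence and returns each
#' distinct peptide together with all its 1-based start positions. Windows
#' containing any non-canonical character (`X`, `*`, ...) are dropped, so
#' ambiguity never creates a match.
#'
#' @param seq Character scalar amino-acid sequence.
#' @param k Peptide length.
#' @return Named list mapping each peptide to an integer vector of start
#'   positions (empty list if the sequence is shorter than `k`).
#' @examples
#' enumerate_peptides("AAAAAAA")  # one peptide, two positions
#' @export
enumerate_peptides <- function(seq, k = 6L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(unname(seq))
  n <- nchar(seq)
  k <- as.integer(k)
  if (n < k) return(structure(list(), names = character(0)))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl(.AA_INVALID, kmers)
  split(starts[ok], kmers[ok])
}

# presence counts of peptides over a list of per-protein peptide-name vectors
.presence_counts <- function(ksets) {
  v <- unlist(ksets, use.names = FALSE)
  if (!length(v)) return(integer(0))
  tab <- table(v)
  structure(as.integer(tab), names = names(tab))
}

# top-n peptides by presence count (descending), ties lexicographic
.top_peptides <- function(ksets, n_top) {
  cnt <- .presence_counts(ksets)
  if (!length(cnt)) return(character(0))
  ord <- order(-cnt, names(cnt), method = "radix")
  utils::head(names(cnt)[ord], n_top)
}

# peptide length used by a list of groups (6 if none carries peptides)
.group_k <- function(groups) {
  for (g in groups) if (length(g$peptides)) return(nchar(names(g$peptides)[1L]))
  6L
}

# score a pre-built peptide index (enumerate_peptides output) against a group
.score_index <- function(idx, group, k) {
  matched <- intersect(names(idx), names(group$peptides))
  if (!length(matched))
    return(list(n_peptides = 0L, frequency_score = 0, covered_aa = 0L))
  starts <- unlist(idx[matched], use.names = FALSE)
  covered <- unique(rep(starts, each = k) + 0:(k - 1L))
  list(n_peptides = length(matched),
       frequency_score = unname(sum(group$peptides[matched])),
       covered_aa = length(covered))
}

#' Score a protein against a peptide group
#'
#' Counts the distinct group peptides present in the protein, sums their
#' within-group frequencies (the frequency score) and measures how many
#' residues are covered by the union of all occurrences of all matched
#' peptides.
#'
#' @param protein Character scalar amino-acid sequence.
#' @param group A [peptide_group()].
#' @return List with `n_peptides`, `frequency_score` and `covered_aa`.
#' @export
score_protein <- function(protein, group) {
  stopifnot(inherits(group, "peptide_group"))
  seq <- toupper(unname(if (is.list(protein)) protein$seq else protein))
  k <- .group_k(list(group))
  .score_index(enumerate_peptides(seq, k), group, k)
}

# TRUE when a is a better hit than b (score desc, n desc, group id asc)
.better_hit <- function(a, b) {
  if (a$frequency_score != b$frequency_score)
    return(a$frequency_score > b$frequency_score)
  if (a$n_peptides != b$n_peptides) return(a$n_peptides > b$n_peptides)
  a$group_id < b$group_id
}

#' Build subfamilies of a protein pool by conserved peptides
#'
#' Greedy, fully deterministic grouping. Proteins shorter than
#' `min_protein_len` are set aside; duplicate sequences train once and are
#' re-attached to their representative's group afterwards. Groups are carved
#' out one at a time:
#'
#' 1. Over the unassigned proteins, find the peptide contained in the most
#'    proteins (presence, not occurrences; ties broken lexicographically).
#' 2. Seed the group with the proteins containing that peptide and rank the
#'    top `peptides_per_group` peptides among them.
#' 3. Refine: membership = unassigned proteins containing at least
#'    `peptides_per_protein` list peptides; the list = top
#'    `peptides_per_group` peptides over the current members. Repeat until
#'    the member set is stable (or `max_iterations`).
#' 4. Emit the group if it has at least `min_group_size` members and remove
#'    its members from the pool; otherwise discard the seed peptide and try
#'    the next one. Stop when no further group can be formed.
#'
#' Stored peptide frequencies are the exact fraction of members containing
#' each peptide.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param config A [ppr_config()].
#' @param family Family label stamped on the groups; group ids are
#'   `<family>_01`, `<family>_02`, ... in order of emission.
#' @return An object of class `ppr_fit`: list with `groups` (list of
#'   [peptide_group()]), `unassigned`, `too_short`, `family` and `config`.
#' @export
build_subfamilies <- function(proteins, config = ppr_config(), family = "G") {
  stopifnot(is.character(proteins))
  if (!length(proteins))
    return(structure(list(groups = list(), unassigned = character(0),
                          too_short = character(0), family = family,
                          config = config), class = "ppr_fit"))
  ids <- names(proteins)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("proteins must be a character vector with unique non-empty names")
  too_short <- ids[nchar(proteins) < config$min_protein_len]
  pool <- setdiff(ids, too_short)
  seqs <- unname(proteins[pool])
  rep_id <- pool[match(seqs, seqs)]      # first id carrying each sequence
  reps <- pool[rep_id == pool]
  # duplicates train once but still count toward group size and membership
  dup_n <- vapply(reps, function(r) sum(rep_id == r), integer(1L))
  ksets <- lapply(proteins[reps],
                  function(s) names(enumerate_peptides(s, config$peptide_len)))
  unassigned <- reps
  groups <- list()
  blacklist <- character(0)
  gi <- 0L
  while (sum(dup_n[unassigned]) >= config$min_group_size) {
    cnt <- .presence_counts(ksets[unassigned])
    if (!length(cnt)) break
    ord <- order(-cnt, names(cnt), method = "radix")
    cand <- names(cnt)[ord]
    # a seed peptide carried by fewer proteins (duplicates included) than the
    # group-size floor can never found a group
    v <- unlist(ksets[unassigned], use.names = FALSE)
    w <- rep(dup_n[unassigned], lengths(ksets[unassigned]))
    wcnt <- vapply(split(w, v), sum, numeric(1L))
    cand <- cand[wcnt[cand] >= config$min_group_size]
    cand <- setdiff(cand, blacklist)
    if (!length(cand)) break
    seed_pep <- cand[[1L]]
    members <- unassigned[vapply(ksets[unassigned],
                                 function(ks) seed_pep %in% ks, logical(1L))]
    plist <- character(0)
    for (iter in seq_len(config$max_iterations)) {
      plist <- .top_peptides(ksets[members], config$peptides_per_group)
      nxt <- unassigned[vapply(ksets[unassigned], function(ks)
        sum(ks %in% plist) >= config$peptides_per_protein, logical(1L))]
      if (setequal(nxt, members)) { members <- nxt; break }
      members <- nxt
      if (!length(members)) break
    }
    if (length(members)) {
      # guard for non-converged exits: keep membership consistent with the
      # final list so every member contains >= peptides_per_protein of it
      plist <- .top_peptides(ksets[members], config$peptides_per_group)
      members <- members[vapply(ksets[members], function(ks)
        sum(ks %in% plist) >= config$peptides_per_protein, logical(1L))]
    }
    members_full <- pool[rep_id %in% members]
    if (length(members_full) < config$min_group_size) {
      blacklist <- c(blacklist, seed_pep)
      next
    }
    # frequency = fraction of members (duplicates included) with the peptide
    freq <- vapply(plist, function(p)
      sum(dup_n[members][vapply(ksets[members], function(ks) p %in% ks,
                                logical(1L))]) / length(members_full),
      numeric(1L))
    gi <- gi + 1L
    gid <- sprintf("%s_%02d", family, gi)
    groups[[gi]] <- peptide_group(gid, family, freq, sort(members_full))
    unassigned <- setdiff(unassigned, members)
  }
  assigned <- unlist(lapply(groups, `[[`, "members"), use.names = FALSE)
  structure(list(groups = groups,
                 unassigned = setdiff(ids, c(assigned, too_short)),
                 too_short = too_short,
                 family = family,
                 config = config),
            class = "ppr_fit")
}

#' @export
print.ppr_fit <- function(x, ...) {
  cat(sprintf("<ppr_fit> family %s: %d group(s), %d unassigned, %d too short\n",
              x$family, length(x$groups), length(x$unassigned),
              length(x$too_short)))
  for (g in x$groups) print(g)
  invisible(x)
}

#' Classify proteins against subfamily peptide lists
#'
#' Scores every protein against every group, keeps groups passing the three
#' significance conditions (at least `min_peptides` matched peptides, a
#' frequency score strictly above `min_score`, at least `min_covered_aa`
#' covered residues) and assigns the protein to the significant group with
#' the highest frequency score. Ties are broken by the number of matched
#' peptides, then by group id. Proteins with no significant group get
#' `NA` group and family.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param groups List of [peptide_group()] objects.
#' @param config A [hotpep_config()] supplying the significance thresholds.
#' @return `data.frame` with one row per protein: `protein_id`, `group_id`,
#'   `family`, `n_peptides`, `frequency_score`, `covered_aa`.
#' @export
classify_proteins <- function(proteins, groups, config = hotpep_config()) {
  stopifnot(is.character(proteins), !is.null(names(proteins)),
            length(groups) >= 1L)
  k <- .group_k(groups)
  rows <- lapply(names(proteins), function(id) {
    idx <- enumerate_peptides(proteins[[id]], k)
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
    if (is.null(best))
      data.frame(protein_id = id, group_id = NA_character_,
                 family = NA_character_, n_peptides = 0L,
                 frequency_score = 0, covered_aa = 0L,
                 stringsAsFactors = FALSE)
    else
      data.frame(protein_id = id, group_id = best$group_id,
                 family = best$family, n_peptides = best$n_peptides,
                 frequency_score = best$frequency_score,
                 covered_aa = best$covered_aa, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' @rdname classify_proteins
#' @param protein A single amino-acid sequence (optionally named).
#' @export
classify_protein <- function(protein, groups, config = hotpep_config()) {
  nm <- names(protein) %||% "protein"
  classify_proteins(structure(unname(protein), names = nm), groups, config)
}

#' Evaluate family-level annotation against known labels
#'
#' Classifies labelled proteins against a set of subfamily peptide lists and
#' tabulates, per true family, the percentage of proteins annotated to each
#' predicted family (or left unassigned). The diagonal of the percentage
#' matrix is the correct-annotation rate.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param labels Named character vector mapping every protein id to its true
#'   family.
#' @param groups List of [peptide_group()] objects (their `family` fields are
#'   the predicted family labels).
#' @param config A [hotpep_config()] supplying significance thresholds.
#' @return An object of class `annotation_evaluation`: list with `percent`
#'   (true family x predicted family matrix, rows summing to 100), `counts`
#'   and the per-protein `calls`.
#' @export
evaluate_annotation <- function(proteins, labels, groups,
                                config = hotpep_config()) {
  stopifnot(is.character(labels), !is.null(names(labels)))
  if (!all(names(proteins) %in% names(labels)))
    stop("labels must cover every protein")
  calls <- classify_proteins(proteins, groups, config)
  truth <- unname(labels[calls$protein_id])
  pred <- ifelse(is.na(calls$family), "unassigned", calls$family)
  fam_levels <- sort(unique(truth))
  pred_levels <- c(sort(unique(c(fam_levels,
                                 vapply(groups, `[[`, "", "family")))),
                   "unassigned")
  counts <- table(true = factor(truth, fam_levels),
                  predicted = factor(pred, pred_levels))
  percent <- 100 * prop.table(counts, 1L)
  structure(list(percent = unclass(as.matrix(percent)),
                 counts = unclass(as.matrix(counts)),
                 calls = calls),
            class = "annotation_evaluation")
}

#' @export
print.annotation_evaluation <- function(x, digits = 1L, ...) {
  cat("<annotation_evaluation> percent of proteins per true family (rows)\n")
  print(round(x$percent, digits))
  invisible(x)
}
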