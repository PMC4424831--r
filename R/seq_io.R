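#' Read sequences from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into a named
#' character vector. Sequence ids are the first whitespace-delimited token of
#' each header and must be unique. Sequences are upper-cased; nucleotide
#' records are validated against the A/C/G/T/N alphabet, protein records
#' against the 20 canonical residues plus 'X'.
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` or `"nucleotide"`; controls alphabet validation.
#' @return Named character vector of sequences (names = record ids), in file
#'   order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKV"), f)
#' read_fasta(f, "protein")
#' @export
read_fasta <- function(path, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(trimws(ids))))
    stop("FASTA record with empty header in ", path)
  ids <- sub("\\s.*$", "", ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s) in ", path, ": ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty))
    stop("empty sequence for record(s): ", paste(empty, collapse = ", "))
  if (type == "nucleotide") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
      stop("non-A/C/G/T/N characters in nucleotide record(s): ",
           paste(ids[bad], collapse = ", "))
  } else {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
    if (any(bad))
      stop("non-amino-acid characters in protein record(s): ",
           paste(ids[bad], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param line_width Residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    s <- seqs[[id]]
    n <- nchar(s)
    starts <- seq.int(1L, n, by = line_width)
    writeLines(c(paste0(">", id), substring(s, starts, pmin(starts + line_width - 1L, n))), con)
  }
  invisible(path)
}

#' Split a genome into overlapping fragments
#'
#' Cuts a genome sequence into windows of `window` bases advancing by
#' `window - overlap`, the unit at which translated peptide matching and
#' fragment merging operate. Every genome position is covered by at least one
#' fragment; the last fragment may be shorter; a trailing window that would
#' add no new positions is not emitted, so a genome of exactly `window` bases
#' yields a single fragment.
#'
#' @param genome Character scalar (optionally named) nucleotide sequence.
#' @param window Fragment size in bases (default 2000).
#' @param overlap Overlap between consecutive fragments in bases (default 100).
#' @param genome_id Id used in the output; defaults to `names(genome)`.
#' @return `data.frame` with columns `genome_id`, `start`, `end` (1-based,
#'   inclusive) and `seq`.
#' @export
fragment_genome <- function(genome, window = 2000L, overlap = 100L,
                            genome_id = NULL) {
  stopifnot(is.character(genome), length(genome) == 1L)
  if (is.null(genome_id)) genome_id <- names(genome) %||% "genome"
  seq <- toupper(unname(genome))
  len <- nchar(seq)
  if (len < 1L) stop("empty genome sequence")
  window <- as.integer(window); overlap <- as.integer(overlap)
  if (!(window > overlap && overlap >= 0L))
    stop("window must be larger than overlap, and overlap non-negative")
  step <- window - overlap
  starts0 <- seq.int(0L, max(0L, len - 1L), by = step)
  # a window whose fresh (non-overlap) part starts at or beyond the end adds
  # nothing: the previous fragment already reaches the genome end
  starts0 <- starts0[starts0 == 0L | starts0 + overlap < len]
  ends <- pmin(starts0 + window, len)
  data.frame(genome_id = genome_id,
             start = starts0 + 1L,
             end = ends,
             seq = substring(seq, starts0 + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1/+2/+3 translate the sequence at offsets 0/1/2; frames -1/-2/-3
#' translate the reverse complement at offsets 0/1/2. The standard genetic
#' code is used; stop codons are emitted as `*` and any codon containing `N`
#' as `X`. Trailing partial codons are dropped, so each frame has
#' `floor((length - offset) / 3)` residues.
#'
#' @param nt_seq Character scalar over A/C/G/T/N (case-insensitive), length
#'   at least 3.
#' @return `data.frame` with columns `frame` (+1..+3, -1..-3), `offset`,
#'   `strand` and `aa_seq`; the source length is kept in attribute `nt_len`
#'   for coordinate mapping.
#' @examples
#' six_frame_translate("ATGGCCTAA")$aa_seq[1]  # "MA*"
#' @export
six_frame_translate <- function(nt_seq) {
  stopifnot(is.character(nt_seq), length(nt_seq) == 1L)
  nt <- toupper(unname(nt_seq))
  if (grepl("[^ACGTN]", nt))
    stop("nucleotide sequence contains characters outside A/C/G/T/N")
  len <- nchar(nt)
  if (len < 3L) stop("sequence shorter than one codon")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  frames <- data.frame(frame = c(1L, 2L, 3L, -1L, -2L, -3L),
                       offset = rep(0:2, 2L),
                       strand = rep(c("+", "-"), each = 3L),
                       stringsAsFactors = FALSE)
  subs <- vapply(seq_len(6L), function(i) {
    src <- if (frames$strand[i] == "+") nt else rc
    o <- frames$offset[i]
    n_codon <- (len - o) %/% 3L
    if (n_codon < 1L) return("")
    substr(src, o + 1L, o + 3L * n_codon)
  }, character(1L))
  nonempty <- nzchar(subs)
  aa <- character(6L)
  if (any(nonempty))
    aa[nonempty] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(subs[nonempty]), if.fuzzy.codon = "X"))
  frames$aa_seq <- aa
  attr(frames, "nt_len") <- len
  frames
}

#' Extract open reading frames from six-frame translations
#'
#' An ORF is a maximal stop-free run of residues within one reading frame,
#' bounded by `*` or the sequence ends; no start codon is required. Only runs
#' strictly longer than `min_len` residues are returned (at the default 50,
#' a 51-residue run is kept and a 50-residue run is not).
#'
#' @param frames Output of [six_frame_translate()] (the `nt_len` attribute is
#'   required to map ORFs back to genome coordinates).
#' @param min_len Minimum exclusive ORF length in residues.
#' @return `data.frame` with columns `frame`, `strand`, `aa_start` (1-based
#'   within the frame), `aa_seq`, and `start`/`end` (1-based inclusive
#'   nucleotide coordinates on the forward strand).
#' @export
extract_orfs <- function(frames, min_len = 50L) {
  nt_len <- attr(frames, "nt_len")
  if (is.null(nt_len)) stop("frames must carry an 'nt_len' attribute ",
                            "(use six_frame_translate())")
  min_len <- as.integer(min_len)
  out <- vector("list", nrow(frames))
  for (i in seq_len(nrow(frames))) {
    aa <- frames$aa_seq[i]
    if (!nzchar(aa)) next
    m <- gregexpr("[^*]+", aa)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    keep <- lens > min_len
    if (!any(keep)) next
    starts <- starts[keep]; lens <- lens[keep]
    o <- frames$offset[i]
    p1 <- o + 3L * (starts - 1L) + 1L
    p2 <- o + 3L * (starts + lens - 1L)
    if (frames$strand[i] == "+") {
      gstart <- p1; gend <- p2
    } else {
      gstart <- nt_len - p2 + 1L; gend <- nt_len - p1 + 1L
    }
    out[[i]] <- data.frame(frame = frames$frame[i],
                           strand = frames$strand[i],
                           aa_start = starts,
                           aa_seq = substring(aa, starts, starts + lens - 1L),
                           start = gstart,
                           end = gend,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out))
    return(data.frame(frame = integer(0), strand = character(0),
                      aa_start = integer(0), aa_seq = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
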