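#' Median position of a peptide across proteins
#'
#' For every protein containing the peptide, takes the 1-based start of its
#' first occurrence; returns the median of those starts over proteins. The
#' median (lower median for an even count) is used rather than the mean so
#' that truncated proteins and length differences do not drag the position.
#'
#' @param peptide Character scalar peptide.
#' @param proteins Character vector of amino-acid sequences.
#' @return Integer position.
#' @export
peptide_position <- function(peptide, proteins) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nzchar(peptide))
  pos <- vapply(proteins, function(s)
    as.integer(regexpr(peptide, s, fixed = TRUE)), integer(1L),
    USE.NAMES = FALSE)
  pos <- pos[pos > 0L]
  if (!length(pos))
    stop("peptide not found in any protein: ", peptide)
  sort(pos)[(length(pos) + 1L) %/% 2L]
}

#' Positional profile of a group's conserved peptides
#'
#' Bins the median positions of a group's peptides among its member proteins
#' into fixed-width intervals of `bin_width` residues (1-based bins
#' `[1, 20]`, `[21, 40]`, ...). Each peptide with at least one occurrence
#' contributes one count to the bin holding its median position; peptides
#' absent from all supplied proteins contribute nothing.
#'
#' @param group A [peptide_group()].
#' @param proteins Named character vector of sequences; restricted to the
#'   group's `members` when that field is non-empty.
#' @param bin_width Bin width in residues.
#' @return `data.frame` of class `position_profile` with columns `group_id`,
#'   `bin_start`, `bin_end`, `count` (only non-empty bins, ordered); the bin
#'   width is kept as attribute `bin_width`.
#' @export
position_profile <- function(group, proteins, bin_width = 20L) {
  stopifnot(inherits(group, "peptide_group"), is.character(proteins))
  bin_width <- as.integer(bin_width)
  if (bin_width < 1L) stop("bin_width must be positive")
  prots <- proteins
  if (length(group$members) && !is.null(names(proteins))) {
    hit <- names(proteins) %in% group$members
    if (any(hit)) prots <- proteins[hit]
  }
  med <- integer(0)
  for (p in names(group$peptides)) {
    m <- tryCatch(peptide_position(p, prots), error = function(e) NA_integer_)
    if (!is.na(m)) med <- c(med, m)
  }
  if (!length(med)) {
    out <- data.frame(group_id = character(0), bin_start = integer(0),
                      bin_end = integer(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    bin0 <- (med - 1L) %/% bin_width
    tab <- table(bin0)
    bs <- as.integer(names(tab)) * bin_width + 1L
    out <- data.frame(group_id = group$id,
                      bin_start = bs,
                      bin_end = bs + bin_width - 1L,
                      count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(out$bin_start), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "bin_width") <- bin_width
  class(out) <- c("position_profile", "data.frame")
  out
}

#' Accumulated positional profile over subfamilies
#'
#' Bin-wise sum of several per-subfamily profiles (all with the same bin
#' width), giving the overall distribution of conserved peptides along the
#' protein sequences.
#'
#' @param profiles List of [position_profile()] outputs.
#' @return A `position_profile` data.frame with `group_id = "accumulated"`.
#' @export
accumulated_profile <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  bw <- unique(vapply(profiles, function(p) attr(p, "bin_width"), integer(1L)))
  if (length(bw) != 1L)
    stop("profiles have mismatched bin widths: ", paste(bw, collapse = ", "))
  all <- do.call(rbind, lapply(profiles, function(p)
    as.data.frame(p)[, c("bin_start", "count"), drop = FALSE]))
  if (!nrow(all)) {
    out <- data.frame(group_id = character(0), bin_start = integer(0),
                      bin_end = integer(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(count ~ bin_start, data = all, FUN = sum)
    agg <- agg[order(agg$bin_start), , drop = FALSE]
    out <- data.frame(group_id = "accumulated",
                      bin_start = as.integer(agg$bin_start),
                      bin_end = as.integer(agg$bin_start) + bw - 1L,
                      count = as.integer(agg$count),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "bin_width") <- bw
  class(out) <- c("position_profile", "data.frame")
  out
}

#' Write a positional profile as TSV
#'
#' @param profile A [position_profile()] data.frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
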