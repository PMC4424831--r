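#' Write subfamily peptide lists as TSV
#'
#' One row per (group, peptide) with columns `group_id`, `family`, `peptide`,
#' `frequency`. Frequencies are printed with 17 significant digits so the
#' file round-trips losslessly through [read_peptide_lists()]. Lines
#' starting with `#` are comments.
#'
#' @param groups List of [peptide_group()] objects (or a `ppr_fit`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_lists <- function(groups, path) {
  if (inherits(groups, "ppr_fit")) groups <- groups$groups
  stopifnot(length(groups) >= 1L)
  rows <- lapply(groups, function(g) {
    if (!length(g$peptides)) return(NULL)
    data.frame(group_id = g$id, family = g$family,
               peptide = names(g$peptides),
               frequency = sprintf("%.17g", unname(g$peptides)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# subfamily peptide lists: group_id, family, peptide, frequency",
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read subfamily peptide lists from TSV
#'
#' @param path Path to a file written by [write_peptide_lists()].
#' @return List of [peptide_group()] objects in file order (member sets are
#'   not stored in the file and come back empty).
#' @export
read_peptide_lists <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(group_id = "character",
                                         family = "character",
                                         peptide = "character",
                                         frequency = "numeric"))
  if (!all(c("group_id", "family", "peptide", "frequency") %in% names(df)))
    stop("peptide-list file must have columns group_id, family, peptide, ",
         "frequency: ", path)
  parts <- split(df, factor(df$group_id, levels = unique(df$group_id)))
  lapply(parts, function(p)
    peptide_group(p$group_id[1L], p$family[1L],
                  structure(p$frequency, names = p$peptide)))
}

#' Write group membership as TSV
#'
#' @param fit A `ppr_fit` from [build_subfamilies()].
#' @param path Output path.
#' @return `path`, invisibly. Columns `protein_id`, `group_id`; unassigned
#'   proteins carry group_id `NA`.
#' @export
write_membership <- function(fit, path) {
  stopifnot(inherits(fit, "ppr_fit"))
  rows <- lapply(fit$groups, function(g)
    data.frame(protein_id = g$members, group_id = g$id,
               stringsAsFactors = FALSE))
  if (length(fit$unassigned))
    rows <- c(rows, list(data.frame(protein_id = fit$unassigned,
                                    group_id = NA_character_,
                                    stringsAsFactors = FALSE)))
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene calls as TSV or GFF3
#'
#' The TSV has columns `genome_id`, `family`, `group_id`, `start`, `end`
#' (1-based inclusive), `frequency_score` (6 decimals) and `n_fragments`.
#' The GFF3 variant emits `gene` features with source `hotpep` and the
#' family/subfamily in the attributes column.
#'
#' @param calls Gene-call `data.frame` from [annotate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_calls <- function(calls, path) {
  out <- calls
  out$frequency_score <- sprintf("%.6f", out$frequency_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_calls
#' @export
write_gene_calls_gff <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(calls)) {
    ids <- sprintf("call%04d", seq_len(nrow(calls)))
    lines <- sprintf("%s\thotpep\tgene\t%d\t%d\t%.6f\t.\t.\tID=%s;family=%s;subfamily=%s",
                     calls$genome_id, calls$start, calls$end,
                     calls$frequency_score, ids, calls$family,
                     calls$group_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene calls written by [write_gene_calls()]
#'
#' @param path File path.
#' @return Gene-call `data.frame`.
#' @export
read_gene_calls <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(genome_id = "character",
                                   family = "character",
                                   group_id = "character",
                                   start = "integer", end = "integer",
                                   frequency_score = "numeric",
                                   n_fragments = "integer"))
}
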