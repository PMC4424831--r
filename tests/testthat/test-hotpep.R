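# shared fixture: a small two-family pool with peptide lists, built once
pool <- generate_family_pool(
  synthetic_spec(2L, 2L, 8L, 40L, protein_len = c(200L, 280L), seed = 31L))
groups <- build_pool_groups(pool, ppr_config(peptides_per_group = 40L))
grp2planted <- map_groups_to_planted(groups, pool$truth)

test_that("frame scoring reproduces the overlap coverage arithmetic", {
  s <- "ACDEFGHI"
  g <- peptide_group("g", "f",
                     c(ACDEFG = 0.5, CDEFGH = 0.5, DEFGHI = 0.5))
  sc <- score_frame(s, g)
  expect_identical(sc$n_peptides, 3L)
  expect_identical(sc$covered_aa, 8L)

  s2 <- "ACDEFGWWWWHIKLMNWWWWPQRSTV"
  g2 <- peptide_group("g", "f",
                      c(ACDEFG = 0.5, HIKLMN = 0.5, PQRSTV = 0.5))
  expect_identical(score_frame(s2, g2)$covered_aa, 18L)

  expect_identical(score_frame("AAAA", g2),
                   list(n_peptides = 0L, frequency_score = 0,
                        covered_aa = 0L))
})

test_that("frame scoring on an embedded protein matches protein scoring", {
  set.seed(32)
  for (i in 1:20) {
    p <- rand_aa_str(60)
    g <- rand_group(p, n_hit = 4L, n_miss = 4L)
    framed <- paste0("*X*", p, "*X*")
    expect_identical(score_frame(framed, g), score_protein(p, g))
  }
})

test_that("significance is the strict conjunction of the three conditions", {
  mk <- function(n, s, c) list(n_peptides = n, frequency_score = s,
                               covered_aa = c)
  expect_true(is_significant(mk(3L, 1.01, 10L)))
  expect_false(is_significant(mk(3L, 1.0, 18L)))    # score must exceed 1.0
  expect_false(is_significant(mk(3L, 2.5, 8L)))     # maximal overlap: 8 < 10
  expect_false(is_significant(mk(2L, 3.0, 12L)))    # needs 3 peptides

  # vectorized over data.frame rows
  df <- data.frame(n_peptides = c(3L, 4L), frequency_score = c(1.2, 0.9),
                   covered_aa = c(12L, 30L))
  expect_identical(is_significant(df), c(TRUE, FALSE))
})

test_that("fragment assignment finds planted genes and ignores noise", {
  set.seed(33)
  gene_prot <- pool$proteins[1L]
  g <- generate_genome(gene_prot, pool$truth, intergenic_len = 400L,
                       seed = 34)
  best <- assign_fragment(substr(g$genome, 1L, 2000L), groups)
  expect_false(is.null(best))
  expect_identical(unname(grp2planted[best$group_id]),
                   pool$truth$subfamily[1L])

  expect_null(assign_fragment(rand_nt_str(2000L), groups))

  # argmax over significant hits
  hitA <- peptide_group("A_01", "A", c(ACDEFG = 1, HIKLMN = 0.6, PQRSTV = 0.4))
  hitB <- peptide_group("B_01", "B", c(ACDEFG = 0.6, HIKLMN = 0.5, PQRSTV = 0.4))
  frag <- paste(vapply(strsplit("ACDEFGWHIKLMNWPQRSTV", "")[[1L]], function(a) {
    codons <- split(names(Biostrings::GENETIC_CODE),
                    unname(Biostrings::GENETIC_CODE))
    codons[[a]][1L]
  }, character(1L)), collapse = "")
  best2 <- assign_fragment(frag, list(hitB, hitA))
  expect_identical(best2$group_id, "A_01")
})

test_that("merging chains same-family hits below the distance cutoff", {
  mk_hits <- function(starts, families, groups_, scores) {
    data.frame(genome_id = "g", start = starts, end = starts + 1999L,
               group_id = groups_, family = families,
               n_peptides = 5L, frequency_score = scores,
               covered_aa = 30L, stringsAsFactors = FALSE)
  }
  # 5700 apart: one gene
  h <- mk_hits(c(1L, 5701L), c("A", "A"), c("A_01", "A_02"), c(2, 3))
  m <- merge_hits(h)
  expect_identical(nrow(m), 1L)
  expect_identical(m$group_id, "A_02")   # taken from the top-scoring hit
  expect_identical(m$start, 1L)
  expect_identical(m$end, 7700L)
  expect_identical(m$n_fragments, 2L)

  # exactly 5800 apart: strict inequality keeps them separate
  h2 <- mk_hits(c(1L, 5801L), c("A", "A"), c("A_01", "A_02"), c(2, 3))
  expect_identical(nrow(merge_hits(h2)), 2L)

  # different families never merge, however close
  h3 <- mk_hits(c(1L, 101L), c("A", "B"), c("A_01", "B_01"), c(2, 2))
  expect_identical(nrow(merge_hits(h3)), 2L)

  # row order does not matter for a fixed output sort
  h4 <- mk_hits(c(1L, 3000L, 9500L), rep("A", 3L),
                c("A_01", "A_02", "A_01"), c(2, 3, 4))
  expect_identical(merge_hits(h4), merge_hits(h4[c(3L, 1L, 2L), ]))
  expect_identical(nrow(merge_hits(h4)), 2L)
})

test_that("fungal annotation recovers planted genes and merges split ones", {
  picks <- pool$proteins[c(1L, 9L, 17L, 25L)]   # one per subfamily
  g <- generate_genome(picks, pool$truth, intergenic_len = 10000L,
                       seed = 35)
  calls <- annotate_genome(g$genome, groups, hotpep_config())
  expect_identical(nrow(calls), 4L)
  expect_identical(unname(grp2planted[calls$group_id]), g$genes$subfamily)
  # call span contains the planted gene
  expect_true(all(calls$start <= g$genes$start & calls$end >= g$genes$end))

  # two same-family copies 3000 bases apart collapse into one call
  twin <- pool$proteins[c(1L, 2L)]
  g2 <- generate_genome(twin, pool$truth, intergenic_len = 3000L, seed = 36)
  calls2 <- annotate_genome(g2$genome, groups, hotpep_config())
  expect_identical(nrow(calls2), 1L)
  expect_identical(calls2$family, "F1")
})

test_that("bacterial mode scores ORFs independently with exact coordinates", {
  picks <- pool$proteins[c(1L, 9L)]
  g <- generate_genome(picks, pool$truth, intergenic_len = 3000L, seed = 37)
  cfg <- hotpep_config(mode = "bacterial")
  calls <- annotate_genome(g$genome, groups, cfg)
  # close hits stay independent in bacterial mode (no 5800-base merging)
  expect_identical(nrow(calls), 2L)
  expect_identical(calls$start, g$genes$start)
  expect_identical(calls$end, g$genes$end)
  expect_identical(unname(grp2planted[calls$group_id]), g$genes$subfamily)
})

test_that("raising any threshold never increases the number of calls", {
  picks <- pool$proteins[c(1L, 9L, 17L)]
  g <- generate_genome(picks, pool$truth, intergenic_len = 10000L,
                       seed = 38)
  base <- nrow(annotate_genome(g$genome, groups, hotpep_config()))
  for (cfg in list(hotpep_config(min_peptides = 10L),
                   hotpep_config(min_score = 5),
                   hotpep_config(min_covered_aa = 40L))) {
    expect_lte(nrow(annotate_genome(g$genome, groups, cfg)), base)
  }
  # absurd thresholds silence everything
  none <- hotpep_config(min_score = 1e6)
  expect_identical(nrow(annotate_genome(g$genome, groups, none)), 0L)
})

test_that("gene-free genomes yield no calls", {
  set.seed(39)
  for (i in 1:5) {
    calls <- annotate_genome(rand_nt_str(8000L), groups, hotpep_config())
    expect_identical(nrow(calls), 0L)
  }
})

test_that("gene calls round-trip through TSV and export valid GFF3", {
  picks <- pool$proteins[c(1L, 9L)]
  g <- generate_genome(picks, pool$truth, intergenic_len = 10000L,
                       seed = 40)
  calls <- annotate_genome(g$genome, groups, hotpep_config())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_calls(calls, f)
  back <- read_gene_calls(f)
  expect_identical(back[, c("genome_id", "family", "group_id", "start",
                            "end", "n_fragments")],
                   calls[, c("genome_id", "family", "group_id", "start",
                             "end", "n_fragments")])
  expect_equal(back$frequency_score, calls$frequency_score,
               tolerance = 1e-6)

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gene_calls_gff(calls, gff)
  lines <- readLines(gff)
  expect_identical(lines[1L], "##gff-version 3")
  expect_identical(length(lines), nrow(calls) + 1L)
  expect_true(all(grepl("\thotpep\tgene\t", lines[-1L], fixed = TRUE)))
})

test_that("genome annotation equals fragment-wise assignment plus merging", {
  set.seed(41)
  picks <- pool$proteins[c(1L, 17L)]
  g <- generate_genome(picks, pool$truth, intergenic_len = 4000L, seed = 42)
  cfg <- hotpep_config()
  frags <- fragment_genome(unname(g$genome), cfg$window, cfg$overlap,
                           genome_id = "genome")
  rows <- list()
  for (i in seq_len(nrow(frags))) {
    best <- assign_fragment(frags$seq[i], groups, cfg)
    if (!is.null(best))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(genome_id = "genome", start = frags$start[i],
                   end = frags$end[i], stringsAsFactors = FALSE), best)
  }
  expected <- merge_hits(do.call(rbind, rows), cfg)
  got <- annotate_genome(structure(unname(g$genome), names = "genome"),
                         groups, cfg)
  expect_identical(got, expected)
})
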