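test_that("peptide enumeration slides a window and drops ambiguous k-mers", {
  expect_identical(enumerate_peptides("ACDEFGH"),
                   list(ACDEFG = 1L, CDEFGH = 2L))
  expect_identical(enumerate_peptides("AAAAAAA"), list(AAAAAA = c(1L, 2L)))
  # any window touching the X is discarded
  expect_identical(enumerate_peptides("ACDXEFGHIKLM"),
                   list(EFGHIK = 5L, FGHIKL = 6L, GHIKLM = 7L))
  expect_length(enumerate_peptides("ACDEF"), 0L)
})

test_that("peptide_group validates lengths, letters and frequencies", {
  expect_error(peptide_group("g", "f", c(ACDEFG = 0)), "frequencies")
  expect_error(peptide_group("g", "f", c(ACDEFG = 1.2)), "frequencies")
  expect_error(peptide_group("g", "f", c(ACDEFG = 1, ACDEF = 1)),
               "same length")
  expect_error(peptide_group("g", "f", c(ACDEFX = 1)), "canonical")
})

test_that("score_protein counts presence once and unions coverage", {
  g <- peptide_group("g", "f", c(ACDEFG = 1.0, CDEFGH = 0.5, GHIKLM = 0.25))
  expect_identical(score_protein("ACDEFGH", g),
                   list(n_peptides = 2L, frequency_score = 1.5,
                        covered_aa = 7L))
  expect_identical(score_protein("WWWWWWWW", g),
                   list(n_peptides = 0L, frequency_score = 0,
                        covered_aa = 0L))
  # a peptide occurring twice counts once but covers both occurrences
  g2 <- peptide_group("g", "f", c(ACDEFG = 0.4))
  expect_identical(score_protein("ACDEFGKKACDEFG", g2),
                   list(n_peptides = 1L, frequency_score = 0.4,
                        covered_aa = 12L))
})

test_that("score_protein matches the brute-force oracle on random instances", {
  set.seed(21)
  for (i in 1:200) {
    seq <- rand_aa_str(sample(20:80, 1L),
                       alphabet = c(AA20, if (i %% 4 == 0) "X"))
    g <- rand_group(seq, n_hit = sample(0:4, 1L), n_miss = sample(1:6, 1L))
    expect_identical(score_protein(seq, g), oracle_score(seq, g))
  }
})

test_that("degenerate pools: empty input, singletons, identical proteins", {
  cfg <- ppr_config(peptides_per_group = 20L)
  expect_length(build_subfamilies(character(0), cfg)$groups, 0L)

  set.seed(22)
  one <- structure(rand_aa_str(100), names = "solo")
  expect_length(build_subfamilies(one, cfg)$groups, 0L)

  trip <- structure(rep(rand_aa_str(100), 3L), names = c("a", "b", "c"))
  fit <- build_subfamilies(trip, cfg)
  expect_length(fit$groups, 1L)
  expect_setequal(fit$groups[[1L]]$members, c("a", "b", "c"))
  expect_true(all(fit$groups[[1L]]$peptides == 1.0))

  short <- c(trip, structure(rand_aa_str(40), names = "stub"))
  expect_identical(build_subfamilies(short, cfg)$too_short, "stub")
})

test_that("planted subfamilies are recovered with self-consistent groups", {
  spec <- synthetic_spec(1L, 3L, 8L, 30L, protein_len = c(200L, 280L),
                        seed = 23L)
  pool <- generate_family_pool(spec)
  cfg <- ppr_config(peptides_per_group = 30L)
  fit <- build_subfamilies(pool$proteins, cfg, family = "F1")
  expect_length(fit$groups, 3L)
  expect_length(fit$unassigned, 0L)

  planted <- split(pool$truth$protein_id, pool$truth$subfamily)
  recovered <- lapply(fit$groups, `[[`, "members")
  canon <- function(part) sort(vapply(part, function(x)
    paste(sort(x), collapse = ","), character(1L)))
  expect_identical(canon(recovered), unname(canon(planted)))

  # membership disjoint across groups
  all_members <- unlist(recovered)
  expect_identical(anyDuplicated(all_members), 0L)

  for (g in fit$groups) {
    # stored frequency == recomputed presence fraction over members
    for (p in names(g$peptides)) {
      frac <- mean(vapply(pool$proteins[g$members],
                          function(s) grepl(p, s, fixed = TRUE), logical(1L)))
      expect_identical(unname(g$peptides[p]), frac)
    }
    expect_true(all(g$peptides > 0 & g$peptides <= 1))
    expect_lte(length(g$peptides), cfg$peptides_per_group)
    # every member carries at least peptides_per_protein list peptides
    for (m in g$members) {
      n_in <- sum(vapply(names(g$peptides), function(p)
        grepl(p, pool$proteins[[m]], fixed = TRUE), logical(1L)))
      expect_gte(n_in, cfg$peptides_per_protein)
    }
  }

  # byte-identical rerun: the grouping is deterministic
  expect_identical(fit, build_subfamilies(pool$proteins, cfg, family = "F1"))
})

test_that("duplicate sequences are trained once and assigned together", {
  spec <- synthetic_spec(1L, 2L, 5L, 24L, protein_len = c(200L, 240L),
                        seed = 24L)
  pool <- generate_family_pool(spec)
  prot <- c(pool$proteins,
            structure(unname(pool$proteins[1L]), names = "copycat"))
  fit <- build_subfamilies(prot, ppr_config(peptides_per_group = 24L))
  grp_of <- function(id) {
    hits <- vapply(fit$groups, function(g) id %in% g$members, logical(1L))
    which(hits)
  }
  expect_identical(grp_of("copycat"), grp_of(names(pool$proteins)[1L]))
})

test_that("classification takes the top-scoring significant group", {
  gA <- peptide_group("A_01", "A",
                      c(ACDEFG = 1.0, HIKLMN = 0.6, PQRSTV = 0.4))
  gB <- peptide_group("B_01", "B",
                      c(ACDEFG = 0.3, HIKLMN = 0.5, PQRSTV = 0.4))
  prot <- c(p = "ACDEFGWHIKLMNWPQRSTV")   # contains all three peptides
  res <- classify_proteins(prot, list(gB, gA))
  expect_identical(res$group_id, "A_01")   # 2.0 beats 1.2
  expect_identical(res$family, "A")

  # two matched peptides fail the n >= 3 condition no matter the score
  g2 <- peptide_group("C_01", "C", c(ACDEFG = 1.0, HIKLMN = 1.0))
  res2 <- classify_protein("ACDEFGWHIKLMN", list(g2))
  expect_true(is.na(res2$group_id))

  # exact ties resolve to the lexicographically smaller group id
  gX <- peptide_group("X_01", "X", c(ACDEFG = 1, HIKLMN = 1, PQRSTV = 1))
  gW <- peptide_group("W_01", "W", c(ACDEFG = 1, HIKLMN = 1, PQRSTV = 1))
  res3 <- classify_protein("ACDEFGWHIKLMNWPQRSTV", list(gX, gW))
  expect_identical(res3$group_id, "W_01")
})

test_that("disjoint planted families never cross-annotate", {
  spec <- synthetic_spec(2L, 2L, 6L, 24L, protein_len = c(200L, 240L),
                        seed = 25L)
  pool <- generate_family_pool(spec)
  groups <- build_pool_groups(pool, ppr_config(peptides_per_group = 24L))
  labels <- structure(pool$truth$family, names = pool$truth$protein_id)
  ev <- evaluate_annotation(pool$proteins, labels, groups)
  expect_identical(unname(diag(ev$percent[c("F1", "F2"), c("F1", "F2")])),
                   c(100, 100))
  expect_identical(unname(ev$percent["F1", "F2"]), 0)
  expect_identical(unname(ev$percent["F2", "F1"]), 0)

  # lists of one family say nothing about proteins of the other
  f2_groups <- Filter(function(g) g$family == "F2", groups)
  f1_ids <- pool$truth$protein_id[pool$truth$family == "F1"]
  ev2 <- evaluate_annotation(pool$proteins[f1_ids], labels[f1_ids], f2_groups)
  expect_identical(unname(ev2$percent["F1", "unassigned"]), 100)
})

test_that("partition recovery stays high under 5% per-residue mutation", {
  spec <- synthetic_spec(1L, 3L, 12L, 40L, protein_len = c(200L, 300L),
                        mutation_rate = 0.05, seed = 26L)
  pool <- generate_family_pool(spec)
  fit <- build_subfamilies(pool$proteins, ppr_config(peptides_per_group = 40L))
  member_grp <- rep(NA_character_, length(pool$proteins))
  names(member_grp) <- names(pool$proteins)
  for (g in fit$groups) member_grp[g$members] <- g$id
  member_grp[is.na(member_grp)] <- "none"
  planted <- pool$truth$subfamily[match(names(member_grp),
                                        pool$truth$protein_id)]
  ari <- mclust::adjustedRandIndex(member_grp, planted)
  expect_gt(ari, 0.9)
})
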