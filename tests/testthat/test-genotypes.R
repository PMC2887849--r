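`%||%` <- function(a, b) if (is.null(a)) b else a

make_toy_table <- function() {
  # 2 pops x 2 inds, 2 loci; individual a2 missing at L2
  a <- array(NA_integer_, c(4, 2, 2))
  a[1, 1, ] <- c(100L, 100L); a[1, 2, ] <- c(104L, 106L)
  a[2, 1, ] <- c(100L, 102L)
  a[3, 1, ] <- c(102L, 102L); a[3, 2, ] <- c(104L, 104L)
  a[4, 1, ] <- c(100L, 102L); a[4, 2, ] <- c(106L, 106L)
  genotype_table(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"),
                 a, c("L1", "L2"))
}

test_that("genotype_table validates and normalizes its inputs", {
  t <- make_toy_table()
  expect_identical(t$pops, c("A", "B"))
  expect_true(all(is.na(t$alleles[2, 2, ])))
  # allele 0 and half-missing calls are coerced to missing
  a <- array(c(0L, 100L, 100L, NA), c(1, 2, 2))
  t2 <- genotype_table("x", "P", a, c("l1", "l2"))
  expect_true(all(is.na(t2$alleles)))
  expect_error(genotype_table(c("x", "y"), "P", a, c("l1", "l2")),
               "length")
  expect_error(genotype_table(character(0), character(0),
                              array(1L, c(0, 1, 2)), "l1"), "individual")
})

test_that("GenePop write/read round-trips genotypes and grouping", {
  t <- make_toy_table()
  txt <- write_genepop(t)
  t2 <- read_genepop(txt)
  expect_identical(t2$alleles[, , ], t$alleles[, , ])
  expect_identical(t2$loci, t$loci)
  # grouping is preserved up to label renaming (labels become the first
  # individual of each Pop block, per GenePop convention)
  expect_identical(as.integer(factor(t2$ind_pop,
                                     levels = unique(t2$ind_pop))),
                   as.integer(factor(t$ind_pop, levels = unique(t$ind_pop))))
  # 2-digit codes round-trip too (allele sizes must fit the width)
  sm <- genotype_table(t$ind_id, t$ind_pop, t$alleles - 90L, t$loci)
  t3 <- read_genepop(write_genepop(sm, digits = 2L))
  expect_identical(unname(t3$alleles), unname(sm$alleles))
})

test_that("GenePop parser handles missing codes and reports bad lines", {
  txt <- paste("title", "locA", "Pop", "ind1 , 000000",
               "ind2 , 100102", sep = "\n")
  t <- read_genepop(txt)
  expect_true(all(is.na(t$alleles[1, 1, ])))
  expect_equal(length(allele_frequencies(t, "locA")), 2L)
  # ragged genotype count names the offending line
  bad <- paste("title", "locA", "Pop", "ind1 , 100102 100102", sep = "\n")
  expect_error(read_genepop(bad), "line 4")
  expect_error(read_genepop(paste("t", "locA", "Pop", "ind1 , 10012",
                                  sep = "\n")),
               "4 or 6", fixed = TRUE)
  # comma-separated locus names on one line
  t4 <- read_genepop(paste("t", "locA, locB", "Pop", "i1 , 100100 102102",
                           sep = "\n"))
  expect_identical(t4$loci, c("locA", "locB"))
})

test_that("write_genepop rejects allele sizes wider than the digit code", {
  a <- array(c(1000L, 1000L), c(1, 1, 2))
  t <- genotype_table("x", "P", a, "l1")
  expect_error(write_genepop(t, digits = 3L), "does not fit")
})

test_that("long-format TSV round-trips", {
  t <- make_toy_table()
  t2 <- read_genotypes_tsv(write_genotypes_tsv(t))
  expect_identical(unname(t2$alleles), unname(t$alleles))
  expect_identical(t2$ind_pop, t$ind_pop)
  expect_identical(t2$loci, t$loci)
})

test_that("allele_frequencies counts gene copies in scope", {
  t <- make_toy_table()
  # pop A, L1: 100/100 and 100/102 -> 100: 3/4, 102: 1/4
  f <- allele_frequencies(t, "L1", "A")
  expect_equal(f, c("100" = 0.75, "102" = 0.25))
  expect_equal(sum(allele_frequencies(t, "L1")), 1, tolerance = 1e-12)
  # all-missing scope returns NULL, not zeros
  a <- array(NA_integer_, c(2, 1, 2))
  tm <- genotype_table(c("x", "y"), c("P", "P"), a, "l1")
  expect_null(allele_frequencies(tm, "l1"))
  expect_error(allele_frequencies(t, "nope"), "unknown locus")
  expect_error(allele_frequencies(t, "L1", "nope"), "unknown population")
})

test_that("pooled frequencies equal the individual-weighted population mix", {
  set.seed(31)
  for (rep in seq_len(5)) {
    t <- rand_table(3, 12, 3, 5, miss = 0.15)
    for (loc in t$loci) {
      pooled <- allele_frequencies(t, loc)
      # rebuild from per-population counts
      cnt <- list()
      for (p in t$pops) {
        g <- t$alleles[t$ind_pop == p, match(loc, t$loci), ]
        n <- sum(!is.na(g[, 1]))
        f <- allele_frequencies(t, loc, p)
        if (!is.null(f)) {
          for (al in names(f)) {
            cnt[[al]] <- (cnt[[al]] %||% 0) + f[[al]] * 2 * n
          }
        }
      }
      mix <- unlist(cnt); mix <- mix / sum(mix)
      expect_equal(pooled[sort(names(pooled))], mix[sort(names(mix))],
                   tolerance = 1e-12)
    }
  }
})

test_that("locus_summaries reproduces hand-computed values", {
  # 4 inds: 100/100, 100/102, 102/102, 100/102 -> p = 0.5
  a <- array(NA_integer_, c(4, 1, 2))
  a[1, 1, ] <- c(100L, 100L); a[2, 1, ] <- c(100L, 102L)
  a[3, 1, ] <- c(102L, 102L); a[4, 1, ] <- c(100L, 102L)
  t <- genotype_table(paste0("i", 1:4), rep("P", 4), a, "loc")
  s <- locus_summaries(t)
  expect_equal(s$allele_count, 2L)
  expect_equal(s$H_o, 0.5)
  expect_equal(s$H_e, 0.5)
  expect_equal(s$percent_missing, 0)
  # monomorphic locus
  am <- array(100L, c(3, 1, 2))
  sm <- locus_summaries(genotype_table(paste0("i", 1:3), rep("P", 3), am,
                                       "loc"))
  expect_equal(sm$allele_count, 1L)
  expect_equal(sm$H_o, 0)
  expect_equal(sm$H_e, 0)
  # no-data locus yields NA markers, not zeros
  an <- array(NA_integer_, c(3, 1, 2))
  sn <- locus_summaries(genotype_table(paste0("i", 1:3), rep("P", 3), an,
                                       "loc"))
  expect_true(is.na(sn$H_o) && is.na(sn$H_e) && is.na(sn$allele_count))
  expect_equal(sn$percent_missing, 100)
  # small-sample correction flag
  sc <- locus_summaries(t, bias_correct = TRUE)
  expect_equal(sc$H_e, 0.5 * 8 / 7)
})

test_that("summaries are invariant to relabeling and individual order", {
  set.seed(5)
  t <- rand_table(3, 10, 4, 4, miss = 0.1)
  s1 <- locus_summaries(t)
  perm <- sample(length(t$ind_id))
  t2 <- genotype_table(t$ind_id[perm], t$ind_pop[perm],
                       t$alleles[perm, , , drop = FALSE], t$loci)
  expect_equal(locus_summaries(t2), s1)
  t3 <- genotype_table(t$ind_id, paste0("renamed_", t$ind_pop), t$alleles,
                       t$loci)
  expect_equal(locus_summaries(t3), s1)
})

test_that("H_e bounds hold and pooled H_o ~ H_e on panmictic simulations", {
  set.seed(61)
  sim <- simulate_genotypes(pop_sim_spec(3, 40, 50, 4, fst = 0,
                                         seed = 6161))
  s <- locus_summaries(sim$table)
  expect_true(all(s$H_e <= 1 - 1 / s$allele_count + 1e-12))
  expect_true(all(s$H_o >= 0 & s$H_o <= 1))
  # under HWE with no structure and no nulls, paired over 50 loci
  expect_lt(abs(mean(s$H_e - s$H_o)), 0.02)
})
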