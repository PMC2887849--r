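geno_from_counts <- function(aa, ab, bb, a = 100L, b = 102L) {
  rbind(matrix(a, aa, 2), cbind(rep(a, ab), rep(b, ab)), matrix(b, bb, 2))
}

test_that("hwe_chi2 reproduces hand-computed worked examples", {
  # exact HWE proportions: chi2 = 0
  h0 <- hwe_chi2(geno_from_counts(25, 50, 25))
  expect_equal(h0$chi2, 0)
  expect_equal(h0$df, 1L)
  expect_equal(h0$p, 1)
  expect_identical(h0$status, "non_significant")
  # heterozygote deficit: expected 25/50/25 -> chi2 = 1+4+1... = 4 exactly
  h1 <- hwe_chi2(geno_from_counts(30, 40, 30))
  expect_equal(h1$chi2, 4)
  expect_equal(h1$df, 1L)
  expect_equal(h1$p, pchisq(4, 1, lower.tail = FALSE))
  expect_identical(h1$status, "significant")
})

test_that("hwe_chi2 edge statuses and warnings", {
  expect_identical(hwe_chi2(matrix(100L, 10, 2))$status, "monomorphic")
  expect_identical(hwe_chi2(matrix(NA_integer_, 5, 2))$status, "untestable")
  expect_identical(hwe_chi2(matrix(integer(0), 0, 2))$status, "untestable")
  # rare allele: expected het cell < 1 triggers the low-count flag
  g <- rbind(matrix(100L, 60, 2), cbind(100L, 102L))
  expect_true(hwe_chi2(g)$low_expected)
  expect_false(hwe_chi2(geno_from_counts(25, 50, 25))$low_expected)
  # df for k alleles is k(k-1)/2
  g3 <- rbind(geno_from_counts(10, 20, 10), matrix(104L, 10, 2),
              cbind(rep(100L, 5), rep(104L, 5)))
  expect_equal(hwe_chi2(g3)$df, 3L)
})

test_that("chi2 is invariant to allele relabeling and all-missing rows", {
  set.seed(12)
  for (rep in seq_len(20)) {
    g <- matrix(sample(c(100L, 102L, 104L), 60, replace = TRUE), 30, 2)
    h1 <- hwe_chi2(g)
    relab <- c("100" = 7L, "102" = 301L, "104" = 55L)
    g2 <- matrix(relab[as.character(g)], 30, 2)
    h2 <- hwe_chi2(g2)
    expect_equal(h1$chi2, h2$chi2)
    expect_equal(h1$df, h2$df)
    h3 <- hwe_chi2(rbind(g, matrix(NA_integer_, 4, 2)))
    expect_equal(h3$chi2, h1$chi2)
    expect_equal(h3$n, h1$n)
  }
})

test_that("hwe_grid covers loci x alphabetical populations with statuses", {
  set.seed(71)
  sim <- simulate_genotypes(pop_sim_spec(3, 30, 4, 3, fst = 0.05,
                                         seed = 711))
  t <- sim$table
  # rename pops so sorted order differs from appearance order
  t2 <- genotype_table(t$ind_id, c(pop_01 = "zeta", pop_02 = "alpha",
                                   pop_03 = "mid")[t$ind_pop],
                       t$alleles, t$loci)
  grid <- hwe_grid(t2)
  expect_identical(colnames(grid$status), c("alpha", "mid", "zeta"))
  expect_identical(rownames(grid$status), t$loci)
  expect_true(all(grid$status %in% c("significant", "non_significant",
                                     "monomorphic", "untestable")))
  # cells match individually run tests, and relabeling changes nothing
  for (li in 1:2) {
    h <- hwe_chi2(t2$alleles[t2$ind_pop == "alpha", li, ])
    expect_identical(grid$status[li, "alpha"], h$status)
  }
  # a population fixed at one allele is monomorphic in that cell
  a <- t2$alleles
  a[t2$ind_pop == "mid", 1, ] <- 100L
  g2 <- hwe_grid(genotype_table(t2$ind_id, t2$ind_pop, a, t2$loci))
  expect_identical(g2$status[1, "mid"], "monomorphic")
})

test_that("hwe_grid writes tsv, text and png renderings", {
  sim <- simulate_genotypes(pop_sim_spec(2, 20, 3, 3, fst = 0.05,
                                         seed = 99))
  grid <- hwe_grid(sim$table)
  tsv <- tempfile(fileext = ".tsv")
  write_hwe_grid(grid, tsv, "tsv")
  back <- read.table(tsv, header = TRUE, sep = "\t", check.names = FALSE)
  expect_identical(back$locus, rownames(grid$status))
  expect_identical(as.matrix(back[, -1]), grid$status,
                   ignore_attr = TRUE)
  txt <- tempfile(fileext = ".txt")
  write_hwe_grid(grid, txt, "text")
  expect_length(readLines(txt), nrow(grid$status))
  png <- tempfile(fileext = ".png")
  write_hwe_grid(grid, png, "png")
  expect_gt(file.size(png), 0)
})

test_that("type-I error of the HWE test is near alpha (reduced run)", {
  set.seed(2024)
  rej <- 0L
  reps <- 400L
  for (i in seq_len(reps)) {
    g <- matrix(sample(c(100L, 102L), 200, replace = TRUE), 100, 2)
    if (identical(hwe_chi2(g)$status, "significant")) rej <- rej + 1L
  }
  rate <- rej / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("deficit_vs_missingness matches the reference implementation", {
  # perfect monotone relations
  up <- data.frame(H_o = rep(0.2, 5), H_e = seq(0.3, 0.7, 0.1),
                   percent_missing = c(1, 2, 5, 7, 9))
  expect_equal(deficit_vs_missingness(up)$r_s, 1)
  down <- up; down$percent_missing <- rev(up$percent_missing)
  expect_equal(deficit_vs_missingness(down)$r_s, -1)
  # tie-aware agreement with cor.test on random data, including ties
  set.seed(303)
  for (rep in seq_len(100)) {
    n <- sample(5:20, 1)
    df <- data.frame(H_o = round(runif(n), 2), H_e = round(runif(n), 2),
                     percent_missing = round(runif(n, 0, 30), 1))
    x <- df$H_e - df$H_o; y <- df$percent_missing
    if (sd(x) == 0 || sd(y) == 0) next
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    got <- deficit_vs_missingness(df)
    expect_equal(got$r_s, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact permutation p agrees with cor.test for small n", {
  set.seed(8)
  for (rep in seq_len(5)) {
    df <- data.frame(H_o = runif(6), H_e = runif(6),
                     percent_missing = runif(6, 0, 20))
    got <- deficit_vs_missingness(df, p_method = "exact")
    ref <- cor.test(df$H_e - df$H_o, df$percent_missing,
                    method = "spearman", exact = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("deficit_vs_missingness input validation", {
  small <- data.frame(H_o = 1:2 / 10, H_e = 2:3 / 10,
                      percent_missing = c(1, 2))
  expect_error(deficit_vs_missingness(small), ">= 3 loci")
  const <- data.frame(H_o = rep(0.1, 4), H_e = rep(0.5, 4),
                      percent_missing = 1:4)
  expect_error(deficit_vs_missingness(const), "constant")
})

test_that("missingness_anova matches anova(lm) and handles edge cases", {
  # hand example: groups {1,3} vs {5,7} -> SSB 16, SSW 4, F = 8, df (1,2)
  r <- missingness_anova(c(1, 3, 5, 7), c("a", "a", "b", "b"))
  expect_equal(r$F, 8)
  expect_equal(r$df_between, 1L)
  expect_equal(r$df_within, 2L)
  expect_equal(r$group_means, c(a = 2, b = 6))
  # all equal -> F = 0, p = 1
  r0 <- missingness_anova(rep(2, 6), rep(c("a", "b"), 3))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # zero within-group variance with group differences -> Inf, p = 0
  ri <- missingness_anova(c(1, 1, 5, 5), c("a", "a", "b", "b"))
  expect_identical(ri$F, Inf)
  expect_equal(ri$p, 0)
  expect_error(missingness_anova(1:3, rep("a", 3)), ">= 2 groups")
  expect_error(missingness_anova(1:2, c("a", "b")), "more observations")
  # reference agreement on random inputs
  set.seed(44)
  for (rep in seq_len(100)) {
    k <- sample(2:5, 1)
    n <- sample((k + 1):25, 1)
    g <- sample(letters[1:k], n, replace = TRUE)
    if (length(unique(g)) < k || max(table(g)) == n) next
    y <- rnorm(n)
    ref <- anova(lm(y ~ factor(g)))
    got <- missingness_anova(y, g)
    expect_equal(got$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(got$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("published panel values reproduce the QC statistics", {
  panel <- editha_panel()
  cor_res <- deficit_vs_missingness(panel)
  expect_equal(cor_res$n, 10L)
  expect_gte(cor_res$r_s, 0.81)
  expect_lt(cor_res$p, 0.01)
  an <- missingness_anova(panel)
  expect_equal(an$df_between, 3L)
  expect_equal(an$df_within, 6L)
  expect_gte(an$F, 15.4)
})
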