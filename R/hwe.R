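#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' Tests one locus in one population against Hardy-Weinberg genotype
#' proportions. Expected counts are `n * p_i^2` for homozygotes and
#' `2 * n * p_i * p_j` for heterozygotes, from the observed allele
#' frequencies; the statistic sums `(obs - exp)^2 / exp` over all
#' `k(k+1)/2` genotype cells and is referred to a chi-square distribution
#' with `k(k-1)/2` degrees of freedom (k = observed alleles). No continuity
#' correction and no cell pooling are applied; instead a low-expected-count
#' flag is set when any expected cell is below 1 or more than 20% of cells
#' are below 5.
#'
#' @param genotypes a two-column matrix (or data frame) of allele sizes, one
#'   row per individual; rows with `NA` are dropped.
#' @param alpha significance level for the status call (default 0.05).
#' @param locus,population optional labels carried into the result.
#' @return A list of class `"hwe_test"`: `chi2`, `df`, `p`, `n`, `k`,
#'   `status` (one of `"significant"`, `"non_significant"`,
#'   `"monomorphic"`, `"untestable"`) and `low_expected`.
#' @examples
#' g <- rbind(matrix(100, 30, 2), cbind(rep(100, 40), rep(102, 40)),
#'            matrix(102, 30, 2))
#' hwe_chi2(g)  # chi2 = 4, df = 1, p ~ 0.0455
#' @export
hwe_chi2 <- function(genotypes, alpha = 0.05, locus = NA_character_,
                     population = NA_character_) {
  g <- as.matrix(genotypes)
  if (ncol(g) != 2L) stop("`genotypes` needs two allele columns",
                          call. = FALSE)
  g <- g[!is.na(g[, 1L]) & !is.na(g[, 2L]), , drop = FALSE]
  n <- nrow(g)
  res <- list(locus = locus, population = population, chi2 = NA_real_,
              df = NA_integer_, p = NA_real_, n = n, k = 0L,
              status = "untestable", low_expected = FALSE, alpha = alpha)
  class(res) <- "hwe_test"
  if (n == 0L) return(res)
  alleles <- sort(unique(as.vector(g)))
  k <- length(alleles)
  res$k <- k
  if (k == 1L) {
    res$status <- "monomorphic"
    return(res)
  }
  freq <- tabulate(match(as.vector(g), alleles), k) / (2 * n)
  # observed unordered genotype counts, cells (i, j) with i <= j
  i1 <- match(pmin(g[, 1L], g[, 2L]), alleles)
  i2 <- match(pmax(g[, 1L], g[, 2L]), alleles)
  obs <- matrix(0, k, k)
  for (r in seq_len(n)) obs[i1[r], i2[r]] <- obs[i1[r], i2[r]] + 1
  expd <- 2 * n * outer(freq, freq)
  diag(expd) <- n * freq^2
  ut <- upper.tri(expd, diag = TRUE)
  o <- obs[ut]; e <- expd[ut]
  res$chi2 <- sum((o - e)^2 / e)
  res$df <- as.integer(k * (k - 1L) / 2L)
  res$p <- stats::pchisq(res$chi2, res$df, lower.tail = FALSE)
  res$status <- if (res$p < alpha) "significant" else "non_significant"
  res$low_expected <- any(e < 1) || mean(e < 5) > 0.2
  res
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE chi-square: chi2 = %.4g, df = %s, p = %.4g [%s]\n",
              x$chi2, x$df, x$p, x$status))
  if (isTRUE(x$low_expected)) cat("  (low expected counts; chi-square",
                                  "approximation may be poor)\n")
  invisible(x)
}

#' Hardy-Weinberg status grid over loci and populations
#'
#' Runs [hwe_chi2()] for every locus in every population and assembles the
#' outcomes into a grid: rows are loci, columns are populations sorted
#' alphabetically. Cells carry one of `significant` (deviation at `alpha`),
#' `non_significant`, `monomorphic` (a single allele observed in that
#' population) or `untestable` (no data).
#'
#' @param table a [genotype_table()].
#' @param alpha significance level (default 0.05).
#' @return A list of class `"hwe_grid"`: `status` (character matrix), `p`
#'   and `chi2` (numeric matrices), `alpha`.
#' @export
hwe_grid <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "genotype_table"))
  pops <- sort(table$pops)
  status <- matrix(NA_character_, length(table$loci), length(pops),
                   dimnames = list(table$loci, pops))
  pmat <- chimat <- matrix(NA_real_, length(table$loci), length(pops),
                           dimnames = dimnames(status))
  for (pi in seq_along(pops)) {
    keep <- table$ind_pop == pops[pi]
    for (li in seq_along(table$loci)) {
      r <- hwe_chi2(table$alleles[keep, li, ], alpha = alpha,
                    locus = table$loci[li], population = pops[pi])
      status[li, pi] <- r$status
      pmat[li, pi] <- r$p
      chimat[li, pi] <- r$chi2
    }
  }
  structure(list(status = status, p = pmat, chi2 = chimat, alpha = alpha),
            class = "hwe_grid")
}

#' @export
print.hwe_grid <- function(x, ...) {
  cat(sprintf("HWE status grid: %d loci x %d populations (alpha = %g)\n",
              nrow(x$status), ncol(x$status), x$alpha))
  cat(format_hwe_grid(x), sep = "\n")
  invisible(x)
}

# Three visual codes: significant = '#', monomorphic = '.', other = ' '.
format_hwe_grid <- function(grid) {
  sym <- matrix(" ", nrow(grid$status), ncol(grid$status))
  sym[grid$status == "significant"] <- "#"
  sym[grid$status == "monomorphic"] <- "."
  sym[grid$status == "untestable"] <- "?"
  w <- max(nchar(rownames(grid$status)))
  paste0(formatC(rownames(grid$status), width = w), " |",
         apply(sym, 1L, paste, collapse = ""), "|")
}

#' Write an HWE status grid
#'
#' @param grid an [hwe_grid()] result.
#' @param path output file.
#' @param format `"tsv"` (status codes), `"text"` (character heat-grid:
#'   `#` significant, `.` monomorphic, `?` untestable, blank otherwise) or
#'   `"png"` (image of the same three-way coding).
#' @return `path`, invisibly.
#' @export
write_hwe_grid <- function(grid, path, format = c("tsv", "text", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "hwe_grid"))
  if (format == "tsv") {
    df <- data.frame(locus = rownames(grid$status), grid$status,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "text") {
    writeLines(format_hwe_grid(grid), path)
  } else {
    code <- matrix(0L, nrow(grid$status), ncol(grid$status))
    code[grid$status == "monomorphic"] <- 1L
    code[grid$status == "significant"] <- 2L
    grDevices::png(path, width = 80 + 14 * ncol(code),
                   height = 80 + 14 * nrow(code))
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(1, 6, 4, 1))
    graphics::image(t(code[rev(seq_len(nrow(code))), , drop = FALSE]),
                    col = c("white", "grey85", "grey30"),
                    zlim = c(0, 2), axes = FALSE)
    graphics::axis(2, at = seq(1, 0, length.out = nrow(code)),
                   labels = rownames(grid$status), las = 2, tick = FALSE)
    graphics::axis(3, at = seq(0, 1, length.out = ncol(code)),
                   labels = colnames(grid$status), las = 2, tick = FALSE)
  }
  invisible(path)
}

#' Heterozygote deficit versus missingness (null-allele diagnostic)
#'
#' Null alleles both depress observed heterozygosity (null heterozygotes are
#' scored as homozygotes) and inflate missingness (null homozygotes fail to
#' amplify). A positive rank correlation between the per-locus heterozygote
#' deficit `H_e - H_o` and percent missing calls is therefore diagnostic of
#' null alleles. Spearman's rank correlation is computed tie-aware (Pearson
#' correlation of midranks); the p-value uses the t approximation
#' `t = r_s * sqrt((n-2)/(1-r_s^2))` with `n - 2` df, two-tailed, or exact
#' permutation enumeration for small n.
#'
#' @param summaries a data frame with columns `H_o`, `H_e` and
#'   `percent_missing` (as from [locus_summaries()]).
#' @param p_method `"t"` (default) or `"exact"` (full permutation
#'   enumeration; n <= 10 only).
#' @return A list of class `"deficit_cor"`: `r_s`, `n`, `p`, `p_method`.
#' @export
deficit_vs_missingness <- function(summaries, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  stopifnot(is.data.frame(summaries),
            all(c("H_o", "H_e", "percent_missing") %in% names(summaries)))
  x <- summaries$H_e - summaries$H_o
  y <- summaries$percent_missing
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 loci with defined H_o, H_e and missingness",
                   call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant deficit or missingness",
         call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  r_s <- stats::cor(rx, ry)
  if (p_method == "t") {
    if (abs(r_s) >= 1) {
      p <- 0
    } else {
      tval <- r_s * sqrt((n - 2) / (1 - r_s^2))
      p <- 2 * stats::pt(-abs(tval), n - 2)
    }
  } else {
    if (n > 10L) stop("exact p only for n <= 10", call. = FALSE)
    P <- all_perms(n)
    stat <- matrix(rx[P], ncol = n) %*% ry
    obs <- sum(rx * ry)
    mu <- mean(stat)
    p <- mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
  }
  structure(list(r_s = r_s, n = n, p = p, p_method = p_method),
            class = "deficit_cor")
}

#' @export
print.deficit_cor <- function(x, ...) {
  cat(sprintf("Heterozygote deficit vs missingness: r_s = %.3f, n = %d, p = %.4g (%s)\n",
              x$r_s, x$n, x$p, x$p_method))
  invisible(x)
}

# All permutations of 1..n as an n! x n integer matrix (n <= 10).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L),
                      deparse.level = 0)
  }
  do.call(rbind, out)
}

#' One-way ANOVA of per-locus missingness by multiplex group
#'
#' Loci amplified in the same multiplex PCR mix share reaction conditions, so
#' systematic amplification failure shows up as a group effect on percent
#' missing calls. Classical one-way fixed-effects ANOVA on the raw
#' percentages: `F = MS_between / MS_within` with `(groups - 1, n - groups)`
#' degrees of freedom.
#'
#' @param summaries either a data frame with columns `percent_missing` and
#'   `group` (as from [locus_summaries()] with `groups=`), or a numeric
#'   vector of values.
#' @param group group labels, required when `summaries` is a numeric vector.
#' @return A list of class `"anova_result"`: `F`, `df_between`, `df_within`,
#'   `p`, `group_means`. With zero within-group variance, `F` is `Inf` and
#'   `p = 0` (or `F = 0`, `p = 1` when all observations are equal).
#' @export
missingness_anova <- function(summaries, group = NULL) {
  if (is.data.frame(summaries)) {
    y <- summaries$percent_missing
    g <- summaries$group
  } else {
    y <- as.numeric(summaries)
    g <- group
  }
  if (is.null(g)) stop("group labels required", call. = FALSE)
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- as.character(g[ok])
  groups <- unique(g)
  k <- length(groups)
  n <- length(y)
  if (k < 2L) stop("need >= 2 groups", call. = FALSE)
  if (n <= k) stop("need more observations than groups", call. = FALSE)
  gm <- vapply(groups, function(lev) mean(y[g == lev]), numeric(1))
  ng <- vapply(groups, function(lev) sum(g == lev), numeric(1))
  ssb <- sum(ng * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  df_b <- k - 1L
  df_w <- n - k
  if (ssw == 0) {
    Fv <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    Fv <- (ssb / df_b) / (ssw / df_w)
    p <- stats::pf(Fv, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(F = Fv, df_between = as.integer(df_b),
                 df_within = as.integer(df_w), p = p, group_means = gm),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}
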