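#' Pairwise Weir-Cockerham Fst between populations
#'
#' For every pair of populations, computes the Weir & Cockerham (1984)
#' moment estimator theta from diploid genotype tables. For each allele at
#' each locus the three variance components are formed from the two samples
#' (r = 2): with sample sizes `n_i`, allele frequencies `p_i` and observed
#' heterozygote proportions `h_i`,
#' \deqn{\bar n = \sum n_i / r, \quad
#'       n_c = (r\bar n - \sum n_i^2/(r\bar n))/(r-1),}
#' \deqn{a = \frac{\bar n}{n_c}\Big[s^2 - \frac{1}{\bar n - 1}\big(\bar p(1-\bar p)
#'       - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\big)\Big],}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\Big[\bar p(1-\bar p) - \frac{r-1}{r}s^2
#'       - \frac{2\bar n - 1}{4\bar n}\bar h\Big], \quad c = \bar h/2,}
#' and theta is the ratio of sums \eqn{\sum a / \sum(a+b+c)} over all
#' alleles and loci (the standard multi-locus combination). Missing calls
#' are excluded per locus; loci monomorphic across both populations of a
#' pair contribute nothing; loci with data in only one member of a pair are
#' dropped for that pair. Negative estimates are retained, not clamped.
#'
#' @param table a [genotype_table()] with at least two populations.
#' @return A symmetric matrix of theta values with zero diagonal and
#'   population labels as dimnames; a pair with no shared polymorphic data
#'   gets `NA`.
#' @export
pairwise_fst <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  pops <- table$pops
  if (length(pops) < 2L) stop("need >= 2 populations", call. = FALSE)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_len(length(pops) - 1L)) {
    for (j in seq(i + 1L, length(pops))) {
      th <- wc_theta_pair(table, pops[i], pops[j])
      m[i, j] <- m[j, i] <- th
    }
  }
  m
}

# Weir-Cockerham theta for one population pair, ratio of sums over all
# alleles and loci.
wc_theta_pair <- function(table, pop1, pop2) {
  keep1 <- table$ind_pop == pop1
  keep2 <- table$ind_pop == pop2
  num <- den <- 0
  r <- 2
  for (li in seq_along(table$loci)) {
    g1 <- table$alleles[keep1, li, , drop = FALSE]
    g2 <- table$alleles[keep2, li, , drop = FALSE]
    g1 <- matrix(g1, ncol = 2L)[!is.na(g1[, , 1L]), , drop = FALSE]
    g2 <- matrix(g2, ncol = 2L)[!is.na(g2[, , 1L]), , drop = FALSE]
    n1 <- nrow(g1); n2 <- nrow(g2)
    if (n1 == 0L || n2 == 0L) next
    alleles <- sort(unique(c(as.vector(g1), as.vector(g2))))
    if (length(alleles) < 2L) next
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p1 <- sum(g1 == al) / (2 * n1)
      p2 <- sum(g2 == al) / (2 * n2)
      h1 <- sum((g1[, 1L] == al) != (g1[, 2L] == al)) / n1
      h2 <- sum((g2[, 1L] == al) != (g2[, 2L] == al)) / n2
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) NA_real_ else num / den
}

#' Read and write labelled distance matrices
#'
#' Plain-text square labelled matrix format: the first line holds the
#' number of labels, then one row per population (`label v1 v2 ...`).
#' Labels containing whitespace are double-quoted; undefined cells are
#' written as `NA`. The round-trip is lossless to 10 significant digits.
#'
#' @param m a symmetric numeric matrix with labels as dimnames and zero
#'   diagonal.
#' @param path optional output file.
#' @return `write_dist_matrix()`: the text, invisibly when `path` is given;
#'   `read_dist_matrix()`: the matrix.
#' @export
write_dist_matrix <- function(m, path = NULL) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  labs <- rownames(m)
  qlabs <- ifelse(grepl("\\s", labs), paste0('"', labs, '"'), labs)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(qlabs[i], paste(formatC(m[i, ], digits = 10, format = "g"),
                          collapse = " "))
  }, character(1))
  text <- paste0(paste(c(nrow(m), rows), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(c(nrow(m), rows), path)
    return(invisible(text))
  }
  text
}

#' @rdname write_dist_matrix
#' @param file path or literal text.
#' @param tol asymmetry tolerance (default 1e-8).
#' @export
read_dist_matrix <- function(file, tol = 1e-8) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- strsplit(paste(file, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || length(lines) < n + 1L) {
    stop("malformed matrix file: bad count line", call. = FALSE)
  }
  labs <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    ln <- trimws(lines[i + 1L])
    if (startsWith(ln, '"')) {
      close <- regexpr('"', substring(ln, 2L), fixed = TRUE)
      labs[i] <- substr(ln, 2L, close)
      rest <- trimws(substring(ln, close + 2L))
    } else {
      sp <- regexpr("\\s", ln)
      labs[i] <- substr(ln, 1L, sp - 1L)
      rest <- trimws(substring(ln, sp + 1L))
    }
    vals <- suppressWarnings(as.numeric(strsplit(rest, "\\s+")[[1]]))
    if (length(vals) != n) {
      stop("row ", i, ": expected ", n, " values, got ", length(vals),
           call. = FALSE)
    }
    m[i, ] <- vals
  }
  d <- abs(m - t(m))
  if (any(d[!is.na(d)] > tol)) {
    stop("matrix is asymmetric beyond tolerance", call. = FALSE)
  }
  dimnames(m) <- list(labs, labs)
  m
}
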