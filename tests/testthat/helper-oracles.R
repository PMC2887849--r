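# Independent oracles and small fixture builders. These deliberately share
# no code with R/: the miner oracle enumerates candidate tracts by direct
# substring comparison, and the Fst oracle computes Weir-Cockerham variance
# components from raw ANOVA sums of squares instead of the closed-form
# a/b/c expressions.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_rotations <- function(m) {
  p <- nchar(m)
  vapply(seq_len(p) - 1L,
         function(k) paste0(substring(m, k + 1L, p), substring(m, 1L, k)),
         character(1))
}

oracle_primitive <- function(m) {
  p <- nchar(m)
  for (d in seq_len(p - 1L)) {
    if (p %% d == 0L && strrep(substr(m, 1L, d), p / d) == m) return(FALSE)
  }
  TRUE
}

# Brute force: at every position and period, count consecutive exact motif
# copies; keep runs >= threshold with primitive motifs; collapse
# overlapping runs of the same canonical class to the one with the most
# copies (leftmost on ties). Coordinates 0-based half-open.
oracle_find_ssrs <- function(sequence, min_repeats = 8L, periods = 2:4) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  runs <- list()
  for (p in periods) {
    if (L < 2L * p) next
    starts <- seq_len(L - 2L * p + 1L)
    m1 <- substring(sequence, starts, starts + p - 1L)
    m2 <- substring(sequence, starts + p, starts + 2L * p - 1L)
    for (i in starts[m1 == m2 & !grepl("[^ACGT]", m1)]) {
      motif <- substr(sequence, i, i + p - 1L)
      if (!oracle_primitive(motif)) next
      k <- 2L
      while (i + (k + 1L) * p - 1L <= L &&
             substring(sequence, i + k * p, i + (k + 1L) * p - 1L) == motif) {
        k <- k + 1L
      }
      if (k < min_repeats) next
      runs[[length(runs) + 1L]] <- data.frame(
        cls = min(oracle_rotations(motif)), motif = motif,
        start = i - 1L, end = i - 1L + k * p, k = k,
        stringsAsFactors = FALSE)
    }
  }
  if (length(runs) == 0L) {
    return(data.frame(cls = character(0), motif = character(0),
                      start = integer(0), end = integer(0), k = integer(0)))
  }
  runs <- do.call(rbind, runs)
  out <- list()
  for (cls in unique(runs$cls)) {
    sub <- runs[runs$cls == cls, , drop = FALSE]
    sub <- sub[order(sub$start, -sub$k), , drop = FALSE]
    while (nrow(sub) > 0L) {
      grp_end <- sub$end[1]
      in_grp <- sub$start < grp_end
      # grow the cluster until no further overlap
      repeat {
        grp_end2 <- max(sub$end[in_grp])
        in_grp2 <- sub$start < grp_end2
        if (identical(in_grp2, in_grp)) break
        in_grp <- in_grp2
      }
      grp <- sub[in_grp, , drop = FALSE]
      best <- grp[order(-grp$k, grp$start), , drop = FALSE][1, ]
      out[[length(out) + 1L]] <- best
      sub <- sub[!in_grp, , drop = FALSE]
    }
  }
  out <- do.call(rbind, out)
  out[order(out$start), , drop = FALSE]
}

# Canonical key for comparing locus sets.
ssr_key <- function(cls, start, end, k) {
  sort(paste(cls, start, end, k, sep = ":"))
}

# Weir-Cockerham theta for one pair from raw ANOVA sums of squares.
oracle_theta <- function(table, pop1, pop2) {
  num <- den <- 0
  for (li in seq_along(table$loci)) {
    gs <- lapply(c(pop1, pop2), function(p) {
      g <- table$alleles[table$ind_pop == p, li, , drop = FALSE]
      g <- matrix(g, ncol = 2L)
      g[!is.na(g[, 1L]), , drop = FALSE]
    })
    ns <- vapply(gs, nrow, integer(1))
    if (any(ns == 0L)) next
    als <- sort(unique(unlist(gs)))
    if (length(als) < 2L) next
    ndot <- sum(ns)
    nc <- (ndot - sum(ns^2) / ndot)  # r - 1 = 1
    for (al in als) {
      x <- lapply(gs, function(g) (g[, 1L] == al) + (g[, 2L] == al))
      pin <- vapply(x, function(v) sum(v) / (2 * length(v)), numeric(1))
      pbar <- sum(ns * pin) / ndot
      ssp <- sum(2 * ns * (pin - pbar)^2)
      ssi <- sum(unlist(mapply(function(v, pi) 2 * (v / 2 - pi)^2, x, pin,
                               SIMPLIFY = FALSE)))
      ssg <- sum(unlist(lapply(x, function(v) ifelse(v == 1L, 0.5, 0))))
      msp <- ssp / 1; msi <- ssi / (ndot - 2); msg <- ssg / ndot
      a <- (msp - msi) / (2 * nc)
      b <- (msi - msg) / 2
      num <- num + a
      den <- den + a + b + msg
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Random small genotype table with missing data.
rand_table <- function(n_pops = 2L, n_per_pop = 15L, n_loci = 4L,
                       k = 4L, miss = 0.1) {
  n <- n_pops * n_per_pop
  sizes <- 100L + 2L * seq_len(k)
  a <- array(sample(sizes, n * n_loci * 2L, replace = TRUE),
             c(n, n_loci, 2L))
  drop <- array(runif(n * n_loci) < miss, c(n, n_loci, 1L))
  a[, , 1L][drop[, , 1L]] <- NA_integer_
  a[, , 2L][drop[, , 1L]] <- NA_integer_
  genotype_table(paste0("ind", seq_len(n)),
                 rep(paste0("P", seq_len(n_pops)), each = n_per_pop),
                 a, paste0("L", seq_len(n_loci)))
}

# Symmetric random matrix with labels and zero diagonal.
rand_dist <- function(n, labs = sprintf("pop%02d", seq_len(n))) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labs, labs)
  m
}

reverse_complement <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}
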