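#' Specification for simulated contigs with planted microsatellites
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bases.
#' @param planted a data frame with columns `motif` (primitive 2-4 bp
#'   motif), `repeat_count`, and optionally `contig` (1-based index;
#'   cycled over contigs when absent) and `pos` (approximate 0-based start;
#'   drawn uniformly when absent/NA).
#' @param base_composition ACGT probabilities for the background (default
#'   uniform).
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @return A list of class `"contig_sim_spec"`.
#' @export
contig_sim_spec <- function(n_contigs, contig_length, planted = NULL,
                            base_composition = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                            seed) {
  if (missing(seed) || is.na(seed)) stop("`seed` is mandatory",
                                         call. = FALSE)
  n_contigs <- as.integer(n_contigs)
  contig_length <- as.integer(contig_length)
  stopifnot(n_contigs >= 1L, contig_length >= 20L,
            length(base_composition) == 4L, all(base_composition > 0))
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("motif", "repeat_count") %in% names(planted)))
    if (is.null(planted$contig)) {
      planted$contig <- rep_len(seq_len(n_contigs), nrow(planted))
    }
    if (is.null(planted$pos)) planted$pos <- NA_integer_
    for (m in planted$motif) canonical_motif(m)  # validates primitivity
    tract <- nchar(planted$motif) * planted$repeat_count
    if (any(tract + 2L > contig_length)) {
      stop("planted repeat longer than contig", call. = FALSE)
    }
  }
  structure(list(n_contigs = n_contigs, contig_length = contig_length,
                 planted = planted,
                 base_composition = base_composition / sum(base_composition),
                 seed = as.integer(seed)),
            class = "contig_sim_spec")
}

#' Simulate contigs with planted perfect repeats
#'
#' Generates random background sequence from the spec's base composition,
#' rejecting any draw that contains a spontaneous tandem run of
#' `min_repeats` or more copies (so the planted truth is exact), then
#' overwrites the planted repeat tracts and sets the immediately adjacent
#' bases so each tract is maximal. Deterministic given the spec seed.
#'
#' @param spec a [contig_sim_spec()].
#' @param min_repeats mining threshold the truth table is built for
#'   (default 8): planted repeats below it are absent from the truth.
#' @param flank_len flank length recorded in the truth table (default 200).
#' @return A list: `fasta` (text), `sequences` (named character vector) and
#'   `truth` (an `"ssr_loci"` data frame of what a correct miner must
#'   report at `min_repeats`).
#' @export
simulate_contigs <- function(spec, min_repeats = 8L, flank_len = 200L) {
  stopifnot(inherits(spec, "contig_sim_spec"))
  bases <- c("A", "C", "G", "T")
  L <- spec$contig_length
  with_seed(spec$seed, {
    seqs <- character(spec$n_contigs)
    for (ci in seq_len(spec$n_contigs)) {
      repeat {
        s <- sample(bases, L, replace = TRUE, prob = spec$base_composition)
        if (!has_tandem_run(s, min_repeats)) break
      }
      seqs[ci] <- paste(s, collapse = "")
    }
    truth_rows <- list()
    if (!is.null(spec$planted)) {
      for (ri in seq_len(nrow(spec$planted))) {
        ci <- spec$planted$contig[ri]
        motif <- toupper(spec$planted$motif[ri])
        k <- spec$planted$repeat_count[ri]
        p <- nchar(motif)
        tract <- strrep(motif, k)
        K <- nchar(tract)
        pos <- spec$planted$pos[ri]
        pos <- if (is.na(pos)) sample.int(L - K - 1L, 1L) else {
          as.integer(pos) + 1L  # spec positions are 0-based
        }
        pos <- max(1L, min(pos, L - K - 1L))  # leave break room
        s <- strsplit(seqs[ci], "", fixed = TRUE)[[1]]
        s[pos:(pos + K - 1L)] <- strsplit(tract, "", fixed = TRUE)[[1]]
        # break any extension of the tract at both boundaries
        if (pos > 1L) {
          s[pos - 1L] <- sample(setdiff(bases, s[pos - 1L + p]), 1L)
        }
        if (pos + K <= L) {
          s[pos + K] <- sample(setdiff(bases, s[pos + K - p]), 1L)
        }
        seqs[ci] <- paste(s, collapse = "")
        if (k >= min_repeats) {
          truth_rows[[length(truth_rows) + 1L]] <- list(
            contig = paste0("contig_", ci), motif_observed = motif,
            motif_class = min_rotation(motif), period = p,
            start = pos - 1L, end = pos - 1L + K, repeat_count = k)
        }
      }
    }
  })
  names(seqs) <- paste0("contig_", seq_len(spec$n_contigs))
  truth <- empty_ssr_loci()
  if (length(truth_rows) > 0L) {
    tr <- do.call(rbind, lapply(truth_rows, as.data.frame))
    tr <- tr[order(tr$contig, tr$start), , drop = FALSE]
    compound <- logical(nrow(tr))
    for (i in seq_len(nrow(tr) - 1L)) {
      j <- i + 1L
      if (tr$contig[i] == tr$contig[j] &&
          tr$start[j] - tr$end[i] <= 10L) {
        compound[i] <- compound[j] <- TRUE
      }
    }
    truth <- data.frame(
      contig = tr$contig, motif_class = tr$motif_class,
      motif_observed = tr$motif_observed, period = tr$period,
      start = tr$start, end = tr$end, repeat_count = tr$repeat_count,
      compound = compound,
      left_flank = substr(seqs[tr$contig],
                          pmax(1L, tr$start - flank_len + 1L), tr$start),
      right_flank = substr(seqs[tr$contig], tr$end + 1L,
                           pmin(nchar(seqs[tr$contig]),
                                tr$end + flank_len)),
      stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    class(truth) <- c("ssr_loci", "data.frame")
  }
  fasta <- paste0(paste0(">", names(seqs), "\n", seqs, collapse = "\n"),
                  "\n")
  list(fasta = fasta, sequences = seqs, truth = truth)
}

# Conservative detector of tandem runs >= min_repeats whole copies of any
# period 2-4 motif (independent of the miner; over-detection is harmless
# because it only triggers a background re-draw).
has_tandem_run <- function(s, min_repeats) {
  L <- length(s)
  for (p in 2:4) {
    if (L <= p) next
    eq <- s[seq_len(L - p)] == s[seq_len(L - p) + p]
    r <- rle(eq)
    if (any(r$values & (r$lengths + p) %/% p >= min_repeats)) return(TRUE)
  }
  FALSE
}

#' Specification for island-model genotype simulation
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population.
#' @param n_loci number of loci.
#' @param n_alleles alleles per locus (scalar or per-locus vector).
#' @param fst generative differentiation parameter in `[0, 1)`; 0 means all
#'   populations share the ancestral frequencies exactly.
#' @param null_rate per-locus null-allele frequency in `[0, 1)` (scalar or
#'   per-locus vector).
#' @param missing_rate baseline genotyping failure probability per call.
#' @param seed integer seed (mandatory).
#' @return A list of class `"pop_sim_spec"`.
#' @export
pop_sim_spec <- function(n_pops, n_per_pop, n_loci, n_alleles = 5L,
                         fst = 0.1, null_rate = 0, missing_rate = 0,
                         seed) {
  if (missing(seed) || is.na(seed)) stop("`seed` is mandatory",
                                         call. = FALSE)
  if (length(fst) != 1L || is.na(fst) || fst < 0 || fst >= 1) {
    stop("`fst` must be in [0, 1)", call. = FALSE)
  }
  n_alleles <- rep_len(as.integer(n_alleles), n_loci)
  null_rate <- rep_len(as.numeric(null_rate), n_loci)
  stopifnot(n_pops >= 1L, n_per_pop >= 1L, n_loci >= 1L,
            all(n_alleles >= 1L), all(null_rate >= 0 & null_rate < 1),
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_pops = as.integer(n_pops),
                 n_per_pop = as.integer(n_per_pop),
                 n_loci = as.integer(n_loci), n_alleles = n_alleles,
                 fst = fst, null_rate = null_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "pop_sim_spec")
}

#' Simulate multi-population microsatellite genotypes
#'
#' Balding-Nichols island model: ancestral allele frequencies at each locus
#' are drawn from a flat Dirichlet; each population's frequencies are drawn
#' from a Dirichlet with concentration `p * (1 - F) / F` around the
#' ancestral vector (so the expected differentiation equals the `fst`
#' parameter); genotypes are drawn under within-population Hardy-Weinberg
#' equilibrium. A hidden null allele is then overlaid per locus: each
#' transmitted allele copy is null with probability `null_rate`;
#' null/null genotypes become missing and null/visible genotypes are
#' recorded as visible homozygotes (the standard allele-dropout model).
#' Baseline missingness is applied independently afterwards. Deterministic
#' given the spec seed.
#'
#' Allele "sizes" follow a dinucleotide ladder starting at 100 bp.
#'
#' @param spec a [pop_sim_spec()].
#' @return A list: `table` (a [genotype_table()]) and `truth` (ancestral and
#'   per-population allele frequencies, null rates, and the spec).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "pop_sim_spec"))
  n_ind <- spec$n_pops * spec$n_per_pop
  loci <- sprintf("locus_%02d", seq_len(spec$n_loci))
  pops <- sprintf("pop_%02d", seq_len(spec$n_pops))
  ind_pop <- rep(pops, each = spec$n_per_pop)
  ind_id <- paste0(ind_pop, "_", sequence(rep(spec$n_per_pop, spec$n_pops)))
  alleles <- array(NA_integer_, c(n_ind, spec$n_loci, 2L))
  anc <- pf <- vector("list", spec$n_loci)
  with_seed(spec$seed, {
    for (li in seq_len(spec$n_loci)) {
      k <- spec$n_alleles[li]
      sizes <- 100L + 2L * (seq_len(k) - 1L)
      p_anc <- rdirichlet(rep(1, k))
      anc[[li]] <- stats::setNames(p_anc, sizes)
      pmat <- matrix(NA_real_, spec$n_pops, k,
                     dimnames = list(pops, sizes))
      for (pi in seq_len(spec$n_pops)) {
        pmat[pi, ] <- if (spec$fst == 0) p_anc else {
          rdirichlet(p_anc * (1 - spec$fst) / spec$fst)
        }
        rows <- which(ind_pop == pops[pi])
        draws <- sample.int(k, 2L * length(rows), replace = TRUE,
                            prob = pmat[pi, ])
        alleles[rows, li, 1L] <- sizes[draws[seq_along(rows)]]
        alleles[rows, li, 2L] <- sizes[draws[length(rows) +
                                               seq_along(rows)]]
      }
      pf[[li]] <- pmat
      nu <- spec$null_rate[li]
      if (nu > 0) {
        z1 <- stats::runif(n_ind) < nu
        z2 <- stats::runif(n_ind) < nu
        both <- z1 & z2
        alleles[both, li, ] <- NA_integer_
        one1 <- z1 & !z2   # first copy null -> homozygote for second
        alleles[one1, li, 1L] <- alleles[one1, li, 2L]
        one2 <- z2 & !z1
        alleles[one2, li, 2L] <- alleles[one2, li, 1L]
      }
      if (spec$missing_rate > 0) {
        drop <- stats::runif(n_ind) < spec$missing_rate
        alleles[drop, li, ] <- NA_integer_
      }
    }
  })
  list(table = genotype_table(ind_id, ind_pop, alleles, loci),
       truth = list(spec = spec, ancestral_freqs = anc,
                    pop_freqs = pf, null_rate = spec$null_rate))
}

# One draw from Dirichlet(alpha) via independent gammas.
rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) {  # guard for tiny concentrations
    x[sample.int(length(alpha), 1L)] <- 1
  }
  x / sum(x)
}
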