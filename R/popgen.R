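#' @title Forensic and population-genetic parameters
#' @description Allele frequencies, heterozygosities, matching probability,
#'   powers of discrimination and exclusion, typical paternity index, and
#'   exact Hardy-Weinberg testing (full enumeration or Monte-Carlo
#'   permutation conditional on allele counts).
#' @name popgen
NULL

# genotype table -> two allele vectors; incomplete genotypes dropped
.gtAlleles <- function(genotypes, level = c("length", "sequence")) {
  level <- match.arg(level)
  a <- if (level == "length") genotypes$des_a else genotypes$seq_a
  b <- if (level == "length") genotypes$des_b else genotypes$seq_b
  hom <- is.na(b) & !is.na(a)
  b[hom] <- a[hom]
  keep <- !is.na(a) & !is.na(b)
  if (any(!keep))
    warning(sum(!keep), " incomplete genotype(s) excluded")
  data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
}

#' Allele frequencies at a locus
#'
#' Counts over 2N chromosomes from complete genotypes; homozygotes count as
#' two copies. Incomplete genotypes are excluded with a warning.
#'
#' @param genotypes genotype data.frame at one locus (columns \code{des_a},
#'   \code{des_b} and/or \code{seq_a}, \code{seq_b}; homozygotes may carry a
#'   single allele record with the b column NA).
#' @param level count alleles by length designation or by sequence.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
alleleFrequencies <- function(genotypes, level = c("length", "sequence")) {
  g <- .gtAlleles(genotypes, level)
  if (!nrow(g)) stop("no complete genotypes")
  tab <- table(c(g$a, g$b))
  f <- as.numeric(tab) / sum(tab)
  names(f) <- names(tab)
  f
}

#' Observed and unbiased expected heterozygosity
#'
#' h_obs is the heterozygote fraction among complete genotypes; h_exp is the
#' unbiased (Nei) estimator \code{(2N/(2N-1)) * (1 - sum p_i^2)}.
#'
#' @inheritParams alleleFrequencies
#' @return List with \code{h_obs} and \code{h_exp}.
#' @export
heterozygosities <- function(genotypes, level = c("length", "sequence")) {
  g <- .gtAlleles(genotypes, level)
  n <- nrow(g)
  if (n < 2L) stop("need at least two complete genotypes for h_exp")
  p <- as.numeric(table(c(g$a, g$b))) / (2 * n)
  list(h_obs = mean(g$a != g$b),
       h_exp = (2 * n / (2 * n - 1)) * (1 - sum(p^2)))
}

#' Forensic identity and kinship parameters at a locus
#'
#' Matching probability is the sum of squared observed genotype-class
#' frequencies; power of discrimination its complement. With
#' \code{h = h_obs} and \code{H = 1 - h_obs}: power of exclusion
#' \code{h^2 * (1 - 2 h H^2)} and typical paternity index \code{1 / (2 H)}.
#'
#' @inheritParams alleleFrequencies
#' @return List with \code{mp}, \code{pd}, \code{pe}, \code{tpi}; when every
#'   genotype is heterozygous (H = 0) the paternity index is infinite and the
#'   \code{tpi_undefined} flag is set.
#' @export
forensicParams <- function(genotypes, level = c("length", "sequence")) {
  g <- .gtAlleles(genotypes, level)
  n <- nrow(g)
  if (n < 2L) stop("need at least two complete genotypes")
  cls <- ifelse(g$a <= g$b, paste(g$a, g$b, sep = "/"),
                paste(g$b, g$a, sep = "/"))
  f <- as.numeric(table(cls)) / n
  mp <- sum(f^2)
  h <- mean(g$a != g$b)
  H <- 1 - h
  tpi <- if (H == 0) Inf else 1 / (2 * H)
  list(mp = mp, pd = 1 - mp, pe = h^2 * (1 - 2 * h * H^2), tpi = tpi,
       tpi_undefined = H == 0)
}

# log multinomial-style probability of one genotype-count table conditional
# on allele counts (Levene): log P = log N! + H log 2 + sum log n_i!
#                                    - log (2N)! - sum log g_ij!
.logTableProb <- function(gmat, alleleCounts) {
  N <- sum(gmat[upper.tri(gmat, diag = TRUE)])
  H <- sum(gmat[upper.tri(gmat)])
  lfactorial(N) + H * log(2) + sum(lfactorial(alleleCounts)) -
    lfactorial(2 * N) - sum(lfactorial(gmat[upper.tri(gmat, diag = TRUE)]))
}

# genotype strings "a/b" -> symmetric count matrix over sorted allele names
.gtCountMatrix <- function(a, b) {
  alleles <- sort(unique(c(a, b)))
  k <- length(alleles)
  m <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  ia <- match(a, alleles)
  ib <- match(b, alleles)
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  cnt <- tabulate((hi - 1L) * k + lo, nbins = k * k)
  m[] <- cnt
  m
}

# enumerate all genotype-count tables with the given allele margin; calls
# fun(gmat) for each. Upper-triangular fill, row by row.
.enumTables <- function(alleleCounts, fun) {
  k <- length(alleleCounts)
  g <- matrix(0L, k, k)
  rec <- function(i, j, rem) {
    if (i > k) { fun(g); return(invisible()) }
    if (j > k) {
      # row i complete: all copies of allele i must have been consumed
      if (rem[i] == 0L) rec(i + 1L, i + 1L, rem)
      return(invisible())
    }
    if (i == j) {
      # homozygote count: uses 2 copies of allele i each
      maxh <- rem[i] %/% 2L
      for (h in 0:maxh) {
        g[i, i] <<- h
        rem2 <- rem
        rem2[i] <- rem2[i] - 2L * h
        rec(i, j + 1L, rem2)
      }
      g[i, i] <<- 0L
    } else {
      maxg <- min(rem[i], rem[j])
      # last cell of row i must absorb all remaining copies of allele i
      lo <- if (j == k) rem[i] else 0L
      if (lo > maxg) return(invisible())
      for (x in lo:maxg) {
        g[i, j] <<- x
        rem2 <- rem
        rem2[i] <- rem2[i] - x
        rem2[j] <- rem2[j] - x
        rec(i, j + 1L, rem2)
      }
      g[i, j] <<- 0L
    }
    invisible()
  }
  # special case k == 1: single table of N homozygotes
  if (k == 1L) {
    g[1L, 1L] <- alleleCounts[1L] %/% 2L
    fun(g)
    return(invisible())
  }
  rec(1L, 1L, as.integer(alleleCounts))
  invisible()
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test on the allele counts: the p-value is the total
#' probability of genotype-count tables (with the observed allele margin)
#' whose conditional probability does not exceed that of the observed table.
#' \code{method = "enumerate"} sums over the full table space (feasible for
#' few alleles / small N); \code{method = "permute"} shuffles the allele
#' vector \code{nPerm} times with a mandatory seed; \code{method = "auto"}
#' enumerates unless the table space exceeds \code{maxTables}.
#'
#' @param genotypes genotype data.frame at one locus (see
#'   \code{\link{alleleFrequencies}}).
#' @param method "auto", "enumerate" or "permute".
#' @param nPerm number of Monte-Carlo permutations (default 100000).
#' @param seed integer seed, required for permutation.
#' @param maxTables table-space bound above which "auto" switches to
#'   permutation (default 1e7).
#' @param level count alleles by length designation or by sequence.
#' @return List with \code{p}, \code{method}, \code{n_tables} (enumeration)
#'   or \code{n_perm} (permutation). Monomorphic loci return p = 1.
#' @export
hweExactTest <- function(genotypes, method = c("auto", "enumerate", "permute"),
                         nPerm = 100000L, seed = NULL, maxTables = 1e7,
                         level = c("length", "sequence")) {
  method <- match.arg(method)
  g <- .gtAlleles(genotypes, level)
  if (!nrow(g)) stop("no complete genotypes")
  obs <- .gtCountMatrix(g$a, g$b)
  alleles <- rownames(obs)
  k <- length(alleles)
  if (k == 1L)
    return(list(p = 1.0, method = "monomorphic"))
  # allele margin from the symmetric view of the genotype-count matrix
  sym <- obs + t(obs)
  diag(sym) <- 2L * diag(obs)
  counts <- as.integer(rowSums(sym))
  names(counts) <- alleles
  if (method == "auto") {
    # crude upper bound on table count: prod over het cells of min margins
    est <- 1
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      est <- est * (min(counts[i], counts[j]) + 1)
    method <- if (est <= maxTables) "enumerate" else "permute"
  }
  logpObs <- .logTableProb(obs, counts)
  tol <- 1e-9
  if (method == "enumerate") {
    env <- new.env()
    env$p <- 0
    env$n <- 0L
    .enumTables(counts, function(gm) {
      lp <- .logTableProb(gm, counts)
      env$n <- env$n + 1L
      if (lp <= logpObs + tol) env$p <- env$p + exp(lp)
    })
    list(p = min(1, env$p), method = "enumerate", n_tables = env$n)
  } else {
    if (is.null(seed)) stop("permutation method requires a seed")
    pool <- rep.int(seq_len(k), counts)
    N <- length(pool) %/% 2L
    # log prob differs across tables only through H log 2 - sum log g!
    const <- lfactorial(N) + sum(lfactorial(counts)) - lfactorial(2 * N)
    statObs <- logpObs - const
    hits <- 0L
    set.seed(seed)
    for (r in seq_len(nPerm)) {
      perm <- sample(pool)
      ia <- perm[seq_len(N)]
      ib <- perm[N + seq_len(N)]
      lo <- pmin(ia, ib)
      hi <- pmax(ia, ib)
      g <- tabulate((hi - 1L) * k + lo, nbins = k * k)
      stat <- sum(lo != hi) * log(2) - sum(lfactorial(g[g > 0L]))
      if (stat <= statObs + tol) hits <- hits + 1L
    }
    list(p = (hits + 1) / (nPerm + 1), method = "permute", n_perm = nPerm)
  }
}

#' Per-locus forensic summary of a cohort
#'
#' @param genotypes genotype data.frame with columns \code{locus},
#'   \code{des_a}, \code{des_b} (and optionally \code{seq_a}, \code{seq_b}).
#' @param hweSeed seed forwarded to \code{\link{hweExactTest}}.
#' @param hweNPerm permutations for the Monte-Carlo fallback at
#'   many-allele loci (cohort-scale default 5000).
#' @param level count alleles by length designation or by sequence.
#' @return data.frame, one row per locus: N, h_obs, h_exp, hom_exp, mp, pd,
#'   pe, tpi, hwe_p.
#' @export
locusPopStats <- function(genotypes, hweSeed = 1L, hweNPerm = 5000L,
                          level = c("length", "sequence")) {
  level <- match.arg(level)
  sp <- split(genotypes, genotypes$locus)
  out <- lapply(sp, function(d) {
    het <- heterozygosities(d, level)
    fp <- forensicParams(d, level)
    hwe <- hweExactTest(d, method = "auto", seed = hweSeed,
                        nPerm = hweNPerm, level = level)
    data.frame(locus = d$locus[1L], n_samples = nrow(d),
               h_obs = het$h_obs, h_exp = het$h_exp,
               hom_exp = 1 - het$h_exp,
               mp = fp$mp, pd = fp$pd, pe = fp$pe, tpi = fp$tpi,
               hwe_p = hwe$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Heterozygosity gain from sequence-level typing
#'
#' Per locus: allele totals (one count per distinct allele in each genotype)
#' at length and sequence resolution, the isometric-heterozygote count, and
#' observed heterozygosity at both levels, plus the global reclassification
#' rate. Structural identity: sequence total = length total + isoalleles.
#'
#' @param genotypes genotype data.frame with sequence detail (see
#'   \code{\link{detectIsoalleles}}).
#' @return List with \code{by_locus} data.frame and the global
#'   \code{n_reclassified} / \code{reclassified_pct}.
#' @export
heterozygosityGain <- function(genotypes) {
  iso <- detectIsoalleles(genotypes)
  g <- iso$genotypes
  seqB <- ifelse(is.na(g$seq_b), g$seq_a, g$seq_b)
  desB <- ifelse(is.na(g$des_b), g$des_a, g$des_b)
  lenDistinct <- 1L + as.integer(g$des_a != desB)
  seqDistinct <- 1L + as.integer(g$seq_a != seqB)
  byLocus <- do.call(rbind, lapply(split(seq_len(nrow(g)), g$locus),
    function(idx) data.frame(
      locus = g$locus[idx[1L]],
      total_alleles_length = sum(lenDistinct[idx]),
      total_alleles_sequence = sum(seqDistinct[idx]),
      isoalleles = sum(g$class[idx] == "length_hom_seq_het"),
      h_obs_length = round(mean(g$des_a[idx] != desB[idx]), 2),
      h_obs_sequence = round(mean(g$seq_a[idx] != seqB[idx]), 2))))
  rownames(byLocus) <- NULL
  list(by_locus = byLocus,
       n_reclassified = iso$n_reclassified,
       reclassified_pct = iso$reclassified_pct)
}
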