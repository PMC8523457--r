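# shared fixtures: everything is built in code at test time

theCatalog <- defaultCatalog()

# a single-locus simulation configuration for focused generator tests
oneLocusConfig <- function(spectrum, locus = "D2S441", nSamples = 100L,
                           seed = 1L, hbShape1 = 24, hbShape2 = 4,
                           stutterIntercept = 0.01, stutterSlope = 0.009,
                           stutterSd = 0.02, readsMeanlog = log(120000),
                           readsSdlog = 0.3) {
  new("SimulationConfig",
      nSamples = as.integer(nSamples),
      spectra = setNames(list(spectrum), locus),
      readsMeanlog = readsMeanlog, readsSdlog = readsSdlog,
      markerWeights = setNames(1, locus),
      hbShape1 = hbShape1, hbShape2 = hbShape2,
      stutterParams = data.frame(locus = locus,
                                 intercept = stutterIntercept,
                                 slope = stutterSlope, sd = stutterSd,
                                 stringsAsFactors = FALSE),
      intermediateFactor = 0.7,
      dropout = data.frame(sample_id = character(), locus = character(),
                           which = character(), stringsAsFactors = FALSE),
      dropin = data.frame(sample_id = character(), locus = character(),
                          sequence_id = character(), units = integer(),
                          partial = integer(), reads = integer(),
                          stringsAsFactors = FALSE),
      seed = as.integer(seed))
}

simpleSpectrum <- function(locus, units, freq, iso = FALSE) {
  sp <- data.frame(sequence_id = paste0(locus, ":", units),
                   units = as.integer(units), partial = 0L,
                   variant_ids = "", freq = freq, stringsAsFactors = FALSE)
  if (iso) {
    v <- sp[1L, , drop = FALSE]
    v$sequence_id <- paste0(v$sequence_id, ":v1")
    v$freq <- sp$freq[1L] / 2
    sp$freq[1L] <- sp$freq[1L] / 2
    sp <- rbind(sp, v)
  }
  sp
}

# brute-force HWE p-value: enumerate every ordering of the allele vector,
# pair consecutive entries and accumulate the exact table distribution
bruteForceHweP <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  N <- n / 2
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  tabKey <- function(x, y) paste(sort(paste(pmin(x, y), pmax(x, y))),
                                 collapse = "|")
  all <- perms(pool)
  keys <- vapply(all, function(v)
    tabKey(v[seq_len(N)], v[N + seq_len(N)]), "")
  probs <- table(keys) / length(keys)
  obs <- probs[[tabKey(a, b)]]
  sum(probs[probs <= obs + 1e-12])
}
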