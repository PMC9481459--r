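# Shared test fixtures, built in code.

GUIDE_A <- "ACGTTGCAGGTCAATCCGGA"   # 50% GC
GUIDE_B <- "TTGACCGTAGCAGTCGATCC"

# Small unique-sequence genome with planted copies of GUIDE_A.
fixture_genome <- function(copies = 4L, chrom_len = 60000L, seed = 3L,
                           n_chrom = 1L, ...) {
  make_genome(n_chrom = n_chrom, chrom_len = chrom_len,
              planted = list(list(guide = GUIDE_A, copies = copies)),
              seed = seed, ...)
}

# A deterministic + strand site on a given genome (no planting needed).
site_at <- function(chrom, start, strand, guide = GUIDE_A, g = NULL) {
  target_sites(chrom, start, strand, guide, g = g)
}

# Brute-force single-end scan oracle: all exact occurrences of `pat`
# (both strands) in a genome, as (chrom, strand, start).
oracle_scan <- function(pat, g) {
  out <- list()
  plen <- nchar(pat)
  for (chrom in names(g)) {
    s <- g[[chrom]]
    n <- nchar(s)
    subs <- substring(s, 1:(n - plen + 1L), plen:n)
    for (strand in c("+", "-")) {
      want <- if (strand == "+") pat else reverse_complement(pat)
      idx <- which(subs == want) - 1L
      if (length(idx)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, start = idx,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0)))
  }
  do.call(rbind, out)
}
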