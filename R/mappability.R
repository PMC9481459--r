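#' Configuration for paired-end read simulation around cut sites
#'
#' Defaults follow the published simulation: 100 paired-end fragments per
#' site, fragment lengths uniform on 200-600 bp, fragments chosen uniformly to
#' span the cut, reside PAM-distal, or reside PAM-proximal, with one-sided
#' edge-to-cut distances drawn from an exponential distribution. Mate lengths
#' of 36 and 75 bp correspond to the two simulated sequencing modes. The
#' exponential mean is a free parameter of this implementation (the source
#' protocol states the distribution but not its rate); the 150 bp default is
#' on the scale of ChIP fragment sizes.
#'
#' @param reads_per_site fragments simulated per site.
#' @param frag_len_min,frag_len_max uniform fragment-length bounds (bp).
#' @param read_len mate length in bp (36 or 75 in the published setup).
#' @param category_probs probabilities for `span`, `pam_distal`,
#'   `pam_proximal` fragment placement.
#' @param edge_offset_mean mean (bp) of the exponential edge-to-cut distance
#'   for one-sided fragments.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(reads_per_site = 100L,
                       frag_len_min = 200L, frag_len_max = 600L,
                       read_len = 36L,
                       category_probs = c(span = 1/3, pam_distal = 1/3,
                                          pam_proximal = 1/3),
                       edge_offset_mean = 150) {
  stopifnot(frag_len_min <= frag_len_max,
            abs(sum(category_probs) - 1) < 1e-8,
            read_len < frag_len_min)
  structure(list(reads_per_site = as.integer(reads_per_site),
                 frag_len_min = as.integer(frag_len_min),
                 frag_len_max = as.integer(frag_len_max),
                 read_len = as.integer(read_len),
                 category_probs = category_probs,
                 edge_offset_mean = edge_offset_mean),
            class = "sim_config")
}

#' Simulate paired-end fragments around cut sites
#'
#' Each fragment either strictly spans the cut, or resides entirely on the
#' PAM-distal or PAM-proximal side with its cut-facing edge at an
#' exponentially distributed distance from the cut. Fragment lengths are
#' uniform on `[frag_len_min, frag_len_max]`. Fragments that would extend past
#' the chromosome are resampled (bounded retries).
#'
#' @param sites non-empty site table.
#' @param g a [genome()] (for chromosome bounds).
#' @param cfg a [sim_config()].
#' @param seed integer seed; the same seed reproduces the same fragments.
#' @return [fragments()] table with extra columns `site` (row index into
#'   `sites`), `category` and `truth_start` (= start; recorded origin).
#' @export
simulate_fragments <- function(sites, g, cfg = sim_config(), seed = 1L) {
  if (nrow(sites) == 0L) stop("no sites")
  set.seed(seed)
  lens <- genome_lengths(g)
  cats <- names(cfg$category_probs)
  n <- cfg$reads_per_site * nrow(sites)
  chrom <- character(n); f0 <- integer(n); f1 <- integer(n)
  site_idx <- integer(n); category <- character(n)
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    cc <- sites$cut[i]; strand <- sites$strand[i]
    chr <- sites$chrom[i]; chr_len <- lens[[chr]]
    # genomic direction of the PAM-proximal side: +1 = right
    prox_dir <- if (strand == "+") 1L else -1L
    for (r in seq_len(cfg$reads_per_site)) {
      cat_r <- sample(cats, 1L, prob = cfg$category_probs)
      for (attempt in 1:100) {
        L <- sample(cfg$frag_len_min:cfg$frag_len_max, 1L)
        if (cat_r == "span") {
          # require f0 < c-1 and f1 > c
          lo <- cc - L + 1L; hi <- cc - 2L
          if (hi < lo) next
          s <- sample(lo:hi, 1L)
        } else {
          d <- ceiling(rexp(1L, rate = 1 / cfg$edge_offset_mean))
          on_right <- (cat_r == "pam_proximal") == (prox_dir == 1L)
          s <- if (on_right) cc + d else cc - d - L
        }
        if (s >= 0L && s + L <= chr_len) break
        s <- NA_integer_
      }
      if (is.na(s)) stop("could not place fragment inside chromosome ", chr)
      k <- k + 1L
      chrom[k] <- chr; f0[k] <- s; f1[k] <- s + L
      site_idx[k] <- i; category[k] <- cat_r
    }
  }
  out <- fragments(chrom, f0, f1, library_size = n)
  out$site <- site_idx
  out$category <- category
  out$truth_start <- out$start
  out
}

#' Extract paired mate sequences from fragments
#'
#' Mate 1 is the first `read_len` bases of the fragment on the forward strand;
#' mate 2 is the reverse complement of the last `read_len` bases.
#'
#' @param frags [fragments()] table.
#' @param g a [genome()].
#' @param read_len mate length (must not exceed any fragment length).
#' @return data.frame with columns `mate1`, `mate2` plus the fragment
#'   coordinates.
#' @export
fragments_to_reads <- function(frags, g, read_len) {
  if (any(frags$end - frags$start < read_len)) {
    stop("fragment shorter than read length")
  }
  m1 <- character(nrow(frags)); m2 <- character(nrow(frags))
  for (i in seq_len(nrow(frags))) {
    m1[i] <- genome_slice(g, frags$chrom[i], frags$start[i],
                          frags$start[i] + read_len)
    m2[i] <- reverse_complement(
      genome_slice(g, frags$chrom[i], frags$end[i] - read_len, frags$end[i]))
  }
  data.frame(chrom = frags$chrom, start = frags$start, end = frags$end,
             mate1 = m1, mate2 = m2, stringsAsFactors = FALSE)
}

#' Write reads to FASTA or FASTQ
#'
#' @param seqs character vector of read sequences.
#' @param path output path.
#' @param format `"fasta"` or `"fastq"` (constant quality `I`).
#' @param ids read identifiers.
#' @export
write_reads <- function(seqs, path, format = c("fasta", "fastq"),
                        ids = sprintf("read%06d", seq_along(seqs))) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(rbind(paste0(">", ids), seqs), path)
  } else {
    writeLines(rbind(paste0("@", ids), seqs, "+",
                     vapply(nchar(seqs), function(n) strrep("I", n), "")),
               path)
  }
  invisible(path)
}

#' Read sequences from FASTQ
#' @param path FASTQ path.
#' @return named character vector of sequences.
#' @export
read_fastq <- function(path) {
  x <- readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# All end-to-end alignments of a single sequence (both strands) within max_mm
# substitutions. Returns data.frame(chrom, strand, start, mm). Exact matching
# (max_mm = 0, the default) uses plain fixed-string search; the mismatch-
# tolerant path goes through Biostrings.
align_single <- function(seq, g, max_mm) {
  pat_f <- toupper(seq)
  pat_r <- reverse_complement(pat_f)
  out <- list()
  for (chrom in names(g)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_f else pat_r
      if (max_mm == 0L) {
        # zero-width lookahead so overlapping occurrences are all reported
        m <- gregexpr(paste0("(?=", pat, ")"), g[[chrom]], perl = TRUE)[[1]]
        if (m[1] == -1L) next
        starts <- as.integer(m) - 1L
        mm <- numeric(length(starts))
      } else {
        hits <- matchPattern(DNAString(pat), DNAString(g[[chrom]]),
                             max.mismatch = max_mm, fixed = TRUE)
        if (length(hits) == 0L) next
        pat_chars <- strsplit(pat, "")[[1]]
        mm <- vapply(seq_along(hits), function(j) {
          sum(strsplit(as.character(hits[[j]]), "")[[1]] != pat_chars)
        }, numeric(1))
        starts <- start(hits) - 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, strand = strand, start = starts, mm = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), mm = numeric(0)))
  }
  do.call(rbind, out)
}

#' Naive exhaustive paired-end aligner (internal oracle)
#'
#' End-to-end, substitution-only alignment of a mate pair by exhaustive
#' genome scan: concordant orientations only (mate 1 forward / mate 2 reverse,
#' or mirrored), ordered mates, implied fragment length at most `max_frag`
#' (1,000 bp default, the concordance window of the published alignment
#' command). Score is minus the total mismatch count. Hits are sorted by score
#' then coordinate and truncated at `max_hits`; `is_best` marks maximal-score
#' hits and `best_is_unique` is TRUE when exactly one hit attains the maximum
#' (uniqueness judged on score only).
#'
#' @param mate1,mate2 mate sequences.
#' @param g a [genome()].
#' @param max_hits maximum hits returned.
#' @param max_mm substitutions tolerated per mate.
#' @param max_frag maximum implied fragment length.
#' @return data.frame with columns chrom, strand, start (fragment start), end
#'   (fragment end), score, is_best, best_is_unique; zero rows if unaligned.
#' @export
naive_align <- function(mate1, mate2, g, max_hits = 10L, max_mm = 0L,
                        max_frag = 1000L) {
  stopifnot(max_hits >= 1L)
  h1 <- align_single(mate1, g, max_mm)
  h2 <- align_single(mate2, g, max_mm)
  len1 <- nchar(mate1); len2 <- nchar(mate2)
  pairs <- list()
  add_pairs <- function(fwd, rev, len_f, len_r) {
    # fwd mate on + strand starting the fragment; rev mate on - strand ending it
    for (a in seq_len(nrow(fwd))) {
      cand <- rev[rev$chrom == fwd$chrom[a], , drop = FALSE]
      if (nrow(cand) == 0L) next
      f0 <- fwd$start[a]
      f1 <- cand$start + len_r
      ok <- cand$start >= f0 & (f1 - f0) <= max_frag & (f1 - f0) >= len_f
      if (!any(ok)) next
      pairs[[length(pairs) + 1L]] <<- data.frame(
        chrom = fwd$chrom[a], strand = "+", start = f0, end = f1[ok],
        score = -(fwd$mm[a] + cand$mm[ok]), stringsAsFactors = FALSE)
    }
  }
  add_pairs(h1[h1$strand == "+", , drop = FALSE],
            h2[h2$strand == "-", , drop = FALSE], len1, len2)
  add_pairs(h2[h2$strand == "+", , drop = FALSE],
            h1[h1$strand == "-", , drop = FALSE], len2, len1)
  if (length(pairs) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      is_best = logical(0), best_is_unique = logical(0)))
  }
  hits <- unique(do.call(rbind, pairs))
  hits <- hits[order(-hits$score, hits$chrom, hits$start, hits$end), , drop = FALSE]
  if (nrow(hits) > max_hits) hits <- hits[seq_len(max_hits), , drop = FALSE]
  best <- max(hits$score)
  hits$is_best <- hits$score == best
  hits$best_is_unique <- sum(hits$is_best) == 1L
  rownames(hits) <- NULL
  hits
}

#' Proportion of ambiguously aligned read pairs
#'
#' A read pair counts as unambiguous when its best alignment coincides with
#' its recorded origin AND that best alignment score is uniquely best. The
#' ambiguous proportion is 1 minus the unambiguous fraction.
#'
#' @param hits_list list of hit tables (one per read pair, as returned by
#'   [naive_align()]).
#' @param truths data.frame with columns `chrom` and `start` giving each
#'   pair's true fragment origin.
#' @return fraction in `[0, 1]`.
#' @export
ambiguity_proportion <- function(hits_list, truths) {
  n <- length(hits_list)
  if (n == 0L) stop("no read pairs")
  stopifnot(nrow(truths) == n)
  unambiguous <- vapply(seq_len(n), function(i) {
    h <- hits_list[[i]]
    if (nrow(h) == 0L) return(FALSE)
    b <- h[h$is_best, , drop = FALSE]
    b$best_is_unique[1] && b$chrom[1] == truths$chrom[i] &&
      b$start[1] == truths$start[i]
  }, logical(1))
  1 - mean(unambiguous)
}

#' Single-end ambiguity (each mate scored independently)
#'
#' Companion to [ambiguity_proportion()] for interpreting a pair as two
#' single-end reads: a mate is unambiguous when its uniquely best single-end
#' alignment is at its true position.
#'
#' @param reads data.frame from [fragments_to_reads()].
#' @param g a [genome()].
#' @param max_mm substitutions tolerated.
#' @return fraction of mates ambiguous, in `[0, 1]`.
#' @export
single_end_ambiguity <- function(reads, g, max_mm = 0L) {
  read_len <- nchar(reads$mate1[1])
  n_ok <- 0L; n <- 0L
  for (i in seq_len(nrow(reads))) {
    for (mate in 1:2) {
      seq_i <- if (mate == 1) reads$mate1[i] else reads$mate2[i]
      truth_start <- if (mate == 1) reads$start[i] else reads$end[i] - read_len
      h <- align_single(seq_i, g, max_mm)
      n <- n + 1L
      if (nrow(h) == 0L) next
      best <- min(h$mm)
      b <- h[h$mm == best, , drop = FALSE]
      if (nrow(b) == 1L && b$chrom[1] == reads$chrom[i] &&
          b$start[1] == truth_start) n_ok <- n_ok + 1L
    }
  }
  1 - n_ok / n
}

#' Mappability of real fragments around binding sites
#'
#' Extracts fragments lying within `window_bp`-wide windows centred at each
#' site's cut coordinate, reconstructs mate sequences from the genome,
#' re-aligns them with [naive_align()] and returns the ambiguous proportion.
#' Default window widths follow the published analysis: 1,500 bp for Cas9
#' ChIP-seq and 2,500 bp for MRE11.
#'
#' @param frags [fragments()] table.
#' @param sites site table.
#' @param g a [genome()].
#' @param window_bp full window width centred at the cut.
#' @param read_len mate length for reconstruction.
#' @param max_hits,max_mm passed to [naive_align()].
#' @return fraction ambiguous.
#' @export
real_read_ambiguity <- function(frags, sites, g, window_bp = 1500L,
                                read_len = 36L, max_hits = 10L, max_mm = 0L) {
  half <- window_bp / 2
  sel <- rep(FALSE, nrow(frags))
  for (i in seq_len(nrow(sites))) {
    sel <- sel | (frags$chrom == sites$chrom[i] &
                    frags$end > sites$cut[i] - half &
                    frags$start < sites$cut[i] + half)
  }
  sub <- frags[sel, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no fragments within any site window")
  reads <- fragments_to_reads(sub, g, read_len)
  hits <- lapply(seq_len(nrow(reads)), function(i) {
    naive_align(reads$mate1[i], reads$mate2[i], g,
                max_hits = max_hits, max_mm = max_mm)
  })
  ambiguity_proportion(hits, data.frame(chrom = sub$chrom, start = sub$start))
}

#' Ingest paired-end alignments from a SAM file
#'
#' Adapter contract for an external aligner: reads a (headered or headerless)
#' SAM file of proper pairs and reduces each pair to a fragment interval
#' (leftmost mate start to rightmost mate end), converting SAM's 1-based
#' coordinates to this package's 0-based half-open convention.
#'
#' @param path SAM file path.
#' @param library_size RPM denominator; defaults to the number of fragments.
#' @return [fragments()] table.
#' @export
read_fragments_sam <- function(path, library_size = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) stop("no alignment records in ", path)
  f <- strsplit(lines, "\t")
  qname <- vapply(f, `[`, "", 1L)
  flag <- as.integer(vapply(f, `[`, "", 2L))
  chrom <- vapply(f, `[`, "", 3L)
  pos <- as.integer(vapply(f, `[`, "", 4L)) - 1L   # SAM is 1-based
  seqlen <- nchar(vapply(f, `[`, "", 10L))
  keep <- chrom != "*" & bitwAnd(flag, 4L) == 0L
  qname <- qname[keep]; chrom <- chrom[keep]
  pos <- pos[keep]; seqlen <- seqlen[keep]
  sp <- split(seq_along(qname), qname)
  rows <- lapply(sp, function(idx) {
    data.frame(chrom = chrom[idx[1]], start = min(pos[idx]),
               end = max(pos[idx] + seqlen[idx]), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  fragments(df$chrom, df$start, df$end, library_size = library_size)
}
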