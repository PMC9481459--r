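#' Discovery configuration for multi-target guide enumeration
#'
#' Parameters of the template-to-guide enumeration and genome search. The
#' defaults follow the published protocol: up to 3 substitutions confined to
#' the 9 most PAM-proximal protospacer positions, GC content restricted to the
#' inclusive band \[0.40, 0.70\], NGG PAM, and at most 1,000 on-target sites
#' evaluated per guide.
#'
#' @param max_template_mismatches maximum substitutions from the template.
#' @param mismatch_zone number of PAM-proximal positions in which
#'   substitutions are allowed.
#' @param gc_min,gc_max inclusive GC-fraction bounds (set to `0`/`1` to
#'   disable filtering).
#' @param site_cap maximum on-target sites retained per guide.
#' @param genome_search_mismatches substitutions tolerated when matching a
#'   guide against the genome (0 = exact, the reproducible default).
#' @return list of class `discovery_config`.
#' @export
discovery_config <- function(max_template_mismatches = 3L,
                             mismatch_zone = 9L,
                             gc_min = 0.40, gc_max = 0.70,
                             site_cap = 1000L,
                             genome_search_mismatches = 0L) {
  stopifnot(max_template_mismatches >= 0,
            max_template_mismatches <= mismatch_zone,
            mismatch_zone <= 20,
            gc_min <= gc_max, site_cap >= 1,
            genome_search_mismatches >= 0)
  structure(list(max_template_mismatches = as.integer(max_template_mismatches),
                 mismatch_zone = as.integer(mismatch_zone),
                 gc_min = gc_min, gc_max = gc_max,
                 site_cap = as.integer(site_cap),
                 genome_search_mismatches = as.integer(genome_search_mismatches)),
            class = "discovery_config")
}

# All substitution patterns touching <= max_mm of the `zone` most PAM-proximal
# positions: list of (string indices, replacement-choice indices). The
# PAM-proximal end is the 3' end of the 20-mer, i.e. string indices 21 - zone
# .. 20.
substitution_patterns <- function(max_mm, zone) {
  pats <- list(list(pos = integer(0), alt = integer(0)))
  if (max_mm == 0L) return(pats)
  zone_idx <- (20L - zone + 1L):20L
  for (k in seq_len(max_mm)) {
    combos <- combn(zone_idx, k)
    alts <- as.matrix(expand.grid(rep(list(1:3), k)))
    for (j in seq_len(ncol(combos))) {
      for (a in seq_len(nrow(alts))) {
        pats[[length(pats) + 1L]] <- list(pos = combos[, j],
                                          alt = as.integer(alts[a, ]))
      }
    }
  }
  pats
}

# The 3 bases different from `base`, in fixed A<C<G<T order.
ALT_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Enumerate multi-target guide candidates from a template
#'
#' For every 20-nt substring of the template and of its reverse complement
#' (each treated as a protospacer whose PAM-proximal end is the 3' end of the
#' substring on its strand), emits the substring plus every variant with 1 to
#' `max_template_mismatches` substitutions confined to the `mismatch_zone`
#' most PAM-proximal positions, filters by GC fraction (inclusive bounds) and
#' deduplicates to unique sequences.
#'
#' @param template nucleotide string, length >= 20, alphabet A/C/G/T.
#' @param cfg a [discovery_config()].
#' @param strands which template strands to enumerate (default both).
#' @return data.frame with columns `sequence`, `template_offset` (0-based
#'   offset of the originating substring on its strand), `template_strand`,
#'   `n_template_mismatch`, `gc` — one row per unique sequence (first
#'   provenance kept).
#' @export
enumerate_candidates <- function(template, cfg = discovery_config(),
                                 strands = c("+", "-")) {
  template <- toupper(template)
  if (nchar(template) < 20L) stop("template shorter than 20 nt")
  if (grepl("[^ACGT]", template)) stop("template must contain only A/C/G/T")
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)

  pats <- substitution_patterns(cfg$max_template_mismatches, cfg$mismatch_zone)
  seq_chunks <- list(); off_chunks <- list()
  str_chunks <- list(); nmm_chunks <- list()

  for (strand in strands) {
    tpl <- if (strand == "+") template else reverse_complement(template)
    n_sub <- nchar(tpl) - 19L
    subs <- substring(tpl, 1:n_sub, 20:nchar(tpl))
    chars <- matrix(unlist(strsplit(subs, ""), use.names = FALSE),
                    nrow = n_sub, ncol = 20L, byrow = TRUE)
    alt_lookup <- vapply(ALT_BASES, identity, character(3))  # 3 x 4, cols A,C,G,T
    for (p in pats) {
      m <- chars
      for (i in seq_along(p$pos)) {
        col <- p$pos[i]
        m[, col] <- alt_lookup[p$alt[i], chars[, col]]
      }
      k <- length(seq_chunks) + 1L
      seq_chunks[[k]] <- do.call(paste0, asplit(m, 2))
      off_chunks[[k]] <- 0:(n_sub - 1L)
      str_chunks[[k]] <- rep(strand, n_sub)
      nmm_chunks[[k]] <- rep(length(p$pos), n_sub)
    }
  }

  out <- data.frame(sequence = unlist(seq_chunks),
                    template_offset = unlist(off_chunks),
                    template_strand = unlist(str_chunks),
                    n_template_mismatch = unlist(nmm_chunks),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  out$gc <- gc_fraction(out$sequence)
  keep <- out$gc >= cfg$gc_min & out$gc <= cfg$gc_max
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find genomic on-target sites of a guide
#'
#' Scans both strands of the genome for occurrences of the 20-nt guide
#' (within `cfg$genome_search_mismatches` substitutions) immediately followed
#' by an NGG PAM on the occurrence's strand. `N` anywhere in the protospacer
#' or PAM disqualifies the locus. Sites are returned in deterministic order
#' (chromosome name lexicographic, then cut coordinate ascending) and
#' truncated at `cfg$site_cap`.
#'
#' @param candidate 20-nt guide sequence.
#' @param g a [genome()].
#' @param cfg a [discovery_config()].
#' @return site table (see [target_sites()]), possibly empty.
#' @export
find_on_targets <- function(candidate, g, cfg = discovery_config()) {
  candidate <- toupper(candidate)
  if (nchar(candidate) != 20L) stop("candidate must be 20 nt")
  stopifnot(inherits(g, "genome"))
  mm <- cfg$genome_search_mismatches
  pat_f <- DNAString(candidate)
  pat_r <- reverseComplement(pat_f)

  chroms <- character(0); starts <- integer(0); strands <- character(0)
  for (chrom in names(g)) {
    subj <- DNAString(g[[chrom]])
    len <- length(subj)
    # + strand: guide at [s, s+20), PAM NGG at [s+20, s+23)
    hits <- matchPattern(pat_f, subj, max.mismatch = mm, fixed = TRUE)
    for (s in start(hits) - 1L) {
      if (s + 23L > len) next
      pam <- genome_slice(g, chrom, s + 20L, s + 23L)
      proto <- genome_slice(g, chrom, s, s + 20L)
      if (is_ngg(pam) && !grepl("N", proto, fixed = TRUE)) {
        chroms <- c(chroms, chrom); starts <- c(starts, s)
        strands <- c(strands, "+")
      }
    }
    # - strand: genome shows revcomp(guide) at [s, s+20), revcomp PAM (CCN)
    # at [s-3, s)
    hits <- matchPattern(pat_r, subj, max.mismatch = mm, fixed = TRUE)
    for (s in start(hits) - 1L) {
      if (s < 3L) next
      pam <- reverse_complement(genome_slice(g, chrom, s - 3L, s))
      proto <- genome_slice(g, chrom, s, s + 20L)
      if (is_ngg(pam) && !grepl("N", proto, fixed = TRUE)) {
        chroms <- c(chroms, chrom); starts <- c(starts, s)
        strands <- c(strands, "-")
      }
    }
  }
  sites <- target_sites(chroms, starts, strands, candidate, g = g)
  ord <- order(sites$chrom, sites$cut, sites$strand)
  sites <- sites[ord, , drop = FALSE]
  if (nrow(sites) > cfg$site_cap) sites <- sites[seq_len(cfg$site_cap), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Spacing statistics between adjacent on-target sites
#'
#' Distances between consecutive cut coordinates of sites on the same
#' chromosome; chromosomes with fewer than two sites contribute no pairs.
#'
#' @param sites site table.
#' @return list with `mean_adjacent_bp`, `median_adjacent_bp`, `n_pairs` and
#'   `defined` (FALSE when no chromosome carries two sites, in which case the
#'   statistics are `NA`).
#' @export
site_spacing_stats <- function(sites) {
  gaps <- numeric(0)
  for (chrom in unique(sites$chrom)) {
    cuts <- sort(sites$cut[sites$chrom == chrom])
    if (length(cuts) >= 2L) gaps <- c(gaps, diff(cuts))
  }
  if (length(gaps) == 0L) {
    return(list(mean_adjacent_bp = NA_real_, median_adjacent_bp = NA_real_,
                n_pairs = 0L, defined = FALSE))
  }
  list(mean_adjacent_bp = mean(gaps), median_adjacent_bp = median(gaps),
       n_pairs = length(gaps), defined = TRUE)
}

#' Per-position nucleotide composition around cut sites
#'
#' For each offset in `[-radius, radius)` relative to the cut (windows
#' oriented PAM-downstream via [oriented_window()]), the fraction of each base
#' across all sites. `N`-padded positions are excluded from the denominator,
#' so fractions at every offset with at least one real base sum to 1.
#'
#' @param g a [genome()].
#' @param sites non-empty site table.
#' @param radius window half-width in bp (the published composition analysis
#'   used 500).
#' @return data.frame with columns `offset`, `A`, `C`, `G`, `T`, `n`.
#' @export
nucleotide_composition <- function(g, sites, radius = 500L) {
  if (nrow(sites) == 0L) stop("no sites")
  wins <- vapply(seq_len(nrow(sites)),
                 function(i) oriented_window(g, sites[i, ], radius), "")
  m <- matrix(unlist(strsplit(wins, ""), use.names = FALSE),
              nrow = length(wins), ncol = 2L * radius, byrow = TRUE)
  offs <- seq.int(-radius, radius - 1L)
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(m == b), numeric(ncol(m)))
  n_real <- rowSums(counts)
  frac <- counts / pmax(n_real, 1)
  data.frame(offset = offs, A = frac[, "A"], C = frac[, "C"],
             G = frac[, "G"], T = frac[, "T"], n = n_real)
}

interval_label_at <- function(intervals, chrom, pos) {
  # intervals: data.frame(chrom, start, end[, label]); half-open lookup
  if (is.null(intervals) || !chrom %in% intervals$chrom) return(NA_character_)
  sel <- intervals$chrom == chrom & intervals$start <= pos & intervals$end > pos
  if (!any(sel)) return("")
  if ("label" %in% names(intervals)) intervals$label[which(sel)[1]] else "hit"
}

#' Annotate sites with gene context and chromatin-state consensus
#'
#' `refseq_label` is `"genic"` when the cut coordinate falls inside any gene
#' interval, else `"intergenic"`. `chromhmm_label` is the plurality label at
#' the cut across the supplied segmentation tracks (the published analysis
#' used four cell lines); ties are broken by a fixed priority order (by
#' default labels sorted by increasing total annotated bp across the tracks,
#' so rarer states win ties). A track missing the site's chromosome
#' contributes the label `"unannotated"`.
#'
#' @param sites site table.
#' @param gene_intervals data.frame (chrom, start, end), half-open.
#' @param chromhmm_tracks list of data.frames (chrom, start, end, label).
#' @param label_priority optional character vector: earlier labels win ties.
#' @return `sites` with `refseq_label` and `chromhmm_label` columns added.
#' @export
annotate_sites <- function(sites, gene_intervals, chromhmm_tracks,
                           label_priority = NULL) {
  if (is.null(label_priority)) {
    tot <- list()
    for (tr in chromhmm_tracks) {
      bp <- tapply(tr$end - tr$start, tr$label, sum)
      for (lb in names(bp)) tot[[lb]] <- (tot[[lb]] %||% 0) + bp[[lb]]
    }
    label_priority <- names(sort(unlist(tot)))
  }
  label_priority <- c(label_priority, "unannotated")
  refseq <- character(nrow(sites)); chmm <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]; pos <- sites$cut[i]
    hit <- interval_label_at(gene_intervals, chrom, pos)
    refseq[i] <- if (!is.na(hit) && nzchar(hit)) "genic" else "intergenic"
    votes <- vapply(chromhmm_tracks, function(tr) {
      lb <- interval_label_at(tr, chrom, pos)
      if (is.na(lb)) "unannotated" else if (!nzchar(lb)) "unannotated" else lb
    }, "")
    tab <- table(votes)
    winners <- names(tab)[tab == max(tab)]
    pri <- match(winners, label_priority)
    pri[is.na(pri)] <- length(label_priority) + 1L
    chmm[i] <- winners[order(pri, winners)][1]
  }
  sites$refseq_label <- refseq
  sites$chromhmm_label <- chmm
  sites
}

#' Summarize annotation labels, grouping rare labels under "Other"
#'
#' Labels with representation below `min_frac` (default 1%) are pooled into an
#' `"Other"` category, the display convention used for chromatin-state
#' summaries.
#'
#' @param labels character vector of per-site labels.
#' @param min_frac minimum fraction for a label to be reported directly.
#' @return named numeric vector of fractions (sums to 1).
#' @export
summarize_labels <- function(labels, min_frac = 0.01) {
  frac <- table(labels) / length(labels)
  keep <- frac >= min_frac
  out <- as.numeric(frac[keep])
  names(out) <- names(frac)[keep]
  if (any(!keep)) out <- c(out, Other = sum(frac[!keep]))
  out
}
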