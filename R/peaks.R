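#' Attribute a peak to the protospacer that best explains it
#'
#' For each peak with fold enrichment at or above `min_fold`, scans both
#' strands of a `window`-bp window centred on the peak for NGG-adjacent
#' 20-mers, ranks them by mismatch count against the guide and returns the
#' minimum-mismatch site. Ties are broken by distance of the cut coordinate to
#' the peak centre, then by leftmost protospacer coordinate.
#'
#' @param peak_center genomic coordinate of the peak summit/centre (0-based).
#' @param fold_enrichment peak fold enrichment; peaks below `min_fold` are
#'   skipped.
#' @param guide 20-nt guide sequence.
#' @param g a [genome()].
#' @param chrom chromosome of the peak.
#' @param window full scan-window width in bp.
#' @param min_fold minimum fold enrichment.
#' @return one-row site table, or zero rows when skipped/unmatched (with
#'   attribute `status` = `"matched"`, `"skipped"` or `"unmatched"`).
#' @export
match_peak_to_target <- function(peak_center, fold_enrichment, guide, g,
                                 chrom, window = 400L, min_fold = 4) {
  guide <- toupper(guide)
  if (nchar(guide) != 20L) stop("guide must be 20 nt")
  if (fold_enrichment < min_fold) {
    out <- empty_sites(); attr(out, "status") <- "skipped"; return(out)
  }
  half <- window %/% 2L
  lo <- max(0L, peak_center - half)
  hi <- min(genome_lengths(g)[[chrom]], peak_center + half)
  cand <- scan_pam_sites(g, chrom, lo, hi)
  if (nrow(cand) == 0L) {
    out <- empty_sites(); attr(out, "status") <- "unmatched"; return(out)
  }
  gchars <- strsplit(guide, "")[[1]]
  cand$mm <- vapply(cand$protospacer, function(p) {
    sum(strsplit(p, "")[[1]] != gchars)
  }, numeric(1))
  cand$cut <- cut_coordinate(cand$start, cand$strand)
  cand$dist <- abs(cand$cut - peak_center)
  cand <- cand[order(cand$mm, cand$dist, cand$start, cand$strand), , drop = FALSE]
  best <- cand[1, ]
  out <- target_sites(chrom, best$start, best$strand, guide, g = g)
  attr(out, "status") <- "matched"
  out
}

# All NGG-adjacent 20-mers on both strands with protospacer fully inside
# [lo, hi) and PAM inside the chromosome. Returns protospacer in guide
# orientation.
scan_pam_sites <- function(g, chrom, lo, hi) {
  seq_len_chr <- genome_lengths(g)[[chrom]]
  starts <- integer(0); strands <- character(0); protos <- character(0)
  if (hi - lo >= 20L) {
    for (s in lo:(hi - 20L)) {
      # + strand: PAM at [s+20, s+23)
      if (s + 23L <= seq_len_chr) {
        pam <- genome_slice(g, chrom, s + 20L, s + 23L)
        proto <- genome_slice(g, chrom, s, s + 20L)
        if (is_ngg(pam) && !grepl("N", proto, fixed = TRUE)) {
          starts <- c(starts, s); strands <- c(strands, "+")
          protos <- c(protos, proto)
        }
      }
      # - strand: PAM (CCN on + strand) at [s-3, s)
      if (s >= 3L) {
        pam <- reverse_complement(genome_slice(g, chrom, s - 3L, s))
        proto <- reverse_complement(genome_slice(g, chrom, s, s + 20L))
        if (is_ngg(pam) && !grepl("N", proto, fixed = TRUE)) {
          starts <- c(starts, s); strands <- c(strands, "-")
          protos <- c(protos, proto)
        }
      }
    }
  }
  data.frame(start = starts, strand = strands, protospacer = protos,
             stringsAsFactors = FALSE)
}

#' Attribute a table of peaks to target sites
#'
#' Vectorized wrapper over [match_peak_to_target()]. Peak input follows a
#' BED-like layout: `chrom`, `start`, `end` plus optional `summit` (absolute
#' coordinate preferred as the centre; otherwise the interval midpoint is
#' used) and `fold_enrichment` columns (narrowPeak-style columns accepted).
#'
#' @param peaks data.frame of peaks.
#' @param guide 20-nt guide.
#' @param g a [genome()].
#' @param window,min_fold see [match_peak_to_target()].
#' @return data.frame with one row per peak: peak coordinates, `status`,
#'   matched site fields (`site_start`, `site_strand`, `n_mismatch`, `cut`)
#'   and `mismatch_label` from [mismatch_partition()].
#' @export
match_peaks_to_targets <- function(peaks, guide, g, window = 400L,
                                   min_fold = 4) {
  centers <- if ("summit" %in% names(peaks)) {
    as.integer(peaks$summit)
  } else {
    as.integer((peaks$start + peaks$end) %/% 2L)
  }
  fe <- if ("fold_enrichment" %in% names(peaks)) peaks$fold_enrichment
        else rep(Inf, nrow(peaks))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    m <- match_peak_to_target(centers[i], fe[i], guide, g, peaks$chrom[i],
                              window = window, min_fold = min_fold)
    status <- attr(m, "status")
    if (nrow(m) == 0L) {
      data.frame(chrom = peaks$chrom[i], peak_center = centers[i],
                 fold_enrichment = fe[i], status = status,
                 site_start = NA_integer_, site_strand = NA_character_,
                 n_mismatch = NA_integer_, cut = NA_integer_,
                 mismatch_label = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = peaks$chrom[i], peak_center = centers[i],
                 fold_enrichment = fe[i], status = status,
                 site_start = m$start, site_strand = m$strand,
                 n_mismatch = m$n_mismatch, cut = m$cut,
                 mismatch_label = mismatch_partition(m$mismatches[[1]]),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Label the zone architecture of a mismatch set
#'
#' Positions are protospacer positions counted from the PAM (1..20).
#' PAM-distal means position >= 12; PAM-proximal means position < 12. The
#' label is a zone tag plus a zero-padded count: no mismatches -> `"00"`; all
#' distal -> `"(dist) NN"`; all proximal -> `"(prox) NN"`; both -> `"(mix)
#' NN"`.
#'
#' @param mismatch_positions sorted integer vector of positions in 1..20.
#' @return character label.
#' @export
mismatch_partition <- function(mismatch_positions) {
  if (length(mismatch_positions) == 0L) return("00")
  if (any(mismatch_positions < 1L | mismatch_positions > 20L)) {
    stop("mismatch positions must be in 1..20")
  }
  n <- length(mismatch_positions)
  distal <- mismatch_positions >= 12L
  zone <- if (all(distal)) "dist" else if (all(!distal)) "prox" else "mix"
  sprintf("(%s) %02d", zone, n)
}

#' Read a BED-like / narrowPeak peak table
#'
#' Accepts 3+ column TSV. narrowPeak files (10 columns) map column 7 to
#' `fold_enrichment` and column 10 (summit offset) to an absolute `summit`;
#' otherwise a `fold_enrichment` 4th/5th column layout
#' (chrom,start,end,summit,fold_enrichment) is used when present.
#'
#' @param path TSV path.
#' @return data.frame with chrom, start, end and optional summit,
#'   fold_enrichment.
#' @export
read_peaks <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 10L) {  # narrowPeak
    out$fold_enrichment <- as.numeric(df[[7]])
    summit_off <- as.integer(df[[10]])
    out$summit <- ifelse(summit_off >= 0, out$start + summit_off,
                         (out$start + out$end) %/% 2L)
  } else {
    if (ncol(df) >= 4L) out$summit <- as.integer(df[[4]])
    if (ncol(df) >= 5L) out$fold_enrichment <- as.numeric(df[[5]])
  }
  out
}
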