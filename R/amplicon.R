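#' Build amplicon target descriptors from sites
#'
#' For each site, two key sequences are taken from the reference: `key_up`
#' ends `key_gap` bp upstream of the cut (occupying
#' `[c - key_gap - key_len, c - key_gap)`) and `key_down` starts `key_gap` bp
#' downstream (`[c + key_gap, c + key_gap + key_len)`). The expected distance
#' between the keys in an unedited read is `2 * key_gap`. The protospacer is
#' stored in genomic plus-strand orientation for read matching.
#'
#' @param sites site table.
#' @param g a [genome()].
#' @param key_gap distance (bp) from the cut to each key (default 20).
#' @param key_len key length (default 20).
#' @return data.frame with per-target columns: chrom, cut, strand,
#'   protospacer_fwd, key_up, key_down, expected_key_distance.
#' @export
amplicon_targets <- function(sites, g, key_gap = 20L, key_len = 20L) {
  n <- nrow(sites)
  key_up <- character(n); key_down <- character(n); proto <- character(n)
  for (i in seq_len(n)) {
    cc <- sites$cut[i]; chrom <- sites$chrom[i]
    key_up[i] <- genome_slice(g, chrom, cc - key_gap - key_len, cc - key_gap)
    key_down[i] <- genome_slice(g, chrom, cc + key_gap, cc + key_gap + key_len)
    proto[i] <- genome_slice(g, chrom, sites$start[i], sites$end[i])
  }
  data.frame(chrom = sites$chrom, cut = sites$cut, strand = sites$strand,
             start = sites$start, protospacer_fwd = proto,
             key_up = key_up, key_down = key_down,
             key_gap = key_gap, key_len = key_len,
             expected_key_distance = 2L * key_gap,
             stringsAsFactors = FALSE)
}

#' Demultiplex an amplicon read pair to a target
#'
#' Aligns the first 50 bp of each mate with the naive aligner and assigns the
#' pair to a target when the implied genomic locus lies within `window` bp of
#' that target's cut coordinate; the nearest target wins ties.
#'
#' @param mate1,mate2 read sequences (>= 50 bp).
#' @param targets table from [amplicon_targets()].
#' @param g a [genome()].
#' @param window assignment window in bp (default 1,000).
#' @param max_mm substitutions tolerated in the 50-bp anchor alignment.
#' @return integer target row index, or `NA` if unassigned.
#' @export
demultiplex_read <- function(mate1, mate2, targets, g, window = 1000L,
                             max_mm = 0L) {
  best_target <- NA_integer_; best_dist <- Inf
  for (seq_i in c(mate1, mate2)) {
    if (nchar(seq_i) < 50L) next
    anchor <- substr(seq_i, 1L, 50L)
    h <- align_single(anchor, g, max_mm)
    if (nrow(h) == 0L) next
    h <- h[h$mm == min(h$mm), , drop = FALSE]
    for (j in seq_len(nrow(h))) {
      d <- ifelse(targets$chrom == h$chrom[j],
                  abs(h$start[j] - targets$cut), Inf)
      if (min(d) <= window && min(d) < best_dist) {
        best_dist <- min(d)
        best_target <- which.min(d)
      }
    }
  }
  best_target
}

#' Call whether a read is edited at a target
#'
#' A mutation is called when the intact 20-nt theoretical protospacer sequence
#' (plus-strand orientation; the reverse complement is also accepted, covering
#' reads reported in either orientation) is absent from the read. Reads too
#' short to possibly contain the protospacer are indeterminate.
#'
#' @param read read sequence.
#' @param target one-row slice of [amplicon_targets()].
#' @return `"edited"`, `"unedited"` or `"indeterminate"`.
#' @export
call_mutation <- function(read, target) {
  read <- toupper(read)
  if (nchar(read) < 20L) return("indeterminate")
  proto <- target$protospacer_fwd[1]
  found <- grepl(proto, read, fixed = TRUE) ||
    grepl(reverse_complement(proto), read, fixed = TRUE)
  if (found) "unedited" else "edited"
}

locate_once <- function(read, key) {
  m <- gregexpr(key, read, fixed = TRUE)[[1]]
  if (length(m) != 1L || m[1] == -1L) return(NA_integer_)
  as.integer(m[1])  # 1-based position in read
}

#' Classify the editing outcome of an edited read
#'
#' Both key sequences must occur exactly once in the read (in order). The
#' observed between-key distance `d` is compared with the expected distance
#' `e`: `d < e` is a deletion of size `e - d`; `d > e` an insertion of size
#' `d - e`; `d == e` with a mutated protospacer an SNV. Subclasses follow the
#' five standard categories: deletions of at most 5 bp (`del<=5`), longer
#' deletions (`del>5`), 1-bp insertions (`ins=1`), longer insertions
#' (`ins>1`), and `SNV`.
#'
#' @param read read sequence (assumed edited per [call_mutation()]).
#' @param target one-row slice of [amplicon_targets()].
#' @return list of class `outcome_call`: `class` (deletion / insertion / SNV /
#'   unclassified), `size`, `subclass`.
#' @export
classify_outcome <- function(read, target) {
  read <- toupper(read)
  p_up <- locate_once(read, target$key_up[1])
  p_dn <- locate_once(read, target$key_down[1])
  if (is.na(p_up) || is.na(p_dn) ||
      p_dn <= p_up + nchar(target$key_up[1]) - 1L) {
    return(structure(list(class = "unclassified", size = NA_integer_,
                          subclass = "unclassified"), class = "outcome_call"))
  }
  d <- p_dn - (p_up + nchar(target$key_up[1]))
  e <- target$expected_key_distance[1]
  if (d < e) {
    size <- e - d
    structure(list(class = "deletion", size = size,
                   subclass = if (size <= 5L) "del<=5" else "del>5"),
              class = "outcome_call")
  } else if (d > e) {
    size <- d - e
    structure(list(class = "insertion", size = size,
                   subclass = if (size == 1L) "ins=1" else "ins>1"),
              class = "outcome_call")
  } else {
    structure(list(class = "SNV", size = 0L, subclass = "SNV"),
              class = "outcome_call")
  }
}

#' @export
print.outcome_call <- function(x, ...) {
  cat(sprintf("outcome: %s (size %s, subclass %s)\n",
              x$class, ifelse(is.na(x$size), "-", x$size), x$subclass))
  invisible(x)
}

#' Side attribution of a deletion relative to the cut
#'
#' Reconstructs the deleted reference interval from the key-anchored,
#' left-aligned comparison of the between-key read segment with the reference,
#' counts deleted bases on the PAM-proximal versus PAM-distal side of the cut
#' and returns the majority side (`"balanced"` on an exact tie, `"n/a"` when
#' the interval cannot be reconstructed).
#'
#' @param read edited read sequence.
#' @param target one-row slice of [amplicon_targets()].
#' @param g a [genome()] (reference for the between-key segment).
#' @return `"proximal"`, `"distal"`, `"balanced"` or `"n/a"`.
#' @export
deletion_side <- function(read, target, g) {
  oc <- classify_outcome(read, target)
  if (oc$class != "deletion") return("n/a")
  read <- toupper(read)
  key_len <- target$key_len[1]; gap <- target$key_gap[1]
  cc <- target$cut[1]
  p_up <- locate_once(read, target$key_up[1])
  p_dn <- locate_once(read, target$key_down[1])
  read_mid <- substr(read, p_up + key_len, p_dn - 1L)
  ref_mid <- genome_slice(g, target$chrom[1], cc - gap, cc + gap)
  k <- oc$size
  rm_c <- strsplit(read_mid, "")[[1]]
  rf_c <- strsplit(ref_mid, "")[[1]]
  # left-aligned placement: longest common prefix of read and reference mid
  p <- 0L
  while (p < length(rm_c) && rm_c[p + 1L] == rf_c[p + 1L]) p <- p + 1L
  g0 <- cc - gap + p            # deleted reference interval [g0, g0 + k)
  g1 <- g0 + k
  if (g1 > cc + gap) return("n/a")
  left_bases <- max(0L, min(g1, cc) - g0)
  right_bases <- k - left_bases
  # proximal = PAM side: genomic right for + sites, left for - sites
  if (target$strand[1] == "+") {
    prox <- right_bases; dist <- left_bases
  } else {
    prox <- left_bases; dist <- right_bases
  }
  if (prox > dist) "proximal" else if (dist > prox) "distal" else "balanced"
}

#' Per-target mutation summary of assigned reads
#'
#' @param reads character vector of reads assigned to one target.
#' @param target one-row slice of [amplicon_targets()].
#' @param g a [genome()] (for deletion side calls).
#' @return list: counts (`assigned`, `edited`, `unedited`, `indeterminate`,
#'   `unclassified`), `mutation_rate`, and a data.frame `calls` with class /
#'   size / subclass / side per edited read.
#' @export
summarize_target_outcomes <- function(reads, target, g) {
  status <- vapply(reads, call_mutation, "", target = target,
                   USE.NAMES = FALSE)
  edited <- reads[status == "edited"]
  calls <- lapply(edited, classify_outcome, target = target)
  side <- vapply(edited, deletion_side, "", target = target, g = g,
                 USE.NAMES = FALSE)
  df <- data.frame(
    class = vapply(calls, `[[`, "", "class"),
    size = vapply(calls, function(x) as.integer(x$size), integer(1)),
    subclass = vapply(calls, `[[`, "", "subclass"),
    side = side, stringsAsFactors = FALSE)
  list(assigned = length(reads),
       edited = sum(status == "edited"),
       unedited = sum(status == "unedited"),
       indeterminate = sum(status == "indeterminate"),
       unclassified = sum(df$class == "unclassified"),
       mutation_rate = if (any(status != "indeterminate")) {
         sum(status == "edited") / sum(status != "indeterminate")
       } else NA_real_,
       calls = df)
}

#' Shannon entropy of editing-outcome distributions
#'
#' Per-target entropy `H = -sum(p * log2(p))` (with `0 * log(0) := 0`) over
#' outcome frequencies, plus the running cumulative entropy across targets in
#' the given order — the quantity used to assess outcome diversity for lineage
#' barcoding.
#'
#' @param per_target list of named numeric frequency vectors, each summing
#'   to 1.
#' @return list: `per_target` (numeric vector of H in bits) and `cumulative`
#'   (running sum).
#' @export
outcome_entropy <- function(per_target) {
  H <- vapply(per_target, function(p) {
    p <- as.numeric(p)
    if (any(p < 0)) stop("negative outcome frequency")
    if (abs(sum(p) - 1) > 1e-8) stop("outcome frequencies must sum to 1")
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  list(per_target = H, cumulative = cumsum(H))
}
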