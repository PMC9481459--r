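## Deterministic synthetic-data generators. Every generator takes a seed and
## is byte-identical across reruns with the same arguments; ground truth is
## returned alongside the data.

# sample() treats a length-1 numeric as 1:x; guard against that
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

random_bases <- function(n, gc_skew = 0) {
  p <- c(A = (1 - gc_skew) / 2 * 0.5, C = (1 + gc_skew) / 2 * 0.5,
         G = (1 + gc_skew) / 2 * 0.5, T = (1 - gc_skew) / 2 * 0.5)
  p <- p / sum(p)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

apply_mismatches <- function(guide, positions) {
  # positions counted from the PAM; returns variant protospacer
  ch <- strsplit(guide, "")[[1]]
  for (p in positions) {
    i <- 21L - p
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic genome with planted protospacers
#'
#' Background bases are i.i.d. (uniform 25% each by default; `gc_skew` biases
#' G/C for stress tests). Each planted copy is the guide (optionally carrying
#' substitutions at stated PAM-counted positions) followed by an NGG PAM on
#' its strand. Planted sites are separated by at least `min_spacing` bp so
#' per-site windows do not overlap, and kept `edge_margin` bp from chromosome
#' ends. Optionally a genomic block is duplicated elsewhere to create
#' alignment-ambiguous regions.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len length of each chromosome (bp).
#' @param planted list of plant specs: each a list with `guide` (20 nt),
#'   `copies`, optional `mismatch_positions` (list, one integer vector per
#'   copy, positions from the PAM) and `strands` (vector recycled over
#'   copies; default alternating `+`/`-`).
#' @param seed integer seed.
#' @param min_spacing minimum distance between planted protospacer starts.
#' @param edge_margin clearance from chromosome ends.
#' @param dup_block optional list `list(chrom, start, len, dest_chrom,
#'   dest_start)` copying a block verbatim to create an exact repeat.
#' @param gc_skew background GC skew in `[-1, 1]`.
#' @return list: `genome` (a [genome()]), `sites` (truth site table).
#' @export
make_genome <- function(n_chrom = 1L, chrom_len = 100000L, planted = list(),
                        seed = 1L, min_spacing = 2000L, edge_margin = 1000L,
                        dup_block = NULL, gc_skew = 0) {
  set.seed(seed)
  seqs <- setNames(
    vapply(seq_len(n_chrom), function(i) random_bases(chrom_len, gc_skew), ""),
    sprintf("chr%d", seq_len(n_chrom)))

  total_copies <- sum(vapply(planted, function(p) p$copies, numeric(1)))
  chrom_of <- character(0); start_of <- integer(0)
  if (total_copies > 0) {
    # lay out non-overlapping slots across chromosomes
    per_chrom <- ceiling(total_copies / n_chrom)
    usable <- chrom_len - 2L * edge_margin
    if (per_chrom * min_spacing > usable) stop("planting capacity exceeded")
    slots <- list()
    B <- usable %/% per_chrom
    J <- max(1L, B - min_spacing - 23L)  # jitter keeping gaps >= min_spacing
    for (chr in names(seqs)) {
      anchors <- edge_margin + (seq_len(per_chrom) - 1L) * B
      slots[[chr]] <- anchors + sample.int(J, per_chrom, replace = TRUE)
    }
    slot_chrom <- rep(names(seqs), each = per_chrom)
    slot_start <- unlist(slots, use.names = FALSE)
    pick <- seq_len(total_copies)
    chrom_of <- slot_chrom[pick]; start_of <- slot_start[pick]
  }

  chroms <- character(0); starts <- integer(0); strands <- character(0)
  guides <- character(0); mms <- list()
  k <- 0L
  for (p in planted) {
    guide <- toupper(p$guide)
    stopifnot(nchar(guide) == 20L)
    strands_p <- rep_len(p$strands %||% c("+", "-"), p$copies)
    mm_list <- p$mismatch_positions %||% rep(list(integer(0)), p$copies)
    mm_list <- rep_len(mm_list, p$copies)
    for (j in seq_len(p$copies)) {
      k <- k + 1L
      chr <- chrom_of[k]; s <- start_of[k]
      proto <- apply_mismatches(guide, mm_list[[j]])
      pam <- paste0(sample(c("A", "C", "G", "T"), 1L), "GG")
      if (strands_p[j] == "+") {
        insert <- paste0(proto, pam)
        proto_start <- s
      } else {
        insert <- reverse_complement(paste0(proto, pam))
        proto_start <- s + 3L
      }
      substr(seqs[[chr]], s + 1L, s + nchar(insert)) <- insert
      chroms <- c(chroms, chr); starts <- c(starts, proto_start)
      strands <- c(strands, strands_p[j]); guides <- c(guides, guide)
      mms[[length(mms) + 1L]] <- sort(as.integer(mm_list[[j]]))
    }
  }

  if (!is.null(dup_block)) {
    src <- substr(seqs[[dup_block$chrom]], dup_block$start + 1L,
                  dup_block$start + dup_block$len)
    dchr <- dup_block$dest_chrom %||% dup_block$chrom
    substr(seqs[[dchr]], dup_block$dest_start + 1L,
           dup_block$dest_start + dup_block$len) <- src
  }

  g <- genome(seqs)
  sites <- target_sites(chroms, starts, strands, guides, g = g)
  ord <- order(sites$chrom, sites$cut, sites$strand)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  list(genome = g, sites = sites)
}

#' Generate fragments with known cut-site classifications
#'
#' Draws per-fragment labels from `mixture` (names from `span`, `dist_p4`,
#' `dist_m4`, `prox_p4`, `prox_m4`, `abut_distal`, `abut_proximal`, `other`)
#' and places fragment edges so that [classify_fragment()] recovers the label
#' by construction. Lengths are uniform on `[200, 600]`.
#'
#' @param sites site table.
#' @param mixture named proportions summing to 1.
#' @param n fragments per site.
#' @param library_size RPM denominator.
#' @param seed integer seed.
#' @param abut_tol abut tolerance used for `abut_*` / `other` placement.
#' @return [fragments()] table with `site` and `truth` columns.
#' @export
make_cutsite_fragments <- function(sites, mixture, n, library_size = NULL,
                                   seed = 1L, abut_tol = 5L) {
  stopifnot(abs(sum(mixture) - 1) < 1e-8)
  set.seed(seed)
  labels <- names(mixture)
  total <- n * nrow(sites)
  chrom <- character(total); f0 <- integer(total); f1 <- integer(total)
  site_idx <- integer(total); truth <- character(total)
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    cc <- sites$cut[i]; strand <- sites$strand[i]
    mirror <- function(a, b) {
      # place in + geometry, then reflect about the bond for - sites
      if (strand == "+") c(a, b) else c(2L * cc - b, 2L * cc - a)
    }
    for (r in seq_len(n)) {
      lab <- sample(labels, 1L, prob = mixture)
      L <- sample(200:600, 1L)
      ivl <- switch(lab,
        span = {
          s <- sample((cc - L + 1L):(cc - 2L), 1L)
          mirror(s, s + L)
        },
        dist_p4 = mirror(cc - L, cc),
        dist_m4 = mirror(cc - 1L - L, cc - 1L),
        prox_p4 = mirror(cc - 1L, cc - 1L + L),
        prox_m4 = mirror(cc, cc + L),
        abut_distal = {
          d <- sample(2:abut_tol, 1L)     # inside tolerance, off the exact edges
          mirror(cc - d - L, cc - d)
        },
        abut_proximal = {
          d <- sample(2:abut_tol, 1L)
          mirror(cc + d, cc + d + L)
        },
        other = {
          d <- sample((abut_tol + 1L):(abut_tol + 200L), 1L)
          if (runif(1) < 0.5) mirror(cc - d - L, cc - d)
          else mirror(cc + d, cc + d + L)
        },
        stop("unknown mixture label: ", lab)
      )
      k <- k + 1L
      chrom[k] <- sites$chrom[i]; f0[k] <- ivl[1]; f1[k] <- ivl[2]
      site_idx[k] <- i; truth[k] <- lab
    }
  }
  out <- fragments(chrom, f0, f1, library_size = library_size %||% total)
  out$site <- site_idx
  out$truth <- truth
  out
}

#' Generate amplicon reads with planted editing outcomes
#'
#' For each read, draws an outcome from `outcome_mix` (names from `unedited`,
#' `del`, `ins`, `snv`) and synthesizes the read from the reference with the
#' edit applied at the cut: deletions remove `size` bases centred at the
#' cleavage bond, insertions add random bases at the bond, SNVs substitute one
#' protospacer base. The read covers `[cut - half, cut + half)` of the edited
#' molecule (both keys included), with mate 2 the reverse complement.
#'
#' @param targets table from [amplicon_targets()].
#' @param g a [genome()].
#' @param outcome_mix named proportions over `unedited` / `del` / `ins` /
#'   `snv`, summing to 1.
#' @param n_reads reads per target.
#' @param half half-width (bp) of the reference window around the cut
#'   (default 75, i.e. 150-bp unedited reads).
#' @param del_sizes,ins_sizes candidate indel sizes, sampled uniformly.
#' @param seed integer seed.
#' @return data.frame: `target` (row index), `mate1`, `mate2`, `truth_class`,
#'   `truth_size`, `truth_side` (deletions; PAM-proximal/distal/balanced by
#'   construction).
#' @export
make_amplicon_reads <- function(targets, g, outcome_mix, n_reads,
                                half = 75L, del_sizes = 1:10, ins_sizes = 1:5,
                                seed = 1L) {
  stopifnot(abs(sum(outcome_mix) - 1) < 1e-8)
  gap <- targets$key_gap[1]
  if (half < gap + targets$key_len[1] + max(ins_sizes)) {
    stop("read window too small to contain both keys")
  }
  set.seed(seed)
  out <- list()
  for (t in seq_len(nrow(targets))) {
    cc <- targets$cut[t]; chrom <- targets$chrom[t]
    ref <- genome_slice(g, chrom, cc - half, cc + half)
    cut_in_ref <- half  # bond between ref positions half-1 and half (0-based)
    proto_off <- targets$start[t] - (cc - half)  # 0-based protospacer offset
    for (r in seq_len(n_reads)) {
      cls <- sample(names(outcome_mix), 1L, prob = outcome_mix)
      size <- NA_integer_; side <- NA_character_
      read <- ref
      if (cls == "del") {
        size <- sample1(del_sizes)
        left <- sample(0:size, 1L)          # bases removed left of the bond
        d0 <- cut_in_ref - left
        read <- paste0(substr(ref, 1L, d0), substr(ref, d0 + size + 1L, nchar(ref)))
        left_bases <- left; right_bases <- size - left
        prox_bases <- if (targets$strand[t] == "+") right_bases else left_bases
        dist_bases <- size - prox_bases
        side <- if (prox_bases > dist_bases) "proximal"
                else if (dist_bases > prox_bases) "distal" else "balanced"
      } else if (cls == "ins") {
        size <- sample1(ins_sizes)
        ins <- random_bases(size)
        read <- paste0(substr(ref, 1L, cut_in_ref), ins,
                       substr(ref, cut_in_ref + 1L, nchar(ref)))
      } else if (cls == "snv") {
        pos <- proto_off + sample(0:19, 1L)  # 0-based position in ref
        orig <- substr(ref, pos + 1L, pos + 1L)
        sub <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
        read <- ref
        substr(read, pos + 1L, pos + 1L) <- sub
        size <- 0L
      }
      out[[length(out) + 1L]] <- data.frame(
        target = t, mate1 = read, mate2 = reverse_complement(read),
        truth_class = switch(cls, unedited = "unedited", del = "deletion",
                             ins = "insertion", snv = "SNV"),
        truth_size = size, truth_side = side, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
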