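#' @importFrom BiocGenerics start end width
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement matchPattern letterFrequency
#' @importFrom stats median quantile rexp runif setNames coef cor sd ks.test
#' @importFrom utils read.table write.table head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

GENOME_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a genome object
#'
#' A genome is a named set of chromosome sequences over the alphabet
#' A/C/G/T/N. Sequences are uppercased on ingest; chromosome names must be
#' unique. All genomic coordinates in this package are 0-based, half-open;
#' 1-based interchange formats (e.g. SAM) are converted at the I/O boundary.
#'
#' @param sequences named character vector (or list) of chromosome sequences.
#' @return An object of class `genome`: a named character vector with derived
#'   lengths available via [genome_lengths()].
#' @export
genome <- function(sequences) {
  sequences <- unlist(sequences)
  if (length(sequences) == 0L) stop("genome needs at least one sequence")
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("all genome sequences must be named")
  }
  if (anyDuplicated(names(sequences))) stop("chromosome names must be unique")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(names(sequences)[bad], collapse = ", "))
  }
  structure(sequences, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome: %d sequence(s), %s bp total\n",
              length(x), format(sum(nchar(unclass(x))), big.mark = ",")))
  for (nm in names(x)) cat(sprintf("  %s: %d bp\n", nm, nchar(x[[nm]])))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param g a [genome()].
#' @return named integer vector of lengths.
#' @export
genome_lengths <- function(g) {
  stopifnot(inherits(g, "genome"))
  setNames(nchar(unclass(g)), names(g))
}

#' Extract a subsequence from a genome
#'
#' Coordinates are 0-based half-open. With `pad = FALSE` any lookup outside
#' `[0, length)` is an error; with `pad = TRUE` out-of-range positions are
#' filled with `N` (used for windows near chromosome ends).
#'
#' @param g a [genome()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param pad pad out-of-range positions with `N` instead of erroring.
#' @return character scalar.
#' @export
genome_slice <- function(g, chrom, start, end, pad = FALSE) {
  stopifnot(inherits(g, "genome"))
  if (!chrom %in% names(g)) stop("unknown chromosome: ", chrom)
  if (end < start) stop("end < start")
  len <- nchar(g[[chrom]])
  if (!pad && (start < 0 || end > len)) {
    stop(sprintf("interval [%d,%d) outside [0,%d) on %s", start, end, len, chrom))
  }
  lo <- max(start, 0L)
  hi <- min(end, len)
  core <- if (hi > lo) substr(g[[chrom]], lo + 1L, hi) else ""
  paste0(strrep("N", max(0L, lo - start)), core, strrep("N", max(0L, end - hi)))
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' GC fraction of a sequence
#'
#' `(#G + #C) / length`. `N` bases (and empty input) are rejected: a candidate
#' protospacer containing `N` is disqualified upstream rather than scored.
#'
#' @param seq character vector of sequences over A/C/G/T.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  if (length(seq) == 0L || any(nchar(seq) == 0L)) stop("empty sequence")
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq))) stop("sequence must contain only A/C/G/T")
  gc <- rowSums(letterFrequency(DNAStringSet(seq), c("G", "C")))
  unname(gc / nchar(seq))
}

#' Cut coordinate of a protospacer
#'
#' SpCas9 cleaves bluntly between the 3rd and 4th protospacer nucleotides
#' counting from the PAM. With 0-based half-open coordinates and `site_start`
#' the left genomic coordinate of the 20-nt protospacer, the returned
#' coordinate `c` places the cleavage bond between genomic bases `c - 1` and
#' `c`; the base adjacent to the bond on the PAM-distal side (the "+4" base)
#' is at `c - 1` for `+` sites and at `c` for `-` sites.
#'
#' @param site_start left genomic coordinate (0-based) of the protospacer.
#' @param strand `"+"` or `"-"`.
#' @return integer genomic coordinate.
#' @export
cut_coordinate <- function(site_start, strand) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ifelse(strand == "+", site_start + 17L, site_start + 3L)
}

#' Cut-centred, PAM-downstream sequence window
#'
#' Returns the `2 * radius` window centred at a site's cut coordinate,
#' reverse-complemented for `-` strand sites so that the PAM always lies
#' downstream (to the right) of the cut. Offset `o` in the returned string
#' (0-based index `o + radius`) corresponds to genomic base `c + o` for `+`
#' sites and `c - 1 - o` for `-` sites; the protospacer occupies offsets
#' `[-17, 3)` and the PAM offsets `[3, 6)` on either strand. Windows running
#' off the chromosome are padded with `N`.
#'
#' @param g a [genome()].
#' @param site single-row site table (see [target_sites()]) or a list with
#'   `chrom`, `strand`, `cut`.
#' @param radius half-window size in bp.
#' @return character scalar of length `2 * radius`.
#' @export
oriented_window <- function(g, site, radius) {
  stopifnot(radius > 0)
  chrom <- as.character(site$chrom[1]); strand <- as.character(site$strand[1])
  cc <- as.integer(site$cut[1])
  s <- genome_slice(g, chrom, cc - radius, cc + radius, pad = TRUE)
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Build a table of protospacer target sites
#'
#' The standard site container used across the package: a data frame with one
#' row per protospacer occurrence. If `g` is supplied, PAM and mismatch
#' annotations are derived from the genome; `guide` is the 20-nt guide written
#' 5'->3' with the PAM-proximal end last. Mismatch positions are counted from
#' the PAM (1 = adjacent to the PAM, 20 = PAM-distal end).
#'
#' @param chrom,start,strand vectors (recycled) describing each occurrence;
#'   `start` is the 0-based left coordinate of the 20-nt protospacer.
#' @param guide guide sequence(s), length 20.
#' @param g optional [genome()] used to fill `pam` and `mismatches`.
#' @return data.frame with columns chrom, start, end, strand, guide, pam, cut,
#'   n_mismatch and a list-column `mismatches` of integer positions.
#' @export
target_sites <- function(chrom, start, strand, guide, g = NULL) {
  n <- max(length(chrom), length(start), length(strand))
  if (n == 0L) return(empty_sites())
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  strand <- rep_len(as.character(strand), n)
  guide <- rep_len(toupper(guide), n)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(nchar(guide) == 20L)) stop("guides must be 20 nt")
  pam <- rep(NA_character_, n)
  mm <- vector("list", n)
  if (!is.null(g)) {
    for (i in seq_len(n)) {
      obs <- site_protospacer(g, chrom[i], start[i], strand[i])
      pam[i] <- obs$pam
      mm[[i]] <- mismatch_positions(guide[i], obs$protospacer)
    }
  } else {
    mm <- rep(list(integer(0)), n)
  }
  out <- data.frame(
    chrom = chrom, start = start, end = start + 20L, strand = strand,
    guide = guide, pam = pam, cut = cut_coordinate(start, strand),
    n_mismatch = vapply(mm, length, integer(1)),
    stringsAsFactors = FALSE
  )
  out$mismatches <- mm
  out
}

empty_sites <- function() {
  out <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), guide = character(0), pam = character(0),
    cut = integer(0), n_mismatch = integer(0), stringsAsFactors = FALSE
  )
  out$mismatches <- list()
  out
}

# Observed protospacer (guide orientation, PAM-proximal end last) and PAM for
# an occurrence at `start` on `strand`.
site_protospacer <- function(g, chrom, start, strand) {
  if (strand == "+") {
    proto <- genome_slice(g, chrom, start, start + 20L, pad = TRUE)
    pam <- genome_slice(g, chrom, start + 20L, start + 23L, pad = TRUE)
  } else {
    proto <- reverse_complement(genome_slice(g, chrom, start, start + 20L, pad = TRUE))
    pam <- reverse_complement(genome_slice(g, chrom, start - 3L, start, pad = TRUE))
  }
  list(protospacer = proto, pam = pam)
}

# Positions (1..20, counting from the PAM) where `observed` differs from
# `guide`; both written 5'->3' with PAM-proximal end last.
mismatch_positions <- function(guide, observed) {
  a <- strsplit(guide, "")[[1]]
  b <- strsplit(observed, "")[[1]]
  idx <- which(a != b)            # string index 1..20, 5'->3'
  sort(21L - idx)                 # position from PAM
}

is_ngg <- function(pam) {
  nchar(pam) == 3L &
    substr(pam, 1, 1) %in% c("A", "C", "G", "T") &
    substr(pam, 2, 3) == "GG"
}

## ---- FASTA / BED / TSV I/O -------------------------------------------------

#' Read a genome from a multi-record FASTA file
#' @param path FASTA file path.
#' @return a [genome()].
#' @export
read_genome <- function(path) {
  x <- readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  genome(setNames(as.character(x), nm))
}

#' Write a genome to FASTA
#' @param g a [genome()].
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_genome <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "genome"))
  writeXStringSet(DNAStringSet(setNames(unclass(g), names(g))), path,
                  width = width)
  invisible(path)
}

#' Write target sites as BED6
#'
#' Columns: chrom, protospacer start, protospacer end (0-based half-open),
#' name = guide sequence, score = mismatch count, strand.
#'
#' @param sites site table from [target_sites()].
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(sites$chrom, sites$start, sites$end, sites$guide,
                   sites$n_mismatch, sites$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read target sites from BED6
#'
#' @param path BED6 path as written by [write_sites_bed()].
#' @param g optional [genome()] to re-derive PAM and mismatch annotations.
#' @return site table.
#' @export
read_sites_bed <- function(path, g = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score", "strand"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer", "character"))
  target_sites(df$chrom, df$start, df$strand, df$name, g = g)
}

#' Construct a paired-end fragment table
#'
#' A fragment is a whole sequenced DNA molecule as a genomic interval
#' (leftmost mate start to rightmost mate end, 0-based half-open), including
#' the unsequenced middle. `library_size` (total mapped fragments in the
#' parent library, the RPM denominator) is stored as an attribute.
#'
#' @param chrom,start,end vectors describing each fragment.
#' @param library_size total mapped fragments in the library; defaults to the
#'   number of fragments supplied.
#' @return data.frame of class `fragments` with attribute `library_size`.
#' @export
fragments <- function(chrom, start, end, library_size = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("fragments must have end > start")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    stringsAsFactors = FALSE)
  attr(out, "library_size") <- as.numeric(library_size %||% nrow(out))
  class(out) <- c("fragments", "data.frame")
  out
}

frag_library_size <- function(frags, library_size = NULL) {
  ls <- library_size %||% attr(frags, "library_size") %||% nrow(frags)
  if (is.null(ls) || is.na(ls) || ls <= 0) stop("library size must be positive")
  as.numeric(ls)
}

#' Read a fragment table from TSV (chrom, start, end)
#' @param path TSV path; a header line is auto-detected.
#' @param library_size RPM denominator; defaults to the number of rows.
#' @return [fragments()] table.
#' @export
read_fragments_tsv <- function(path, library_size = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  fragments(df$chrom, df$start, df$end, library_size = library_size)
}

#' Write a fragment table to TSV
#' @param frags [fragments()] table.
#' @param path output path.
#' @export
write_fragments_tsv <- function(frags, path) {
  write.table(frags[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
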