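## Cut-site-resolved fragment analytics.
##
## Coordinate model: the blunt Cas9 cut falls between genomic bases c-1 and c
## where c = cut_coordinate(start, strand). On a + site (PAM to the right of
## the protospacer) the PAM-proximal side is genomic-right of the bond and the
## "+4" base (fourth protospacer nucleotide from the PAM) sits at c-1; on a -
## site the proximal side is genomic-left and the +4 base sits at c. Minus
## sites are handled by reflecting fragment intervals about the bond
## (f0' = 2c - f1, f1' = 2c - f0), which maps them exactly onto + geometry.

# Vectorized classification in + geometry. Exact (0-tolerance) species edges:
#   dist_p4: f1 == c      (distal fragment retaining the +4 base)
#   dist_m4: f1 == c - 1  (distal fragment lacking the +4 base)
#   prox_p4: f0 == c - 1  (proximal fragment with filled-in +4 base)
#   prox_m4: f0 == c      (proximal fragment lacking the +4 base)
classify_plus <- function(f0, f1, cc, abut_tol) {
  n <- length(f0)
  category <- rep("other", n)
  species <- rep("none", n)
  side <- rep(NA_character_, n)

  span <- f0 < cc - 1L & f1 > cc
  left <- !span & f1 <= cc            # wholly PAM-distal (+ geometry)
  right <- !span & !left & f0 >= cc - 1L  # PAM-proximal (may carry +4 overhang)

  side[left] <- "distal"
  side[right] <- "proximal"
  category[span] <- "span"
  category[left & (cc - f1 <= abut_tol)] <- "abut_distal"
  # proximal edge distance measured from c; the filled-in +4 overhang
  # (f0 == c-1) counts as distance 0
  category[right & (pmax(f0, cc) - cc <= abut_tol)] <- "abut_proximal"

  species[f1 == cc & left] <- "dist_p4"
  species[f1 == cc - 1L & left] <- "dist_m4"
  species[f0 == cc - 1L & right] <- "prox_p4"
  species[f0 == cc & right] <- "prox_m4"
  species[category == "span" | category == "other"] <- "none"
  data.frame(category = category, species = species, side = side,
             stringsAsFactors = FALSE)
}

classify_fragments_at <- function(f0, f1, cc, strand, abut_tol = 5L) {
  if (strand == "-") {
    tmp <- 2L * cc - f1
    f1 <- 2L * cc - f0
    f0 <- tmp
  }
  classify_plus(f0, f1, cc, abut_tol)
}

#' Classify a fragment relative to a cut site
#'
#' Categories: `span` (fragment strictly covers both bases flanking the
#' cleavage bond), `abut_proximal` / `abut_distal` (fragment lies wholly on
#' one side with its cut-facing edge within `abut_tol` bp of the cut;
#' "proximal" always denotes the PAM-containing side), or `other`. One-sided
#' fragments additionally receive a species call by exact edge position:
#' `dist_p4`, `dist_m4`, `prox_p4`, `prox_m4` distinguish whether the
#' fragment retains the +4 nucleotide, separating blunt from staggered
#' (filled-in) cleavage products.
#'
#' @param frag single fragment (list or one-row data.frame with `chrom`,
#'   `start`, `end`).
#' @param site single-row site table.
#' @param abut_tol abut tolerance in bp (inclusive; default 5).
#' @return list with `category`, `species`, `side`.
#' @export
classify_fragment <- function(frag, site, abut_tol = 5L) {
  if (frag$chrom[1] != site$chrom[1]) stop("fragment/site chromosome mismatch")
  r <- classify_fragments_at(frag$start[1], frag$end[1], site$cut[1],
                             site$strand[1], abut_tol)
  list(category = r$category, species = r$species, side = r$side)
}

#' Span/abut/species counts at a cut site, RPM-scaled
#'
#' Counts fragments per category scaled by `1e6 / library_size`. `prox_rpm`
#' and `dist_rpm` tally all one-sided fragments by side regardless of the abut
#' tolerance (the caller restricts fragments to the analysis window).
#'
#' @param frags [fragments()] table (same chromosome as `site`).
#' @param site single-row site table.
#' @param abut_tol abut tolerance in bp.
#' @param library_size RPM denominator (defaults to the fragments attribute).
#' @return named list: `span_rpm`, `abut_rpm`, `other_rpm`, `prox_rpm`,
#'   `dist_rpm`, `dist_p4_rpm`, `dist_m4_rpm`, `prox_p4_rpm`, `prox_m4_rpm`,
#'   `total_rpm`.
#' @export
count_span_abut <- function(frags, site, abut_tol = 5L, library_size = NULL) {
  ls <- frag_library_size(frags, library_size)
  sub <- frags[frags$chrom == site$chrom[1], , drop = FALSE]
  cl <- classify_fragments_at(sub$start, sub$end, site$cut[1],
                              site$strand[1], abut_tol)
  rpm <- function(x) sum(x) * 1e6 / ls
  list(
    span_rpm = rpm(cl$category == "span"),
    abut_rpm = rpm(cl$category %in% c("abut_proximal", "abut_distal")),
    other_rpm = rpm(cl$category == "other"),
    prox_rpm = rpm(!is.na(cl$side) & cl$side == "proximal"),
    dist_rpm = rpm(!is.na(cl$side) & cl$side == "distal"),
    dist_p4_rpm = rpm(cl$species == "dist_p4"),
    dist_m4_rpm = rpm(cl$species == "dist_m4"),
    prox_p4_rpm = rpm(cl$species == "prox_p4"),
    prox_m4_rpm = rpm(cl$species == "prox_m4"),
    total_rpm = rpm(rep(TRUE, nrow(sub)))
  )
}

#' RPM of fragments overlapping a window centred at the cut
#'
#' Published window widths by assay: 200 kb for 53BP1 and gamma-H2AX, 2,500 bp
#' for MRE11, 1,500 bp for Cas9 — available via `window_width_preset()`.
#'
#' @param frags [fragments()] table.
#' @param site single-row site table.
#' @param width full window width in bp.
#' @param library_size RPM denominator.
#' @return RPM (numeric scalar).
#' @export
window_rpm <- function(frags, site, width, library_size = NULL) {
  stopifnot(width > 0)
  ls <- frag_library_size(frags, library_size)
  lo <- site$cut[1] - width / 2
  hi <- site$cut[1] + width / 2
  n <- sum(frags$chrom == site$chrom[1] & frags$end > lo & frags$start < hi)
  n * 1e6 / ls
}

#' Preset full window widths (bp) by assay name
#' @param mark one of `"mre11"`, `"cas9"`, `"gammaH2AX"`, `"53bp1"`, `"atac"`.
#' @return width in bp.
#' @export
window_width_preset <- function(mark) {
  presets <- c(mre11 = 2500, cas9 = 1500, gammaH2AX = 200000,
               `53bp1` = 200000, atac = 3000)
  key <- tolower(mark)
  names(presets) <- tolower(names(presets))
  if (!key %in% names(presets)) stop("unknown mark: ", mark)
  unname(presets[key])
}

new_profile <- function(offsets, values, radius, bin = 1L, step = 1L) {
  structure(list(offsets = as.numeric(offsets), values = as.numeric(values),
                 radius = radius, bin = bin, step = step),
            class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf(
    "enrichment profile: %d points, offsets [%g, %g], bin %g bp, step %g bp\n",
    length(x$offsets), min(x$offsets), max(x$offsets), x$bin, x$step))
  cat(sprintf("  max %.4g RPM at offset %g\n",
              max(x$values), x$offsets[which.max(x$values)]))
  invisible(x)
}

#' @export
as.data.frame.enrichment_profile <- function(x, ...) {
  data.frame(offset = x$offsets, value = x$values)
}

#' Base-pair-resolution fragment pileup around cut sites
#'
#' Whole-fragment coverage (including the unsequenced middle of each
#' paired-end fragment) tallied at each base within `radius` bp of the cut,
#' oriented PAM-downstream (offset `o` maps to genomic base `c + o` on `+`
#' sites and `c - 1 - o` on `-` sites), summed over sites and RPM-scaled.
#' Published half-window radii: 1,250 bp (MRE11), 750 bp (Cas9), 1,500 bp
#' (ATAC) — i.e. full windows of 2,500 / 1,500 / 3,000 bp.
#'
#' @param frags [fragments()] table.
#' @param sites site table (one or more rows; profiles are summed).
#' @param radius half-window in bp.
#' @param library_size RPM denominator.
#' @return an `enrichment_profile` with offsets `-radius .. radius - 1`.
#' @export
bp_pileup <- function(frags, sites, radius, library_size = NULL) {
  stopifnot(radius > 0)
  ls <- frag_library_size(frags, library_size)
  width <- 2L * radius
  acc <- numeric(width)
  for (i in seq_len(nrow(sites))) {
    cc <- sites$cut[i]
    sub <- frags[frags$chrom == sites$chrom[i], , drop = FALSE]
    lo <- cc - radius; hi <- cc + radius
    sub <- sub[sub$end > lo & sub$start < hi, , drop = FALSE]
    if (nrow(sub) == 0L) next
    cov <- numeric(width + 1L)
    a <- pmax(sub$start, lo) - lo
    b <- pmin(sub$end, hi) - lo
    for (j in seq_along(a)) {
      cov[a[j] + 1L] <- cov[a[j] + 1L] + 1
      cov[b[j] + 1L] <- cov[b[j] + 1L] - 1
    }
    cov <- cumsum(cov[seq_len(width)])
    if (sites$strand[i] == "-") cov <- rev(cov)
    acc <- acc + cov
  }
  new_profile(seq.int(-radius, radius - 1L), acc * 1e6 / ls, radius)
}

#' Sliding-window RPM profile around cut sites
#'
#' RPM of fragments overlapping a `bin`-wide window whose centre slides from
#' `-radius` to `+radius` in increments of `step`, oriented PAM-downstream and
#' summed over sites. Published preset geometries: ATAC fine = 4 bp window / 1
#' bp step / 1.5 kb extent; ATAC wide = 1 kb / 1 kb / 50 kb; gamma-H2AX and
#' 53BP1 = 10 kb / 10 kb / 2 Mb.
#'
#' @param frags [fragments()] table.
#' @param sites site table.
#' @param radius profile extent in bp.
#' @param bin window width in bp (`<= 2 * radius`).
#' @param step centre increment in bp.
#' @param library_size RPM denominator.
#' @return an `enrichment_profile`.
#' @export
sliding_window_profile <- function(frags, sites, radius, bin, step,
                                   library_size = NULL) {
  stopifnot(bin <= 2 * radius, step >= 1)
  ls <- frag_library_size(frags, library_size)
  centers <- seq.int(-radius, radius, by = step)
  acc <- numeric(length(centers))
  half <- bin / 2
  for (i in seq_len(nrow(sites))) {
    cc <- sites$cut[i]
    sub <- frags[frags$chrom == sites$chrom[i], , drop = FALSE]
    if (nrow(sub) == 0L) next
    sgn <- if (sites$strand[i] == "+") 1 else -1
    # oriented fragment interval in offset units
    if (sgn > 0) { o0 <- sub$start - cc; o1 <- sub$end - cc }
    else { o0 <- cc - sub$end; o1 <- cc - sub$start }
    s0 <- sort(o0); s1 <- sort(o1)
    # overlap count per window = #(o0 < hi) - #(o1 <= lo)
    hi <- centers + half; lo <- centers - half
    acc <- acc + (findInterval(hi, s0, left.open = TRUE) -
                    findInterval(lo, s1))
  }
  new_profile(centers, acc * 1e6 / ls, radius, bin, step)
}

#' Preset sliding-window geometries
#' @param name `"atac_fine"`, `"atac_wide"` or `"gamma_53bp1"`.
#' @return list with `radius`, `bin`, `step` in bp.
#' @export
sliding_window_preset <- function(name) {
  presets <- list(
    atac_fine = list(radius = 1500, bin = 4, step = 1),
    atac_wide = list(radius = 50000, bin = 1000, step = 1000),
    gamma_53bp1 = list(radius = 2e6, bin = 10000, step = 10000)
  )
  if (!name %in% names(presets)) stop("unknown preset: ", name)
  presets[[name]]
}

#' Position-wise background subtraction of two profiles
#'
#' Subtracts a control (e.g. Cas9-negative) profile from a treatment profile
#' with identical geometry. Negative values are retained, not clipped.
#'
#' @param treatment,control `enrichment_profile` objects with identical
#'   offsets and geometry.
#' @return an `enrichment_profile` of differences.
#' @export
background_subtract <- function(treatment, control) {
  if (!identical(treatment$offsets, control$offsets) ||
      !identical(c(treatment$radius, treatment$bin, treatment$step),
                 c(control$radius, control$bin, control$step))) {
    stop("profile geometry mismatch")
  }
  new_profile(treatment$offsets, treatment$values - control$values,
              treatment$radius, treatment$bin, treatment$step)
}

#' Full width at half maximum of an enrichment profile
#'
#' Width between the outermost linearly interpolated half-maximum crossings
#' around the global peak: the first upward crossing scanning inward from the
#' left end and the last downward crossing scanning inward from the right.
#'
#' @param profile an `enrichment_profile` with a positive maximum.
#' @return width in bp.
#' @export
fwhm <- function(profile) {
  v <- profile$values; o <- profile$offsets
  pk <- which.max(v)
  if (v[pk] <= 0) stop("profile has no positive maximum")
  half <- v[pk] / 2
  above <- v >= half
  first <- which(above)[1]
  last <- which(above)[length(which(above))]
  left <- if (first == 1L) {
    stop("half maximum never crossed on the left within the window")
  } else {
    o[first - 1L] + (half - v[first - 1L]) / (v[first] - v[first - 1L]) *
      (o[first] - o[first - 1L])
  }
  right <- if (last == length(v)) {
    stop("half maximum never crossed on the right within the window")
  } else {
    o[last] + (half - v[last]) / (v[last + 1L] - v[last]) *
      (o[last + 1L] - o[last])
  }
  right - left
}

#' Fragment-length distributions and exponential-decay fit of the excess
#'
#' Records the length of every fragment within `window_radius` of any cut
#' site, histograms the two conditions (RPM-scaled, 10-bp bins over
#' `length_range`), forms the excess (treated minus control) and fits
#' `A * exp(-L / lambda)` to the excess by unweighted least squares. The fit
#' is refused (error of class `multicut_fit_refused`) when the excess is
#' non-positive everywhere.
#'
#' @param frags_treated,frags_control [fragments()] tables.
#' @param sites site table defining the windows.
#' @param window_radius half-window in bp (published analysis: fragments
#'   within 1.5 kb of expected target sites, i.e. a 3 kb window).
#' @param length_range fit/histogram range in bp.
#' @param bin histogram bin width in bp.
#' @param library_size_treated,library_size_control RPM denominators.
#' @return list of class `fragment_length_fit`: `mids`, `hist_treated`,
#'   `hist_control`, `excess`, `A`, `lambda`, `rss`.
#' @export
fragment_length_analysis <- function(frags_treated, frags_control, sites,
                                     window_radius = 1500L,
                                     length_range = c(50L, 600L), bin = 10L,
                                     library_size_treated = NULL,
                                     library_size_control = NULL) {
  lst <- frag_library_size(frags_treated, library_size_treated)
  lsc <- frag_library_size(frags_control, library_size_control)
  in_windows <- function(frags) {
    sel <- rep(FALSE, nrow(frags))
    for (i in seq_len(nrow(sites))) {
      sel <- sel | (frags$chrom == sites$chrom[i] &
                      frags$end > sites$cut[i] - window_radius &
                      frags$start < sites$cut[i] + window_radius)
    }
    frags[sel, , drop = FALSE]
  }
  breaks <- seq(length_range[1], length_range[2], by = bin)
  mids <- head(breaks, -1) + bin / 2
  hist_rpm <- function(frags, ls) {
    len <- frags$end - frags$start
    len <- len[len >= length_range[1] & len < length_range[2]]
    counts <- tabulate(findInterval(len, breaks), nbins = length(mids))
    counts * 1e6 / ls
  }
  ht <- hist_rpm(in_windows(frags_treated), lst)
  hc <- hist_rpm(in_windows(frags_control), lsc)
  excess <- ht - hc
  if (all(excess <= 0)) {
    stop(structure(
      list(message = "excess is non-positive everywhere; fit refused",
           call = sys.call()),
      class = c("multicut_fit_refused", "error", "condition")))
  }
  df <- data.frame(L = mids, y = excess)
  pos <- df$y > 0
  lam0 <- tryCatch({
    fit0 <- stats::lm(log(y) ~ L, data = df[pos, , drop = FALSE])
    max(10, -1 / coef(fit0)[["L"]])
  }, error = function(e) 120)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-L / lambda), data = df,
                           start = list(A = max(df$y), lambda = lam0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  structure(list(mids = mids, hist_treated = ht, hist_control = hc,
                 excess = excess, A = unname(est["A"]),
                 lambda = unname(est["lambda"]),
                 rss = sum(stats::residuals(fit)^2)),
            class = "fragment_length_fit")
}

#' @export
print.fragment_length_fit <- function(x, ...) {
  cat(sprintf(
    "fragment-length excess fit: A = %.4g RPM, decay length lambda = %.1f bp (RSS %.3g)\n",
    x$A, x$lambda, x$rss))
  invisible(x)
}

#' RPM of cut-spanning fragments per site
#'
#' Restricts the analysis to fragments classified `span` (fragments covering
#' the cleavage bond, i.e. intact or re-ligated molecules) and reports their
#' RPM per site.
#'
#' @param frags [fragments()] table.
#' @param sites site table.
#' @param library_size RPM denominator.
#' @return numeric vector, one RPM per site.
#' @export
spanning_read_fraction <- function(frags, sites, library_size = NULL) {
  ls <- frag_library_size(frags, library_size)
  vapply(seq_len(nrow(sites)), function(i) {
    sub <- frags[frags$chrom == sites$chrom[i], , drop = FALSE]
    cl <- classify_fragments_at(sub$start, sub$end, sites$cut[i],
                                sites$strand[i])
    sum(cl$category == "span") * 1e6 / ls
  }, numeric(1))
}

#' Export an enrichment profile as TSV or bedGraph
#'
#' @param profile an `enrichment_profile`.
#' @param path output path.
#' @param format `"tsv"` (offset, value) or `"bedgraph"` (requires `chrom`
#'   and `center` to anchor offsets genomically).
#' @param chrom,center genomic anchor for bedGraph output.
#' @export
write_profile <- function(profile, path, format = c("tsv", "bedgraph"),
                          chrom = NULL, center = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(data.frame(offset = profile$offsets, value = profile$values),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(chrom) || is.null(center)) {
      stop("bedGraph output needs chrom and center")
    }
    pos <- center + profile$offsets
    write.table(data.frame(chrom, pos, pos + profile$step, profile$values),
                path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
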