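# Hand-derived truth table for the span/abut/species rules, written from the
# blunt/staggered cleavage model (+ geometry: PAM right of the protospacer,
# bond between genomic bases c-1 and c, +4 base at c-1, proximal side right):
#   span          <=> fragment covers a base left of c-1 AND the base c
#   distal  (left) fragment: last covered base is c-1-d for edge gap d >= 0;
#       d == 0 (f1 = c)      -> dist_p4  (retains the +4 base)
#       d == 1 (f1 = c-1)    -> dist_m4  (lost the +4 base)
#       d <= 5               -> abut_distal, else other
#   proximal (right) fragment: first covered base c-1+e;
#       e == 0 (f0 = c-1)    -> prox_p4  (fill-in duplicated the +4 base)
#       e == 1 (f0 = c)      -> prox_m4
#       first base within 5 bp of c  -> abut_proximal, else other
truth_plus <- function(f0, f1, cc, tol = 5L) {
  if (f0 < cc - 1L && f1 > cc) return(list(cat = "span", sp = "none"))
  if (f1 <= cc) {                     # wholly left = PAM-distal
    d <- cc - f1
    sp <- if (d == 0L) "dist_p4" else if (d == 1L) "dist_m4" else "none"
    cat <- if (d <= tol) "abut_distal" else "other"
    return(list(cat = cat, sp = sp))
  }
  e <- f0 - (cc - 1L)                 # right side, may carry the +4 overhang
  sp <- if (e == 0L) "prox_p4" else if (e == 1L) "prox_m4" else "none"
  cat <- if (max(f0, cc) - cc <= tol) "abut_proximal" else "other"
  list(cat = cat, sp = sp)
}

test_that("exhaustive edge sweep matches the hand-derived species truth table on both strands", {
  cc <- 1000L
  len <- 150L
  for (strand in c("+", "-")) {
    site <- site_at("chrX", if (strand == "+") cc - 17L else cc - 3L, strand)
    stopifnot(site$cut == cc)
    for (edge in (cc - 8L):(cc + 8L)) {
      # left-anchored fragment ending at `edge`, right-anchored starting there
      for (geom in c("ends_at", "starts_at")) {
        f0 <- if (geom == "ends_at") edge - len else edge
        f1 <- f0 + len
        got <- classify_fragment(list(chrom = "chrX", start = f0, end = f1),
                                 site)
        # truth evaluated in + geometry after reflecting - fragments
        if (strand == "+") {
          want <- truth_plus(f0, f1, cc)
        } else {
          want <- truth_plus(2L * cc - f1, 2L * cc - f0, cc)
        }
        info <- sprintf("strand %s f0 %d f1 %d", strand, f0, f1)
        expect_identical(got$category, want$cat, info = info)
        expect_identical(got$species, want$sp, info = info)
      }
    }
  }
})

test_that("specification examples classify as stated", {
  cc <- 5000L
  site <- site_at("chr1", cc - 17L, "+")
  expect_identical(
    classify_fragment(list(chrom = "chr1", start = cc - 300L, end = cc + 200L),
                      site)$category, "span")
  got <- classify_fragment(list(chrom = "chr1", start = cc, end = cc + 250L), site)
  expect_identical(got$category, "abut_proximal")
  expect_identical(got$species, "prox_m4")
  got <- classify_fragment(list(chrom = "chr1", start = cc - 250L, end = cc - 1L),
                           site)
  expect_identical(got$category, "abut_distal")
  expect_identical(got$species, "dist_m4")
  expect_error(
    classify_fragment(list(chrom = "chr2", start = 0L, end = 10L), site),
    "mismatch")
})

test_that("span/abut counts are RPM-scaled and partition the window", {
  cc <- 5000L
  site <- site_at("chr1", cc - 17L, "+")
  fr <- fragments("chr1",
                  c(cc - 300L, cc - 250L, cc, cc - 400L, cc + 100L),
                  c(cc + 200L, cc - 1L, cc + 250L, cc - 100L, cc + 400L),
                  library_size = 1e6)
  counts <- count_span_abut(fr, site)
  expect_equal(counts$span_rpm, 1)
  expect_equal(counts$abut_rpm, 2)
  expect_equal(counts$other_rpm, 2)
  expect_equal(counts$span_rpm + counts$abut_rpm + counts$other_rpm,
               counts$total_rpm)
  expect_equal(counts$prox_rpm, 2)   # one-sided right fragments
  expect_equal(counts$dist_rpm, 2)
  expect_equal(counts$prox_m4_rpm, 1)
  expect_equal(counts$dist_m4_rpm, 1)
  # two span fragments among 1e6 -> span_rpm 2.0
  fr2 <- fragments("chr1", rep(cc - 300L, 2), rep(cc + 200L, 2),
                   library_size = 1e6)
  expect_equal(count_span_abut(fr2, site)$span_rpm, 2)
  expect_error(count_span_abut(fragments("chr1", 1L, 10L, library_size = 0),
                               site), "positive")
})

test_that("all cut-site outputs are invariant under strand mirroring", {
  # a + site with fragments, and the mirror-image - site with reflected
  # fragments, must give identical counts and profiles
  cc <- 5000L
  site_p <- site_at("chr1", cc - 17L, "+")
  site_m <- site_at("chr1", cc - 3L, "-")
  stopifnot(site_m$cut == cc)
  set.seed(77)
  n <- 400L
  f0 <- cc + sample(-700:600, n, replace = TRUE)
  f1 <- f0 + sample(150:500, n, replace = TRUE)
  fr_p <- fragments("chr1", f0, f1, library_size = 1e6)
  fr_m <- fragments("chr1", 2L * cc - f1, 2L * cc - f0, library_size = 1e6)
  expect_equal(count_span_abut(fr_p, site_p), count_span_abut(fr_m, site_m))
  expect_equal(window_rpm(fr_p, site_p, 1500L), window_rpm(fr_m, site_m, 1500L))
  prof_p <- bp_pileup(fr_p, site_p, radius = 750L)
  prof_m <- bp_pileup(fr_m, site_m, radius = 750L)
  expect_equal(prof_p$values, prof_m$values)
  sw_p <- sliding_window_profile(fr_p, site_p, 1500L, 4L, 1L)
  sw_m <- sliding_window_profile(fr_m, site_m, 1500L, 4L, 1L)
  expect_equal(sw_p$values, sw_m$values)
})

test_that("window RPM equals a brute-force overlap count", {
  set.seed(11)
  cc <- 50000L
  site <- site_at("chr1", cc - 17L, "+")
  f0 <- sample.int(100000L, 800L) - 1L
  f1 <- f0 + sample(100:900, 800L, replace = TRUE)
  fr <- fragments("chr1", f0, f1, library_size = 2e6)
  for (width in c(1500L, 2500L, 20000L)) {
    lo <- cc - width / 2; hi <- cc + width / 2
    brute <- sum(vapply(seq_along(f0), function(i) {
      f1[i] > lo && f0[i] < hi
    }, logical(1)))
    expect_equal(window_rpm(fr, site, width), brute * 1e6 / 2e6)
  }
  expect_equal(window_rpm(fr[0, ], site, 1500L, library_size = 10), 0)
  expect_identical(window_width_preset("mre11"), 2500)
  expect_identical(window_width_preset("cas9"), 1500)
  expect_identical(window_width_preset("gammaH2AX"), 2e5)
})

test_that("base-pair pileups cover fragments, conserve mass, and mirror symmetry", {
  cc <- 5000L
  site <- site_at("chr1", cc - 17L, "+")
  fr <- fragments("chr1", cc - 100L, cc + 100L, library_size = 1e6)
  prof <- bp_pileup(fr, site, radius = 300L)
  expect_equal(prof$values[prof$offsets >= -100 & prof$offsets < 100],
               rep(1, 200))
  expect_equal(prof$values[abs(prof$offsets) > 100], numeric(sum(abs(prof$offsets) > 100)))
  # conservation: integral equals total overlap length * 1e6 / library
  set.seed(3)
  f0 <- cc + sample(-400:350, 120L, replace = TRUE)
  f1 <- f0 + sample(50:200, 120L, replace = TRUE)
  frr <- fragments("chr1", f0, f1, library_size = 1e6)
  p2 <- bp_pileup(frr, site, radius = 600L)
  overlap <- sum(pmin(f1, cc + 600L) - pmax(f0, cc - 600L))
  expect_equal(sum(p2$values), overlap)
  # symmetric fragment set -> symmetric profile
  fs <- fragments("chr1", c(cc - 50L, cc - 10L), c(cc + 10L, cc + 50L),
                  library_size = 1e6)
  p3 <- bp_pileup(fs, site, radius = 100L)
  expect_equal(p3$values, rev(p3$values))
})

test_that("sliding windows reduce to disjoint binning and flatten uniform coverage", {
  cc <- 50000L
  site <- site_at("chr1", cc - 17L, "+")
  # uniform tiling every 100 bp -> flat wide-window profile
  f0 <- seq(cc - 60000L, cc + 60000L, by = 100L)
  fr <- fragments("chr1", f0, f0 + 300L, library_size = 1e6)
  prof <- sliding_window_profile(fr, site, radius = 5000L, bin = 1000L,
                                 step = 1000L)
  expect_lte(diff(range(prof$values)) / mean(prof$values), 0.05)
  # bin == step: equals an independent disjoint-binning oracle
  set.seed(13)
  r0 <- cc + sample(-3000:2700, 150L, replace = TRUE)
  fr2 <- fragments("chr1", r0, r0 + sample(50:300, 150L, replace = TRUE),
                   library_size = 1e6)
  prof2 <- sliding_window_profile(fr2, site, radius = 2000L, bin = 500L,
                                  step = 500L)
  for (j in seq_along(prof2$offsets)) {
    lo <- cc + prof2$offsets[j] - 250L
    hi <- cc + prof2$offsets[j] + 250L
    brute <- sum(fr2$end > lo & fr2$start < hi)
    expect_equal(prof2$values[j], brute)
  }
  geom <- sliding_window_preset("atac_fine")
  expect_equal(c(geom$radius, geom$bin, geom$step), c(1500, 4, 1))
  geom <- sliding_window_preset("gamma_53bp1")
  expect_equal(c(geom$radius, geom$bin, geom$step), c(2e6, 1e4, 1e4))
})

test_that("background subtraction is position-wise, retains negatives, and round-trips", {
  cc <- 5000L
  site <- site_at("chr1", cc - 17L, "+")
  t_fr <- fragments("chr1", cc - 100L, cc + 100L, library_size = 1e6)
  c_fr <- fragments("chr1", cc - 50L, cc + 150L, library_size = 1e6)
  tp <- bp_pileup(t_fr, site, 300L)
  cp <- bp_pileup(c_fr, site, 300L)
  diffp <- background_subtract(tp, cp)
  expect_equal(diffp$values, tp$values - cp$values)
  expect_true(any(diffp$values < 0))
  expect_equal(background_subtract(tp, tp)$values, numeric(600))
  zero <- bp_pileup(t_fr[0, ], site, 300L, library_size = 1e6)
  expect_equal(background_subtract(tp, zero)$values, tp$values)
  # subtract then re-add round-trips
  back <- background_subtract(tp, background_subtract(zero, cp))
  expect_equal(back$values, tp$values + cp$values)
  wrong <- bp_pileup(c_fr, site, 200L)
  expect_error(background_subtract(tp, wrong), "geometry")
})

test_that("FWHM reproduces closed forms and is translation invariant", {
  off <- -500:499
  tri <- multicut:::new_profile(off, pmax(0, 1 - abs(off) / 100), 500L)
  expect_equal(fwhm(tri), 100)
  gauss <- multicut:::new_profile(off, exp(-off^2 / (2 * 100^2)), 500L)
  expect_equal(fwhm(gauss), 2 * sqrt(2 * log(2)) * 100, tolerance = 2 / 235)
  shifted <- multicut:::new_profile(off, exp(-(off - 120)^2 / (2 * 100^2)), 500L)
  expect_equal(fwhm(shifted), fwhm(gauss), tolerance = 1e-6)
  flat <- multicut:::new_profile(off, rep(0, 1000), 500L)
  expect_error(fwhm(flat), "positive")
  high <- multicut:::new_profile(off, rep(1, 1000), 500L)
  expect_error(fwhm(high), "half maximum")
})

test_that("fragment-length excess fitting recovers a planted exponential decay", {
  g <- genome(c(chr1 = strrep("ACGT", 25000)))
  site <- site_at("chr1", 50000L, "+")
  set.seed(55)
  n_ctrl <- 20000L
  mk <- function(lens) {
    lens <- pmin(pmax(round(lens), 51L), 599L)
    f0 <- 50000L + sample(-1400:900, length(lens), replace = TRUE)
    fragments("chr1", f0, f0 + lens, library_size = 1e6)
  }
  ctrl_lens <- runif(n_ctrl, 50, 600)
  ctrl <- mk(ctrl_lens)
  excess_lens <- 50 + rexp(5000L, rate = 1 / 120)
  treat <- mk(c(ctrl_lens, excess_lens))
  fit <- fragment_length_analysis(treat, ctrl, site,
                                  library_size_treated = 1e6,
                                  library_size_control = 1e6)
  expect_lt(abs(fit$lambda - 120) / 120, 0.10)
  expect_true(all(fit$hist_treated >= fit$hist_control - 1e-9))
  # identical conditions -> refusal
  expect_error(fragment_length_analysis(ctrl, ctrl, site),
               class = "multicut_fit_refused")
})

test_that("spanning-read RPM matches the classifier and recovers planted mixtures", {
  fx <- fixture_genome(copies = 2L)
  mix <- c(span = 0.3, prox_m4 = 0.4, dist_p4 = 0.3)
  fr <- make_cutsite_fragments(fx$sites, mix, n = 2000L, seed = 9L)
  rpm <- spanning_read_fraction(fr, fx$sites)
  for (i in seq_len(nrow(fx$sites))) {
    cs <- count_span_abut(fr[fr$site == i, ], fx$sites[i, ],
                          library_size = attr(fr, "library_size"))
    expect_equal(rpm[i], cs$span_rpm)
  }
  # 30% planted spanning fraction recovered (binomial tolerance)
  total_rpm <- 1e6
  expect_equal(sum(rpm) / total_rpm, 0.3, tolerance = 0.05)
  # all one-sided fragments -> zero spanning signal
  fr1 <- make_cutsite_fragments(fx$sites, c(prox_m4 = 0.5, dist_m4 = 0.5),
                                n = 200L, seed = 10L)
  expect_equal(spanning_read_fraction(fr1, fx$sites), c(0, 0))
})

test_that("profiles export to TSV and bedGraph", {
  cc <- 5000L
  site <- site_at("chr1", cc - 17L, "+")
  fr <- fragments("chr1", cc - 100L, cc + 100L, library_size = 1e6)
  prof <- bp_pileup(fr, site, radius = 150L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, tsv)
  back <- read.table(tsv, header = TRUE)
  expect_equal(back$value, prof$values)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_profile(prof, bg, format = "bedgraph", chrom = "chr1", center = cc)
  raw <- read.table(bg)
  expect_equal(raw$V2[1], cc - 150L)
})
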