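# Independent enumeration oracle: all variants of one 20-mer with up to
# max_mm substitutions confined to the `zone` most PAM-proximal (3'-most)
# positions, by exhaustive expansion.
oracle_variants <- function(seq20, max_mm, zone) {
  stopifnot(nchar(seq20) == 20L)
  zone_idx <- (20L - zone + 1L):20L
  out <- seq20
  for (k in seq_len(max_mm)) {
    combos <- combn(zone_idx, k)
    for (j in seq_len(ncol(combos))) {
      pos <- combos[, j]
      alt_sets <- lapply(pos, function(i) {
        setdiff(c("A", "C", "G", "T"), substr(seq20, i, i))
      })
      grid <- expand.grid(alt_sets, stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        v <- seq20
        for (q in seq_along(pos)) {
          substr(v, pos[q], pos[q]) <- grid[r, q]
        }
        out <- c(out, v)
      }
    }
  }
  unique(out)
}

test_that("candidate enumeration matches the exhaustive substitution oracle", {
  tpl <- GUIDE_A
  # small zone, full set equality against the oracle
  cfg <- discovery_config(max_template_mismatches = 2L, mismatch_zone = 4L,
                          gc_min = 0, gc_max = 1)
  got <- enumerate_candidates(tpl, cfg, strands = "+")$sequence
  want <- oracle_variants(tpl, 2L, 4L)
  expect_setequal(got, want)
  expect_length(got, 1 + choose(4, 1) * 3 + choose(4, 2) * 9)  # 67

  # the standard zone-9 / 3-mismatch setting yields 1 + 27 + 324 + 2268
  cfg9 <- discovery_config(gc_min = 0, gc_max = 1)
  got9 <- enumerate_candidates(tpl, cfg9, strands = "+")$sequence
  expect_length(got9, 2620L)
  expect_length(unique(got9), 2620L)
  # all mismatches confined to the 9 PAM-proximal string positions (12..20)
  tpl_chars <- strsplit(tpl, "")[[1]]
  diffs <- vapply(got9, function(v) {
    d <- which(strsplit(v, "")[[1]] != tpl_chars)
    length(d) <= 3L && all(d >= 12L)
  }, logical(1))
  expect_true(all(diffs))
})

test_that("a 20-nt template with no mismatches yields the substring and its reverse complement", {
  tpl <- GUIDE_A
  cfg <- discovery_config(max_template_mismatches = 0L, gc_min = 0, gc_max = 1)
  got <- enumerate_candidates(tpl, cfg)
  expect_setequal(got$sequence, c(tpl, reverse_complement(tpl)))
  # palindromic template: forward and reverse complement coincide
  pal <- "ACGTACGTACACGTACGTAC"   # not palindromic; build one
  pal <- paste0("ACGTACGTAC", reverse_complement("ACGTACGTAC"))
  expect_identical(pal, reverse_complement(pal))
  expect_identical(nrow(enumerate_candidates(pal, cfg)), 1L)
})

test_that("enumeration is invariant to template case and rejects bad templates", {
  cfg <- discovery_config(max_template_mismatches = 1L, gc_min = 0, gc_max = 1)
  up <- enumerate_candidates(GUIDE_A, cfg)
  lo <- enumerate_candidates(tolower(GUIDE_A), cfg)
  expect_setequal(up$sequence, lo$sequence)
  expect_error(enumerate_candidates("ACGT", cfg), "shorter")
  expect_error(enumerate_candidates(paste0(GUIDE_A, "N"), cfg), "A/C/G/T")
})

test_that("GC filter bounds are inclusive", {
  # 8/20 GC = 0.40 exactly; 7/20 = 0.35 below the band
  tpl40 <- paste0(strrep("A", 12), strrep("G", 8))
  tpl35 <- paste0(strrep("A", 13), strrep("G", 7))
  cfg <- discovery_config(max_template_mismatches = 0L)
  expect_true(tpl40 %in% enumerate_candidates(tpl40, cfg)$sequence)
  expect_false(tpl35 %in% enumerate_candidates(tpl35, cfg)$sequence)
  # 14/20 = 0.70 retained, 15/20 = 0.75 dropped
  tpl70 <- paste0(strrep("A", 6), strrep("C", 14))
  tpl75 <- paste0(strrep("A", 5), strrep("C", 15))
  expect_true(tpl70 %in% enumerate_candidates(tpl70, cfg)$sequence)
  expect_false(tpl75 %in% enumerate_candidates(tpl75, cfg)$sequence)
})

test_that("on-target search recovers exactly the planted sites and requires the PAM", {
  fx <- fixture_genome(copies = 3L, chrom_len = 100000L, seed = 21L)
  # add a decoy: guide sequence followed by a non-PAM
  g_str <- unclass(fx$genome)[["chr1"]]
  decoy_pos <- 90000L
  substr(g_str, decoy_pos + 1L, decoy_pos + 23L) <- paste0(GUIDE_A, "ATT")
  g <- genome(c(chr1 = g_str))
  hits <- find_on_targets(GUIDE_A, g)
  expect_identical(nrow(hits), 3L)
  expect_equal(hits$start, fx$sites$start)
  expect_equal(hits$strand, fx$sites$strand)
  expect_true(all(is_ngg(hits$pam)))
  expect_true(all(hits$n_mismatch == 0L))
  # candidate followed by ATT only -> no sites
  g2 <- genome(c(chr1 = paste0(strrep("T", 500), GUIDE_A, "ATT", strrep("T", 500))))
  expect_identical(nrow(find_on_targets(GUIDE_A, g2)), 0L)
})

test_that("on-target search agrees with a naive substring-scan oracle", {
  fx <- make_genome(n_chrom = 2L, chrom_len = 25000L,
                    planted = list(list(guide = GUIDE_A, copies = 4L),
                                   list(guide = GUIDE_B, copies = 2L)),
                    seed = 9L, min_spacing = 1500L)
  for (guide in c(GUIDE_A, GUIDE_B)) {
    hits <- find_on_targets(guide, fx$genome)
    orc <- oracle_scan(guide, fx$genome)
    # oracle finds all occurrences; keep the NGG-flanked ones
    keep <- vapply(seq_len(nrow(orc)), function(i) {
      pam <- if (orc$strand[i] == "+") {
        genome_slice(fx$genome, orc$chrom[i], orc$start[i] + 20L,
                     orc$start[i] + 23L, pad = TRUE)
      } else {
        reverse_complement(genome_slice(fx$genome, orc$chrom[i],
                                        orc$start[i] - 3L, orc$start[i],
                                        pad = TRUE))
      }
      is_ngg(pam)
    }, logical(1))
    orc <- orc[keep, , drop = FALSE]
    expect_identical(nrow(hits), nrow(orc))
    expect_setequal(paste(hits$chrom, hits$start, hits$strand),
                    paste(orc$chrom, orc$start, orc$strand))
  }
})

test_that("the site cap truncates deterministically ordered sites", {
  fx <- make_genome(n_chrom = 1L, chrom_len = 80000L,
                    planted = list(list(guide = GUIDE_A, copies = 15L)),
                    seed = 13L)
  cfg <- discovery_config(site_cap = 10L)
  hits <- find_on_targets(GUIDE_A, fx$genome, cfg)
  expect_identical(nrow(hits), 10L)
  expect_false(is.unsorted(hits$cut))
  # the retained 10 are the genomically first 10
  all_hits <- find_on_targets(GUIDE_A, fx$genome, discovery_config())
  expect_identical(nrow(all_hits), 15L)
  expect_equal(hits$start, all_hits$start[1:10])
})

test_that("mismatch vectors report PAM-counted positions of planted substitutions", {
  fx <- make_genome(
    n_chrom = 1L, chrom_len = 40000L,
    planted = list(list(guide = GUIDE_A, copies = 4L,
                        mismatch_positions = list(integer(0), c(2L), c(5L, 9L),
                                                  c(1L, 4L, 8L)))),
    seed = 31L)
  expect_setequal(vapply(fx$sites$mismatches, paste, "", collapse = ","),
                  c("", "2", "5,9", "1,4,8"))
  expect_setequal(fx$sites$n_mismatch, 0:3)
})

test_that("adjacent-site spacing statistics match a brute-force oracle", {
  s <- target_sites(rep("chr1", 3), c(83L, 283L, 883L), "+", GUIDE_A)
  st <- site_spacing_stats(s)   # cuts at 100, 300, 900
  expect_equal(st$mean_adjacent_bp, 400)
  expect_equal(st$median_adjacent_bp, 400)
  expect_identical(st$n_pairs, 2L)

  one_per <- target_sites(c("chr1", "chr2"), c(100L, 100L), "+", GUIDE_A)
  st0 <- site_spacing_stats(one_per)
  expect_identical(st0$n_pairs, 0L)
  expect_false(st0$defined)
  expect_true(is.na(st0$mean_adjacent_bp))

  set.seed(8)
  chroms <- sample(c("chr1", "chr2", "chr3"), 40, replace = TRUE)
  starts <- sample.int(1e6, 40)
  rnd <- target_sites(chroms, starts, "+", GUIDE_A)
  st_r <- site_spacing_stats(rnd)
  gaps <- unlist(lapply(split(rnd$cut, rnd$chrom), function(x) diff(sort(x))))
  expect_equal(st_r$mean_adjacent_bp, mean(gaps))
  expect_equal(st_r$median_adjacent_bp, median(gaps))
  expect_identical(st_r$n_pairs, length(gaps))
})

test_that("nucleotide composition is orientation-invariant and sums to one", {
  fx_p <- make_genome(planted = list(list(guide = GUIDE_A, copies = 6L,
                                          strands = "+")),
                      seed = 17L, chrom_len = 60000L)
  comp_p <- nucleotide_composition(fx_p$genome, fx_p$sites, radius = 25L)
  # protospacer offsets [-17, 3) are identical across sites: fraction 1.0
  proto_rows <- comp_p$offset >= -17 & comp_p$offset < 3
  expect_true(all(apply(comp_p[proto_rows, c("A", "C", "G", "T")], 1, max) == 1))
  # recovered consensus equals the guide
  consensus <- apply(comp_p[proto_rows, c("A", "C", "G", "T")], 1,
                     function(r) c("A", "C", "G", "T")[which.max(r)])
  expect_identical(paste(consensus, collapse = ""), GUIDE_A)
  # GG of the PAM at offsets 4 and 5
  expect_true(all(comp_p$G[comp_p$offset %in% c(4, 5)] == 1))
  # fractions sum to 1 at every offset
  expect_equal(rowSums(comp_p[, c("A", "C", "G", "T")]),
               rep(1, nrow(comp_p)))
  # minus-strand plantings give the identical protospacer block
  fx_m <- make_genome(planted = list(list(guide = GUIDE_A, copies = 6L,
                                          strands = "-")),
                      seed = 18L, chrom_len = 60000L)
  comp_m <- nucleotide_composition(fx_m$genome, fx_m$sites, radius = 25L)
  expect_equal(comp_m[proto_rows, c("A", "C", "G", "T")],
               comp_p[proto_rows, c("A", "C", "G", "T")])
  expect_error(nucleotide_composition(fx_p$genome, empty_sites(), 10L), "no sites")
})

test_that("site annotation labels gene context and chromatin-state consensus", {
  sites <- target_sites(c("chr1", "chr1", "chr2"), c(100L, 5000L, 100L),
                        "+", GUIDE_A)
  genes <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  mk_track <- function(lab1, lab2) {
    data.frame(chrom = "chr1", start = c(0L, 3000L), end = c(3000L, 10000L),
               label = c(lab1, lab2))
  }
  tracks <- list(mk_track("Quies", "Quies"), mk_track("Quies", "Quies"),
                 mk_track("Tx", "Tx"), mk_track("Tx", "Tx"))
  ann <- annotate_sites(sites, genes, tracks,
                        label_priority = c("Tx", "Quies"))
  expect_identical(ann$refseq_label, c("genic", "intergenic", "intergenic"))
  # 2-2 tie between Quies and Tx resolved by priority (Tx first)
  expect_identical(ann$chromhmm_label[1], "Tx")
  # chr2 missing from every track -> unannotated
  expect_identical(ann$chromhmm_label[3], "unannotated")
  # default priority favours the rarer label on ties: make Tx rarer
  tracks2 <- list(mk_track("Quies", "Quies"), mk_track("Quies", "Tx"),
                  mk_track("Tx", "Quies"), mk_track("Tx", "Quies"))
  ann2 <- annotate_sites(sites[1, ], genes, tracks2)
  expect_identical(ann2$chromhmm_label, "Tx")
})

test_that("label summaries pool sub-1% labels under Other", {
  labels <- c(rep("Quies", 600), rep("Tx", 395), rep("Enh", 5))
  s <- summarize_labels(labels)
  expect_setequal(names(s), c("Quies", "Tx", "Other"))
  expect_equal(unname(s["Other"]), 0.005)
  expect_equal(sum(s), 1)
})
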