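test_that("pattern parsing reports widths and rejects unsupported syntax", {
  expect_identical(parse_pattern("N-{P}-[ST]-{P}")$width_min, 4L)
  p <- parse_pattern("C-x(13)-C")
  expect_identical(p$width_min, 15L)
  expect_identical(p$width_max, 15L)
  expect_identical(parse_pattern("[ST]-x(2)-[DE]")$width_min, 4L)
  v <- parse_pattern("A-x(2,4)-B")
  expect_identical(c(v$width_min, v$width_max), c(4L, 6L))
  expect_error(parse_pattern("N-[ST"), "unsupported")
  expect_error(parse_pattern("N-<x>-C"), "unsupported")
})

test_that("scanning finds planted motifs at their positions", {
  set.seed(8)
  carrier <- strsplit(random_aa_string(60), "")[[1]]
  carrier[20:23] <- c("N", "A", "T", "A")
  s <- c(prot = paste(carrier, collapse = ""))
  h <- scan_prosite("N-{P}-[ST]-{P}", s)
  expect_true(any(h$start == 20 & h$matched == "NATA"))
  h2 <- scan_prosite("[ST]-x-[RK]", c(p = "ASSKA"))
  expect_identical(h2$matched, "SSK")
  expect_identical(h2$start, 2L)
  # sequence shorter than the pattern width: no hits
  expect_identical(nrow(scan_prosite("C-x(13)-C", c(p = "CAC"))), 0L)
})

test_that("overlapping matches are all reported, non-overlap mode is greedy", {
  s <- c(p = "SSKK")   # PKC pattern matches at both 1 (SSK) and 2 (SKK)
  h <- scan_prosite("[ST]-x-[RK]", s)
  expect_identical(h$start, c(1L, 2L))
  h2 <- scan_prosite("[ST]-x-[RK]", s, overlapping = FALSE)
  expect_identical(h2$start, 1L)
})

test_that("the scanner agrees with an independent regex oracle on random sequences", {
  patterns <- c("N-{P}-[ST]-{P}", "[ST]-x-[RK]", "[ST]-x(2)-[DE]",
                "G-{EDRKHPFYW}-x(2)-[STAGCN]-{P}", "x-G-[RK]-[RK]",
                "[RK](2)-x-[ST]", "C-x(13)-C", "A-x(1,3)-C",
                "<M-x-[DE]", "L-L>")
  set.seed(99)
  for (i in 1:300) {
    pat <- patterns[(i %% length(patterns)) + 1L]
    s <- random_aa_string(sample(10:60, 1))
    mine <- scan_prosite(pat, c(s = s))
    oracle <- prosite_regex_oracle(pat, s)
    expect_identical(mine$start, oracle$start, info = paste(pat, s))
    expect_identical(mine$matched, oracle$matched, info = paste(pat, s))
  }
})

test_that("every published phenolamine PTM motif matches its class pattern at its offset", {
  sites <- read.delim(system.file("extdata", "ptm_sites_phenolamine.tsv",
                                  package = "tsitescreen"),
                      comment.char = "#", stringsAsFactors = FALSE)
  catalog <- read_pattern_catalog()
  expect_gt(nrow(sites), 100L)
  set.seed(13)
  for (r in seq_len(nrow(sites))) {
    motif <- sites$motif[r]
    pos <- sites$position[r]
    pat <- catalog[[sites$pattern_id[r]]]
    # embed the motif at its printed offset in a random carrier
    carrier <- strsplit(random_aa_string(pos + nchar(motif) + 30L), "")[[1]]
    carrier[pos:(pos + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
    hits <- scan_prosite(pat, c(x = paste(carrier, collapse = "")))
    expect_true(any(hits$start == pos),
                info = paste(sites$receptor[r], motif, pos))
  }
})

test_that("fixed-width patterns produce equal-length matches", {
  set.seed(14)
  for (pat in c("N-{P}-[ST]-{P}", "C-x(13)-C", "[RK](2)-x-[ST]")) {
    p <- parse_pattern(pat)
    widths <- integer()
    for (i in 1:20) {
      h <- scan_prosite(p, c(s = random_aa_string(80)))
      widths <- c(widths, nchar(h$matched))
    }
    expect_true(all(widths == p$width_min))
  }
})

test_that("channel features report present, variant, and not-evaluable states", {
  set.seed(15)
  feats <- channel_features()
  # PAR planted 2 residues before the TM2 annotation
  v <- strsplit(random_aa_string(120), "")[[1]]
  v[48:50] <- c("P", "A", "R")
  prot <- c(sub1 = paste(v, collapse = ""))
  rep1 <- check_features(prot, list(TM2 = c(53, 72)),
                         feats[feats$feature_id == "pore_filter_PAR", ])
  expect_identical(rep1$status, "present")
  expect_identical(rep1$observed, "PAR")
  # KDR instead of GEK in the pore window: variant with observed residues
  v2 <- strsplit(random_aa_string(120), "")[[1]]
  v2[48:50] <- c("K", "D", "R")
  v2[45:47] <- c("W", "W", "W")  # no GEK anywhere in the window
  rep2 <- check_features(c(sub2 = paste(v2, collapse = "")),
                         list(TM2 = c(51, 70)),
                         feats[feats$feature_id == "pore_filter_GEK", ])
  expect_identical(rep2$status, "variant")
  expect_identical(rep2$observed, "KDR")
  # missing annotation: not evaluable
  rep3 <- check_features(prot, list(),
                         feats[feats$feature_id == "pore_filter_GEK", ])
  expect_identical(rep3$status, "not_evaluable")
  # absolute features: absent cys-loop
  noc <- c(s = gsub("C", "A", random_aa_string(100)))
  rep4 <- check_features(noc, list(),
                         feats[feats$feature_id == "cys_loop", ])
  expect_identical(rep4$status, "absent")
  # DEEA + MFL planted
  v3 <- strsplit(random_aa_string(150), "")[[1]]
  v3[40:43] <- c("D", "E", "E", "A")
  v3[90:92] <- c("M", "F", "L")
  rep5 <- check_features(c(sc1 = paste(v3, collapse = "")), list(),
                         feats[feats$feature_id %in%
                                 c("selectivity_filter_DEEA",
                                   "fast_inactivation_MFL"), ])
  expect_true(all(rep5$status == "present"))
  expect_identical(rep5$position, c(40L, 90L))
})

test_that("hydropathy helper proposes a planted hydrophobic segment", {
  set.seed(16)
  hydrophilic <- paste(sample(c("D", "E", "K", "R", "N", "Q"), 60,
                              replace = TRUE), collapse = "")
  tm <- paste(sample(c("I", "L", "V", "F"), 21, replace = TRUE), collapse = "")
  prot <- c(p = paste0(hydrophilic, tm, hydrophilic))
  seg <- kyte_doolittle_tm(prot)
  expect_identical(nrow(seg), 1L)
  expect_true(seg$start >= 55 && seg$end <= 90)
})
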