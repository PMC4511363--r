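test_that("candidate rules flag length, proline context and adjacent basics", {
  # LLQALR-like short peptide: length flag fails, peptide still reported
  rep1 <- evaluate_candidates("LLQALRAAAAAAAK")
  short <- rep1[rep1$sequence == "LLQALR", ]
  expect_equal(nrow(short), 1L)
  expect_false(short$length_ok)
  # adjacent basic residues inside the peptide
  rep2 <- evaluate_candidates("AAAKRTESTKGGGG")
  kr <- rep2[rep2$sequence == "AAAK", ]
  expect_false(kr$no_adjacent_basics)   # K followed by R at the boundary
  # blocked K.P junction inside a peptide
  rep3 <- evaluate_candidates("AAAKPEPTIDERGGGK")
  blocked <- rep3[rep3$sequence == "AAAKPEPTIDER", ]
  expect_equal(nrow(blocked), 1L)
  expect_false(blocked$no_proline_block)
})

test_that("rule flags agree with a regex oracle on random proteins", {
  set.seed(21)
  for (i in 1:20) {
    prot <- random_protein(sample(12:60, 1))
    rep <- evaluate_candidates(prot)
    for (j in seq_len(nrow(rep))) {
      seq <- rep$sequence[j]
      after <- if (rep$end[j] < nchar(prot))
        substring(prot, rep$end[j] + 1, rep$end[j] + 1) else ""
      before <- if (rep$start[j] > 1)
        substring(prot, rep$start[j] - 1, rep$start[j] - 1) else ""
      expect_equal(rep$length_ok[j], nchar(seq) >= 8 && nchar(seq) <= 15)
      expect_equal(rep$no_proline_block[j],
                   !grepl("^P", seq) && !grepl("[KR]P", paste0(seq, after)))
      expect_equal(rep$no_adjacent_basics[j],
                   !grepl("[KR][KR]", paste0(before, seq, after)))
    }
  }
})

test_that("ranking prefers rule-satisfying peptides, ties by position", {
  rep <- evaluate_candidates("LLQALRAAAAAAAKGGGGGGGGGK")
  expect_equal(rep$sequence[1], "AAAAAAAK")  # first full-score peptide
  expect_true(all(diff(rep$score) <= 0))
})

test_that("uniqueness screen applies the cleavage-context rule", {
  bg <- c(P1 = "MMMALLQALRDMMM",   # preceded by A: not liberable
          P2 = "MMMKLLQALRDMMM",   # preceded by K: liberable
          P3 = "MMMMMMM")
  expect_equal(uniqueness_screen("LLQALR", bg["P1"])$verdict,
               "shared-context-unique")
  s <- uniqueness_screen("LLQALR", bg[c("P1", "P2")])
  expect_equal(s$verdict, "shared")
  expect_equal(s$conflicts, "P2")
  expect_equal(uniqueness_screen("LLQALR", bg["P3"])$verdict, "unique")
  # a hit at position 1 counts as liberable (mature N-terminus)
  expect_equal(uniqueness_screen("LLQALR", c(P4 = "LLQALRMMM"))$verdict,
               "shared")
})

test_that("uniqueness verdicts are invariant under background order", {
  bg <- c(A = "MMMALLQALRD", B = "KKKLLQALRD", C = "GGGG")
  s1 <- uniqueness_screen("LLQALR", bg)
  s2 <- uniqueness_screen("LLQALR", rev(bg))
  expect_equal(s1$verdict, s2$verdict)
  expect_setequal(s1$conflicts, s2$conflicts)
})

test_that("QconCAT assembly releases every peptide on digestion", {
  d <- assemble_qconcat(c("AAAK", "CCCR"), tag = "HHHHHH")
  expect_equal(d$sequence, "AAAKCCCRHHHHHH")
  expect_true(all(c("AAAK", "CCCR") %in% digest(d$sequence, 0)$sequence))
  expect_equal(d$molar_mass, peptide_mass(d$sequence, "average"))
  expect_equal(d$release, c(1L, 1L))
  # single peptide, empty tag: concatamer is the peptide itself
  expect_equal(assemble_qconcat("AAAK")$sequence, "AAAK")
  expect_error(assemble_qconcat(c("AAAK", "PCCR")), "begins with P")
  expect_error(assemble_qconcat(c("AAAA", "CCCR")), "end in K or R")
})

test_that("assembly then digestion recovers the peptide multiset", {
  set.seed(31)
  for (i in 1:10) {
    peps <- replicate(sample(2:5, 1), {
      body <- random_protein(sample(4:10, 1))
      body <- gsub("[KRP]", "A", body)      # keep internal sites out
      paste0(body, sample(c("K", "R"), 1))
    })
    d <- assemble_qconcat(peps, tag = "HHHHHH")
    released <- digest(d$sequence, 0)$sequence
    for (p in unique(peps))
      expect_gte(sum(released == p), sum(peps == p))
  }
})

test_that("mass/molar conversion reproduces the weighed standard", {
  molar_mass <- 5.8 / 99.15 * 1e12 / 1e6      # back-computed from the pair
  expect_equal(ug_to_pmol(5.8, molar_mass), 99.15, tolerance = 1e-6)
  expect_equal(ug_to_pmol(5.8, 58497), 99.15, tolerance = 1e-4)
  expect_equal(ug_to_pmol(0, 58497), 0)
  x <- 12.34
  expect_equal(pmol_to_ug(ug_to_pmol(x, 43210), 43210), x,
               tolerance = 1e-9)
  expect_error(ug_to_pmol(1, 0), "positive")
})

test_that("labelling-efficiency correction recovers the true ratio", {
  expect_equal(labelling_efficiency_correction(1.7, 0), 1.7)
  # synthetic leakage: true analyte A, spike S, unlabelled fraction f
  A <- 30; S <- 50; f <- 0.05
  observed <- (A + f * S) / ((1 - f) * S)
  corrected <- labelling_efficiency_correction(observed, f)
  expect_equal(S * corrected, A, tolerance = 1e-12)
  uncorrected_err <- abs(S * observed - A)
  expect_lt(abs(S * corrected - A), uncorrected_err)
  expect_warning(out <- labelling_efficiency_correction(0.01, 0.5),
                 "negative")
  expect_true(is.na(out))
  expect_error(labelling_efficiency_correction(1, 1), "\\[0, 1\\)")
})

test_that("designs round-trip through FASTA and the sidecar table", {
  d <- assemble_qconcat(c("LLQALR", "AAAGGGK"), tag = "HHHHHH")
  fa <- tempfile(fileext = ".fasta"); csv <- tempfile(fileext = ".csv")
  tab <- write_design(d, fa, csv)
  back <- read_fasta(fa)
  expect_equal(unname(back), d$sequence)
  tab2 <- utils::read.csv(csv)
  expect_equal(tab2$sequence, d$peptides)
  expect_equal(tab2$heavy_mono - tab2$light_mono,
               d$nitrogen * N15_SHIFT, tolerance = 1e-6,
               ignore_attr = TRUE)
})
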