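test_that("find_matches agrees with knowns, the regex oracle and Biostrings", {
  expect_equal(find_matches("GGTTTATCC", "TTTAT", "given")$position, 3L)
  expect_equal(find_matches("CTAATGA", "YTAATKV", "given")$position, 1L)
  asc <- find_matches("GGCGCGCC", "GGCGCGCC", "both")
  expect_equal(asc$position, c(1L, 1L))
  expect_setequal(asc$strand, c("+", "-"))
  expect_equal(nrow(find_matches("ACG", "YTAATKV")), 0L)  # pattern > seq
  set.seed(61)
  for (i in 1:25) {
    b <- random_dna(sample(50:400, 1))
    code <- sample(c("TTTAT", "YTAATKV", "GGATCC", "WWNAT", "RYK"), 1)
    got <- find_matches(b, code, "both")
    ora <- oracle_scan(b, code, "both")
    expect_equal(got$position, ora$position)
    expect_equal(got$strand, ora$strand)
    # third route: Biostrings degenerate matching, plus strand
    bs <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(code), Biostrings::DNAString(b), fixed = FALSE))
    expect_equal(got$position[got$strand == "+"], sort(bs))
  }
})

test_that("circular scans see windows across the origin seam", {
  # TTTAT split by the origin: ...TTT | AT...
  s <- nuc_seq(paste0("AT", random_dna(20), "TTT"), topology = "circular")
  hits <- find_matches(s, "TTTAT", "given")
  expect_true(23L %in% hits$position)
  lin <- nuc_seq(as.character(s), topology = "linear")
  expect_false(23L %in% find_matches(lin, "TTTAT", "given")$position)
})

test_that("fixed replacement scrub applies the stated substitution", {
  res <- scrub_noncoding("GGTTTATCC", spacer_rules())
  expect_equal(as.character(res$seq), "GGTTGGGCC")
  expect_true(res$report$converged)
  expect_equal(nrow(res$report$residual), 0L)
  expect_equal(res$report$edits$from, "TTTAT")
  expect_equal(res$report$edits$to, "TTGGG")
  # a minus-strand occurrence gets the reverse-complemented replacement
  res2 <- scrub_noncoding(oracle_revcomp("GGTTTATCC"), spacer_rules())
  expect_equal(as.character(res2$seq), oracle_revcomp("GGTTGGGCC"))
  # no matches: unchanged, zero edits
  res3 <- scrub_noncoding("GGGGCCCC", spacer_rules())
  expect_equal(as.character(res3$seq), "GGGGCCCC")
  expect_equal(nrow(res3$report$edits), 0L)
})

test_that("fixed-replacement rules take priority over substitute_min", {
  # Hox-like match sits left of the TTTAT match, but TTTAT is fixed first
  s <- paste0("CTAATGA", random_dna(10), "TTTAT")
  set.seed(3)
  res <- scrub_noncoding(s, spacer_rules())
  expect_equal(res$report$edits$rule[1], "AbdB")
})

test_that("plant-then-scrub converges to a certified zero-residual state", {
  cutters <- c("NheI", "SbfI", "SpeI", "SacII", "AgeI")
  rules <- spacer_rules(cutters)
  patterns <- c("TTTAT", "YTAATKV",
                vapply(cutters, function(nm)
                  restriction_enzyme(nm)$recognition, character(1)))
  spec <- fixture_spec(97, 10000, 0.42, planted = list(
    list(pattern = degenerate_pattern("TTTAT", "AbdB"), count = 20,
         strand = "random"),
    list(pattern = degenerate_pattern("YTAATKV", "Hox-like"), count = 20,
         strand = "random"),
    list(pattern = degenerate_pattern("GCTAGC", "NheI"), count = 4,
         strand = "random"),
    list(pattern = degenerate_pattern("CCTGCAGG", "SbfI"), count = 4,
         strand = "random")))
  fx <- generate_fixture(spec)
  res <- scrub_noncoding(fx$seq, rules)
  expect_true(res$report$converged)
  expect_equal(seq_length(res$seq), 10000L)               # length preserved
  # independent certification, package route and regex-oracle route
  vc <- verify_clean(res$seq, rules)
  expect_true(vc$clean)
  expect_true(oracle_clean(as.character(res$seq), patterns))
  # every edit lies inside the sequence
  expect_true(all(res$report$edits$position >= 1 &
                  res$report$edits$position <= 10000))
  # idempotence: scrubbing the converged output again does nothing
  res2 <- scrub_noncoding(res$seq, rules)
  expect_equal(nrow(res2$report$edits), 0L)
  expect_equal(as.character(res2$seq), as.character(res$seq))
})

test_that("scrub works across the origin of circular sequences", {
  core <- scrub_noncoding(random_dna(300), spacer_rules())$seq
  # plant TTTAT across the seam: TAT at start, TT at end
  b <- paste0("TAT", substr(as.character(core), 1, 290), "TT")
  s <- nuc_seq(b, topology = "circular")
  expect_true(294L %in% find_matches(s, "TTTAT", "given")$position)
  res <- scrub_noncoding(s, spacer_rules())
  expect_true(res$report$converged)
  expect_true(verify_clean(res$seq, spacer_rules())$clean)
  expect_equal(seq_length(res$seq), seq_length(s))
})

test_that("conflicting fixed replacements fail explicitly with a report", {
  rules <- list(
    forbidden_rule("TTTAT", action = "fixed_replacement",
                   replacement = "TTGGG", strand_policy = "given"),
    forbidden_rule("TTGGG", action = "fixed_replacement",
                   replacement = "TTTAT", strand_policy = "given"))
  err <- expect_error(scrub_noncoding("AATTTATAA", rules, max_iter = 50),
                      class = "rlgl_scrub_error")
  expect_false(err$report$converged)
  expect_gt(nrow(err$report$residual), 0L)
})

test_that("replacement text validation catches malformed rules", {
  expect_error(forbidden_rule("TTTAT", action = "fixed_replacement",
                              replacement = "TTGG"), "same length")
  expect_error(forbidden_rule("TTTAT", action = "fixed_replacement",
                              replacement = "TTGGN"), "concrete")
})

test_that("synonymous coding scrub destroys the site and conserves protein", {
  res <- scrub_coding_synonymous("ATGCCTGCAGGA", "CCTGCAGG")
  expect_equal(translate_cds(res$seq), "MPAG")
  expect_equal(nrow(find_matches(res$seq, "CCTGCAGG", "both")), 0L)
  expect_equal(nrow(res$report$edits), 1L)   # a single codon change suffices
  expect_equal(sum(strsplit(as.character(res$seq), "")[[1]] !=
                   strsplit("ATGCCTGCAGGA", "")[[1]]), 1L)
  # CDS without the site is untouched
  res2 <- scrub_coding_synonymous("ATGAAATTTGGG", "CCTGCAGG")
  expect_equal(as.character(res2$seq), "ATGAAATTTGGG")
  expect_equal(nrow(res2$report$edits), 0L)
})

test_that("coding scrub conserves translation on random CDS fixtures", {
  set.seed(71)
  sites <- c(SbfI = "CCTGCAGG", StuI = "AGGCCT", NheI = "GCTAGC")
  for (i in 1:20) {
    nm <- sample(names(sites), 1)
    site <- sites[[nm]]
    orf <- random_orf_chr(60)
    # overwrite whole codons with the site padded in-frame (site at a codon
    # boundary, padding keeps frame): always leaves a synonymous escape
    k <- sample(5:40, 1)
    pad <- c(CCTGCAGG = "C", AGGCCT = "", GCTAGC = "")[[site]]
    block <- paste0(site, pad)
    block <- paste0(block, strrep("A", (3 - nchar(block) %% 3) %% 3))
    cds0 <- paste0(substr(orf, 1, 3 * (k - 1)), block,
                   substr(orf, 3 * (k - 1) + nchar(block) + 1, nchar(orf)))
    if (nchar(cds0) %% 3 != 0) next
    before <- nrow(find_matches(cds0, site, "both"))
    if (before == 0) next
    res <- scrub_coding_synonymous(cds0, degenerate_pattern(site, nm))
    expect_equal(nrow(find_matches(res$seq, site, "both")), 0L)
    # codon-by-codon conservation, independent translation route
    aa_pkg <- translate_cds(res$seq)
    aa_ora <- paste(seqinr::translate(strsplit(tolower(cds0), "")[[1]]),
                    collapse = "")
    expect_equal(aa_pkg, aa_ora)
  }
})

test_that("coding scrub fails explicitly when no synonymous escape exists", {
  # ATG TGG ATG TGG: Met and Trp codons only; destroy any window? plant a
  # site made entirely of Met/Trp codons: ATGG repeated contains no
  # degenerate escape. Use pattern equal to the full sequence.
  err <- expect_error(
    scrub_coding_synonymous("ATGTGGATGTGG", "ATGTGGATGTGG"),
    class = "rlgl_scrub_error")
  expect_false(err$report$converged)
})

test_that("verify_clean reports residual matches with positions", {
  set.seed(81)
  vc <- verify_clean(paste0(random_dna(20), "ACCGGT", random_dna(20)),
                     spacer_rules("AgeI"))
  expect_false(vc$clean)
  expect_true(21L %in% vc$matches$position)
  res <- scrub_noncoding(random_dna(500), spacer_rules("AgeI"))
  expect_true(verify_clean(res$seq, spacer_rules("AgeI"))$clean)
})
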