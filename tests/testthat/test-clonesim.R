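test_that("bundled enzyme chemistry matches the standard catalog", {
  tab <- enzyme_table()
  expect_equal(nrow(tab), 13L)
  # frozen overhang regressions (validated against the REBASE catalog)
  ov <- function(nm) {
    e <- restriction_enzyme(nm)
    lo <- min(e$cut_top, e$cut_bottom); hi <- max(e$cut_top, e$cut_bottom)
    list(seq = substr(e$recognition, lo + 1, hi), kind = e$overhang)
  }
  expect_equal(ov("EcoRI"), list(seq = "AATT", kind = "5p"))
  expect_equal(ov("BamHI"), list(seq = "GATC", kind = "5p"))
  expect_equal(ov("BglII"), list(seq = "GATC", kind = "5p"))
  expect_equal(ov("SbfI"),  list(seq = "TGCA", kind = "3p"))
  expect_equal(ov("SacII"), list(seq = "GC",   kind = "3p"))
  expect_equal(ov("FseI"),  list(seq = "CCGG", kind = "3p"))
  expect_equal(ov("NotI"),  list(seq = "GGCC", kind = "5p"))
  expect_equal(ov("StuI"),  list(seq = "",     kind = "blunt"))
  # every recognition sequence is palindromic
  for (i in seq_len(nrow(tab)))
    expect_equal(oracle_revcomp(tab$recognition[i]), tab$recognition[i])
  expect_error(restriction_enzyme("HindIII"), "unknown enzyme")
})

test_that("digest produces correct fragment counts and end chemistry", {
  set.seed(91)
  clean <- function(n) scrub_noncoding(random_dna(n),
                                       spacer_rules(c("EcoRI", "BamHI",
                                                      "StuI")))$seq$bases
  # circular plasmid, one EcoRI site -> one linear fragment, AATT 5' ends
  plas <- nuc_seq(paste0("GAATTC", clean(94)), "p", "circular")
  fr <- digest(plas, "EcoRI")
  expect_length(fr, 1L)
  expect_equal(fragment_length(fr[[1]]), 100L)
  expect_equal(fr[[1]]$left_end, list(overhang = "AATT", polarity = "5p"))
  expect_equal(fr[[1]]$right_end, list(overhang = "AATT", polarity = "5p"))
  # circular plasmid, one StuI site -> one blunt fragment
  plas2 <- nuc_seq(paste0("AGGCCT", clean(60)), "p2", "circular")
  fr2 <- digest(plas2, "StuI")
  expect_length(fr2, 1L)
  expect_equal(fr2[[1]]$left_end$polarity, "blunt")
  expect_equal(fr2[[1]]$right_end$polarity, "blunt")
  # linear 60-mer, two BamHI sites -> 3 fragments, lengths sum to 60
  lin <- nuc_seq(paste0(substr(clean(60), 1, 14), "GGATCC",
                        substr(clean(60), 15, 34), "GGATCC",
                        substr(clean(60), 35, 48)), "lin")
  expect_equal(seq_length(lin), 60L)
  fr3 <- digest(lin, "BamHI")
  expect_length(fr3, 3L)
  expect_equal(sum(vapply(fr3, fragment_length, integer(1))), 60L)
  expect_equal(fr3[[2]]$left_end, list(overhang = "GATC", polarity = "5p"))
  # absent enzyme: uncut substrate with a warning flag
  fr4 <- digest(nuc_seq(clean(50)), "XhoI")
  expect_length(fr4, 1L)
  expect_match(fr4[[1]]$warning, "uncut")
})

test_that("digest/ligate round-trips and conserves nucleotides", {
  set.seed(101)
  enz_pool <- c("EcoRI", "BamHI", "AscI", "SbfI", "StuI", "XhoI")
  for (i in 1:40) {
    picks <- sample(enz_pool, 2)
    backbone <- scrub_noncoding(random_dna(sample(150:400, 1)),
                                spacer_rules(picks))$seq$bases
    nsites <- sample(1:3, 1)
    ins <- sample(nchar(backbone) - 10, nsites)
    b <- backbone
    for (p in sort(ins, decreasing = TRUE)) {
      site <- restriction_enzyme(sample(picks, 1))$recognition
      b <- paste0(substr(b, 1, p), site, substr(b, p + 1, nchar(b)))
    }
    circ <- sample(c(TRUE, FALSE), 1)
    s <- nuc_seq(b, "sub", if (circ) "circular" else "linear")
    fr <- digest(s, picks)
    expect_equal(length(fr), if (circ) nsites else nsites + 1L)
    expect_equal(sum(vapply(fr, fragment_length, integer(1))), nchar(b))
    lg <- ligate(fr, circularize = circ, enzymes = picks)
    if (circ) expect_true(same_circle(as.character(lg$map$seq), b))
    else expect_equal(as.character(lg$map$seq), b)
  }
})

test_that("BamHI x BglII religation leaves a scar cut by neither enzyme", {
  set.seed(111)
  clean <- scrub_noncoding(random_dna(120),
                           spacer_rules(c("BamHI", "BglII")))$seq$bases
  a <- nuc_seq(paste0(substr(clean, 1, 30), "GGATCC", substr(clean, 31, 60)))
  b <- nuc_seq(paste0(substr(clean, 61, 90), "AGATCT",
                      substr(clean, 91, 120)))
  fa <- digest(a, "BamHI")
  fb <- digest(b, "BglII")
  lg <- ligate(list(fa[[1]], fb[[2]]), enzymes = c("BamHI", "BglII"))
  junction <- substr(as.character(lg$map$seq), 30, 37)
  expect_equal(substr(junction, 2, 7), "GGATCT")         # the hybrid scar
  expect_equal(lg$junctions$recut_by, "")
  expect_equal(nrow(find_matches(lg$map$seq, "GGATCC", "both")), 0L)
  expect_equal(nrow(find_matches(lg$map$seq, "AGATCT", "both")), 0L)
})

test_that("ligation junction reporting and compatibility rules", {
  set.seed(121)
  clean <- scrub_noncoding(random_dna(80),
                           spacer_rules(c("EcoRI", "BamHI")))$seq$bases
  e1 <- digest(nuc_seq(paste0(substr(clean, 1, 20), "GAATTC",
                              substr(clean, 21, 40))), "EcoRI")
  # EcoRI end + EcoRI end regenerates a cuttable GAATTC
  lg <- ligate(list(e1[[1]], e1[[2]]), enzymes = "EcoRI")
  expect_match(lg$junctions$recut_by, "EcoRI")
  expect_equal(as.character(lg$map$seq),
               paste0(substr(clean, 1, 20), "GAATTC", substr(clean, 21, 40)))
  # EcoRI overhang (AATT) cannot ligate to BamHI overhang (GATC)
  b1 <- digest(nuc_seq(paste0(substr(clean, 41, 60), "GGATCC",
                              substr(clean, 61, 80))), "BamHI")
  expect_error(ligate(list(e1[[1]], b1[[2]])), "incompatible")
  # blunt ligates blunt
  st <- digest(nuc_seq(paste0(substr(clean, 1, 10), "AGGCCT",
                              substr(clean, 11, 20))), "StuI")
  lg2 <- ligate(list(st[[1]], st[[2]]), enzymes = "StuI")
  expect_match(lg2$junctions$recut_by, "StuI")   # blunt religation restores
})

test_that("PCR with published tailed primers yields the expected structure", {
  pr <- enhancer_primers()
  fwd <- primer(pr$sequence[pr$primer == "BE2.5 Fwd"], "BE2.5F",
                min_anneal = 20)
  rev <- primer(pr$sequence[pr$primer == "BE3.5 Rvs"], "BE3.5R",
                min_anneal = 20)
  set.seed(131)
  fa <- substr(fwd$full, nchar(fwd$full) - 19, nchar(fwd$full))
  ra <- substr(rev$full, nchar(rev$full) - 19, nchar(rev$full))
  tpl <- nuc_seq(paste0(random_dna(60), fa, random_dna(380),
                        oracle_revcomp(ra), random_dna(60)))
  amp <- simulate_pcr(tpl, fwd, rev)
  expect_equal(amp$left_end$polarity, "blunt")
  # product carries both full primers at its termini, tails included
  expect_true(startsWith(as.character(amp$body), fwd$full))
  expect_true(endsWith(as.character(amp$body), oracle_revcomp(rev$full)))
  expect_match(as.character(amp$body), "GGCGCGCC")   # AscI tail
  expect_match(as.character(amp$body), "CCTGCAGG")   # SbfI tail
  # full fwd primer + inter-footprint template + full rev primer
  expect_equal(fragment_length(amp),
               nchar(fwd$full) + 380L + nchar(rev$full))
})

test_that("degenerate primer bases anneal to compatible template bases", {
  pr <- enhancer_primers()
  fwd_full <- pr$sequence[pr$primer == "sub1orthoF1"]   # contains S
  fwd <- primer(fwd_full, "sub1orthoF1", min_anneal = 15)
  anneal <- substr(fwd_full, nchar(fwd_full) - 14, nchar(fwd_full))
  expect_match(anneal, "S")
  set.seed(141)
  for (b in c("C", "G")) {                 # S = G or C
    concrete <- gsub("S", b, anneal)
    tpl <- nuc_seq(paste0(random_dna(40), concrete, random_dna(100),
                          oracle_revcomp("GTCATGCATGGTCATG"),
                          random_dna(30)))
    amp <- simulate_pcr(tpl, fwd, primer("GTCATGCATGGTCATG", "r", 16))
    # annealed degenerate position resolves to the template base
    expect_match(as.character(amp$body), concrete, fixed = TRUE)
  }
  tplA <- nuc_seq(paste0(random_dna(40), gsub("S", "A", anneal),
                         random_dna(60)))
  expect_error(simulate_pcr(tplA, fwd, primer("GTCATGCATGGTCATG", "r", 16)),
               class = "rlgl_pcr_error")
})

test_that("PCR fails explicitly on missing or ambiguous primer sites", {
  set.seed(151)
  f <- primer("GATCCATGCATGGTCA", "f", 16)
  r <- primer("TTGGCCAATTGGCCTA", "r", 16)
  tpl1 <- nuc_seq(paste0(f$full, random_dna(100)))   # rev footprint absent
  err1 <- expect_error(simulate_pcr(tpl1, f, r), class = "rlgl_pcr_error")
  expect_match(conditionMessage(err1), "no amplicon")
  tpl2 <- nuc_seq(paste0(f$full, random_dna(50), f$full, random_dna(50),
                         oracle_revcomp(r$full)))
  err2 <- expect_error(simulate_pcr(tpl2, f, r), class = "rlgl_pcr_error")
  expect_match(conditionMessage(err2), "ambiguous")
})

test_that("homology-arm assembly is seamless and checks both arms", {
  set.seed(161)
  v <- random_dna(300)
  core <- random_dna(150)
  insert <- paste0(substr(v, 286, 300), core, substr(v, 1, 15))
  asm <- infusion_assemble(nuc_seq(v, "vec"), nuc_seq(insert, "ins"),
                           arm_len = 15)
  expect_equal(asm$seq$topology, "circular")
  expect_equal(seq_length(asm$seq), 300 + nchar(insert) - 30)
  expect_equal(as.character(asm$seq), paste0(v, core))
  bad <- paste0(random_dna(15), core, substr(v, 1, 15))
  expect_error(infusion_assemble(nuc_seq(v), nuc_seq(bad), 15), "5' end")
  bad2 <- paste0(substr(v, 286, 300), core, random_dna(15))
  expect_error(infusion_assemble(nuc_seq(v), nuc_seq(bad2), 15), "3' end")
})

test_that("assembly then unique-site digest and religation round-trips", {
  set.seed(171)
  v <- paste0(scrub_noncoding(random_dna(140), spacer_rules("XhoI"))$seq$bases,
              "CTCGAG",
              scrub_noncoding(random_dna(140), spacer_rules("XhoI"))$seq$bases)
  core <- scrub_noncoding(random_dna(100), spacer_rules("XhoI"))$seq$bases
  insert <- paste0(substr(v, nchar(v) - 14, nchar(v)), core, substr(v, 1, 15))
  asm <- infusion_assemble(nuc_seq(v, "vec"), nuc_seq(insert, "ins"), 15)
  fr <- digest(asm, "XhoI")
  expect_length(fr, 1L)
  relig <- ligate(fr, circularize = TRUE, enzymes = "XhoI")
  expect_true(same_circle(as.character(relig$map$seq),
                          as.character(asm$seq)))
})
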