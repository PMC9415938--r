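# Hydropathy, C-terminal transmembrane detection, CpcG/CpcL separation and
# canonical vs FaRLiP ApcE classification.

test_that("hydropathy windows equal the Kyte-Doolittle means", {
  # homopolymer windows give the scale value itself
  expect_equal(hydropathy(strrep("L", 19))$score, 3.8)
  expect_equal(hydropathy(strrep("R", 19))$score, -4.5)
  # mixed sequence against the brute-force oracle
  set.seed(301)
  p <- random_protein(25)
  expect_equal(hydropathy(p)$score, hydropathy_oracle(p, 19))
  p2 <- random_protein(120)
  expect_equal(hydropathy(p2, 11)$score, hydropathy_oracle(p2, 11))
})

test_that("unknown residues count as zero hydropathy with a warning", {
  expect_warning(h <- hydropathy(paste0(strrep("L", 18), "X")), "unknown")
  expect_equal(h$score, 3.8 * 18 / 19)
})

test_that("C-terminal transmembrane detection obeys the position rule", {
  body <- hydrophilic_tail(150)
  tailp <- paste0(body, strrep("L", 20))
  tm <- detect_cterm_tm(hydropathy(tailp))
  expect_false(is.null(tm))
  expect_gte(tm[["end"]], nchar(tailp) - 60 + 1)
  # same helix at the N-terminus does not count
  headp <- paste0(strrep("L", 20), body)
  expect_null(detect_cterm_tm(hydropathy(headp)))
  # all-Gly protein is everywhere below threshold
  expect_null(detect_cterm_tm(hydropathy(strrep("G", 120))))
})

test_that("detection agrees with the brute-force run scan on random proteins", {
  set.seed(302)
  agree <- 0L
  for (i in 1:200) {
    n <- sample(80:300, 1)
    p <- random_protein(n)
    # occasionally graft a hydrophobic patch to exercise the positive path
    if (i %% 4 == 0) {
      at <- sample(n - 25, 1)
      p <- paste0(substring(p, 1, at), strrep("L", sample(15:30, 1)),
                  substring(p, at + 1))
    }
    got <- detect_cterm_tm(hydropathy(p))
    want <- tm_oracle(p)
    same <- (is.null(got) && is.null(want)) ||
      (!is.null(got) && !is.null(want) && all(got == want))
    agree <- agree + same
  }
  expect_equal(agree, 200L)
})

test_that("rod linkers split into CpcG and CpcL by the C-terminal helix", {
  cpcg <- ref_seq("cpcG_ref")
  cpcl <- ref_seq("cpcL_ref")
  g <- build_genome(list(list(protein = cpcg), list(protein = cpcl)),
                    genome_id = "rl")
  calls <- classify_linkers(g, REFS)
  expect_equal(calls$klass, c("CpcG", "CpcL"))
  # the CpcL exemplar helix agrees with the hand-run oracle
  want <- tm_oracle(cpcl)
  expect_equal(c(calls$tm_start[[2]], calls$tm_end[[2]]), unname(want))
})

test_that("appending a hydrophobic tail flips CpcG to CpcL; prepending does not", {
  cpcg <- ref_seq("cpcG_ref")
  hits <- find_domains(cpcg, REFS, kinds = "PBS-linker")
  expect_equal(classify_rod_linker("a", cpcg, hits)$klass, "CpcG")
  flipped <- paste0(cpcg, strrep("L", 20))
  expect_equal(classify_rod_linker("b", flipped,
    find_domains(flipped, REFS, kinds = "PBS-linker"))$klass, "CpcL")
  fronted <- paste0(strrep("L", 20), cpcg)
  expect_equal(classify_rod_linker("c", fronted,
    find_domains(fronted, REFS, kinds = "PBS-linker"))$klass, "CpcG")
})

test_that("ApcE variants separate by repeat count, Cys and motif", {
  g <- build_genome(list(list(protein = ref_seq("apcE_ref")),
                         list(protein = ref_seq("apcE_farlip_ref"))),
                    genome_id = "ae")
  calls <- classify_linkers(g, REFS)
  expect_equal(calls$klass, c("ApcE-canonical", "ApcE-FaRLiP"))
  expect_equal(calls$linker_repeat_count, c(3L, 2L))
  expect_equal(calls$n_domain_cys, c(TRUE, FALSE))
  expect_equal(calls$n_domain_motif, c("ExACS", "PEDVT"))
})

test_that("two repeats with Cys present stays canonical with a discordance note", {
  far <- ref_seq("apcE_farlip_ref")
  # restore the chromophore Cys in the FaRLiP N-domain (reference column 84)
  hits <- find_domains(far, REFS, kinds = c("PBS-linker", "phycobiliprotein"))
  pbp <- hits[hits$domain_kind == "phycobiliprotein", ][1, ]
  with_cys <- paste0(substring(far, 1, 83), "C", substring(far, 85))
  call <- classify_apce("x", with_cys,
                        find_domains(with_cys, REFS,
                                     kinds = c("PBS-linker", "phycobiliprotein")),
                        REFS)
  expect_equal(call$klass, "ApcE-canonical")
  expect_equal(call$linker_repeat_count, 2L)
  expect_match(call$evidence, "discordant")
})

test_that("ApcE classification is invariant to linker-repeat order", {
  # rebuild the canonical exemplar with its two distinct repeats swapped
  ndom <- substring(ref_seq("apcE_farlip_ref"), 1, 160)
  set.seed(303)
  repA <- mutate_protein(ref_seq("LNK_ref"), 0.15)
  repB <- mutate_protein(ref_seq("LNK_ref"), 0.15)
  spacer <- random_protein(10)
  v1 <- paste0(ndom, spacer, repA, spacer, repB)
  v2 <- paste0(ndom, spacer, repB, spacer, repA)
  c1 <- classify_apce("v1", v1, find_domains(v1, REFS), REFS)
  c2 <- classify_apce("v2", v2, find_domains(v2, REFS), REFS)
  expect_equal(c1$klass, c2$klass)
  expect_equal(c1$linker_repeat_count, c2$linker_repeat_count)
  expect_equal(c1$klass, "ApcE-FaRLiP")
})

test_that("proteins without the expected domains fall to linker-other", {
  set.seed(304)
  p <- random_protein(150)
  expect_equal(classify_rod_linker("x", p,
    find_domains(p, REFS, kinds = "PBS-linker"))$klass, "linker-other")
  lnk_only <- paste0(random_protein(10), ref_seq("LNK_ref"))
  expect_equal(classify_apce("y", lnk_only,
    find_domains(lnk_only, REFS), REFS)$klass, "linker-other")
})
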