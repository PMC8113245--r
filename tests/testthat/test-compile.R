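fluor <- load_preset("gpcv2-fluor")$design

test_that("the four-color preset compiles with stage-1 expression gating", {
  cc <- compile_design(fluor)
  expect_s3_class(cc, "gpc_construct")
  expect_equal(cc$stage, 1L)
  expect_equal(sum(cc$features$type == "site"), 6)  # 3 pairs
  expressed <- cc$features$label[cc$features$expressed]
  expect_setequal(expressed, c("Cre_N", "Cre_C", "BFP", "Zeo"))
  # nothing downstream of the first terminator is expressed
  expect_false(any(cc$features$expressed[!is.na(cc$features$stage) &
                                         cc$features$stage > 1]))
})

test_that("an empty cascade compiles to promoter-leader-payload", {
  d <- circuit_design("v2", list(),
                      terminal_payloads = list(payload_block("GFP")),
                      name = "empty")
  cc <- compile_design(d)
  expect_equal(n_stages(d), 0)
  expect_length(enumerate_stages(d), 1)
  expect_identical(cc$sequence, oracle_assemble(d))
  expect_true("GFP" %in% cc$features$label[cc$features$expressed])
})

test_that("a random 2-GPC design matches the hand-assembled concatenation", {
  d <- random_design(42, 2, "v2")
  expect_identical(compile_design(d)$sequence, oracle_assemble(d))
})

test_that("excision removes exactly the cassette plus one site equivalent", {
  cc <- compile_design(fluor)
  s <- fluor$gpcs[[1]]$recombinase$sites
  c2 <- excise_stage(cc)
  # brute-force length bookkeeping: span(left..right) is replaced by the scar
  i <- as.integer(regexpr(s$left_site, cc$sequence, fixed = TRUE))
  rest <- substr(cc$sequence, i + nchar(s$left_site), nchar(cc$sequence))
  j <- as.integer(regexpr(s$right_site, rest, fixed = TRUE))
  span <- nchar(s$left_site) + j - 1L + nchar(s$right_site)
  expect_equal(nchar(c2$sequence), nchar(cc$sequence) - span + nchar(s$scar_site))
  expect_equal(c2$stage, 2L)
  expect_setequal(c2$features$label[c2$features$expressed],
                  c("Flp_N", "Flp_C", "GFP"))
  expect_equal(sum(grepl("loxP_scar", c2$features$label)), 1)
})

test_that("excising past the terminal stage raises NoMoreStages", {
  last <- enumerate_stages(fluor)$stage4
  expect_error(excise_stage(last), class = "gpcsim_no_more_stages")
})

test_that("enumerate_stages yields N+1 constructs, plus DELETED when att-wrapped", {
  expect_length(enumerate_stages(fluor), 4)
  st <- enumerate_stages(load_preset("attp-gpcv2-crispr")$design)
  expect_length(st, 5)
  expect_true(st$DELETED$deleted)
  # DELETED retains only the ITR flanks and the att scar
  expect_setequal(st$DELETED$features$type, c("itr", "scar"))
  expect_false(any(st$DELETED$features$expressed))
})

test_that("scar peptide starts as bare M and stays in frame across stages", {
  sp1 <- scar_peptide(fluor, 1)
  expect_identical(sp1$peptide, "M")
  expect_true(sp1$frame_ok)
  for (k in 2:4) {
    sp <- scar_peptide(fluor, k)
    expect_true(sp$frame_ok)
    # independent translation oracle agrees
    expect_identical(sp$peptide, oracle_translate(paste0("ATG", sp$scar)))
  }
})

test_that("scar peptide is undefined for v1 designs", {
  d <- circuit_design("v1", list(
    gpc_unit(1, recombinase_module("Cre", "GIB"), list(payload_block("A")))))
  expect_error(scar_peptide(d, 1), class = "gpcsim_unsupported_version")
})

test_that("whole-circuit amplicons shrink with excision; the scar record grows", {
  stages <- enumerate_stages(fluor)
  fwd <- substr(fluor$promoter, nchar(fluor$promoter) - 19, nchar(fluor$promoter))
  # reverse primer inside the terminal payload (present at all stages)
  term_seq <- fluor$terminal_payloads[[1]]$sequence
  rev <- revcomp_str(substr(term_seq, 1, 20))
  lens <- vapply(stages, function(cc)
    predict_amplicon(cc, fwd, rev)$length, 0)
  expect_true(all(diff(lens) < 0))       # cassettes drop out one by one...
  # ...while the cumulative scar between promoter and payload grows:
  scar_lens <- vapply(stages, function(cc) nchar(cc$scar$cumulative), 0)
  expect_true(all(diff(scar_lens) > 0))
  # index oracle: amplicon length equals rev_end - fwd_start + 1
  cc <- stages$stage2
  amp <- predict_amplicon(cc, fwd, rev)
  i <- as.integer(regexpr(fwd, cc$sequence, fixed = TRUE))
  j <- as.integer(regexpr(revcomp_str(rev), cc$sequence, fixed = TRUE))
  expect_equal(amp$length, j + 20 - i)
})

test_that("scar-region amplicons strictly lengthen as the cascade runs", {
  # the stage of a cascade is read from the amplicon spanning the scar
  # region: forward primer at the promoter end, reverse primer just inside
  # the promoter-proximal cassette; each completed stage inserts one scar
  # unit between them
  d <- random_design(7, 3, "v2")
  stages <- enumerate_stages(d)
  fwd <- substr(d$promoter, nchar(d$promoter) - 19, nchar(d$promoter))
  lens <- vapply(1:3, function(k)
    predict_amplicon(stages[[k]], fwd,
                     revcomp_str(substr(d$gpcs[[k]]$recombinase$split_halves[1],
                                        1, 20)))$length, 0)
  expect_true(all(diff(lens) > 0))
})

test_that("missing or multi-mapping primers raise AmbiguousPrimer", {
  cc <- compile_design(fluor)
  expect_error(predict_amplicon(cc, "GGGGGGGGGGGGGGGGGGGG", "AAAA"),
               class = "gpcsim_ambiguous_primer")
  p2a <- builtin_parts()$P2A  # occurs once per GPC: multi-mapping
  expect_error(predict_amplicon(cc, substr(p2a, 1, 20),
                                revcomp_str(substr(fluor$terminal_payloads[[1]]$sequence, 1, 20))),
               class = "gpcsim_ambiguous_primer")
})
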