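test_that("COIB classifier matches the invariant truth table exhaustively", {
  refs <- test_refs()
  bases <- c("A", "C", "G", "T", "N", "R", "Y")
  grid <- expand.grid(b1 = bases, b2 = bases, stringsAsFactors = FALSE)
  queries <- mapply(function(b1, b2)
    set_base(set_base(refs$COIB$sequence, 241, b1), 364, b2),
    grid$b1, grid$b2)
  got <- call_coib(unname(queries), refs)
  oracle <- ifelse(grid$b1 == "T" & grid$b2 == "A", "COI_RS",
            ifelse(grid$b1 == "A" & grid$b2 == "A", "COI_h1",
            ifelse(grid$b1 == "A" & grid$b2 == "G", "COI_h2",
            ifelse(grid$b1 == "G" & grid$b2 == "A", "COI_h3",
            ifelse(grid$b1 == "G" & grid$b2 == "G", "COI_h4",
                   "UNDETERMINED")))))
  expect_equal(got$value, oracle)
  expect_equal(got$base1164, grid$b1)
  expect_equal(got$base1287, grid$b2)
})

test_that("a diagnostic site falling in a query deletion is UNDETERMINED", {
  refs <- test_refs()
  r <- refs$COIB$sequence
  # delete a 9 bp block containing mCOI1164 (position 241)
  q <- paste0(substr(r, 1, 236), substr(r, 246, nchar(r)))
  expect_equal(call_coib(q, refs)$value, "UNDETERMINED")
})

test_that("Tpi exon calls follow gTpi183Y", {
  refs <- test_refs()
  q <- vapply(c("C", "T", "Y", "G", "N"),
              function(b) set_base(refs$TPI$sequence, 183, b), character(1))
  got <- call_tpie4(unname(q), refs)
  expect_equal(got$value, c("TpiC", "TpiR", "TpiH", "UNDETERMINED", "UNDETERMINED"))
  expect_equal(got$base183, c("C", "T", "Y", "G", "N"))
})

test_that("non-homologous queries error under strict, degrade otherwise", {
  refs <- test_refs()
  junk <- paste(rep("ACGT", 30), collapse = "")
  set.seed(5)
  junk <- rand_dna(200)
  # a random sequence is overwhelmingly unlikely to reach 70% identity
  expect_error(call_coib(junk, refs), "not homologous")
  got <- call_coib(junk, refs, strict = FALSE)
  expect_equal(got$value, "UNDETERMINED")
})

test_that("intron typing: clean haplotype, het-indel exclusion, short window", {
  refs <- test_refs()
  panel <- build_panel(5, seed = 9, refs = refs)
  win <- refs$TPI$intron
  exon <- substr(refs$TPI$sequence, 1, win[1] - 1)

  for (h in names(panel$sequences)) {
    q <- paste0(exon, panel$sequences[[h]])
    got <- call_tpii4(q, refs)
    expect_equal(got$status, "HAPLOTYPE")
    expect_equal(got$haplotype_seq, unname(panel$sequences[[h]]))
  }

  # 20-base ambiguity run inside the intron -> excluded
  hap <- panel$sequences[[2]]
  mess <- paste0(substr(hap, 1, 60), strrep("W", 20), substr(hap, 81, nchar(hap)))
  got <- call_tpii4(paste0(exon, mess), refs)
  expect_equal(got$status, "HET_INDEL_EXCLUDED")
  expect_equal(got$haplotype_seq, "")

  # run shorter than k survives; isolated ambiguity is resolved to the
  # lexicographically smallest compatible base
  one <- paste0(substr(hap, 1, 60), "Y", substr(hap, 62, nchar(hap)))
  expect_false(grepl("[RYSWKMBDHVN]{5,}", one))  # oracle: no qualifying run
  got <- call_tpii4(paste0(exon, one), refs)
  expect_equal(got$status, "HAPLOTYPE")
  expect_equal(substr(got$haplotype_seq, 61, 61), "C")

  # intron window truncated below 50 bases -> UNDETERMINED
  stub <- paste0(exon, substr(panel$base, 1, 30))
  got <- call_tpii4(stub, refs)
  expect_equal(got$status, "UNDETERMINED")
})

test_that("injecting an ambiguity run always flips HAPLOTYPE to excluded", {
  refs <- test_refs()
  panel <- build_panel(6, seed = 31, refs = refs)
  win <- refs$TPI$intron
  exon <- substr(refs$TPI$sequence, 1, win[1] - 1)
  set.seed(77)
  amb <- c("R", "Y", "S", "W", "K", "M")
  for (k in 1:15) {
    hap <- panel$sequences[[sample(length(panel$sequences), 1)]]
    q0 <- paste0(exon, hap)
    expect_equal(call_tpii4(q0, refs)$status, "HAPLOTYPE")
    len <- sample(5:40, 1)
    start <- sample(seq_len(nchar(hap) - len), 1)
    run <- paste(sample(amb, len, TRUE), collapse = "")
    hap2 <- paste0(substr(hap, 1, start - 1), run,
                   substr(hap, start + len, nchar(hap)))
    expect_equal(call_tpii4(paste0(exon, hap2), refs)$status,
                 "HET_INDEL_EXCLUDED")
  }
})

test_that("haplotype id assignment is stable, seeded and idempotent", {
  s <- c("ACGTACGT", "acgtacgt", "TTTTCCCC")
  a <- assign_haplotype_ids(s)
  expect_equal(a$ids[1], a$ids[2])
  expect_equal(length(unique(a$ids)), 2)
  expect_equal(names(a$registry), c("Hap01", "Hap02"))

  # empty input: empty registry delta
  e <- assign_haplotype_ids(character(0), a$registry)
  expect_equal(e$registry, a$registry)

  # pre-seeded registry is honored and numbering continues its series
  reg <- c(Ecu01 = "AAAA", Ecu02 = "CCCC")
  b <- assign_haplotype_ids(c("CCCC", "GGGG", "AAAA"), reg)
  expect_equal(b$ids, c("Ecu02", "Ecu03", "Ecu01"))

  # idempotence: re-running with the updated registry reproduces the ids
  b2 <- assign_haplotype_ids(c("CCCC", "GGGG", "AAAA"), b$registry)
  expect_equal(b2$ids, b$ids)
  expect_equal(b2$registry, b$registry)
})
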