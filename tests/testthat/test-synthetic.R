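test_that("build_panel: determinism, distinctness, degenerate cases", {
  refs <- test_refs()
  p1 <- build_panel(14, n_substitutions = 4, n_indels = 1, seed = 7, refs = refs)
  p2 <- build_panel(14, n_substitutions = 4, n_indels = 1, seed = 7, refs = refs)
  expect_identical(p1$sequences, p2$sequences)
  # oracle: pairwise string comparison confirms all variants distinct
  expect_equal(length(unique(p1$sequences)), 14)
  expect_true(any(nchar(p1$sequences) != nchar(p1$base)))  # indels present

  solo <- build_panel(1, seed = 3, refs = refs)
  expect_equal(unname(solo$sequences), solo$base)

  # distinct haplotypes unreachable with a zero edit budget
  expect_error(build_panel(5, n_substitutions = 0, n_indels = 0, seed = 1,
                           refs = refs), "distinct haplotypes")
})

test_that("simulated truth matches requested composition in degenerate specs", {
  refs <- test_refs()
  panel <- build_panel(4, seed = 2, refs = refs)
  spec <- list(population_id = "pop", n = 40,
               coi_freqs = c(COI_h2 = 1),
               tpi_freqs = c(TpiC = 1),
               intron_hap_freqs = setNames(rep(0.25, 4), names(panel$sequences)),
               seed = 5)
  sim <- simulate_collection(spec, panel, refs)
  calls <- classify_specimens(sim$specimens, refs, registry = panel$sequences)
  expect_true(all(calls$coi_call == "COI_h2"))

  # male_fraction 0 forbids TpiH entirely
  spec2 <- modifyList(spec, list(male_fraction = 0,
                                 tpi_freqs = c(TpiC = 0.6, TpiR = 0.4)))
  sim2 <- simulate_collection(spec2, panel, refs)
  expect_false(any(sim2$truth$tpi_true == "TpiH"))
  calls2 <- classify_specimens(sim2$specimens, refs, registry = panel$sequences)
  expect_false(any(calls2$tpi_call == "TpiH"))
  expect_false(any(sim2$truth$het_indel))

  # TpiH with no males is rejected up front
  expect_error(simulate_collection(
    modifyList(spec, list(male_fraction = 0, tpi_freqs = c(TpiC = .9, TpiH = .1))),
    panel, refs), "male_fraction")
})

test_that("classifier reproduces simulation truth exactly on clean collections", {
  refs <- test_refs()
  panel <- build_panel(6, seed = 41, refs = refs)
  spec <- list(population_id = "tr", n = 250,
               coi_freqs = c(COI_RS = 0.1, COI_h1 = 0.1, COI_h2 = 0.5,
                             COI_h3 = 0.2, COI_h4 = 0.1),
               tpi_freqs = c(TpiC = 0.7, TpiR = 0.2, TpiH = 0.1),
               intron_hap_freqs = setNames(c(.3, .3, .1, .1, .1, .1),
                                           names(panel$sequences)),
               het_indel_rate = 0, male_fraction = 0.5, seed = 1234)
  sim <- simulate_collection(spec, panel, refs)
  calls <- classify_specimens(sim$specimens, refs, registry = panel$sequences)
  expect_equal(calls$coi_call, sim$truth$coi_true)
  expect_equal(calls$tpi_call, sim$truth$tpi_true)
  expect_equal(calls$intron_hap_id, sim$truth$intron_hap_true)
})

test_that("het-indel specimens are excluded and only arise in males", {
  refs <- test_refs()
  panel <- build_panel(3, seed = 17, refs = refs)
  spec <- list(population_id = "het", n = 120,
               coi_freqs = c(COI_h2 = 1), tpi_freqs = c(TpiC = 1),
               intron_hap_freqs = setNames(c(.5, .3, .2), names(panel$sequences)),
               het_indel_rate = 0.5, male_fraction = 0.5, seed = 77)
  sim <- simulate_collection(spec, panel, refs)
  expect_true(any(sim$truth$het_indel))
  expect_true(all(sim$truth$sex[sim$truth$het_indel] == "M"))
  calls <- classify_specimens(sim$specimens, refs, registry = panel$sequences)
  expect_equal(calls$intron_status == "HET_INDEL_EXCLUDED", sim$truth$het_indel)
  clean <- !sim$truth$het_indel
  expect_equal(calls$intron_hap_id[clean], sim$truth$intron_hap_true[clean])
})

test_that("law of large numbers: truth frequencies converge to the spec", {
  refs <- test_refs()
  panel <- build_panel(3, seed = 8, refs = refs)
  coi <- c(COI_RS = 0.05, COI_h1 = 0.1, COI_h2 = 0.6, COI_h3 = 0.15,
           COI_h4 = 0.1)
  spec <- list(population_id = "lln", n = 10000, coi_freqs = coi,
               tpi_freqs = c(TpiC = 1),
               intron_hap_freqs = setNames(c(.5, .3, .2), names(panel$sequences)),
               seed = 31415)
  sim <- simulate_collection(spec, panel, refs)
  obs <- table(factor(sim$truth$coi_true, levels = names(coi))) / spec$n
  for (cat in names(coi)) {
    tol <- 3 * sqrt(coi[cat] * (1 - coi[cat]) / spec$n)
    expect_lt(abs(obs[[cat]] - coi[[cat]]), tol)
  }
})

test_that("identical (spec, seed) produce byte-identical output files", {
  refs <- test_refs()
  panel <- build_panel(3, seed = 19, refs = refs)
  spec <- list(population_id = "det", n = 30,
               coi_freqs = c(COI_h2 = .8, COI_RS = .2),
               tpi_freqs = c(TpiC = .9, TpiH = .1),
               intron_hap_freqs = setNames(c(.5, .3, .2), names(panel$sequences)),
               het_indel_rate = 0.2, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_collection(spec, panel, refs, dir = d1)
  simulate_collection(spec, panel, refs, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_setequal(list.files(d1), c("det_coib.fasta", "det_tpi.fasta",
                                    "det_samples.tsv", "det_truth.csv"))
})

test_that("ecuador fixture reproduces the printed marginal counts", {
  fx <- test_fixture()
  sp <- fx$specimens
  hosts <- table(sp$host[!is.na(sp$seq_coib)])
  expect_equal(unname(hosts[c("soft_corn", "hard_corn", "rice")]),
               c(78L, 290L, 124L), ignore_attr = TRUE)
  expect_equal(sum(!is.na(sp$seq_coib)), 492)
  tpi <- table(sp$host[!is.na(sp$seq_tpie4)])
  expect_equal(unname(tpi[c("soft_corn", "hard_corn", "rice")]),
               c(61L, 242L, 128L), ignore_attr = TRUE)
  expect_equal(sum(!is.na(sp$seq_tpii4)), 285)
  expect_equal(sum(fx$truth$coi_true == "COI_RS", na.rm = TRUE), 4)
  expect_equal(sum(fx$truth$tpi_true == "TpiR", na.rm = TRUE), 0)
  # deterministic rebuild
  fx2 <- ecuador_fixture(test_refs())
  expect_identical(fx2$specimens, fx$specimens)
  expect_identical(fx2$truth, fx$truth)
})
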