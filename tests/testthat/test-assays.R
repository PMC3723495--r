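test_that("perfect chemistry on a nucleosome-free unmethylated molecule", {
  ref <- generate_reference(400, 0.04, 0.06, seed = 3, n_gcg = 0)
  mol <- structure(list(
    molecule_id = "mol1", class = "demethylated",
    cpg_methylation = rep(0L, length(ref$cpg_sites)),
    nucleosome_intervals = matrix(integer(0), ncol = 2,
                                  dimnames = list(NULL, c("start", "end"))),
    gpc_accessible = rep(1L, length(ref$gpc_sites))
  ), class = "molecule_truth")
  clone <- apply_assays(list(mol), ref, perfect_assay_params(), seed = 1)[[1]]
  b <- strsplit(clone, "")[[1]]
  # every GpC C stays C (accessible, enzyme-marked); every other C reads T
  expect_true(all(b[ref$gpc_sites + 1] == "C"))
  expect_true(all(b[ref$cpg_sites + 1] == "T"))
  expect_true(all(b[ref$control_c_sites + 1] == "T"))
  # and the independently written converter agrees base by base
  expect_identical(clone, oracle_perfect_clone(ref, mol))
})

test_that("perfect chemistry on a fully methylated, fully covered molecule", {
  ref <- generate_reference(400, 0.04, 0.06, seed = 3, n_gcg = 0)
  mol <- structure(list(
    molecule_id = "mol1", class = "hypermethylated",
    cpg_methylation = rep(1L, length(ref$cpg_sites)),
    nucleosome_intervals = matrix(c(0L, 400L), ncol = 2,
                                  dimnames = list(NULL, c("start", "end"))),
    gpc_accessible = rep(0L, length(ref$gpc_sites))
  ), class = "molecule_truth")
  clone <- apply_assays(list(mol), ref, perfect_assay_params(), seed = 1)[[1]]
  b <- strsplit(clone, "")[[1]]
  expect_true(all(b[ref$cpg_sites + 1] == "C"))       # endogenous mark kept
  expect_true(all(b[ref$gpc_sites + 1] == "T"))       # refractory to enzyme
  expect_true(all(b[ref$control_c_sites + 1] == "T"))
  expect_identical(clone, oracle_perfect_clone(ref, mol))
})

test_that("incomplete conversion is binomial at the configured rate", {
  ref <- generate_reference(1200, 0.01, 0.01, seed = 5, n_gcg = 0)
  n_ctl <- length(ref$control_c_sites)
  n_mol <- ceiling(10000 / n_ctl) + 1
  free <- molecule_class_spec("free", 0, tss_occupied_prob = 0,
                              flank_occupied = FALSE)
  pop <- generate_population(ref, population_spec(
    0, c(free = n_mol), classes = list(free = free), seed = 6))
  params <- assay_params(gpc_methylase_efficiency = 1,
                         bisulfite_conversion_rate = 0.99,
                         inappropriate_conversion_rate = 0,
                         sequencing_error_rate = 0)
  clones <- apply_assays(pop, ref, params, seed = 7)
  ctl1 <- ref$control_c_sites + 1
  obs <- unlist(lapply(clones, function(s) {
    substring(s, ctl1, ctl1) == "T"
  }))
  n <- length(obs)
  expect_gte(n, 10000)
  expect_lt(abs(mean(obs) - 0.99), 3 * sqrt(0.99 * 0.01 / n))
})

test_that("seeded assay runs are bit-reproducible and seeds matter", {
  ref <- fixture_reference()
  spec <- population_spec(0, c(intermediate = 5), seed = 8)
  pop <- generate_population(ref, spec)
  a <- apply_assays(pop, ref, assay_params(), seed = 42)
  b <- apply_assays(pop, ref, assay_params(), seed = 42)
  expect_identical(a, b)
  d <- apply_assays(pop, ref, assay_params(), seed = 43)
  expect_false(identical(unclass(a), unclass(d)))
})

test_that("amplification bias weights clones by primer-region methylation", {
  ref <- generate_reference(400, 0.05, 0.05, seed = 9, n_gcg = 0)
  primers <- rbind(c(0L, 60L), c(340L, 400L))
  in_primer <- ref$cpg_sites[ref$cpg_sites < 60 | ref$cpg_sites >= 340]
  expect_gte(length(in_primer), 2)
  seq_u <- chartr("C", "T", ref$sequence)       # no methylated CpG anywhere
  put_c <- function(s, pos0) {
    for (p in pos0 + 1) substr(s, p, p) <- "C"
    s
  }
  seq_m <- put_c(seq_u, in_primer[1:2])          # 2 methylated primer CpGs
  clones <- c(u = seq_u, m = seq_m)

  # weight 1: uniform sampling
  out <- amplify_with_bias(clones, ref, primers, 1, 20000, seed = 1)
  fr <- mean(names(out) == "u")
  expect_lt(abs(fr - 0.5), 3 * sqrt(0.25 / 20000))

  # weight 0: hard exclusion of methylated-primer clones
  out <- amplify_with_bias(clones, ref, primers, 0, 500, seed = 2)
  expect_true(all(names(out) == "u"))

  # weight 0.5 with 0 vs 2 primer mCpGs: odds 1 : 0.25 -> 80% unmethylated
  out <- amplify_with_bias(clones, ref, primers, 0.5, 10000, seed = 3)
  fr <- mean(names(out) == "u")
  expect_lt(abs(fr - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))

  expect_error(amplify_with_bias(clones, ref, primers, 0.5, 0), "n_out")
})

test_that("simulated Ct values encode quantity and noise correctly", {
  d <- data.frame(assay = "expression", target = "g", condition = "sample",
                  day = 0, true_quantity = 1)
  ct <- generate_ct_table(d, base_ct = 20, noise_sd = 0, n_replicates = 3)
  expect_equal(ct$ct, rep(20, 3))

  d$true_quantity <- 0.25   # 4-fold down = 2 cycles later
  ct <- generate_ct_table(d, base_ct = 20, noise_sd = 0, n_replicates = 1)
  expect_equal(ct$ct, 22)

  d$true_quantity <- 1
  ct <- generate_ct_table(d, base_ct = 20, noise_sd = 0.1,
                          n_replicates = 1000, seed = 4)
  expect_lt(abs(sd(ct$ct) - 0.1) / 0.1, 0.10)

  expect_error(generate_ct_table(d, noise_sd = -1), "noise_sd")
  d$true_quantity <- 0
  expect_error(generate_ct_table(d), "true_quantity")
})

test_that("clone FASTA and Ct TSV round trips are faithful", {
  ref <- fixture_reference()
  pop <- generate_population(ref, population_spec(
    0, c(hypermethylated = 3), seed = 2))
  clones <- apply_assays(pop, ref, assay_params(), seed = 2)
  fa <- tempfile(fileext = ".fasta")
  write_clones(clones, fa)
  back <- read_clones(fa)
  expect_identical(back, setNames(as.character(clones), names(clones)))

  d <- data.frame(assay = "mnase", target = "III",
                  condition = c("mono", "naked"), day = 0,
                  true_quantity = c(0.5, 1))
  ct <- generate_ct_table(d, seed = 1)
  tsv <- tempfile(fileext = ".tsv")
  write_ct_table(ct, tsv)
  expect_equal(read_ct_table(tsv), ct)
})
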