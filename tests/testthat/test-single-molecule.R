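make_profile <- function(n_meth, n_unmeth, n_undet = 0,
                         gpc = NULL, qc = TRUE) {
  cpg_state <- c(rep("methylated", n_meth), rep("unmethylated", n_unmeth),
                 rep("undetermined", n_undet))
  structure(list(
    clone_id = "p",
    cpg_calls = data.frame(pos = seq_along(cpg_state) * 10L,
                           state = cpg_state, stringsAsFactors = FALSE),
    gpc_calls = gpc %||% data.frame(pos = integer(0), state = character(0)),
    conversion_rate_observed = 1, n_control_informative = 10L,
    qc_pass = qc), class = "molecule_profile")
}

test_that("methylation classes respect the <=2 mCpG and >=90% definitions", {
  expect_identical(classify_methylation(make_profile(0, 25))$methylation_class,
                   "demethylated")
  expect_identical(classify_methylation(make_profile(2, 23))$methylation_class,
                   "demethylated")
  expect_identical(classify_methylation(make_profile(3, 22))$methylation_class,
                   "intermediate")
  expect_identical(classify_methylation(make_profile(25, 0))$methylation_class,
                   "hypermethylated")
  # undetermined sites leave numerator and denominator
  cls <- classify_methylation(make_profile(23, 0, 2))
  expect_identical(cls$methylation_class, "hypermethylated")
  expect_identical(cls$assayed_cpg_count, 23L)
})

test_that("unclassifiable and QC-failed molecules are handled explicitly", {
  expect_message(cls <- classify_methylation(make_profile(1, 3)), "excluding")
  expect_true(cls$excluded)
  expect_true(is.na(cls$methylation_class))
  expect_error(classify_methylation(make_profile(0, 25, qc = FALSE)), "QC")
})

test_that("raising max_methylated never shrinks the demethylated count", {
  set.seed(77)
  profiles <- lapply(1:40, function(i) {
    n_m <- sample(0:20, 1)
    make_profile(n_m, 20 - n_m)
  })
  counts <- vapply(0:20, function(mx) {
    sum(vapply(profiles, function(p) {
      classify_methylation(p, max_methylated = mx)$methylation_class ==
        "demethylated"
    }, logical(1)))
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("footprint intervals span to the nearest accessible evidence", {
  # accessible at 10 & 260 flanking inaccessible 60, 220: (11, 260), 249 bp
  gpc <- fixture_gpc_profile(c(10, 60, 220, 260),
                             c("methylated", "unmethylated", "unmethylated",
                               "methylated"))
  fp <- call_footprints(gpc, 400)
  expect_identical(nrow(fp), 1L)
  expect_identical(fp$start, 11L)
  expect_identical(fp$end, 260L)
  expect_identical(fp$length, 249L)
  expect_identical(fp$left_bound, "accessible_gpc")

  # 139 bp < 150: discarded
  gpc <- fixture_gpc_profile(c(10, 80, 150),
                             c("methylated", "unmethylated", "methylated"))
  expect_identical(nrow(call_footprints(gpc, 400)), 0L)

  # everything inaccessible: single edge-to-edge footprint
  gpc <- fixture_gpc_profile(c(50, 150, 350),
                             rep("unmethylated", 3))
  fp <- call_footprints(gpc, 400)
  expect_identical(fp$start, 0L)
  expect_identical(fp$end, 400L)
  expect_identical(fp$length, 400L)
  expect_identical(fp$left_bound, "amplicon_edge")

  # undetermined GpCs neither break nor bound runs
  gpc <- fixture_gpc_profile(c(10, 60, 120, 220, 260),
                             c("methylated", "unmethylated", "undetermined",
                               "unmethylated", "methylated"))
  fp <- call_footprints(gpc, 400)
  expect_identical(nrow(fp), 1L)
  expect_identical(fp$length, 249L)

  # all undetermined: occupancy cannot be assessed
  gpc <- fixture_gpc_profile(c(10, 60), rep("undetermined", 2))
  expect_null(call_footprints(gpc, 400))
  expect_identical(classify_tss_occupancy(NULL, 200), "undetermined")
})

test_that("footprint caller agrees with the brute-force oracle", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    len <- 400L
    pos <- sort(sample(0:(len - 1), n))
    state <- random_gpc_states(n)
    for (ml in c(50L, 150L)) {
      got <- call_footprints(fixture_gpc_profile(pos, state), len,
                             min_length = ml)
      want <- oracle_footprints(pos, state, len, min_length = ml)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_identical(got$start, want$start)
        expect_identical(got$end, want$end)
        expect_identical(got$length, want$length)
      }
    }
  }
})

test_that("raising min_length never increases the occupied count", {
  set.seed(99)
  profiles <- lapply(1:30, function(i) {
    n <- sample(5:25, 1)
    fixture_gpc_profile(sort(sample(0:399, n)), random_gpc_states(n))
  })
  occupied <- vapply(c(50, 100, 150, 200, 300), function(ml) {
    sum(vapply(profiles, function(g) {
      classify_tss_occupancy(call_footprints(g, 400, ml), 200) == "occupied"
    }, logical(1)))
  }, 0)
  expect_true(all(diff(occupied) <= 0))
})

test_that("TSS occupancy is containment of the TSS in a retained footprint", {
  fp <- data.frame(start = 100L, end = 300L, length = 200L)
  expect_identical(classify_tss_occupancy(fp, 200), "occupied")
  expect_identical(classify_tss_occupancy(fp, 350), "depleted")
  expect_identical(classify_tss_occupancy(fp[0, ], 200), "depleted")
})

test_that("occupancy calls equal ground truth under perfect chemistry", {
  ref <- fixture_reference()
  occ <- molecule_class_spec("occ", 0.05, enforce = "demethylated",
                             tss_occupied_prob = 1)
  free <- molecule_class_spec("free", 0.05, enforce = "demethylated",
                              tss_occupied_prob = 0)
  res <- fixture_called_population(ref, c(occ = 15, free = 15),
                                   classes = list(occ = occ, free = free),
                                   seed = 17)
  for (i in seq_along(res$pop)) {
    truth_occ <- {
      iv <- res$pop[[i]]$nucleosome_intervals
      nrow(iv) > 0 && any(iv[, 1] <= ref$tss_position &
                            ref$tss_position < iv[, 2])
    }
    called <- classify_tss_occupancy(
      call_footprints(res$profiles[[i]], ref$length), ref$tss_position)
    expect_identical(called, ifelse(truth_occ, "occupied", "depleted"))
  }
})

test_that("population summaries report joint and marginal counts coherently", {
  ref <- fixture_reference()
  res <- fixture_called_population(
    ref, c(demethylated = 10, hypermethylated = 22), seed = 3)
  s <- summarize_population(res$profiles, ref)
  expect_identical(s$n, 32L)
  expect_equal(s$pct_demethylated, 31.3)
  # joint margins equal the univariate counts
  expect_identical(sum(s$joint["demethylated", ]),
                   sum(s$molecules$methylation_class == "demethylated"))
  expect_identical(sum(s$joint[, "depleted"]),
                   sum(s$molecules$tss_occupancy == "depleted"))
  expect_identical(sum(s$joint), s$n)
  # identical molecules give per-site percentages of exactly 0 or 100
  res1 <- fixture_called_population(ref, c(hypermethylated = 1), seed = 5)
  prof <- res1$profiles[[1]]
  s1 <- summarize_population(rep(list(prof), 4), ref)
  expect_true(all(s1$per_site_pct %in% c(0, 100)))
  expect_error(summarize_population(list(), ref), "no QC-passing")
})

test_that("lollipop rendering is invertible and marks the TSS column", {
  ref <- fixture_reference()
  res <- fixture_called_population(
    ref, c(demethylated = 3, hypermethylated = 3), seed = 19)
  for (track in c("cpg", "gpc")) {
    lines <- render_lollipop(res$profiles, ref, track)
    expect_identical(length(lines), 7L)           # header + 6 clones
    expect_identical(sum(strsplit(lines[1], "")[[1]] == "*"), 1L)
    mat <- parse_lollipop(lines, track)
    field <- paste0(track, "_calls")
    for (i in seq_along(res$profiles)) {
      expect_identical(unname(mat[i, ]), res$profiles[[i]][[field]]$state)
    }
  }
  # single fully methylated molecule renders as all-M
  p <- make_profile(5, 0)
  line <- render_lollipop(list(p), ref, "cpg")[2]
  expect_match(line, "MMMMM$")
})
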