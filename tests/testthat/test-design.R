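make_entries <- function(dir, specs) {
  lapply(names(specs), function(nm) {
    fa <- write_ref_fixture(dir, nm, length = 5000L,
                            seed = derive_seed(1, nm))
    organism_spec(nm, fa, specs[[nm]])
  })
}

test_that("largest_remainder matches the brute-force oracle", {
  # full enumeration on small problems
  set.seed(100)
  for (rep in 1:40) {
    n <- sample(2:4, 1)
    total <- sample(3:16, 1)
    pct <- rdirichlet_test(n) * 100
    got <- largest_remainder(pct / 100 * total, total)
    expect_identical(got, as.integer(oracle_apportion(pct, total)),
                     info = paste("n =", n, "total =", total,
                                  "pct =", paste(round(pct, 3), collapse = ",")))
  }
  # hand-derived case: 33.4/33.3/33.3 of 10 -> 4,3,3
  expect_identical(largest_remainder(c(33.4, 33.3, 33.3) / 100 * 10, 10),
                   c(4L, 3L, 3L))
  # remainder ties break by declaration order
  expect_identical(largest_remainder(c(2.5, 2.5), 5), c(3L, 2L))
  expect_identical(largest_remainder(c(1.25, 1.25, 1.25, 1.25), 5),
                   c(2L, 1L, 1L, 1L))
})

test_that("largest_remainder matches the floor/ceil oracle up to 6 categories", {
  set.seed(200)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    total <- sample(5:50, 1)
    pct <- rdirichlet_test(n) * 100
    got <- largest_remainder(pct / 100 * total, total)
    expect_identical(got, oracle_apportion_fc(pct, total),
                     info = paste("n =", n, "total =", total))
    expect_identical(sum(got), total)
  }
})

test_that("abundance specs validate their modes", {
  expect_identical(abundance_spec("absolute", 500)$value, 500L)
  expect_error(abundance_spec("absolute", 2.5), "integer")
  expect_error(abundance_spec("relative", 150), "\\[0, 100\\]")
  expect_error(abundance_spec("random", 5), "no value")
})

test_that("sample_design validation catches inconsistent designs", {
  dir <- withr::local_tempdir()
  # percentages summing over 100
  expect_error(
    sample_design(make_entries(dir, list(
      a = abundance_spec("relative", 60), b = abundance_spec("relative", 50))),
      total_reads = 1000),
    "sum to 110")
  # absolute + fill_remainder exceeding total
  fa <- write_ref_fixture(dir, "h", 5000L)
  expect_error(
    sample_design(list(
      organism_spec("h", fa, host = TRUE, fill_remainder = TRUE),
      make_entries(dir, list(v = abundance_spec("absolute", 2000)))[[1]]),
      total_reads = 1000),
    "over-allocated")
  # duplicate organism names
  expect_error(
    sample_design(list(
      organism_spec("a", fa, abundance_spec("absolute", 1)),
      organism_spec("a", fa, abundance_spec("absolute", 1)))),
    "duplicate organism name")
  # relative mode without a total
  expect_error(
    sample_design(make_entries(dir, list(a = abundance_spec("relative", 10)))),
    "total_reads is required")
})

test_that("resolve_abundances honours the three modes and conserves totals", {
  dir <- withr::local_tempdir()
  # absolute mode is the identity
  d <- sample_design(make_entries(dir, list(
    a = abundance_spec("absolute", 110000),
    b = abundance_spec("absolute", 120000))))
  r <- resolve_abundances(d)
  expect_identical(unname(r$counts), c(110000L, 120000L))
  expect_identical(r$total, 230000L)

  # relative: one organism at 0.5% of 100000 -> exactly 500
  d2 <- sample_design(c(make_entries(dir, list(
    v = abundance_spec("relative", 0.5))),
    list(organism_spec("h", write_ref_fixture(dir, "h2"), host = TRUE,
                       fill_remainder = TRUE))),
    total_reads = 100000)
  r2 <- resolve_abundances(d2)
  expect_identical(r2$counts[["v"]], 500L)
  expect_identical(r2$counts[["h"]], 99500L)

  # mixed absolute + relative + random conserves the exact total
  d3 <- sample_design(make_entries(dir, list(
    a = abundance_spec("absolute", 300),
    b = abundance_spec("relative", 12.34),
    c = abundance_spec("random"),
    e = abundance_spec("random"))),
    total_reads = 5000)
  r3 <- resolve_abundances(d3, seed = 17)
  expect_identical(sum(r3$counts), 5000L)
  expect_identical(r3$counts[["a"]], 300L)
  expect_identical(r3$counts[["b"]], as.integer(round(12.34 / 100 * 5000)))
  expect_true(all(r3$counts >= 0))
  # deterministic under the same seed, different under another
  expect_identical(resolve_abundances(d3, seed = 17)$counts, r3$counts)
  expect_false(identical(resolve_abundances(d3, seed = 18)$counts[["c"]],
                         r3$counts[["c"]]))
})

test_that("conservation holds across random designs (property sweep)", {
  dir <- withr::local_tempdir()
  fa <- replicate(4, write_ref_fixture(dir, paste0("o", sample.int(1e6, 1)),
                                       length = 2000L))
  set.seed(999)
  for (i in 1:25) {
    total <- sample(50:5000, 1)
    modes <- sample(c("absolute", "relative", "random"), 4, TRUE)
    if (!any(modes == "random")) modes[4] <- "random" # absorb leftover
    abs_budget <- total %/% 4
    specs <- lapply(seq_along(modes), function(j) {
      switch(modes[j],
             absolute = abundance_spec("absolute", sample(0:abs_budget, 1)),
             relative = abundance_spec("relative", runif(1, 0, 20)),
             random = abundance_spec("random"))
    })
    entries <- lapply(1:4, function(j)
      organism_spec(paste0("org", j), fa[j], specs[[j]]))
    d <- sample_design(entries, total_reads = total, seed = i)
    r <- resolve_abundances(d)
    expect_identical(sum(r$counts), total)
    expect_true(all(r$counts >= 0))
    # relative report consistency: within half a read of the request
    rel_j <- which(modes == "relative")
    for (j in rel_j) {
      expect_lt(abs(100 * r$counts[[j]] / total - specs[[j]]$value),
                100 / (2 * total) + 1e-9)
    }
  }
})

test_that("distribute_subtaxa splits exactly", {
  expect_identical(distribute_subtaxa(100, 4, "equal"), rep(25L, 4))
  expect_identical(distribute_subtaxa(10, 3, "equal"), c(4L, 3L, 3L))
  expect_identical(distribute_subtaxa(0, 3, "equal"), rep(0L, 3))
  r1 <- distribute_subtaxa(1000, 5, "random", seed = 11)
  expect_identical(sum(r1), 1000L)
  expect_true(all(r1 >= 0))
  expect_identical(distribute_subtaxa(1000, 5, "random", seed = 11), r1)
})

test_that("taxa with subtaxa resolve through the taxon budget", {
  dir <- withr::local_tempdir()
  members <- lapply(c("m1", "m2", "m3"), function(nm)
    taxon_member(nm, write_ref_fixture(dir, nm, 3000L)))
  d <- sample_design(list(
    taxon_spec("complex", abundance_spec("absolute", 10), members, "equal"),
    organism_spec("solo", write_ref_fixture(dir, "solo", 3000L),
                  abundance_spec("absolute", 90))))
  r <- resolve_abundances(d)
  expect_identical(unname(r$counts[c("m1", "m2", "m3")]), c(4L, 3L, 3L))
  expect_identical(unname(r$taxon[["m1"]]), "complex")
  expect_true(is.na(r$taxon[["solo"]]))
  expect_identical(sum(r$counts), 100L)
  # members may not carry their own abundance
  expect_error(
    taxon_spec("bad", abundance_spec("absolute", 10),
               list(organism_spec("x", "x.fa", abundance_spec("absolute", 5)))),
    "must not carry")
})

test_that("parse_design reads YAML, JSON and TSV and applies defaults", {
  dir <- withr::local_tempdir()
  fa <- write_ref_fixture(dir, "orgA", 4000L)
  cfg <- list(name = "s1", total_reads = 1000, seed = 7,
              organisms = list(list(name = "orgA",
                                    reference = basename(fa),
                                    abundance = list(mode = "relative",
                                                     value = 100))))
  yml <- file.path(dir, "design.yaml")
  yaml::write_yaml(cfg, yml)
  d <- parse_design(yml)
  expect_identical(d$scenario, "environmental") # default
  expect_identical(d$replicates, 1L)            # default
  expect_identical(d$seed, 7L)
  expect_equal(d$length_model$mean, 2000)       # default model

  jsn <- file.path(dir, "design.json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  d2 <- parse_design(jsn)
  expect_identical(resolve_abundances(d2)$counts,
                   resolve_abundances(d)$counts)

  tsv <- file.path(dir, "design.tsv")
  writeLines(c("name\treference\tmode\tvalue",
               paste0("orgA\t", basename(fa), "\tabsolute\t500")), tsv)
  d3 <- parse_design(tsv)
  expect_identical(d3$total_reads, 500L)

  # missing reference is a hard error naming the organism
  cfg$organisms[[1]]$reference <- "missing.fasta"
  yaml::write_yaml(cfg, yml)
  expect_error(parse_design(yml), "organism 'orgA'.*missing.fasta")
})

test_that("make_dilution_series builds levels x replicates seeded designs", {
  dir <- withr::local_tempdir()
  base <- host_pathogen_design(dir, total = 1000L, pathogen_reads = 500L)
  batch <- make_dilution_series(base, "pathogen",
                                levels = c(500, 100, 50, 10, 5),
                                replicates = 20)
  expect_length(batch, 100)
  seeds <- vapply(batch, `[[`, integer(1), "seed")
  expect_identical(anyDuplicated(seeds), 0L)
  # every level-10 design resolves the pathogen to exactly 10 reads
  lvl10 <- Filter(function(d) grepl("_L10_", d$name), batch)
  expect_length(lvl10, 20)
  for (d in lvl10) {
    r <- resolve_abundances(d)
    expect_identical(r$counts[["pathogen"]], 10L)
    expect_identical(r$counts[["host"]], 990L)
  }
  # a level exceeding the total is rejected
  expect_error(make_dilution_series(base, "pathogen", levels = 2000),
               "exceeds total_reads")
  expect_error(make_dilution_series(base, "nope", levels = 10),
               "not a top-level entry")
})
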