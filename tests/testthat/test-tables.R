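test_that("layout round-trips through delimited text unchanged", {
  layout <- tibble::tibble(
    plot_id = paste0("p", 1:4), row = c(0, 0, 1, 1), col = c(0, 1, 0, 1),
    block = c(1, 1, 2, 2), treatment = c("WW", "WS", "WW", "WS"),
    genotype = c("g1", "g2", "g1", "g2")
  )
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_field_table(layout, tmp)
  back <- read_field_tables(tmp)$layout
  expect_equal(as.data.frame(back[1:3]), as.data.frame(layout[1:3]))
  expect_equal(as.character(back$treatment), layout$treatment)
  expect_equal(as.character(back$genotype), layout$genotype)
})

test_that("schema and referential violations are rejected with typed errors", {
  layout <- tibble::tibble(
    plot_id = paste0("p", 1:4), row = c(0, 0, 1, 1), col = c(0, 1, 0, 1),
    block = 1, treatment = "WW", genotype = paste0("g", 1:4)
  )
  expect_error(validate_layout(layout[setdiff(names(layout), "block")]),
               class = "fieldkrige_schema_error")
  bad <- layout; bad$row <- c(0, 0, 0, 1); bad$col <- c(0, 1, 1, 0)
  expect_error(validate_layout(bad), class = "fieldkrige_layout_error")

  ltmp <- withr::local_tempfile(fileext = ".tsv")
  stmp <- withr::local_tempfile(fileext = ".tsv")
  write_field_table(layout, ltmp)
  write_field_table(tibble::tibble(plot_id = "p9", nitrate = 1), stmp)
  expect_error(read_field_tables(ltmp, soil_path = stmp),
               class = "fieldkrige_referential_error")
})

test_that("sample-depth filter is strict and runs before the OTU filter", {
  counts <- rbind(c(9000, 999), c(9000, 1000), c(20000, 30000))
  otus <- make_otus(counts)
  out <- filter_otu_table(otus, min_sample_depth = 10000,
                          min_otu_total = 0, max_otu_total = Inf)
  expect_equal(out$sample_id, otus$sample_id[2:3])

  counts2 <- rbind(c(49, 60, 100000, 150001), c(50, 40, 100000, 50000))
  out2 <- filter_otu_table(make_otus(counts2), min_sample_depth = 1,
                           min_otu_total = 100, max_otu_total = 200000)
  expect_equal(setdiff(names(out2), c("sample_id", "plot_id", "compartment")),
               c("otu_02", "otu_03"))

  clean <- make_otus(matrix(6000, 3, 4))
  expect_equal(filter_otu_table(clean, 10000, 100, 200000),
               clean, ignore_attr = TRUE)
  expect_error(filter_otu_table(make_otus(matrix(1, 2, 2)),
                                min_sample_depth = 10),
               class = "fieldkrige_empty_table_error")
})

test_that("filtering is idempotent on random tables", {
  set.seed(11)
  for (i in 1:10) {
    counts <- matrix(rnbinom(20 * 30, mu = 500, size = 0.3), 20, 30)
    otus <- make_otus(counts)
    f1 <- tryCatch(filter_otu_table(otus, 4000, 50, 50000),
                   error = function(e) NULL)
    if (is.null(f1)) next
    f2 <- filter_otu_table(f1, 4000, 50, 50000)
    expect_equal(f2, f1, ignore_attr = TRUE)
  }
})

test_that("depth scaling matches every sample total to the maximum", {
  otus <- make_otus(rbind(c(60, 40), c(150, 50)))
  out <- scale_to_common_depth(otus)
  expect_equal(unname(rowSums(otu_counts(out))), c(200, 200))
  expect_equal(otu_counts(out)[1, ], 2 * otu_counts(otus)[1, ])

  same <- make_otus(rbind(c(60, 40), c(30, 70)))
  expect_equal(scale_to_common_depth(same), same)
  expect_error(scale_to_common_depth(make_otus(rbind(c(0, 0), c(1, 2)))),
               class = "fieldkrige_domain_error")
})

test_that("depth scaling preserves proportions, zeros, and rank order", {
  set.seed(3)
  counts <- matrix(rnbinom(10 * 25, mu = 200, size = 0.5), 10, 25)
  otus <- make_otus(counts)
  out <- scale_to_common_depth(otus)
  m0 <- otu_counts(otus); m1 <- otu_counts(out)
  expect_equal(m1 / rowSums(m1), m0 / rowSums(m0), tolerance = 1e-12)
  expect_identical(m1 == 0, m0 == 0)
  for (i in seq_len(nrow(m0))) {
    expect_equal(order(m1[i, ]), order(m0[i, ]))
  }
})
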