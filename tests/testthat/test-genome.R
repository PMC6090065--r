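test_that("mutation filters apply strict thresholds exactly as stated", {
  rec <- data.frame(
    position = 1:7,
    frequency = c(0.05, 0.10, 0.50, 0.90, 0.30, 0.10, 0.25),
    p_value   = c(0.001, 0.010, 0.020, 0.001, 0.001, 0.010, 0.005),
    quality   = c(10, 6.0, 10, 5.9, 8, 6.0, 20),
    gene      = c(NA, NA, NA, NA, "crl", NA, "insH1"))
  out <- filter_mutations(rec)
  # boundary record (freq 0.1, p 0.01, qual 6.0) survives; sub-threshold
  # and deny-listed records do not
  expect_setequal(out$kept$position, c(2, 6))
  expect_equal(sort(out$report$position), c(1, 3, 4, 5, 7))
  expect_equal(out$report$reason[out$report$position == 1], "low_frequency")
  expect_equal(out$report$reason[out$report$position == 3], "high_p_value")
  expect_equal(out$report$reason[out$report$position == 4], "low_quality")
  expect_equal(out$report$reason[out$report$position == 5], "deny_list_gene")
  # deny list uses glob matching (rhs*, rsx*)
  rhs <- data.frame(position = 1, frequency = 0.5, p_value = 0.001,
                    quality = 30, gene = "rhsB")
  expect_equal(nrow(filter_mutations(rhs)$kept), 0L)
  # subset + idempotence
  again <- filter_mutations(out$kept)
  expect_equal(again$kept, out$kept)
  expect_true(all(out$kept$position %in% rec$position))
  expect_error(filter_mutations(data.frame(position = 1, frequency = 1.5,
                                           p_value = 0.1, quality = 1)),
               class = "fluxpath_validation_error")
})

test_that("duplication calls are maximal runs above twice the mean depth", {
  # flat track: nothing called
  expect_equal(nrow(call_duplications(rep(50, 5000))), 0L)
  # constructed 10 kb track at depth 50 with a 300 bp region at depth 120
  depths <- rep(50, 10000)
  depths[2001:2300] <- 120
  calls <- call_duplications(depths)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 2001L)
  expect_equal(calls$end, 2300L)
  expect_equal(calls$length, 300L)
  expect_equal(calls$mean_depth, 120)
  # brute-force scan oracle: every position in a call is above threshold and
  # the call cannot be extended
  thr <- 2 * mean(depths)
  expect_true(all(depths[calls$start:calls$end] > thr))
  expect_false(depths[calls$start - 1L] > thr)
  expect_false(depths[calls$end + 1L] > thr)
  # 199 bp region above threshold is rejected (minimum 200)
  short <- rep(50, 10000)
  short[3001:3199] <- 150
  expect_equal(nrow(call_duplications(short)), 0L)
  # exactly 200 passes
  ok <- rep(50, 10000)
  ok[3001:3200] <- 150
  expect_equal(call_duplications(ok)$length, 200L)
})

test_that("simulated coverage tracks recover planted duplications", {
  cov <- simulate_coverage(8000, 500,
                           data.frame(start = 2501, end = 2900),
                           seed = 17, dup_factor = 2.4)
  calls <- call_duplications(cov$depths)
  expect_equal(nrow(calls), 1L)
  # call overlaps the planted interval
  expect_lte(calls$start, 2900L)
  expect_gte(calls$end, 2501L)
  expect_gte(calls$length, 200L)
  # no planted interval, no call
  flat <- simulate_coverage(8000, 500, seed = 18)
  expect_equal(nrow(call_duplications(flat$depths)), 0L)
  # 150 bp interval is below the minimum length
  tiny <- simulate_coverage(8000, 500,
                            data.frame(start = 100, end = 249),
                            seed = 19, dup_factor = 2.4)
  expect_equal(nrow(call_duplications(tiny$depths)), 0L)
  # determinism and truth bookkeeping
  again <- simulate_coverage(8000, 500,
                             data.frame(start = 2501, end = 2900),
                             seed = 17, dup_factor = 2.4)
  expect_identical(cov$depths, again$depths)
  expect_equal(cov$truth$start, 2501)
  expect_error(simulate_coverage(100, 10, data.frame(start = 50, end = 200),
                                 seed = 1),
               class = "fluxpath_validation_error")
  expect_error(simulate_coverage(1000, 10,
                                 data.frame(start = c(1, 50),
                                            end = c(60, 100)), seed = 1),
               class = "fluxpath_validation_error")
})

test_that("coverage and mutation tables round-trip through text formats", {
  cov <- simulate_coverage(500, 60, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(position = seq_along(cov$depths),
                                depth = cov$depths),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_coverage(path)
  expect_equal(back$depths, as.numeric(cov$depths))
  calls <- data.frame(start = 101L, end = 400L, mean_depth = 130.5,
                      length = 300L)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_duplications_bed(calls, bed, chrom = "U00096")
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(fields[1], "U00096")
  expect_equal(as.integer(fields[2]), 100L)   # 0-based half-open start
  expect_equal(as.integer(fields[3]), 400L)
})
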