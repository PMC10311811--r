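# Block pairing, switch distance, per-block comparison, the 12-metric
# panel, and pairwise summaries.

test_that("blocks pair with the unique overlapping counterpart, else none", {
  ha1 <- phasing_from_sizes(c(2, 2), tool_name = "a", normalized = TRUE)
  # self-pairing: every block pairs with its identical twin
  self <- pair_blocks(ha1, ha1)
  expect_equal(self$ha2_block_id, self$block_id)
  expect_true(all(self$reason == "unique"))

  # zero overlap
  ha2 <- phasing(tibble::tibble(
    block_id = "z", position = c(1000L, 1010L), h1 = c(0L, 1L)
  ), tool_name = "b", chromosome = "chr10", normalized = TRUE)
  none <- pair_blocks(ha1, ha2)
  expect_true(all(none$reason == "none"))
  expect_true(all(is.na(none$ha2_block_id)))

  # multiple overlap collapses to none-with-reason
  big <- phasing(tibble::tibble(
    block_id = "big", position = c(10L, 20L, 30L, 40L), h1 = c(0L, 1L, 0L, 1L)
  ), tool_name = "a", chromosome = "chr10", normalized = TRUE)
  two <- phasing(tibble::tibble(
    block_id = c("p", "p", "q", "q"),
    position = c(10L, 20L, 30L, 40L), h1 = c(0L, 1L, 0L, 1L)
  ), tool_name = "b", chromosome = "chr10", normalized = TRUE)
  multi <- pair_blocks(big, two)
  expect_equal(multi$reason, "multiple")
  expect_true(is.na(multi$ha2_block_id))

  # pairing agrees with an exhaustive overlap scan on random instances
  set.seed(21)
  for (rep in 1:10) {
    a <- random_phasing(60, "a")
    b <- random_phasing(60, "b")
    got <- pair_blocks(a, b)
    want <- vapply(got$block_id, function(id) oracle_pair(a, b, id),
                   character(1))
    expect_equal(got$ha2_block_id, unname(want))
  }
})

test_that("different chromosomes are a usage error", {
  a <- phasing_from_sizes(2, chromosome = "chr1", normalized = TRUE)
  b <- phasing_from_sizes(2, chromosome = "chr2", normalized = TRUE)
  expect_error(pair_blocks(a, b), class = "hapcompare_usage_error")
})

test_that("switch distance counts agreement-vector transitions", {
  b1 <- make_block(1:2 * 10, c(0, 1))
  expect_equal(switch_count(b1, b1), 0L)
  # swapping the two haplotypes is the same phasing
  expect_equal(switch_count(b1, make_block(1:2 * 10, c(1, 0))), 0L)
  # one internal flip in a 4-site block costs one switch
  expect_equal(
    switch_count(make_block(1:4 * 10, c(0, 0, 0, 0)),
                 make_block(1:4 * 10, c(0, 0, 1, 1))),
    1L
  )
  # alternating agreement at sites (1,3,5) vs (2,4) costs four switches
  expect_equal(
    switch_count(make_block(1:5 * 10, c(0, 0, 0, 0, 0)),
                 make_block(1:5 * 10, c(0, 1, 0, 1, 0))),
    4L
  )
  # differing site sets cannot be compared
  expect_true(is.na(switch_count(b1, make_block(c(10, 30), c(0, 1)))))
  expect_true(is.na(switch_count(b1, make_block(1:3 * 10, c(0, 1, 0)))))
})

test_that("switch distance equals the exhaustive minimum-switch oracle", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    pos <- sort(sample(1:500, n))
    b1 <- make_block(pos, sample(0:1, n, replace = TRUE))
    b2 <- make_block(pos, sample(0:1, n, replace = TRUE))
    expect_identical(switch_count(b1, b2), oracle_min_switches(b1, b2))
  }
})

test_that("switch distance is symmetric and invariant to haplotype swap", {
  set.seed(37)
  for (rep in 1:50) {
    n <- sample(2:10, 1)
    pos <- sort(sample(1:500, n))
    b1 <- make_block(pos, sample(0:1, n, replace = TRUE))
    b2 <- make_block(pos, sample(0:1, n, replace = TRUE))
    sc <- switch_count(b1, b2)
    expect_identical(switch_count(b2, b1), sc)
    expect_identical(switch_count(b1, make_block(pos, 1L - b2$h1)), sc)
    expect_identical(switch_count(make_block(pos, 1L - b1$h1), b2), sc)
  }
})

test_that("the six-pair worked example reproduces the printed row pattern", {
  cmp <- worked_example_comparisons()
  expect_equal(cmp$ha1_snv_num, c(2L, 7L, 4L, 2L, 2L, 2L))
  expect_equal(cmp$ha2_snv_num, c(1L, 4L, 4L, 3L, 2L, 2L))
  expect_equal(cmp$snv_match, c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(cmp$hap_match, c(NA, NA, FALSE, NA, TRUE, TRUE))
  expect_equal(cmp$switch_count, c(NA, NA, 1L, NA, 0L, 0L))
})

test_that("the 12 metrics aggregate the worked example as hand-summed", {
  m <- switch_metrics(worked_example_comparisons())
  expect_equal(m$blk_w_0sw, 2L)
  expect_equal(m$blk_w_NAsw, 3L)
  expect_equal(m$blk_w_sw, 1L)
  expect_equal(m$snv_in_blk_w_0sw, 4L)
  expect_equal(m$snv_in_blk_w_NAsw, 11L)
  expect_equal(m$snv_in_blk_w_sw, 4L)
  expect_equal(m$total_sw, 1L)
  expect_equal(m$snv_by_sw, 4.0)
  expect_equal(m$sw_per_blk, 1.0)
})

test_that("metrics partition blocks and SNVs and satisfy their ratios", {
  set.seed(41)
  for (rep in 1:30) {
    a <- random_phasing(80, "a")
    b <- random_phasing(80, "b")
    cmp <- compare_phasings(a, b)
    m <- switch_metrics(cmp$blocks)
    o <- oracle_metrics(cmp$blocks)
    for (f in names(o)) expect_equal(m[[f]], o[[f]], info = f)
    expect_equal(m$blk_w_0sw + m$blk_w_NAsw + m$blk_w_sw, nrow(cmp$blocks))
    expect_equal(
      m$snv_in_blk_w_0sw + m$snv_in_blk_w_NAsw + m$snv_in_blk_w_sw,
      sum(cmp$blocks$ha1_snv_num)
    )
  }
  # all-identical comparisons: ratios are NA, never 0
  m0 <- switch_metrics(tibble::tibble(
    block_id = "1", ha1_snv_num = 3L, ha2_snv_num = 3L,
    snv_match = TRUE, hap_match = TRUE, switch_count = 0L
  ))
  expect_equal(m0$blk_w_sw, 0L)
  expect_equal(m0$total_sw, 0L)
  expect_true(is.na(m0$snv_by_sw))
  expect_true(is.na(m0$sw_per_blk))
  expect_true(is.na(m0$snv_per_blk_w_sw))
})

test_that("pairwise summary percentages follow the half-up convention", {
  s <- summarize_pairwise(
    worked_example_comparisons(),
    list(tool_name = "HA1", total_blocks = 6L, total_snvs = 19L),
    ha2_name = "HA2"
  )
  expect_equal(s$disagree_blocks, 4L)          # 3 NA + 1 switched
  expect_equal(s$disagree_snvs, 2L + 7L + 2L + 4L)
  expect_equal(s$block_disagree_pct, round_half_up(100 * 4 / 6, 2))
  expect_equal(s$snv_disagree_pct, round_half_up(100 * 15 / 19, 2))
})

test_that("self-comparison yields zero disagreement everywhere", {
  set.seed(43)
  a <- random_phasing(100, "a")
  g <- glance(compare_phasings(a, a))
  expect_equal(g$disagree_blocks, 0L)
  expect_equal(g$disagree_snvs, 0L)
  expect_equal(g$block_disagree_pct, 0)
  expect_equal(g$snv_disagree_pct, 0)
  expect_equal(g$total_sw, 0L)
  expect_equal(g$blk_w_0sw, length(unique(a$block_id)))
})

test_that("the vectorized comparison equals row-wise compare_block_pair", {
  set.seed(47)
  for (rep in 1:10) {
    a <- random_phasing(70, "a")
    b <- random_phasing(70, "b")
    fast <- compare_phasings(a, b)$blocks
    pairs <- pair_blocks(a, b)
    slow <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
      id <- pairs$block_id[i]
      b1 <- a[a$block_id == id, c("position", "h1")]
      b2 <- if (is.na(pairs$ha2_block_id[i])) NULL else
        b[b$block_id == pairs$ha2_block_id[i], c("position", "h1")]
      compare_block_pair(b1, b2, block_id = id)
    }))
    expect_equal(as.data.frame(fast), as.data.frame(slow))
  }
})

test_that("compare_all covers ordered pairs, honours exclusions, is asymmetric", {
  set.seed(53)
  res <- list(
    a = random_phasing(60, "a"),
    b = random_phasing(60, "b"),
    c = random_phasing(60, "c")
  )
  ps <- compare_all(res)
  expect_equal(nrow(ps), 6L)

  ps2 <- compare_all(res, exclude = "a:b")
  expect_equal(nrow(ps2), 5L)
  expect_equal(nrow(ps2[ps2$ha1_name == "a" & ps2$ha2_name == "b", ]), 0L)
  expect_equal(nrow(ps2[ps2$ha1_name == "b" & ps2$ha2_name == "a", ]), 1L)

  # asymmetry: HA1 supplies the denominators
  ab <- ps[ps$ha1_name == "a" & ps$ha2_name == "b", ]
  ba <- ps[ps$ha1_name == "b" & ps$ha2_name == "a", ]
  expect_equal(ab$ha1_total_snvs, sum(!is.na(res$a$h1)))
  expect_equal(ba$ha1_total_snvs, sum(!is.na(res$b$h1)))

  expect_error(compare_all(list(a = res$a, a2 = res$a)[c(1, 1)]),
               class = "hapcompare_usage_error")
})

test_that("disagreement matrices render counts, diagonal zeros and exclusions", {
  set.seed(59)
  res <- list(a = random_phasing(60, "a"), b = random_phasing(60, "b"))
  ps <- compare_all(res, exclude = "b:a")
  m <- disagreement_matrix(ps, "block")
  expect_equal(m$a[1], "0")
  expect_equal(m$a[2], "-")
  r <- ps[ps$ha1_name == "a", ]
  expect_equal(
    m$b[1],
    format_count_pct(r$disagree_blocks, r$ha1_total_blocks)
  )
  pm <- disagreement_matrix(ps, "snv", values = "pct")
  expect_equal(pm$b[1], r$snv_disagree_pct)
  expect_true(is.na(pm$a[2]))
})

test_that("comparison outputs are invariant to input file sort order", {
  set.seed(61)
  a <- random_phasing(80, "a")
  b <- random_phasing(80, "b")
  # relabel a's blocks so that block-ID order differs from position order
  ids <- unique(a$block_id)
  relabel <- setNames(as.character(rev(seq_along(ids))), ids)
  a_rel <- phasing(
    tibble::tibble(block_id = relabel[a$block_id], position = a$position,
                   h1 = a$h1),
    tool_name = "a", chromosome = "chr10"
  )
  f_by_id <- tempfile()
  f_by_pos <- tempfile()
  write_block_file(a_rel, f_by_id, dialect = "hapcut2")   # by block ID
  write_block_file(a_rel, f_by_pos, dialect = "peath")    # by position
  expect_false(identical(readLines(f_by_id), readLines(f_by_pos)))
  r1 <- normalize_phasing(read_block_file(f_by_id, tool_name = "a"))
  r2 <- normalize_phasing(read_block_file(f_by_pos, tool_name = "a"))
  g1 <- glance(compare_phasings(r1, b))
  g2 <- glance(compare_phasings(r2, b))
  expect_equal(g1, g2)
  g3 <- glance(compare_phasings(b, r1))
  g4 <- glance(compare_phasings(b, r2))
  expect_equal(g3, g4)
  unlink(c(f_by_id, f_by_pos))
})
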