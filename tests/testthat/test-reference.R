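# Gold-standard overlap, position filtering, and depth filtering.

test_that("position overlap counts set intersections with half-up percent", {
  p <- phasing(tibble::tibble(
    block_id = "b", position = c(10L, 20L, 30L), h1 = c(0L, 1L, 0L)
  ), tool_name = "t", chromosome = "chr10", normalized = TRUE)
  ov <- position_overlap(p, c(20L, 30L, 40L, 50L))
  expect_equal(ov$inferred_total, 3L)
  expect_equal(ov$overlap_count, 2L)
  expect_equal(ov$overlap_pct, 66.67)

  # superset known set: 100.00%
  ov2 <- position_overlap(p, 1:100)
  expect_equal(ov2$overlap_pct, 100)

  # a result against its own position set is always 100%
  set.seed(3)
  r <- random_phasing(50)
  expect_equal(position_overlap(r, r$position)$overlap_pct, 100)

  empty <- normalize_phasing(phasing(tibble::tibble(
    block_id = character(), position = integer(), h1 = integer()
  )))
  expect_error(position_overlap(empty, 1:10),
               class = "hapcompare_empty_input_error")
})

test_that("position filtering drops sites, re-applies the singleton rule, idempotent", {
  p <- phasing(tibble::tibble(
    block_id = rep(c("a", "b"), c(3, 2)),
    position = c(10L, 20L, 30L, 50L, 60L),
    h1 = c(0L, 1L, 0L, 1L, 0L)
  ), tool_name = "t", chromosome = "chr10", normalized = TRUE)

  # identity when keeping everything
  expect_equal(as.data.frame(filter_to_positions(p, p$position)),
               as.data.frame(p))

  # partial keep retains a 2-site block
  f1 <- filter_to_positions(p, c(10L, 30L, 50L, 60L))
  expect_equal(f1$position, c(10L, 30L, 50L, 60L))
  expect_equal(unique(f1$block_id), c("a", "b"))

  # a block reduced to one site is dropped entirely
  f2 <- filter_to_positions(p, c(10L, 30L, 50L))
  expect_equal(unique(f2$block_id), "a")
  expect_equal(f2$position, c(10L, 30L))

  # idempotent and commutes with normalization
  set.seed(17)
  r <- random_phasing(60)
  keep <- sample(r$position, 40)
  once <- filter_to_positions(r, keep)
  expect_equal(as.data.frame(filter_to_positions(once, keep)),
               as.data.frame(once))
  expect_equal(as.data.frame(normalize_phasing(once)), as.data.frame(once))
})

test_that("intersecting positions of two results builds the keep set", {
  a <- phasing(tibble::tibble(block_id = "a", position = c(10L, 20L, 30L),
                              h1 = c(0L, 1L, 0L)),
               normalized = TRUE, chromosome = "chr10")
  b <- phasing(tibble::tibble(block_id = "b", position = c(20L, 30L, 40L),
                              h1 = c(0L, 1L, 0L)),
               normalized = TRUE, chromosome = "chr10")
  expect_equal(intersect_positions(a, b), c(20L, 30L))
  expect_equal(intersect_positions(a, a), a$position)
  c0 <- phasing(tibble::tibble(block_id = "c", position = c(100L, 110L),
                               h1 = c(0L, 1L)),
                normalized = TRUE, chromosome = "chr10")
  expect_equal(intersect_positions(a, c0), integer())
})

test_that("position-set files read single-column and BED-like layouts", {
  f <- tempfile()
  writeLines(c("30", "10", "20"), f)
  expect_equal(read_positions(f), c(10L, 20L, 30L))
  writeLines(c("chr10\t9\t10", "chr10\t19\t21"), f)
  expect_equal(read_positions(f), c(10L, 20L, 21L))
  write_positions(c(5L, 2L, 5L), f)
  expect_equal(read_positions(f), c(2L, 5L))
  unlink(f)
})

make_frags <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  on.exit(unlink(f))
  read_fragments(
    f,
    index_to_position = tibble::tibble(variant_index = 1:20,
                                       position = 1:20 * 100L)
  )
}

test_that("site depths count covering fragments and need a position map", {
  fs <- make_frags(c(
    "1 r1 7 01 QQ",
    "1 r2 7 1 Q",
    "2 r3 7 0 9 1 QQ"
  ))
  d <- site_depths(fs)
  expect_equal(d$depth[d$variant_index == 7L], 3L)
  expect_equal(d$position[d$variant_index == 7L], 700L)

  # randomized sets agree with a naive per-position loop
  set.seed(23)
  for (rep in 1:5) {
    lines <- vapply(1:10, function(i) {
      idx <- sort(sample(1:20, sample(2:5, 1)))
      segs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
      body <- paste(vapply(segs, function(s) {
        paste(s[1], paste(sample(0:1, length(s), TRUE), collapse = ""))
      }, character(1)), collapse = " ")
      paste(length(segs), paste0("r", i), body,
            paste(rep("Q", length(idx)), collapse = ""))
    }, character(1))
    fs <- make_frags(lines)
    d <- site_depths(fs)
    naive <- table(fs$variant_index)
    expect_equal(d$depth, as.integer(naive[as.character(d$variant_index)]))
  }

  no_map <- read_fragments({
    f <- tempfile(); writeLines("1 r1 3 01 QQ", f); f
  })
  expect_error(site_depths(no_map), class = "hapcompare_mapping_error")
})

test_that("depth filtering masks shallow sites, drops thin fragments, is monotone", {
  fs <- make_frags(c(
    "1 r1 1 0101 QQQQ",     # covers 1-4
    "1 r2 2 010 QQQ",       # covers 2-4
    "1 r3 3 01 QQ",         # covers 3-4
    "1 r4 10 01 QQ"         # covers 10-11 (depth 1 each)
  ))
  # DP1: only sub-2-variant fragments would go; nothing does here
  f1 <- filter_by_depth(fs, 1)
  expect_equal(sort(unique(f1$fragment_id)), c("r1", "r2", "r3", "r4"))

  # DP2: variants 1, 10, 11 fall below depth 2 -> masked everywhere;
  # fragment r4 then covers nothing and is removed
  f2 <- filter_by_depth(fs, 2)
  expect_false(any(f2$variant_index %in% c(1L, 10L, 11L)))
  expect_false("r4" %in% f2$fragment_id)

  # DP3: only variants 3 and 4 (depth 3) survive
  f3 <- filter_by_depth(fs, 3)
  expect_equal(sort(unique(f3$variant_index)), c(3L, 4L))

  # monotone in min_depth on random inputs
  set.seed(29)
  for (rep in 1:5) {
    lines <- vapply(1:12, function(i) {
      idx <- sort(sample(1:15, sample(2:5, 1)))
      segs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
      body <- paste(vapply(segs, function(s) {
        paste(s[1], paste(sample(0:1, length(s), TRUE), collapse = ""))
      }, character(1)), collapse = " ")
      paste(length(segs), paste0("r", i), body,
            paste(rep("Q", length(idx)), collapse = ""))
    }, character(1))
    fs <- make_frags(lines)
    prev_frags <- Inf
    prev_sites <- NULL
    for (dp in c(1, 5, 10)) {
      fdp <- filter_by_depth(fs, dp)
      nf <- length(unique(fdp$fragment_id))
      expect_lte(nf, prev_frags)
      sites <- unique(fdp$variant_index)
      if (!is.null(prev_sites)) expect_true(all(sites %in% prev_sites))
      prev_frags <- nf
      prev_sites <- sites
    }
  }
})

test_that("known-haplotype sets load all genotype classes from phased VCF", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    "chr10\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0|0",
    "chr10\t200\t.\tA\tT\t.\tPASS\t.\tGT\t1|1",
    "chr10\t300\t.\tA\tT\t.\tPASS\t.\tGT\t0|1",
    "chr10\t400\t.\tA\tT\t.\tPASS\t.\tGT\t1|0"
  ), f)
  k <- read_known_haplotypes(f)
  expect_equal(k$position, c(100L, 200L, 300L, 400L))
  het <- read_known_haplotypes(f, het_only = TRUE)
  expect_equal(het$position, c(300L, 400L))
  unlink(f)
})
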