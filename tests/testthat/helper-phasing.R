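# Fixture builders and independent oracles shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a single block tibble from positions and h1 alleles.
make_block <- function(positions, h1) {
  tibble::tibble(position = as.integer(positions), h1 = as.integer(h1))
}

# Build a phasing object from a vector of block sizes; positions are
# consecutive multiples of 10, h1 alleles taken from `h1` or random.
phasing_from_sizes <- function(sizes, h1 = NULL, tool_name = "tool",
                               chromosome = "chr10", normalized = FALSE) {
  n <- sum(sizes)
  h1 <- h1 %||% sample(0:1, n, replace = TRUE)
  phasing(
    tibble::tibble(
      block_id = rep(sprintf("b%04d", seq_along(sizes)), sizes),
      position = seq_len(n) * 10L,
      h1 = as.integer(h1)
    ),
    tool_name = tool_name, chromosome = chromosome, normalized = normalized
  )
}

# Random normalized phasing result over a shared position grid.
random_phasing <- function(n_sites = 60, tool_name = "rnd",
                           max_block = 6, drop_prob = 0.1,
                           unphase_prob = 0) {
  sizes <- integer()
  while (sum(sizes) < n_sites) {
    sizes <- c(sizes, sample(2:max_block, 1))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_sites)
  if (sizes[length(sizes)] < 2) sizes <- sizes[-length(sizes)]
  n <- sum(sizes)
  keep <- runif(n) > drop_prob
  h1 <- sample(0:1, n, replace = TRUE)
  h1[runif(n) < unphase_prob] <- NA_integer_
  raw <- phasing(
    tibble::tibble(
      block_id = rep(sprintf("b%04d", seq_along(sizes)), sizes),
      position = seq_len(n) * 10L,
      h1 = h1
    )[keep, ],
    tool_name = tool_name, chromosome = "chr10"
  )
  normalize_phasing(raw)
}

# --- Independent oracles -------------------------------------------------

# Exhaustive minimum-switch oracle: tries every subset of suffix-flip
# positions (gaps 2..n) with and without a global relabeling and returns
# the smallest number of switch operations turning b2's h1 into b1's h1.
# NA when the ordered position lists differ. Only for n <= ~12.
oracle_min_switches <- function(b1, b2) {
  o1 <- order(b1$position); o2 <- order(b2$position)
  if (length(o1) != length(o2) || !all(b1$position[o1] == b2$position[o2])) {
    return(NA_integer_)
  }
  target <- b1$h1[o1]
  start <- b2$h1[o2]
  n <- length(target)
  if (n == 0) return(0L)
  best <- NA_integer_
  for (g in 0:1) {
    for (mask in 0:(2^(max(n - 1, 0)) - 1)) {
      flips <- as.integer(intToBits(mask))[seq_len(max(n - 1, 0))]
      cum <- (g + cumsum(c(0L, flips))) %% 2L
      if (all(((start + cum) %% 2L) == target)) {
        k <- sum(flips)
        if (is.na(best) || k < best) best <- k
      }
    }
  }
  best
}

# Naive per-category re-aggregation of the 12 switch metrics.
oracle_metrics <- function(comparisons) {
  z <- na <- pos <- 0L
  snv_z <- snv_na <- snv_pos <- 0L
  tot <- 0L
  for (i in seq_len(nrow(comparisons))) {
    sc <- comparisons$switch_count[i]
    n1 <- comparisons$ha1_snv_num[i]
    if (is.na(sc)) {
      na <- na + 1L; snv_na <- snv_na + n1
    } else if (sc == 0L) {
      z <- z + 1L; snv_z <- snv_z + n1
    } else {
      pos <- pos + 1L; snv_pos <- snv_pos + n1; tot <- tot + sc
    }
  }
  list(
    blk_w_0sw = z, blk_w_NAsw = na, blk_w_sw = pos,
    snv_in_blk_w_0sw = snv_z, snv_in_blk_w_NAsw = snv_na,
    snv_in_blk_w_sw = snv_pos,
    snv_per_blk_w_0sw = if (z > 0) snv_z / z else NA_real_,
    snv_per_blk_w_NAsw = if (na > 0) snv_na / na else NA_real_,
    snv_per_blk_w_sw = if (pos > 0) snv_pos / pos else NA_real_,
    total_sw = tot,
    snv_by_sw = if (tot > 0) snv_pos / tot else NA_real_,
    sw_per_blk = if (pos > 0) tot / pos else NA_real_
  )
}

# Exhaustive overlap scan used as the block-pairing oracle.
oracle_pair <- function(ha1, ha2, id) {
  pos1 <- ha1$position[ha1$block_id == id]
  hits <- unique(ha2$block_id[ha2$position %in% pos1])
  if (length(hits) == 1) hits else NA_character_
}

# The Table-3-style worked example: six block pairs with SNV counts
# (2,1),(7,4),(4,4),(2,3),(2,2),(2,2); pair 3 has one internal phase flip,
# pairs 5 and 6 are identical (pair 6 up to haplotype swap).
worked_example_comparisons <- function() {
  b <- function(n, start, h1) make_block(start + 10L * seq_len(n), h1)
  pairs <- list(
    list(b(2, 0L, c(0, 1)), b(1, 0L, 0)),
    list(b(7, 100L, rep(0, 7)), b(4, 100L, rep(0, 4))),
    list(b(4, 300L, c(0, 0, 0, 0)), b(4, 300L, c(0, 0, 1, 1))),
    list(b(2, 500L, c(1, 0)), b(3, 500L, c(1, 0, 1))),
    list(b(2, 600L, c(0, 1)), b(2, 600L, c(0, 1))),
    list(b(2, 700L, c(1, 0)), b(2, 700L, c(0, 1)))
  )
  dplyr::bind_rows(lapply(seq_along(pairs), function(i) {
    compare_block_pair(pairs[[i]][[1]], pairs[[i]][[2]], block_id = i)
  }))
}
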