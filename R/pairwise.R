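# The core analysis: block pairing, per-block comparison, switch distance,
# the 12-metric switch panel, and pairwise disagreement summaries.
#
# One result acts as the reference (HA1) and the other (HA2) is compared to
# it block by block: for each HA1 block the unique HA2 block sharing at
# least one position is its counterpart (zero or multiple overlapping HA2
# blocks leave the HA1 block uncompared, an NA row). If the two blocks
# cover identical ordered positions the switch distance is the number of
# transitions in the site-wise agreement vector — the minimum number of
# suffix phase switches needed to turn one phasing into the other, invariant
# to swapping either block's two haplotypes.

#' Pair blocks of two phasing results by position overlap
#'
#' For each HA1 block, finds the unique HA2 block sharing at least one
#' position. Zero overlapping HA2 blocks gives reason `"none"`, more than
#' one gives `"multiple"`; either way the HA1 block has no usable
#' counterpart and will be reported as an NA comparison.
#'
#' @param ha1,ha2 Normalized `phasing` objects on the same chromosome.
#' @return Tibble with one row per HA1 block (canonical order): `block_id`,
#'   `ha2_block_id` (`NA` when unpaired), `n_shared`, `reason` (`"unique"`,
#'   `"none"`, `"multiple"`).
#' @export
pair_blocks <- function(ha1, ha2) {
  assert_normalized(ha1, "ha1")
  assert_normalized(ha2, "ha2")
  c1 <- phasing_chromosome(ha1)
  c2 <- phasing_chromosome(ha2)
  if (!is.na(c1) && !is.na(c2) && c1 != c2) {
    hc_abort(
      paste0("cannot compare results on different chromosomes (", c1,
             " vs ", c2, ")"),
      "usage_error"
    )
  }
  m <- match(ha1$position, ha2$position)
  tibble(
    block_id = ha1$block_id,
    ha2_of_site = ha2$block_id[m]
  ) |>
    group_by(.data$block_id) |>
    summarise(
      hit = list(unique(.data$ha2_of_site[!is.na(.data$ha2_of_site)])),
      n_shared = sum(!is.na(.data$ha2_of_site)),
      .groups = "drop"
    ) |>
    # preserve HA1's canonical block order
    dplyr::slice(match(unique(ha1$block_id), .data$block_id)) |>
    mutate(
      n_hit = lengths(.data$hit),
      ha2_block_id = ifelse(.data$n_hit == 1L,
                            vapply(.data$hit, function(h) h[1] %||% NA_character_,
                                   character(1)),
                            NA_character_),
      reason = dplyr::case_when(
        .data$n_hit == 1L ~ "unique",
        .data$n_hit == 0L ~ "none",
        TRUE ~ "multiple"
      )
    ) |>
    select("block_id", "ha2_block_id", "n_shared", "reason")
}

#' Switch distance between two blocks
#'
#' Returns `NA` when the two blocks do not cover identical ordered position
#' lists (different site sets cannot be allele-compared). Otherwise forms
#' the agreement vector `a_i = [h1 of b2 == h1 of b1]` over positions in
#' increasing order and counts the transitions `a_i != a_(i+1)`: the
#' minimum number of suffix phase switches needed to make the two phasings
#' identical up to global relabeling. It is 0 exactly when the blocks match
#' up to swapping the two haplotypes.
#'
#' @param b1,b2 Data frames with columns `position` and `h1` (no unphased
#'   sites) — typically single blocks of normalized phasing results.
#' @return Non-negative integer, or `NA` when the site sets differ.
#' @export
#' @examples
#' b1 <- tibble::tibble(position = 1:4 * 10L, h1 = c(0L, 0L, 0L, 0L))
#' b2 <- tibble::tibble(position = 1:4 * 10L, h1 = c(0L, 0L, 1L, 1L))
#' switch_count(b1, b2)
switch_count <- function(b1, b2) {
  p1 <- order(b1$position)
  p2 <- order(b2$position)
  pos1 <- b1$position[p1]
  pos2 <- b2$position[p2]
  if (length(pos1) != length(pos2) || !all(pos1 == pos2)) {
    return(NA_integer_)
  }
  h1 <- b1$h1[p1]
  h2 <- b2$h1[p2]
  if (anyNA(h1) || anyNA(h2)) {
    hc_abort(
      "unphased site reached switch_count(); normalize inputs first",
      "internal_error"
    )
  }
  a <- h1 == h2
  if (length(a) < 2L) return(0L)
  sum(a[-1] != a[-length(a)])
}

#' Compare one HA1 block with its paired HA2 block
#'
#' Records the SNV counts of both blocks, whether the site sets match
#' (identical ordered positions), whether the haplotypes match (site sets
#' match and switch distance 0), and the switch count. With no counterpart
#' (`b2 = NULL`) the HA2 count is 0 and both flags are unmet/`NA`.
#'
#' @param b1 HA1 block (data frame with `position`, `h1`).
#' @param b2 Paired HA2 block, or `NULL` when unpaired.
#' @param block_id Label reported for the row (default `"1"`).
#' @return One-row tibble: `block_id`, `ha1_snv_num`, `ha2_snv_num`,
#'   `snv_match`, `hap_match`, `switch_count`.
#' @export
compare_block_pair <- function(b1, b2 = NULL, block_id = "1") {
  n1 <- nrow(b1)
  if (is.null(b2)) {
    return(tibble(
      block_id = as.character(block_id),
      ha1_snv_num = n1, ha2_snv_num = 0L,
      snv_match = FALSE, hap_match = NA, switch_count = NA_integer_
    ))
  }
  sc <- switch_count(b1, b2)
  snv_match <- !is.na(sc)
  tibble(
    block_id = as.character(block_id),
    ha1_snv_num = n1,
    ha2_snv_num = nrow(b2),
    snv_match = snv_match,
    hap_match = if (snv_match) sc == 0L else NA,
    switch_count = sc
  )
}

# Vectorized block-by-block comparison table (one row per HA1 block).
comparison_table <- function(ha1, ha2) {
  pairs <- pair_blocks(ha1, ha2)
  ha2_sizes <- table(ha2$block_id)

  m <- match(ha1$position, ha2$position)
  sites <- tibble(
    block_id = ha1$block_id,
    position = ha1$position,
    agree = ha1$h1 == ha2$h1[m],
    ha2_block = ha2$block_id[m]
  )
  per_block <- sites |>
    group_by(.data$block_id) |>
    summarise(
      ha1_snv_num = n(),
      n_found = sum(!is.na(.data$ha2_block)),
      sw = if (anyNA(.data$agree)) NA_integer_ else {
        a <- .data$agree
        if (length(a) < 2L) 0L else sum(a[-1] != a[-length(a)])
      },
      .groups = "drop"
    )

  out <- pairs |>
    left_join(per_block, by = "block_id") |>
    mutate(
      ha2_snv_num = ifelse(is.na(.data$ha2_block_id), 0L,
                           as.integer(ha2_sizes[.data$ha2_block_id])),
      # identical ordered position lists: unique counterpart, every HA1
      # site found in it, and equal sizes
      snv_match = .data$reason == "unique" &
        .data$n_found == .data$ha1_snv_num &
        .data$ha2_snv_num == .data$ha1_snv_num,
      switch_count = ifelse(.data$snv_match, .data$sw, NA_integer_),
      hap_match = ifelse(.data$snv_match, .data$switch_count == 0L, NA)
    ) |>
    select("block_id", "ha1_snv_num", "ha2_snv_num", "snv_match",
           "hap_match", "switch_count")
  out
}

#' The 12 switch-distance metrics
#'
#' Aggregates a block-comparison table into the twelve-number switch panel:
#' block counts by category (`blk_w_0sw` agreed with zero switches,
#' `blk_w_NAsw` not comparable because site sets differed, `blk_w_sw`
#' disagreed with a positive switch count), HA1 SNV counts in each
#' category, mean SNVs per block in each category, the total switch count,
#' and the per-disagreement-block ratios `snv_by_sw` (SNVs per switch) and
#' `sw_per_blk` (switches per block), both over `sw > 0` blocks only.
#' Ratios with a zero denominator are `NA`, never 0.
#'
#' @param comparisons Tibble from [compare_phasings()]/[tidy()] or
#'   [compare_block_pair()] rows.
#' @return One-row tibble with the 12 metric columns.
#' @export
switch_metrics <- function(comparisons) {
  sc <- comparisons$switch_count
  n1 <- comparisons$ha1_snv_num
  cat <- ifelse(is.na(sc), "na", ifelse(sc == 0L, "zero", "pos"))

  blk <- function(k) sum(cat == k)
  snv <- function(k) sum(n1[cat == k])
  per <- function(k) if (blk(k) > 0L) snv(k) / blk(k) else NA_real_
  total_sw <- sum(sc[cat == "pos"])

  tibble(
    blk_w_0sw = blk("zero"),
    blk_w_NAsw = blk("na"),
    blk_w_sw = blk("pos"),
    snv_in_blk_w_0sw = snv("zero"),
    snv_in_blk_w_NAsw = snv("na"),
    snv_in_blk_w_sw = snv("pos"),
    snv_per_blk_w_0sw = per("zero"),
    snv_per_blk_w_NAsw = per("na"),
    snv_per_blk_w_sw = per("pos"),
    total_sw = total_sw,
    snv_by_sw = if (total_sw > 0L) snv("pos") / total_sw else NA_real_,
    sw_per_blk = if (blk("pos") > 0L) total_sw / blk("pos") else NA_real_
  )
}

#' Summarize a block-comparison table into disagreement rates
#'
#' A block disagrees unless its haplotypes matched (`hap_match` `TRUE`);
#' uncomparable blocks (`NA`) count as disagreements. The disagreement SNV
#' count sums the HA1 sites inside disagreement blocks, and both
#' percentages use HA1's totals as denominators, so the summary is
#' asymmetric in (HA1, HA2) by construction.
#'
#' @param comparisons Block-comparison tibble (one row per HA1 block).
#' @param ha1 The normalized HA1 `phasing` (denominators), or a list with
#'   `total_blocks`/`total_snvs`.
#' @param ha2_name HA2 label.
#' @return One-row tibble: names, totals, `disagree_blocks`,
#'   `disagree_snvs`, `block_disagree_pct`, `snv_disagree_pct` (half-up,
#'   2 decimals), plus the 12 metric columns.
#' @export
summarize_pairwise <- function(comparisons, ha1, ha2_name = "HA2") {
  if (nrow(comparisons) == 0L) {
    hc_abort("no block comparisons to summarize", "empty_input_error")
  }
  if (inherits(ha1, "phasing")) {
    ha1_name <- phasing_tool(ha1)
    total_blocks <- length(unique(ha1$block_id))
    total_snvs <- sum(phased_rows(ha1))
  } else {
    ha1_name <- ha1$tool_name %||% "HA1"
    total_blocks <- ha1$total_blocks
    total_snvs <- ha1$total_snvs
  }
  dis <- !(comparisons$hap_match %in% TRUE)
  disagree_blocks <- sum(dis)
  disagree_snvs <- sum(comparisons$ha1_snv_num[dis])
  dplyr::bind_cols(
    tibble(
      ha1_name = ha1_name,
      ha2_name = ha2_name,
      ha1_total_blocks = total_blocks,
      ha1_total_snvs = total_snvs,
      disagree_blocks = disagree_blocks,
      disagree_snvs = disagree_snvs,
      block_disagree_pct = round_half_up(100 * disagree_blocks / total_blocks, 2),
      snv_disagree_pct = round_half_up(100 * disagree_snvs / total_snvs, 2)
    ),
    switch_metrics(comparisons)
  )
}

#' Compare two phasing results block by block
#'
#' Runs the full pairwise comparison with `ha1` as the reference: pairs
#' blocks by unique position overlap, builds the per-block comparison table
#' (SNV counts, match flags, switch counts), and summarizes it into
#' disagreement rates and the 12 switch metrics. `tidy()` on the returned
#' object gives the per-block table, `glance()` the one-row summary.
#'
#' @param ha1,ha2 Normalized `phasing` objects on the same chromosome.
#' @return A `phasing_comparison` object (list with `blocks`, `summary`,
#'   `ha1_name`, `ha2_name`).
#' @export
compare_phasings <- function(ha1, ha2) {
  assert_normalized(ha1, "ha1")
  assert_normalized(ha2, "ha2")
  blocks <- comparison_table(ha1, ha2)
  summary <- summarize_pairwise(blocks, ha1, ha2_name = phasing_tool(ha2))
  structure(
    list(
      blocks = blocks,
      summary = summary,
      ha1_name = phasing_tool(ha1),
      ha2_name = phasing_tool(ha2)
    ),
    class = "phasing_comparison"
  )
}

#' @export
print.phasing_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<phasing_comparison: %s (HA1) vs %s (HA2)>\n  blocks: %s  SNVs: %s  total switches: %d\n",
    x$ha1_name, x$ha2_name,
    format_count_pct(s$disagree_blocks, s$ha1_total_blocks),
    format_count_pct(s$disagree_snvs, s$ha1_total_snvs),
    s$total_sw
  ))
  invisible(x)
}

#' @export
tidy.phasing_comparison <- function(x, ...) x$blocks

#' @export
glance.phasing_comparison <- function(x, ...) x$summary

#' All ordered pairwise comparisons among several results
#'
#' Compares every ordered (HA1, HA2) pair of the supplied results, except
#' self-pairs and explicitly excluded ordered pairs (e.g. a
#' position-filtered result against its own parent). The output is
#' asymmetric: each row uses HA1's block and SNV totals as denominators.
#'
#' @param results List of normalized `phasing` objects with distinct tool
#'   names (a named list overrides the objects' own names).
#' @param exclude Ordered pairs to skip: a list of length-2 character
#'   vectors `c(ha1, ha2)`, or a character vector of `"ha1:ha2"` strings.
#' @return A `pairwise_set`: tibble with one row per computed pair (the
#'   [summarize_pairwise()] columns), with the exclusions recorded in
#'   attribute `excluded`.
#' @seealso [disagreement_matrix()] for the matrix rendering.
#' @export
compare_all <- function(results, exclude = NULL) {
  if (!is.list(results) || length(results) < 2L) {
    hc_abort("`results` must be a list of >= 2 phasing objects", "usage_error")
  }
  nm <- names(results)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- vapply(results, phasing_tool, character(1))
  }
  if (anyDuplicated(nm)) {
    hc_abort("duplicate tool names in `results`", "usage_error")
  }
  for (i in seq_along(results)) assert_normalized(results[[i]], nm[i])

  if (is.character(exclude)) {
    exclude <- strsplit(exclude, ":", fixed = TRUE)
  }
  excl_key <- vapply(
    exclude %||% list(),
    function(p) paste(p[1], p[2], sep = "\r"), character(1)
  )

  rows <- list()
  for (i in seq_along(results)) {
    for (j in seq_along(results)) {
      if (i == j) next
      if (paste(nm[i], nm[j], sep = "\r") %in% excl_key) next
      cmp <- compare_phasings(results[[i]], results[[j]])
      s <- cmp$summary
      s$ha1_name <- nm[i]
      s$ha2_name <- nm[j]
      rows[[length(rows) + 1L]] <- s
    }
  }
  out <- bind_rows(rows)
  attr(out, "excluded") <- lapply(exclude %||% list(), function(p) p[1:2])
  attr(out, "tool_names") <- nm
  class(out) <- c("pairwise_set", class(out))
  out
}

#' Render pairwise comparisons as a disagreement matrix
#'
#' Lays a [compare_all()] result out as a matrix with one row per HA1 and
#' one column per HA2, diagonal 0 and excluded cells `"-"`. With
#' `values = "rendered"` cells read `"459/32,150 (1.43%)"`
#' (thousands separators only in this human-readable form); `"count"` and
#' `"pct"` give numeric matrices for machine use.
#'
#' @param x A `pairwise_set` from [compare_all()].
#' @param what `"block"` or `"snv"` disagreements.
#' @param values `"rendered"`, `"count"` or `"pct"`.
#' @return A tibble, first column `ha1` (with the denominator in the
#'   rendered form), one column per HA2.
#' @export
disagreement_matrix <- function(x, what = c("block", "snv"),
                                values = c("rendered", "count", "pct")) {
  what <- match.arg(what)
  values <- match.arg(values)
  nm <- attr(x, "tool_names") %||% unique(c(x$ha1_name, x$ha2_name))
  count_col <- if (what == "block") "disagree_blocks" else "disagree_snvs"
  denom_col <- if (what == "block") "ha1_total_blocks" else "ha1_total_snvs"
  pct_col <- if (what == "block") "block_disagree_pct" else "snv_disagree_pct"
  excluded <- attr(x, "excluded") %||% list()
  excl_key <- vapply(excluded, function(p) paste(p[1], p[2], sep = "\r"),
                     character(1))

  denoms <- setNames(rep(NA_integer_, length(nm)), nm)
  for (n in nm) {
    hit <- x[[denom_col]][x$ha1_name == n]
    if (length(hit) > 0L) denoms[n] <- hit[1]
  }

  rows <- lapply(nm, function(a) {
    cells <- lapply(nm, function(b) {
      if (a == b) {
        return(switch(values, rendered = "0", count = 0L, pct = 0))
      }
      if (paste(a, b, sep = "\r") %in% excl_key) {
        return(switch(values, rendered = "-", count = NA_integer_, pct = NA_real_))
      }
      r <- x[x$ha1_name == a & x$ha2_name == b, , drop = FALSE]
      if (nrow(r) == 0L) {
        return(switch(values, rendered = "-", count = NA_integer_, pct = NA_real_))
      }
      switch(values,
        rendered = format_count_pct(r[[count_col]], r[[denom_col]]),
        count = r[[count_col]],
        pct = r[[pct_col]]
      )
    })
    names(cells) <- nm
    ha1_lab <- if (values == "rendered" && !is.na(denoms[a])) {
      sprintf("%s (%s %s)", a, format_count(denoms[a]),
              if (what == "block") "blocks" else "SNVs")
    } else {
      a
    }
    dplyr::bind_cols(tibble(ha1 = ha1_lab), as_tibble(cells))
  })
  bind_rows(rows)
}

#' The 12-metric table for all computed pairs
#'
#' @param x A `pairwise_set` from [compare_all()].
#' @return Tibble with `ha1_name`, `ha2_name` and the 12 metric columns.
#' @export
switch_metric_table <- function(x) {
  as_tibble(x)[c(
    "ha1_name", "ha2_name",
    "blk_w_0sw", "blk_w_NAsw", "blk_w_sw",
    "snv_in_blk_w_0sw", "snv_in_blk_w_NAsw", "snv_in_blk_w_sw",
    "snv_per_blk_w_0sw", "snv_per_blk_w_NAsw", "snv_per_blk_w_sw",
    "total_sw", "snv_by_sw", "sw_per_blk"
  )]
}
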