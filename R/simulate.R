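# Synthetic diploid phasing generator: ground-truth haplotypes plus
# tool-style corrupted derivations with a complete injection log. The log
# records, per site, the emitted block, the cumulative phase-flip state,
# and whether the site was dropped or left unphased — enough to predict
# every downstream comparison metric without running the comparison code.

#' Simulation configuration
#'
#' Defaults emulate the block-size landscape of short-read phasing output:
#' blocks of 2--10 sites heavily skewed towards 2--3 (geometric-decay
#' weights giving a mean near 3.5 SNVs/block), a small fraction of much
#' longer blocks, and mean inter-SNV spacing of ~900 bp (roughly one het
#' SNV per kilobase). Corruption rates default to a 1% per-gap switch
#' probability and a few percent of dropped or unphased sites — the order
#' of magnitude at which tools disagree on otherwise comparable output.
#'
#' @param n_sites Number of heterozygous sites to simulate (>= 2).
#' @param chromosome Chromosome label.
#' @param position_spacing Mean gap between adjacent sites, bp (geometric).
#' @param typical_block_range Inclusive size range of typical blocks.
#' @param typical_block_decay Geometric decay of size weights within the
#'   typical range (weight of size k is `decay^(k - min)`).
#' @param long_block_fraction Probability a block is drawn long instead.
#' @param long_block_size Mean size of long blocks (Poisson, floored at the
#'   top of the typical range + 1).
#' @param switch_prob Per-gap probability that phase flips from that site
#'   onward (classic switch-error model).
#' @param drop_site_prob Per-site probability of being absent from a
#'   derived output.
#' @param unphase_prob Per-site probability of being emitted unphased
#'   (`"-"`).
#' @param extra_block_break_prob Per-gap probability of an additional block
#'   split, so two derivations of the same truth have differing block
#'   boundaries.
#' @param seed Integer seed; every simulation output is a pure function of
#'   (config, seed).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_sites = 5000L,
                              chromosome = "chr10",
                              position_spacing = 900,
                              typical_block_range = c(2L, 10L),
                              typical_block_decay = 0.45,
                              long_block_fraction = 0.002,
                              long_block_size = 500L,
                              switch_prob = 0.01,
                              drop_site_prob = 0.02,
                              unphase_prob = 0.01,
                              extra_block_break_prob = 0.02,
                              seed = 1L) {
  cfg <- list(
    n_sites = as.integer(n_sites),
    chromosome = as.character(chromosome),
    position_spacing = as.numeric(position_spacing),
    typical_block_range = as.integer(typical_block_range),
    typical_block_decay = as.numeric(typical_block_decay),
    long_block_fraction = as.numeric(long_block_fraction),
    long_block_size = as.integer(long_block_size),
    switch_prob = as.numeric(switch_prob),
    drop_site_prob = as.numeric(drop_site_prob),
    unphase_prob = as.numeric(unphase_prob),
    extra_block_break_prob = as.numeric(extra_block_break_prob),
    seed = as.integer(seed)
  )
  probs <- c("switch_prob", "drop_site_prob", "unphase_prob",
             "extra_block_break_prob", "long_block_fraction")
  bad <- character()
  for (p in probs) {
    if (is.na(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) bad <- c(bad, p)
  }
  if (is.na(cfg$n_sites) || cfg$n_sites < 2L) bad <- c(bad, "n_sites")
  if (is.na(cfg$position_spacing) || cfg$position_spacing < 1) {
    bad <- c(bad, "position_spacing")
  }
  if (length(cfg$typical_block_range) != 2L ||
      cfg$typical_block_range[1] < 2L ||
      cfg$typical_block_range[2] < cfg$typical_block_range[1]) {
    bad <- c(bad, "typical_block_range")
  }
  if (is.na(cfg$seed)) bad <- c(bad, "seed")
  if (length(bad) > 0L) {
    hc_abort(
      paste0("invalid simulation config field(s): ", paste(bad, collapse = ", ")),
      "config_error"
    )
  }
  structure(cfg, class = "simulation_config")
}

#' Load a simulation configuration from a YAML file
#'
#' @param path YAML file whose keys are [simulation_config()] arguments.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    hc_abort(
      paste0("unknown simulation config field(s): ",
             paste(unknown, collapse = ", ")),
      "config_error"
    )
  }
  do.call(simulation_config, vals)
}

truth_id <- function(truth) {
  paste0("n", nrow(truth), "_p", sum(as.numeric(truth$position)),
         "_h", sum(truth$h1))
}

#' Simulate ground-truth diploid haplotypes
#'
#' Positions are strictly increasing with geometric gaps; the first
#' haplotype's alleles are i.i.d. uniform over {0, 1} and the second is the
#' complement (all sites heterozygous). Deterministic given
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A `truth_haplotypes` tibble with columns `position`, `h1`, `h2`.
#' @export
simulate_truth <- function(config) {
  if (!inherits(config, "simulation_config")) {
    hc_abort("`config` must be a simulation_config", "config_error")
  }
  with_rng_seed(config$seed, {
    gaps <- rgeom(config$n_sites, 1 / config$position_spacing) + 1L
    pos <- cumsum(gaps)
    h1 <- rbinom(config$n_sites, 1L, 0.5)
    out <- tibble(
      position = as.integer(pos),
      h1 = as.integer(h1),
      h2 = 1L - as.integer(h1)
    )
    new_tibble(out,
      nrow = nrow(out),
      chromosome = config$chromosome,
      truth_id = truth_id(out),
      class = "truth_haplotypes"
    )
  })
}

# Sample a block segmentation (vector of block indices, one per site).
sample_segmentation <- function(n_sites, config) {
  lo <- config$typical_block_range[1]
  hi <- config$typical_block_range[2]
  sizes_pool <- lo:hi
  weights <- config$typical_block_decay^(sizes_pool - lo)
  sizes <- integer()
  total <- 0L
  while (total < n_sites) {
    if (runif(1) < config$long_block_fraction) {
      s <- max(hi + 1L, stats::rpois(1, config$long_block_size))
    } else {
      s <- sample(sizes_pool, 1L, prob = weights)
    }
    sizes <- c(sizes, s)
    total <- total + s
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (total - n_sites)
  assignment <- rep(seq_along(sizes), times = sizes)
  # extra per-gap breaks so two derivations differ in boundaries
  if (config$extra_block_break_prob > 0 && n_sites > 1L) {
    same <- diff(assignment) == 0L
    brk <- same & runif(n_sites - 1L) < config$extra_block_break_prob
    assignment <- cumsum(c(1L, as.integer(diff(assignment) != 0L | brk)))
  }
  assignment
}

#' Derive a corrupted tool-style result from simulated truth
#'
#' Partitions the truth into phase blocks, then injects the corruption
#' modes real tools exhibit: per-gap phase switches that persist to the
#' block end (the classic switch-error model), dropped sites, unphased
#' (`"-"`) sites, and (via `extra_block_break_prob` and independent
#' segmentation sampling) block boundaries that differ between derivations
#' of the same truth. Every event is recorded in the injection log, from
#' which [expected_metrics()] predicts the full downstream comparison.
#'
#' @param truth A `truth_haplotypes` object from [simulate_truth()].
#' @param config A [simulation_config()].
#' @param tool_name Label for the derived result.
#' @param seed Seed for this derivation (default: config seed offset by a
#'   hash of `tool_name`, so different tools get different corruptions).
#' @param segmentation Optional precomputed block-index vector (one entry
#'   per truth site), e.g. another derivation's `log$block_index`, to force
#'   shared block boundaries.
#' @return List with elements `result` (a raw `phasing`; normalize before
#'   comparing) and `log` (an `injection_log` tibble with columns
#'   `position`, `block_index`, `block_id`, `flip`, `dropped`, `unphased`).
#' @export
derive_phasing <- function(truth, config, tool_name = "sim_tool",
                           seed = NULL, segmentation = NULL) {
  if (!inherits(truth, "truth_haplotypes")) {
    hc_abort("`truth` must come from simulate_truth()", "usage_error")
  }
  if (!inherits(config, "simulation_config")) {
    hc_abort("`config` must be a simulation_config", "config_error")
  }
  n <- nrow(truth)
  seed <- as.integer(
    seed %||%
      ((config$seed + sum(utf8ToInt(tool_name)) * 131L) %% .Machine$integer.max)
  )
  with_rng_seed(seed, {
    assignment <- segmentation %||% sample_segmentation(n, config)
    if (length(assignment) != n) {
      hc_abort("`segmentation` must have one entry per truth site",
               "usage_error")
    }
    new_block <- c(TRUE, diff(assignment) != 0L)
    orientation <- rbinom(max(assignment), 1L, 0.5)  # per-block relabeling
    sw <- rbinom(n, 1L, config$switch_prob)
    sw[new_block] <- 0L                              # switches act on gaps
    flip_cum <- stats::ave(sw, assignment, FUN = cumsum)
    flip <- (orientation[assignment] + flip_cum) %% 2L
    dropped <- runif(n) < config$drop_site_prob
    unphased <- !dropped & runif(n) < config$unphase_prob

    log <- new_tibble(
      tibble(
        position = truth$position,
        block_index = as.integer(assignment),
        block_id = sprintf("B%06d", assignment),
        flip = as.integer(flip),
        dropped = dropped,
        unphased = unphased
      ),
      nrow = n,
      truth_id = attr(truth, "truth_id"),
      tool_name = tool_name,
      class = "injection_log"
    )

    emit <- !dropped
    h1 <- ifelse(unphased[emit], NA_integer_,
                 as.integer(xor(truth$h1[emit] == 1L, flip[emit] == 1L)))
    result <- phasing(
      tibble(
        block_id = log$block_id[emit],
        position = truth$position[emit],
        h1 = h1,
        h2 = ifelse(is.na(h1), NA_integer_, 1L - h1)
      ),
      tool_name = tool_name,
      chromosome = attr(truth, "chromosome")
    )
    list(result = result, log = log)
  })
}

# Effective (emitted, phased) sites of a log, with blocks of >= 2 such
# sites — mirrors what normalization leaves of the derived result.
effective_log <- function(log) {
  eff <- log[!log$dropped & !log$unphased, , drop = FALSE]
  if (nrow(eff) > 0L) {
    keep <- names(which(table(eff$block_id) >= 2L))
    eff <- eff[eff$block_id %in% keep, , drop = FALSE]
  }
  eff
}

#' Predict comparison metrics from two injection logs
#'
#' Closed-form oracle for the whole pipeline: computes the block-comparison
#' outcome of two derivations *from their logs alone* — effective sites are
#' those neither dropped nor unphased, blocks with fewer than two survive
#' nowhere, pairing is by unique position overlap, and at a common site the
#' two derivations agree exactly when their cumulative flip states are
#' equal (the truth allele cancels). Never calls the comparison code, so
#' agreement between this prediction and the pipeline is an end-to-end
#' check of both.
#'
#' @param log_a,log_b `injection_log`s from [derive_phasing()] on the same
#'   truth (A plays HA1).
#' @return One-row tibble with the 12 [switch_metrics()] columns plus
#'   `disagree_blocks` and `disagree_snvs`.
#' @export
expected_metrics <- function(log_a, log_b) {
  if (!inherits(log_a, "injection_log") || !inherits(log_b, "injection_log")) {
    hc_abort("inputs must be injection_log objects", "usage_error")
  }
  if (!identical(attr(log_a, "truth_id"), attr(log_b, "truth_id"))) {
    hc_abort("injection logs come from different truths", "usage_error")
  }
  a <- effective_log(log_a)
  b <- effective_log(log_b)

  b_of_pos <- setNames(b$block_id, as.character(b$position))
  b_sizes <- table(b$block_id)
  b_flip <- setNames(b$flip, as.character(b$position))

  blocks <- split(seq_len(nrow(a)), a$block_id)
  cat <- character(length(blocks))
  n1 <- integer(length(blocks))
  sw_total <- 0L
  i <- 0L
  for (rows in blocks) {
    i <- i + 1L
    pos <- as.character(a$position[rows])
    n1[i] <- length(rows)
    hit <- unique(b_of_pos[pos])
    hit <- hit[!is.na(hit)]
    if (length(hit) != 1L ||
        sum(!is.na(b_of_pos[pos])) != n1[i] ||
        as.integer(b_sizes[hit]) != n1[i]) {
      cat[i] <- "na"
      next
    }
    agree <- a$flip[rows] == b_flip[pos]
    sw <- if (n1[i] < 2L) 0L else sum(agree[-1] != agree[-n1[i]])
    if (sw == 0L) cat[i] <- "zero" else {
      cat[i] <- "pos"
      sw_total <- sw_total + sw
    }
  }

  blk <- function(k) sum(cat == k)
  snv <- function(k) sum(n1[cat == k])
  per <- function(k) if (blk(k) > 0L) snv(k) / blk(k) else NA_real_
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
    total_sw = sw_total,
    snv_by_sw = if (sw_total > 0L) snv("pos") / sw_total else NA_real_,
    sw_per_blk = if (blk("pos") > 0L) sw_total / blk("pos") else NA_real_,
    disagree_blocks = blk("na") + blk("pos"),
    disagree_snvs = snv("na") + snv("pos")
  )
}

#' Write an injection log as tab-separated text
#'
#' @param log An `injection_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_injection_log <- function(log, path) {
  readr::write_tsv(as_tibble(log), path)
  invisible(path)
}
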